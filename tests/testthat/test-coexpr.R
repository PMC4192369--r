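# Guilt-by-association machinery: probe concordance, top-K correlate lists,
# intersection/overlap permutation tests, and the eQTL scan.

test_that("probe concordance recovers exactly the planted concordant probes", {
  ok <- vapply(1:30, function(s) {
    ex <- gen_expression(expr_sim_spec(probes_per_gene = 6,
      n_noise_probes = 11, module_r = 0.85, n_strains = 70, seed = s))
    got <- probe_concordance(ex$expr, ex$probes, ex$truth$focal_gene)
    setequal(got$probes, ex$truth$focal_concordant)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("probe concordance edge cases", {
  strains <- 20
  set.seed(1)
  base <- rnorm(strains)
  expr <- rbind(p1 = base, p2 = base, p3 = rnorm(strains))
  ann <- data.table::data.table(probe_id = c("p1", "p2", "p3"),
    gene_id = c("gA", "gA", "gB"))
  # identical probe rows: r = 1, both retained
  got <- probe_concordance(expr, ann, "gA")
  expect_setequal(got$probes, c("p1", "p2"))
  expect_equal(got$cor["p1", "p2"], 1)
  # single-probe gene returned flagged untestable
  single <- probe_concordance(expr, ann, "gB")
  expect_equal(single$probes, "p3")
  expect_true(single$untestable)
  expect_error(probe_concordance(expr, ann, "gC"), "no probes")
})

test_that("mutually independent probes yield a singleton concordant set", {
  sizes <- vapply(1:20, function(s) {
    set.seed(s)
    expr <- matrix(rnorm(8 * 70), 8, 70,
      dimnames = list(paste0("p", 1:8), NULL))
    ann <- data.table::data.table(probe_id = rownames(expr), gene_id = "g")
    length(probe_concordance(expr, ann, "g")$probes)
  }, numeric(1))
  expect_true(all(sizes == 1))
})

test_that("top-K correlate lists rank by signed r and exclude the focal probe", {
  ex <- gen_expression(expr_sim_spec(n_genes = 40, module_r = 0.9,
    module_genes = sprintf("gene%05d", 1:5), n_noise_probes = 0, seed = 3))
  focal <- ex$truth$focal_concordant[1]
  all_others <- top_k_correlates(ex$expr, focal, k = nrow(ex$expr) - 1)
  expect_equal(nrow(all_others), nrow(ex$expr) - 1)
  expect_false(focal %in% all_others$probe_id)
  expect_true(all(diff(all_others$r) <= 1e-12))
  # planted module members occupy the top ranks
  module_probes <- setdiff(ex$probes$probe_id[
    ex$probes$gene_id %in% ex$truth$module_genes], focal)
  top <- all_others$probe_id[seq_len(2 * length(module_probes))]
  expect_true(all(module_probes %in% top))
  expect_error(top_k_correlates(ex$expr, focal, k = nrow(ex$expr)), "k exceeds")
})

test_that("top-K ranking is invariant to positive affine transforms", {
  ex <- gen_expression(expr_sim_spec(n_genes = 20, seed = 5,
    module_genes = sprintf("gene%05d", 1:3)))
  focal <- ex$truth$focal_concordant[1]
  a <- top_k_correlates(ex$expr, focal, k = 10)
  ex$expr[focal, ] <- 3.7 * ex$expr[focal, ] + 11
  b <- top_k_correlates(ex$expr, focal, k = 10)
  expect_equal(a$probe_id, b$probe_id)
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("zero-variance probes are excluded from ranking", {
  set.seed(6)
  expr <- matrix(rnorm(5 * 30), 5, 30,
    dimnames = list(paste0("p", 1:5), NULL))
  expr[3, ] <- 2
  expect_message(out <- top_k_correlates(expr, "p1", k = 3), "zero-variance")
  expect_false("p3" %in% out$probe_id)
})

test_that("list intersection is exact and deduplicates genes", {
  ann <- data.table::data.table(probe_id = paste0("p", 1:6),
    gene_id = c("gA", "gA", "gB", "gC", "gD", "gE"))
  l1 <- c("p1", "p2", "p3", "p5")
  l2 <- c("p2", "p1", "p3", "p6")
  out <- intersect_lists(list(l1, l2), ann)
  expect_setequal(out$probes, c("p1", "p2", "p3"))
  expect_equal(out$genes, c("gA", "gB"))  # p1, p2 collapse to gA
  expect_equal(intersect_lists(list(l1, l1), ann)$probes, l1)
  expect_equal(length(intersect_lists(list(c("p1"), c("p4")))$probes), 0)
  expect_error(intersect_lists(list(l1)), "2")
})

test_that("sequential hypergeometric simulator matches brute-force sampling", {
  # total-variation distance on a small instance
  n_rep <- 1e5
  set.seed(31)
  brute <- brute_intersection_sizes(n_lists = 3, k = 5, N = 12, n_rep)
  seq_sizes <- with(list(), {
    set.seed(32)
    crossgene:::sim_intersection_sizes(3, 5, 12, n_rep)
  })
  tab_b <- tabulate(brute + 1, nbins = 6) / n_rep
  tab_s <- tabulate(seq_sizes + 1, nbins = 6) / n_rep
  expect_lt(sum(abs(tab_b - tab_s)) / 2, 0.02)
})

test_that("two-list intersection size matches the exact hypergeometric pmf", {
  set.seed(33)
  sizes <- crossgene:::sim_intersection_sizes(2, 3, 6, 1e5)
  obs <- tabulate(sizes + 1, nbins = 4)
  expected <- stats::dhyper(0:3, 3, 3, 3) * 1e5
  chi <- sum((obs - expected)^2 / expected)
  expect_lt(chi, stats::qchisq(0.999, df = 3))
})

test_that("multi-list overlap p-value contracts hold", {
  r <- multi_list_overlap_p(3, 10, 100, observed = 0, n_perm = 1000, seed = 1)
  expect_equal(r$p_emp, 1)
  expect_error(multi_list_overlap_p(2, 50, 10, 5), "exceed")
  a <- multi_list_overlap_p(3, 10, 100, 3, n_perm = 2000, seed = 2)
  b <- multi_list_overlap_p(3, 10, 100, 3, n_perm = 2000, seed = 2)
  expect_identical(a$p_emp, b$p_emp)
})

test_that("two-set overlap p converges to the exact hypergeometric tail", {
  nA <- 40; nB <- 30; N <- 200; obs <- 12
  r <- two_set_overlap_p(nA, nB, N, obs, n_perm = 2e5, seed = 3)
  se <- sqrt(r$exact_p * (1 - r$exact_p) / 2e5)
  expect_lt(abs(r$p_emp - r$exact_p), 3 * se + 1 / 2e5)
  # observed at the expectation gives an exact tail near 0.5 (sizes large
  # enough that discreteness of the overlap count is negligible)
  r2 <- two_set_overlap_p(900, 800, 4000, round(900 * 800 / 4000),
    n_perm = 1000, seed = 4)
  expect_lt(abs(r2$exact_p - 0.5), 0.05)
  # nA = N forces the overlap to equal nB
  r3 <- two_set_overlap_p(N, nB, N, observed = nB, n_perm = 1000, seed = 5)
  expect_equal(r3$p_emp, 1)
  expect_equal(r3$exact_p, 1)
})

test_that("eQTL scan classifies a cis-driven trait as cis", {
  cls <- vapply(1:20, function(s) {
    cr <- gen_cross(cross_sim_spec(seed = s))
    mk <- cr$markers[cr$markers$chrom == cr$truth$chrom]
    drv <- mk$marker_id[which.min(abs(mk$pos_bp - cr$truth$pos_bp))]
    set.seed(s + 500)
    trait <- cr$geno[, drv] + rnorm(nrow(cr$geno), 0, 0.4)
    gl <- cr$genes[cr$genes$gene_id == cr$truth$planted_gene]
    eqtl_scan(trait, cr$geno, cr$markers, gl, n_perm = 100,
      seed = s)$classification
  }, character(1))
  expect_gte(mean(cls == "cis"), 0.9)
})

test_that("eQTL scan calls a pure-noise trait none at the calibrated rate", {
  cls <- vapply(1:40, function(s) {
    cr <- gen_cross(cross_sim_spec(n_chrom = 3, markers_per_chrom = 15,
      qtl_marker = 5, seed = s))
    set.seed(s + 900)
    trait <- rnorm(nrow(cr$geno))
    gl <- cr$genes[cr$genes$gene_id == cr$truth$planted_gene]
    eqtl_scan(trait, cr$geno, cr$markers, gl, n_perm = 100,
      seed = s)$classification
  }, character(1))
  rate <- mean(cls != "none")
  se <- sqrt(0.05 * 0.95 / 40)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("a trait driven from another chromosome is classified trans", {
  cr <- gen_cross(cross_sim_spec(seed = 77))
  other <- cr$markers[cr$markers$chrom != cr$truth$chrom]$marker_id[5]
  set.seed(78)
  trait <- cr$geno[, other] + rnorm(nrow(cr$geno), 0, 0.3)
  gl <- cr$genes[cr$genes$gene_id == cr$truth$planted_gene]
  out <- eqtl_scan(trait, cr$geno, cr$markers, gl, n_perm = 100, seed = 79)
  expect_equal(out$classification, "trans")
})
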