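# The generators must be seed-deterministic, calibrated under null
# configurations, and carry truth records sufficient to score recovery.

test_that("generators are seed-deterministic", {
  a <- gen_cross(cross_sim_spec(seed = 11))
  b <- gen_cross(cross_sim_spec(seed = 11))
  expect_identical(a$geno, b$geno)
  expect_identical(a$markers, b$markers)
  expect_identical(a$genes, b$genes)
  gh <- gen_genes(50, prefix = "hgene", seed = 2)
  g1 <- gen_gwas(gwas_sim_spec(n_individuals = 100, causal_gene = gh$gene_id[1],
    seed = 5), gh)
  g2 <- gen_gwas(gwas_sim_spec(n_individuals = 100, causal_gene = gh$gene_id[1],
    seed = 5), gh)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$snps, g2$snps)
  e1 <- gen_expression(expr_sim_spec(seed = 3))
  e2 <- gen_expression(expr_sim_spec(seed = 3))
  expect_identical(e1$expr, e2$expr)
})

test_that("null cross gives uniform marker p-values across replicates", {
  p <- vapply(1:500, function(s) {
    gen_cross(cross_sim_spec(n_chrom = 1, markers_per_chrom = 4,
      qtl_marker = 2, qtl_effect = 0, genes_per_chrom = 1,
      seed = s))$markers$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a strong planted QTL attains the chromosome's minimum p", {
  # recovery study: a loosely linked map (recomb 0.25 between adjacent
  # markers) so the scan can resolve the causal marker; ties attain the min
  hits <- vapply(1:200, function(s) {
    cr <- gen_cross(cross_sim_spec(n_strains = 37, n_chrom = 2,
      markers_per_chrom = 20, recomb_prob = 0.25, qtl_marker = 10,
      qtl_effect = 2, noise_sd = 1, seed = s))
    chr <- cr$markers[cr$markers$chrom == cr$truth$chrom]
    chr$p[chr$marker_id == cr$truth$qtl_marker] <= min(chr$p)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("zero recombination makes all markers on a chromosome identical", {
  cr <- gen_cross(cross_sim_spec(n_chrom = 2, markers_per_chrom = 10,
    recomb_prob = 0, qtl_marker = 3, seed = 4))
  for (chr in unique(cr$markers$chrom)) {
    expect_equal(length(unique(cr$markers[cr$markers$chrom == chr]$p)), 1)
  }
})

test_that("cross spec validates its invariants", {
  expect_error(cross_sim_spec(n_strains = 2), "n_strains")
  expect_error(cross_sim_spec(recomb_prob = 0.7), "recomb_prob")
  expect_error(cross_sim_spec(qtl_marker = 10000), "qtl_marker")
})

test_that("GWAS dosage correlation within blocks tracks the target", {
  gh <- gen_genes(40, prefix = "hgene", seed = 1)
  for (r in c(0.3, 0.6)) {
    gw <- gen_gwas(gwas_sim_spec(n_individuals = 800, n_blocks = 5,
      snps_per_block = 8, within_block_r = r, causal_gene = gh$gene_id[1],
      causal_beta = 0, seed = 7), gh)
    for (b in 1:5) {
      cc <- stats::cor(gw$panel[, (b - 1) * 8 + 1:8])
      expect_lt(abs(mean(cc[upper.tri(cc)]) - r), 0.15)
    }
  }
})

test_that("zero within-block correlation gives independent SNPs", {
  gh <- gen_genes(40, prefix = "hgene", seed = 1)
  gw <- gen_gwas(gwas_sim_spec(n_individuals = 1000, n_blocks = 4,
    snps_per_block = 10, within_block_r = 0, causal_gene = gh$gene_id[1],
    causal_beta = 0, seed = 2), gh)
  cc <- stats::cor(gw$panel[, 1:10])
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.05)
})

test_that("null GWAS p-values are uniform across replicates", {
  gh <- gen_genes(30, prefix = "hgene", seed = 9)
  p <- vapply(1:300, function(s) {
    gen_gwas(gwas_sim_spec(n_individuals = 200, n_blocks = 2,
      snps_per_block = 3, causal_gene = gh$gene_id[1], causal_beta = 0,
      seed = s), gh)$snps$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("gen_gwas rejects an unknown causal gene", {
  gh <- gen_genes(10, prefix = "hgene", seed = 1)
  expect_error(gen_gwas(gwas_sim_spec(causal_gene = "nope", seed = 1), gh),
    "causal_gene")
})

test_that("homology map coverage, bijection and forced pairs", {
  gh <- gen_genes(1000, prefix = "hgene", seed = 1)
  gm <- gen_genes(1200, prefix = "mgene", seed = 2)
  full <- gen_homology(gh, gm, coverage = 1, seed = 3)
  expect_setequal(full$human_gene_id, gh$gene_id)
  part <- gen_homology(gh, gm, coverage = 0.883, seed = 3)
  expect_equal(nrow(part), 883)
  expect_equal(anyDuplicated(part$mouse_gene_id), 0)
  expect_equal(anyDuplicated(part$human_gene_id), 0)
  forced <- gen_homology(gh, gm, coverage = 0.1, seed = 4,
    force_pairs = data.frame(human_gene_id = "hgene00007",
      mouse_gene_id = "mgene00003"))
  expect_true(any(forced$human_gene_id == "hgene00007" &
    forced$mouse_gene_id == "mgene00003"))
  expect_error(gen_homology(gh, gm, coverage = 0), "coverage")
  expect_error(gen_homology(gh, gm, coverage = 1.2), "coverage")
})

test_that("expression generator reproduces the multi-probe focal structure", {
  # 6 concordant + 11 non-concordant probes = 17 probes for the focal gene
  ex <- gen_expression(expr_sim_spec(probes_per_gene = 6,
    n_noise_probes = 11, seed = 2))
  focal <- ex$truth$focal_gene
  expect_equal(sum(ex$probes$gene_id == focal), 17)
  expect_equal(length(ex$truth$focal_concordant), 6)
  expect_equal(sum(ex$probes$gene_id == focal &
    ex$probes$target_class == "intron"), 11)
})

test_that("planted module probes pairwise-correlate near the target", {
  ex <- gen_expression(expr_sim_spec(module_r = 0.9, n_strains = 70,
    seed = 4))
  ids <- ex$probes$probe_id[ex$probes$gene_id %in% ex$truth$module_genes &
    ex$probes$target_class != "intron"]
  cc <- stats::cor(t(ex$expr[ids, ]))
  expect_gte(mean(cc[upper.tri(cc)] >= 0.5), 0.95)
})

test_that("expression rows are standardized and spec validates", {
  ex <- gen_expression(expr_sim_spec(n_genes = 10, seed = 1,
    module_genes = sprintf("gene%05d", 1:2)))
  expect_equal(unname(rowMeans(ex$expr)), rep(0, nrow(ex$expr)),
    tolerance = 1e-12)
  expect_equal(unname(apply(ex$expr, 1, sd)), rep(1, nrow(ex$expr)),
    tolerance = 1e-12)
  expect_error(expr_sim_spec(n_strains = 3), "n_strains")
  expect_error(expr_sim_spec(module_r = 1.2), "module_r")
})
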