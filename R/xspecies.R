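# Cross-species concordance: homolog joining, genomic-control lambda with a
# permutation null, rank-rank hypergeometric overlap (RRHO), and
# Bonferroni-corrected single-gene overlap.

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1, lower.tail = FALSE)  # 0.4549364

#' Join human and mouse gene p-value tables through a homology map
#'
#' Rows are kept only for mapped pairs present in both tables. Many-to-many
#' mappings are resolved before the join by keeping, for each duplicated
#' human or mouse id, the pair whose human p-value is smallest (remaining
#' duplicates dropped with a message). Counts are attached as the
#' `"counts"` attribute: n_human_total, n_mapped, coverage.
#'
#' @param human human gene p table (gene_id, p).
#' @param mouse mouse gene p table (gene_id, p).
#' @param map homology map (human_gene_id, mouse_gene_id).
#' @return data.table: human_gene_id, mouse_gene_id, p_human, p_mouse.
#' @export
join_homologs <- function(human, mouse, map) {
  m <- data.table::as.data.table(map)
  m <- merge(m,
    data.table::data.table(human_gene_id = human$gene_id, p_human = human$p),
    by = "human_gene_id")
  m <- merge(m,
    data.table::data.table(mouse_gene_id = mouse$gene_id, p_mouse = mouse$p),
    by = "mouse_gene_id")
  data.table::setorder(m, p_human, human_gene_id)
  dup <- duplicated(m$human_gene_id) | duplicated(m$mouse_gene_id)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate homology pair(s), keeping the ",
      "smallest human p per id")
    m <- m[!dup]
  }
  if (nrow(m) == 0) {
    stop("homology join produced an empty table", call. = FALSE)
  }
  data.table::setcolorder(m, c("human_gene_id", "mouse_gene_id",
    "p_human", "p_mouse"))
  data.table::setorder(m, human_gene_id)
  attr(m, "counts") <- list(n_human_total = nrow(human), n_mapped = nrow(m),
    coverage = nrow(m) / nrow(human))
  m
}

#' Genomic-control lambda
#'
#' The median-based inflation factor of Devlin-Roeder genomic control:
#' p-values are converted to upper-tail 1-df chi-squared quantiles and the
#' median is divided by the null median (`qchisq(0.5, 1, lower = FALSE)`,
#' about 0.45494). Lambda near 1 indicates no inflation; above 1, the set's
#' p-values are smaller than chance.
#'
#' @param p_values p-values in `(0, 1]`.
#' @return lambda (positive scalar).
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  check_prob(p_values, "p")
  stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    CHISQ1_MEDIAN
}

#' Permutation test for the lambda of a gene set
#'
#' Computes lambda over the human p-values of `test_set`, then draws
#' `n_perm` random gene sets of the same size (without replacement) from the
#' joined table and recomputes lambda. The default estimator follows the
#' classical permutation rule, `p_perm = #\{lambda_rand > lambda_obs\} /
#' n_perm` (strict inequality); `estimator = "plus_one"` uses the
#' `(r + 1) / (n + 1)` variant, which is conservative and bounded away
#' from 0.
#'
#' @param joined output of [join_homologs()].
#' @param test_set human gene ids (subset of the joined table; >= 2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param estimator `"strict"` (default) or `"plus_one"`.
#' @return A list: lambda_obs, n_set, n_perm, p_perm, seed.
#' @export
lambda_perm_test <- function(joined, test_set, n_perm = 1e5, seed = 1L,
                             estimator = c("strict", "plus_one")) {
  estimator <- match.arg(estimator)
  if (length(test_set) < 2) stop("test_set must contain >= 2 genes",
    call. = FALSE)
  if (!all(test_set %in% joined$human_gene_id)) {
    stop("test_set contains genes absent from the joined table", call. = FALSE)
  }
  chisq <- stats::qchisq(joined$p_human, df = 1, lower.tail = FALSE)
  names(chisq) <- joined$human_gene_id
  lambda_obs <- stats::median(chisq[test_set]) / CHISQ1_MEDIAN
  k <- length(test_set)
  n <- length(chisq)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      lam <- stats::median(chisq[sample.int(n, k)]) / CHISQ1_MEDIAN
      if (lam > lambda_obs) exceed <- exceed + 1L
    }
    p_perm <- if (estimator == "strict") exceed / n_perm else
      (exceed + 1) / (n_perm + 1)
    list(lambda_obs = lambda_obs, n_set = k, n_perm = n_perm, p_perm = p_perm,
      seed = seed)
  })
}

#' Rank-rank hypergeometric overlap test
#'
#' Both lists are ranked ascending by p-value (most significant first; ties
#' broken by gene id for determinism). Over a grid of rank-threshold pairs
#' `(i*step, j*step)` the upper-tail hypergeometric p of the overlap between
#' the top `i*step` of list A and the top `j*step` of list B in a universe of
#' size N is computed; the peak of the `-log10(p)` map is the observed
#' statistic. Family-wise significance comes from permutations that shuffle
#' list B's ranks while holding A fixed (exchangeability under the null of no
#' rank association): `p_fwer = (#\{max_perm >= max_obs\} + 1) / (n_perm + 1)`.
#'
#' @param scores_a,scores_b named p-value vectors over the same gene universe
#'   (no missing values).
#' @param step rank step size (default `max(1, floor(N / 100))`).
#' @param n_perm permutations for the familywise p.
#' @param seed integer seed.
#' @return A list: step, logp_map (matrix, thresholds on A as rows),
#'   max_logp, p_fwer, n_perm, seed.
#' @export
rrho_test <- function(scores_a, scores_b, step = NULL, n_perm = 200L,
                      seed = 1L) {
  genes <- names(scores_a)
  if (is.null(genes) || !setequal(genes, names(scores_b))) {
    stop("scores must be named vectors over the same gene universe",
      call. = FALSE)
  }
  if (anyNA(scores_a) || anyNA(scores_b)) {
    stop("missing values not allowed", call. = FALSE)
  }
  scores_b <- scores_b[genes]
  N <- length(genes)
  if (is.null(step)) step <- max(1L, floor(N / 100))
  if (step >= N) stop("step must be smaller than the universe size",
    call. = FALSE)
  grid <- seq.int(step, N, by = step)
  rank_a <- order(order(scores_a, genes))  # 1 = smallest p, ties by gene id
  rank_b <- order(order(scores_b, genes))

  max_map <- function(rb, return_map = FALSE) {
    ord_b <- order(rb)           # genes by ascending B rank
    ra_by_b <- rank_a[ord_b]
    lp <- matrix(0, length(grid), length(grid))
    for (ii in seq_along(grid)) {
      ov <- cumsum(ra_by_b <= grid[ii])[grid]
      lp[ii, ] <- -stats::phyper(ov - 1, grid[ii], N - grid[ii], grid,
        lower.tail = FALSE, log.p = TRUE) / log(10)
    }
    if (return_map) lp else max(lp)
  }
  lp_obs <- max_map(rank_b, return_map = TRUE)
  dimnames(lp_obs) <- list(paste0("a", grid), paste0("b", grid))
  max_obs <- max(lp_obs)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (max_map(sample.int(N)) >= max_obs) exceed <- exceed + 1L
    }
    list(step = step, logp_map = lp_obs, max_logp = max_obs,
      p_fwer = (exceed + 1) / (n_perm + 1), n_perm = n_perm, seed = seed)
  })
}

#' Bonferroni-corrected single-gene overlap
#'
#' Tests each mouse-significant gene's human homologue at the
#' Bonferroni-corrected level `alpha / n_set` (the number of genes compared).
#'
#' @param mouse_sig mouse gene ids declared significant.
#' @param joined output of [join_homologs()].
#' @param alpha familywise level.
#' @return A list: threshold, n_tested, hits (data.table of mapped pairs with
#'   `p_human <= threshold`, sorted by p).
#' @export
bonferroni_overlap <- function(mouse_sig, joined, alpha = 0.05) {
  if (length(mouse_sig) == 0) stop("mouse_sig is empty", call. = FALSE)
  threshold <- alpha / length(mouse_sig)
  tested <- joined[joined$mouse_gene_id %in% mouse_sig]
  hits <- tested[tested$p_human <= threshold]
  data.table::setorder(hits, p_human, human_gene_id)
  list(threshold = threshold, n_tested = nrow(tested), hits = hits[])
}

#' Expected-vs-observed quantiles for a QQ plot
#'
#' @param p_values p-values.
#' @return data.table with `expected` and `observed` -log10 quantiles.
#' @export
qq_table <- function(p_values) {
  n <- length(p_values)
  data.table::data.table(expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(p_values)))
}
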