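# Internal helpers: seeding, fast marker scans, small validators.

#' Derive a per-stage random seed from a global seed
#'
#' Every stage of the pipeline draws its randomness from a substream keyed by
#' the stage name, so a stage can be rerun in isolation and reproduce exactly
#' what it did inside a full run.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"simulate/cross"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  codes <- utf8ToInt(as.character(stage))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Run expr with a local RNG state; restores the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Welch two-sample t-test p-values for a quantitative trait against every
# column of a 0/1 genotype matrix, vectorized over markers. Monomorphic
# columns get p = 1 (flagged via the "monomorphic" attribute).
welch_scan <- function(geno, trait) {
  stopifnot(nrow(geno) == length(trait))
  n1 <- colSums(geno == 1)
  n0 <- nrow(geno) - n1
  mono <- n1 == 0 | n0 == 0 | n1 == 1 & n0 == 1
  sum1 <- colSums(geno * trait)
  m1 <- sum1 / n1
  m0 <- (sum(trait) - sum1) / n0
  # group variances via sums of squares
  sumsq1 <- colSums(geno * trait^2)
  v1 <- (sumsq1 - n1 * m1^2) / pmax(n1 - 1, 1)
  v0 <- ((sum(trait^2) - sumsq1) - n0 * m0^2) / pmax(n0 - 1, 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / (pmax(v1 / n1, .Machine$double.xmin)^2 / pmax(n1 - 1, 1) +
    pmax(v0 / n0, .Machine$double.xmin)^2 / pmax(n0 - 1, 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[mono | !is.finite(p)] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  attr(p, "monomorphic") <- mono
  attr(p, "stat") <- ifelse(mono, 0, tstat)
  p
}

check_prob <- function(x, name, open_left = TRUE) {
  bad <- !is.finite(x) | x > 1 | (if (open_left) x <= 0 else x < 0)
  if (any(bad)) {
    stop(sprintf("%s must lie in %s: offending value %g", name,
      if (open_left) "(0, 1]" else "[0, 1]", x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}
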