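# Shared fixture builders (all generated in code; nothing on disk).

tiny_markers <- function() {
  data.table::data.table(
    chrom = c("1", "1", "1", "2", "2"),
    pos_bp = c(100, 300, 500, 100, 200),
    marker_id = paste0("m", 1:5),
    p = c(0.02, 0.04, 0.10, 0.20, 0.50))
}

tiny_genes <- function(start_bp, chrom = "1", len = 10) {
  data.table::data.table(
    gene_id = sprintf("g%02d", seq_along(start_bp)),
    chrom = rep(chrom, length.out = length(start_bp)),
    start_bp = start_bp, end_bp = start_bp + len)
}

# brute-force intersection of n random k-subsets of [N]
brute_intersection_sizes <- function(n_lists, k, N, n_rep) {
  vapply(seq_len(n_rep), function(i) {
    length(Reduce(intersect,
      lapply(seq_len(n_lists), function(j) sample.int(N, k))))
  }, integer(1))
}

# upper-tail 1-df chi-squared quantile via the normal quantile: a 1-df
# chi-squared variable is Z^2, so Q(p) = qnorm(p / 2)^2 -- independent of
# qchisq, used as the oracle for the gene statistic and lambda
chisq1_quantile_oracle <- function(p) qnorm(p / 2)^2
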