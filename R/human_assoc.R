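# Gene-based association testing: SNP-to-gene assignment, the
# sum-of-chi-squared gene statistic, and an empirical p-value simulated under
# the LD correlation structure of a reference panel (VEGAS-style).

#' Assign SNPs to genes within a flanking window
#'
#' A SNP is assigned to every gene whose interval, extended by `window_bp` on
#' each side, covers the SNP's position (a SNP may belong to several
#' overlapping genes). Genes with no assigned SNP are reported with
#' `n_snps = 0`; downstream testing skips them.
#'
#' @param snps SNP table: snp_id, chrom, pos_bp.
#' @param genes gene table: gene_id, chrom, start_bp, end_bp.
#' @param window_bp flanking window, bp (default 50 kb).
#' @return data.table: gene_id, n_snps, snp_ids (list column of SNP ids
#'   ordered by position).
#' @export
assign_snps_to_genes <- function(snps, genes, window_bp = 50000) {
  stopifnot(window_bp >= 0)
  s <- data.table::as.data.table(snps)
  assign_one <- function(chr, lo, hi) {
    sel <- s$chrom == chr & s$pos_bp >= lo & s$pos_bp <= hi
    s$snp_id[sel][order(s$pos_bp[sel])]
  }
  ids <- mapply(assign_one, genes$chrom, genes$start_bp - window_bp,
    genes$end_bp + window_bp, SIMPLIFY = FALSE)
  data.table::data.table(gene_id = genes$gene_id,
    n_snps = lengths(ids), snp_ids = unname(ids))
}

#' Sum-of-chi-squared gene statistic
#'
#' Converts each SNP p-value to its upper-tail 1-df chi-squared quantile and
#' sums: `T = sum_i Q(p_i)`. Under SNP independence the null distribution of
#' `T` is chi-squared with n df; LD is handled by [gene_empirical_p()].
#'
#' @param p_values SNP p-values in `(0, 1]`. A p of 0 is an error (the
#'   statistic would be infinite); floor p-values first, e.g. at 1e-300.
#' @return The observed statistic `T_obs`.
#' @export
gene_statistic <- function(p_values) {
  if (any(p_values <= 0)) {
    stop("p = 0 gives an infinite statistic; floor p-values first",
      call. = FALSE)
  }
  check_prob(p_values, "SNP p")
  sum(stats::qchisq(p_values, df = 1, lower.tail = FALSE))
}

#' SNP-SNP correlation from a reference panel, repaired to PSD
#'
#' Computes the Pearson correlation of dosage columns, dropping monomorphic
#' SNPs (recorded in the `"dropped"` attribute, with a warning), then repairs
#' the matrix to positive semi-definiteness by clipping eigenvalues at a
#' small floor and renormalizing to unit diagonal — sample correlation from
#' finite panels can be indefinite after SNP filtering.
#'
#' @param panel individuals x SNP dosage matrix with SNP ids as column names.
#' @param snp_ids SNPs to use (must be columns of `panel`).
#' @param eig_floor eigenvalue floor for the PSD repair.
#' @return Correlation matrix over the retained SNPs; attribute `"dropped"`
#'   lists monomorphic SNPs removed.
#' @export
ld_correlation <- function(panel, snp_ids, eig_floor = 1e-8) {
  if (nrow(panel) < 2) stop("need >= 2 individuals", call. = FALSE)
  miss <- setdiff(snp_ids, colnames(panel))
  if (length(miss)) {
    stop("SNPs absent from panel: ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  x <- panel[, snp_ids, drop = FALSE]
  mono <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) removed from LD panel: ",
      paste(snp_ids[mono], collapse = ", "))
    x <- x[, !mono, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no polymorphic SNPs left", call. = FALSE)
  cc <- stats::cor(x)
  e <- eigen(cc, symmetric = TRUE)
  if (min(e$values) < eig_floor) {
    v <- pmax(e$values, eig_floor)
    cc <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(cc))
    cc <- cc / tcrossprod(d)
  }
  dimnames(cc) <- list(colnames(x), colnames(x))
  attr(cc, "dropped") <- snp_ids[mono]
  cc
}

#' Empirical gene-based p-value under the LD null
#'
#' Draws multivariate normal vectors `z ~ MVN(0, corr)`, forms the null
#' statistic `T_sim = sum(z^2)`, and estimates
#' `p_emp = (#\{T_sim >= T_obs\} + 1) / (n_sims + 1)`. Ties count against
#' rejection and the +1 correction keeps the estimate in `(0, 1]`. With
#' `staged = TRUE`, simulation proceeds through `stages`, escalating only
#' while the running `p_emp` is below `10 / n_total` (too few exceedances to
#' trust the estimate); clearly non-significant genes stop cheap.
#'
#' @param T_obs observed statistic.
#' @param corr SNP correlation matrix (PSD; see [ld_correlation()]).
#' @param n_sims simulations for the non-staged mode (>= 100).
#' @param seed integer seed.
#' @param staged use the escalating schedule instead of a flat `n_sims`.
#' @param stages simulation counts per stage.
#' @return A list: gene_id (NA here; filled by callers), n_snps, T_obs,
#'   n_sims (simulations actually used), p_emp, stage label.
#' @export
gene_empirical_p <- function(T_obs, corr, n_sims = 1e4, seed = 1L,
                             staged = FALSE, stages = c(1e3, 1e4, 1e6)) {
  stopifnot(T_obs >= 0)
  corr <- as.matrix(corr)
  if (!staged && n_sims < 100) stop("n_sims must be >= 100", call. = FALSE)
  R <- tryCatch(chol(corr), error = function(e) {
    e <- eigen(corr, symmetric = TRUE)
    t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(corr)))
  })
  m <- ncol(corr)
  sim_count <- function(ns) {
    exceed <- 0
    done <- 0
    while (done < ns) {
      chunk <- min(ns - done, 1e5)
      z <- matrix(stats::rnorm(chunk * m), chunk, m) %*% R
      exceed <- exceed + sum(rowSums(z * z) >= T_obs)
      done <- done + chunk
    }
    exceed
  }
  with_seed(seed, {
    if (!staged) {
      exceed <- sim_count(n_sims)
      return(list(n_snps = m, T_obs = T_obs, n_sims = n_sims,
        p_emp = (exceed + 1) / (n_sims + 1), stage = "flat"))
    }
    total <- 0; exceed <- 0
    for (k in seq_along(stages)) {
      exceed <- exceed + sim_count(stages[k] - total)
      total <- stages[k]
      p_emp <- (exceed + 1) / (total + 1)
      if (p_emp >= 10 / total || k == length(stages)) {
        return(list(n_snps = m, T_obs = T_obs, n_sims = total,
          p_emp = p_emp, stage = paste0("stage", k)))
      }
    }
  })
}

#' Gene-based association test over a SNP summary table
#'
#' The driver: assigns SNPs to genes, computes the sum-of-chi-squared
#' statistic per gene, and simulates each gene's empirical p-value under the
#' LD structure estimated from `panel`. Genes without SNPs are returned with
#' `n_snps = 0` and `p_emp = NA`.
#'
#' @param snps SNP table: snp_id, chrom, pos_bp, p.
#' @param genes gene table.
#' @param panel reference dosage matrix (columns named by snp_id).
#' @param window_bp SNP assignment window (default 50 kb).
#' @param n_sims simulations per gene (flat mode) or final-stage budget.
#' @param seed integer seed; each gene gets a substream keyed by its id.
#' @param staged escalate simulations per [gene_empirical_p()].
#' @param p_floor floor applied to SNP p-values before the chi-squared
#'   transform.
#' @param stages stage schedule for `staged = TRUE`.
#' @return data.table: gene_id, n_snps, T_obs, n_sims, p_emp, stage.
#' @export
gene_based_test <- function(snps, genes, panel, window_bp = 50000,
                            n_sims = 1e4, seed = 1L, staged = FALSE,
                            p_floor = 1e-300, stages = c(1e3, 1e4, n_sims)) {
  asn <- assign_snps_to_genes(snps, genes, window_bp)
  pmap <- stats::setNames(pmax(snps$p, p_floor), snps$snp_id)
  res <- vector("list", nrow(asn))
  for (i in seq_len(nrow(asn))) {
    ids <- asn$snp_ids[[i]]
    if (length(ids) == 0) {
      res[[i]] <- data.table::data.table(gene_id = asn$gene_id[i], n_snps = 0L,
        T_obs = NA_real_, n_sims = 0L, p_emp = NA_real_, stage = NA_character_)
      next
    }
    cc <- suppressWarnings(ld_correlation(panel, ids))
    kept <- setdiff(ids, attr(cc, "dropped"))
    T_obs <- gene_statistic(unname(pmap[kept]))
    r <- gene_empirical_p(T_obs, cc,
      n_sims = n_sims, seed = substream_seed(seed, asn$gene_id[i]),
      staged = staged, stages = stages)
    res[[i]] <- data.table::data.table(gene_id = asn$gene_id[i],
      n_snps = r$n_snps, T_obs = r$T_obs, n_sims = r$n_sims, p_emp = r$p_emp,
      stage = r$stage)
  }
  data.table::rbindlist(res)
}
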