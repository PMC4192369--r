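# Guilt-by-association machinery: probe concordance filtering, top-K
# correlate lists, multi-list intersection and two-universe overlap with
# permutation significance, and a minimal eQTL scan with cis/trans
# classification.

# intersection sizes of n_lists random k-subsets of [N] by sequential
# conditional hypergeometric draws (uses the caller's RNG state)
sim_intersection_sizes <- function(n_lists, k, N, n_perm) {
  isz <- rep(k, n_perm)
  for (j in seq_len(n_lists - 1)) {
    isz <- stats::rhyper(n_perm, m = isz, n = N - isz, k = k)
  }
  isz
}

# two-sided p for a Pearson correlation via the t transform, n - 2 df
cor_test_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, n - 2)
}

#' Concordant probe set for a gene
#'
#' From all probes annotated to `gene_id`, finds the largest mutually
#' concordant set: every retained probe must correlate with every other
#' retained probe at Pearson `r >= r_min` with correlation-test `p <= p_max`
#' (t transform, n - 2 df, two-sided). The set is a maximal clique of the
#' pairwise concordance graph, greedily grown from the highest-degree probe
#' (ties by probe id). A single-probe gene is returned as-is, flagged
#' untestable.
#'
#' @param expr probes x strains matrix, rownames = probe ids.
#' @param probes probe annotation (probe_id, gene_id).
#' @param gene_id focal gene.
#' @param r_min,p_max concordance thresholds.
#' @return A list: probes (retained probe ids), untestable (flag), cor
#'   (full pairwise correlation matrix of the gene's probes), p (matrix of
#'   correlation-test p-values).
#' @export
probe_concordance <- function(expr, probes, gene_id, r_min = 0.5,
                              p_max = 0.05) {
  ids <- sort(probes$probe_id[probes$gene_id == gene_id])
  if (length(ids) == 0) stop("gene ", gene_id, " has no probes", call. = FALSE)
  if (length(ids) == 1) {
    return(list(probes = ids, untestable = TRUE, cor = matrix(1, 1, 1,
      dimnames = list(ids, ids)), p = matrix(0, 1, 1,
      dimnames = list(ids, ids))))
  }
  n <- ncol(expr)
  cc <- stats::cor(t(expr[ids, , drop = FALSE]))
  pp <- cor_test_p(cc, n)
  diag(pp) <- 0
  adj <- cc >= r_min & pp <= p_max
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  # greedy maximal clique from the highest-degree probe, ties by probe id
  seed_probe <- ids[order(-deg, ids)][1]
  clique <- seed_probe
  candidates <- ids[adj[seed_probe, ]]
  while (length(candidates)) {
    candidates <- candidates[order(-deg[candidates], candidates)]
    nxt <- candidates[1]
    clique <- c(clique, nxt)
    candidates <- setdiff(candidates, nxt)
    candidates <- candidates[adj[nxt, candidates]]
  }
  clique <- sort(clique)
  list(probes = clique, untestable = length(ids) == 1, cor = cc, p = pp)
}

#' Top-K correlates of a probe across the whole array
#'
#' Ranks every other probe by signed Pearson correlation with the focal
#' probe, descending (coexpression implies positive association; set
#' `absolute = TRUE` to rank by |r|). Ties are broken by probe id; the focal
#' probe and zero-variance probes are excluded (the latter with a message).
#'
#' @param expr probes x strains matrix.
#' @param probe_id focal probe.
#' @param k list length (`k <= nrow(expr) - 1`).
#' @param absolute rank by absolute correlation instead.
#' @return data.table: probe_id, r — the top k correlates in rank order.
#' @export
top_k_correlates <- function(expr, probe_id, k = 20000, absolute = FALSE) {
  stopifnot(probe_id %in% rownames(expr))
  others <- setdiff(rownames(expr), probe_id)
  if (k > length(others)) stop("k exceeds the number of other probes",
    call. = FALSE)
  sds <- apply(expr[others, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " zero-variance probe(s) from ranking")
    others <- others[sds > 0]
  }
  r <- as.vector(stats::cor(expr[probe_id, ], t(expr[others, , drop = FALSE])))
  key <- if (absolute) abs(r) else r
  ord <- order(-key, others)[seq_len(min(k, length(others)))]
  data.table::data.table(probe_id = others[ord], r = r[ord])
}

#' Intersect probe lists and map to genes
#'
#' @param lists two or more character vectors of probe ids.
#' @param probes probe annotation (probe_id, gene_id); optional — without it
#'   only the probe intersection is returned.
#' @return A list: probes (the exact set intersection), genes (unique gene
#'   ids of the intersected probes; probes of the same gene deduplicated).
#' @export
intersect_lists <- function(lists, probes = NULL) {
  stopifnot(length(lists) >= 2)
  common <- Reduce(intersect, lists)
  genes <- if (is.null(probes)) NULL else
    sort(unique(probes$gene_id[match(common, probes$probe_id)]))
  list(probes = common, genes = genes)
}

#' Permutation p-value for the intersection of several random lists
#'
#' Estimates how often `n_lists` random subsets of size `k` drawn from a
#' universe of `N` items share at least `observed` common elements. Instead
#' of materializing subsets, the intersection is simulated by sequential
#' conditional draws — `I_1 = k`, `I_{j+1} ~ Hypergeometric(N, I_j, k)` —
#' which is distribution-identical to explicit subset sampling and runs in
#' O(n_lists) per replicate.
#'
#' @param n_lists number of lists (>= 2).
#' @param k list size.
#' @param N universe size.
#' @param observed observed intersection size.
#' @param n_perm replicates.
#' @param seed integer seed.
#' @param convention `"plus_one"` (default) reports
#'   `(#\{I >= observed\} + 1) / (n_perm + 1)`; `"strict"` reports
#'   `#\{I > observed\} / n_perm` (the classical divide-by-n rule with strict
#'   exceedance).
#' @return A list: set_sizes, N, observed, n_perm, p_emp, seed.
#' @export
multi_list_overlap_p <- function(n_lists, k, N, observed, n_perm = 1e6,
                                 seed = 1L,
                                 convention = c("plus_one", "strict")) {
  convention <- match.arg(convention)
  if (k > N) stop("k must not exceed N", call. = FALSE)
  stopifnot(n_lists >= 2, observed <= k, observed >= 0)
  with_seed(seed, {
    isz <- sim_intersection_sizes(n_lists, k, N, n_perm)
    p_emp <- if (convention == "plus_one") {
      (sum(isz >= observed) + 1) / (n_perm + 1)
    } else {
      sum(isz > observed) / n_perm
    }
    list(set_sizes = rep(k, n_lists), N = N, observed = observed,
      n_perm = n_perm, p_emp = p_emp, seed = seed)
  })
}

#' Overlap significance of two gene sets in a common universe
#'
#' Permutation p (random subsets of sizes `nA` and `nB` from `[N]`; one
#' hypergeometric draw per replicate) and the exact hypergeometric upper
#' tail `P(X >= observed)`, `X ~ Hypergeom(N, nA, nB)`, are both reported.
#'
#' @param nA,nB set sizes.
#' @param N universe size.
#' @param observed observed overlap.
#' @param n_perm replicates.
#' @param seed integer seed.
#' @param convention as in [multi_list_overlap_p()].
#' @return A list: set_sizes, N, observed, n_perm, p_emp, exact_p, seed.
#' @export
two_set_overlap_p <- function(nA, nB, N, observed, n_perm = 1e6, seed = 1L,
                              convention = c("plus_one", "strict")) {
  convention <- match.arg(convention)
  stopifnot(nA <= N, nB <= N, observed <= min(nA, nB), observed >= 0)
  exact_p <- stats::phyper(observed - 1, nA, N - nA, nB, lower.tail = FALSE)
  with_seed(seed, {
    ov <- stats::rhyper(n_perm, m = nA, n = N - nA, k = nB)
    p_emp <- if (convention == "plus_one") {
      (sum(ov >= observed) + 1) / (n_perm + 1)
    } else {
      sum(ov > observed) / n_perm
    }
    list(set_sizes = c(nA, nB), N = N, observed = observed, n_perm = n_perm,
      p_emp = p_emp, exact_p = exact_p, seed = seed)
  })
}

#' Minimal eQTL scan with cis/trans classification
#'
#' Scans every marker with a Welch two-group comparison of the expression
#' trait by genotype, and calibrates genome-wide significance by the
#' max-statistic permutation method: the threshold is the 95th percentile of
#' the maximal |t| over `n_perm` strain-label permutations. The peak marker
#' is classified `cis` if it is significant and lies within `cis_window_bp`
#' of the gene on the same chromosome, `trans` if significant elsewhere,
#' `none` otherwise. Monomorphic markers are skipped with a warning.
#'
#' @param expr_trait expression values per strain (aligned with `geno` rows).
#' @param geno strains x markers 0/1 genotype matrix (columns named by
#'   marker id).
#' @param markers marker map (chrom, pos_bp, marker_id).
#' @param gene_location list or one-row table with chrom, start_bp, end_bp.
#' @param cis_window_bp window around the gene within which a significant
#'   peak is called cis (default 10 Mb, a conventional cis window for mouse
#'   crosses where mapping resolution is broad).
#' @param n_perm label permutations for the genome-wide threshold.
#' @param seed integer seed.
#' @return A list: scan (marker_id, chrom, pos_bp, stat, p), peak_marker,
#'   peak_stat, threshold, classification, cis_window_bp.
#' @export
eqtl_scan <- function(expr_trait, geno, markers, gene_location,
                      cis_window_bp = 1e7, n_perm = 200L, seed = 1L) {
  stopifnot(length(expr_trait) == nrow(geno))
  geno <- geno[, markers$marker_id, drop = FALSE]
  p <- welch_scan(geno, expr_trait)
  mono <- attr(p, "monomorphic")
  if (any(mono)) warning(sum(mono), " monomorphic marker(s) skipped")
  stat <- abs(attr(p, "stat"))
  stat[mono] <- 0
  scan <- data.table::data.table(marker_id = markers$marker_id,
    chrom = markers$chrom, pos_bp = markers$pos_bp, stat = stat,
    p = as.numeric(p))
  with_seed(seed, {
    max_null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pb <- welch_scan(geno, expr_trait[sample.int(length(expr_trait))])
      sb <- abs(attr(pb, "stat"))
      sb[attr(pb, "monomorphic")] <- 0
      max_null[b] <- max(sb)
    }
    threshold <- stats::quantile(max_null, 0.95, names = FALSE)
    peak <- which.max(stat)
    significant <- stat[peak] > threshold
    in_cis <- scan$chrom[peak] == as.character(gene_location$chrom) &&
      scan$pos_bp[peak] >= gene_location$start_bp - cis_window_bp &&
      scan$pos_bp[peak] <= gene_location$end_bp + cis_window_bp
    classification <- if (!significant) "none" else if (in_cis) "cis" else
      "trans"
    list(scan = scan, peak_marker = scan$marker_id[peak],
      peak_stat = stat[peak], threshold = threshold,
      classification = classification, cis_window_bp = cis_window_bp)
  })
}
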