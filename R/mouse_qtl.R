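# Marker-to-gene p-value interpolation for a mouse QTL scan.

#' Interpolate gene-level p-values from a marker-level QTL scan
#'
#' Each gene is anchored at its start position. A gene lying between two
#' flanking markers at positions `a < x < b` with p-values `p_a`, `p_b`
#' receives the linear interpolation on the raw p scale,
#' `p(x) = p_a + (x - a) / (b - a) * (p_b - p_a)`; a gene positioned halfway
#' between two markers therefore gets the p-value halfway between the two
#' marker values. A gene exactly at a marker takes that marker's p
#' (`at-marker`); a gene before the first or after the last marker of its
#' chromosome takes the nearest marker's p (`clamped-left` / `clamped-right`
#' -- clamping rather than extrapolation, which could leave `(0, 1]`).
#'
#' @param markers marker map: chrom, pos_bp, p (positions strictly increasing
#'   within chromosome).
#' @param genes gene table: gene_id, chrom, start_bp.
#' @param scale `"p"` (default) interpolates on the raw p scale; `"log10"`
#'   interpolates on -log10(p) and transforms back.
#' @return data.table: gene_id, chrom, anchor_bp, p, method.
#' @export
interpolate_gene_p <- function(markers, genes, scale = c("p", "log10")) {
  scale <- match.arg(scale)
  check_prob(markers$p, "marker p")
  missing_chrom <- setdiff(unique(genes$chrom), unique(markers$chrom))
  if (length(missing_chrom)) {
    stop("no markers on chromosome(s): ", paste(missing_chrom, collapse = ", "),
      call. = FALSE)
  }
  out <- vector("list", length(unique(genes$chrom)))
  i <- 0L
  for (chr in unique(genes$chrom)) {
    mk <- markers[markers$chrom == chr]
    data.table::setorder(mk, pos_bp)
    if (anyDuplicated(mk$pos_bp)) {
      stop("duplicate marker positions on chromosome ", chr, call. = FALSE)
    }
    gn <- genes[genes$chrom == chr]
    x <- gn$start_bp
    mp <- if (scale == "log10") -log10(mk$p) else mk$p
    if (nrow(mk) < 2) {
      warning("chromosome ", chr, " has a single marker: genes clamped to it")
      p <- rep(mk$p, length(x))
      method <- ifelse(x == mk$pos_bp, "at-marker",
        ifelse(x < mk$pos_bp, "clamped-left", "clamped-right"))
    } else {
      idx <- findInterval(x, mk$pos_bp)
      p <- numeric(length(x))
      method <- character(length(x))
      at <- x %in% mk$pos_bp
      method[at] <- "at-marker"
      p[at] <- mk$p[match(x[at], mk$pos_bp)]
      left <- !at & idx == 0
      method[left] <- "clamped-left"
      p[left] <- mk$p[1]
      right <- !at & idx == nrow(mk)
      method[right] <- "clamped-right"
      p[right] <- mk$p[nrow(mk)]
      mid <- !at & !left & !right
      method[mid] <- "interpolated"
      a <- mk$pos_bp[idx[mid]]; b <- mk$pos_bp[idx[mid] + 1]
      pa <- mp[idx[mid]]; pb <- mp[idx[mid] + 1]
      v <- pa + (x[mid] - a) / (b - a) * (pb - pa)
      p[mid] <- if (scale == "log10") 10^(-v) else v
    }
    i <- i + 1L
    out[[i]] <- data.table::data.table(gene_id = gn$gene_id, chrom = chr,
      anchor_bp = x, p = p, method = method)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, anchor_bp)
  res[]
}

#' Select significant genes from a gene p-value table
#'
#' @param table gene p-value table with columns gene_id and p.
#' @param alpha significance threshold (genes with `p <= alpha` are kept).
#' @return Character vector of gene ids sorted by ascending p, ties broken by
#'   gene id.
#' @export
select_significant <- function(table, alpha = 0.05) {
  if (nrow(table) == 0) stop("empty gene p-value table", call. = FALSE)
  hit <- table[table$p <= alpha]
  hit$gene_id[order(hit$p, hit$gene_id)]
}
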