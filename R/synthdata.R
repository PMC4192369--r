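# Seeded generators for every input the pipeline consumes: a recombinant
# inbred (RI) cross with a planted QTL, LD-blocked GWAS summary statistics
# with a planted causal gene, an incomplete one-to-one homology map, and an
# exon-array-like expression matrix with a planted coexpression module.

#' Specification for a simulated recombinant-inbred cross
#'
#' Describes a biparental RI panel (BXD-like: every strain homozygous at every
#' locus, genotypes coded 0/1 for the two parental alleles) with markers laid
#' out on a regular grid and one planted quantitative trait locus.
#'
#' @param n_strains number of strains (default 37: 35 RI lines plus the two
#'   parental strains).
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param recomb_prob probability of recombination between adjacent markers,
#'   in `[0, 0.5]`.
#' @param qtl_marker index (1-based, over all markers in map order) of the
#'   planted causal marker.
#' @param qtl_effect additive effect of the `1` allele on the phenotype, in
#'   phenotype-SD units.
#' @param noise_sd standard deviation of the phenotype noise.
#' @param genes_per_chrom number of annotated genes per chromosome.
#' @param marker_spacing_bp distance between adjacent markers, bp.
#' @param gene_len_bp gene length, bp.
#' @param seed integer seed.
#' @return A `cross_sim_spec` list.
#' @export
cross_sim_spec <- function(n_strains = 37L, n_chrom = 5L,
                           markers_per_chrom = 40L, recomb_prob = 0.1,
                           qtl_marker = 20L, qtl_effect = 2, noise_sd = 1,
                           genes_per_chrom = 30L, marker_spacing_bp = 2e6,
                           gene_len_bp = 2e4, seed = 1L) {
  stopifnot(n_strains >= 3, n_chrom >= 1, markers_per_chrom >= 2,
    recomb_prob >= 0, recomb_prob <= 0.5, noise_sd >= 0,
    genes_per_chrom >= 1, marker_spacing_bp > 0)
  n_markers <- n_chrom * markers_per_chrom
  if (qtl_marker < 1 || qtl_marker > n_markers) {
    stop("qtl_marker must index a marker in 1..", n_markers, call. = FALSE)
  }
  structure(list(n_strains = as.integer(n_strains),
    n_chrom = as.integer(n_chrom),
    markers_per_chrom = as.integer(markers_per_chrom),
    recomb_prob = recomb_prob, qtl_marker = as.integer(qtl_marker),
    qtl_effect = qtl_effect, noise_sd = noise_sd,
    genes_per_chrom = as.integer(genes_per_chrom),
    marker_spacing_bp = marker_spacing_bp, gene_len_bp = gene_len_bp,
    seed = as.integer(seed)), class = "cross_sim_spec")
}

#' Simulate an RI cross, phenotype and single-marker QTL scan
#'
#' Genotypes follow a Markov chain along each chromosome: the first marker is
#' a fair coin per strain and each subsequent marker recombines with
#' probability `recomb_prob`. The phenotype is
#' `qtl_effect * genotype[qtl_marker] + N(0, noise_sd)`. Per-marker p-values
#' come from a Welch two-group comparison of phenotype by genotype, mimicking
#' the output of a single-marker interval-mapping scan; a monomorphic marker
#' is recorded with p = 1 and a warning.
#'
#' @param spec a [cross_sim_spec()].
#' @return A list: `markers` (marker map: chrom, pos_bp, marker_id, p),
#'   `genes` (gene_id, chrom, start_bp, end_bp), `geno` (strains x markers 0/1
#'   matrix), `pheno` (phenotype vector), `truth` (planted marker id, its
#'   chromosome and position, the effect size, and the id of the gene placed
#'   over the planted marker).
#' @export
gen_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_sim_spec"))
  with_seed(spec$seed, {
    m <- spec$markers_per_chrom
    chroms <- as.character(seq_len(spec$n_chrom))
    geno <- matrix(0L, spec$n_strains, spec$n_chrom * m)
    for (c in seq_len(spec$n_chrom)) {
      g <- matrix(0L, spec$n_strains, m)
      g[, 1] <- stats::rbinom(spec$n_strains, 1, 0.5)
      if (m > 1) {
        flips <- matrix(stats::rbinom(spec$n_strains * (m - 1), 1,
          spec$recomb_prob), spec$n_strains, m - 1)
        g[, -1] <- (g[, 1] + t(apply(flips, 1, cumsum))) %% 2L
      }
      geno[, (c - 1) * m + seq_len(m)] <- g
    }
    marker_id <- sprintf("m%04d", seq_len(ncol(geno)))
    colnames(geno) <- marker_id
    pos <- rep(1 + spec$marker_spacing_bp * (seq_len(m) - 1), spec$n_chrom)
    chrom <- rep(chroms, each = m)

    pheno <- spec$qtl_effect * geno[, spec$qtl_marker] +
      stats::rnorm(spec$n_strains, 0, spec$noise_sd)
    p <- welch_scan(geno, pheno)
    if (any(attr(p, "monomorphic"))) {
      warning(sum(attr(p, "monomorphic")),
        " monomorphic marker(s): p-value recorded as 1")
    }
    markers <- data.table::data.table(chrom = chrom, pos_bp = pos,
      marker_id = marker_id, p = as.numeric(p))

    # genes scattered uniformly; gene 1 of the QTL chromosome is relocated to
    # span the planted marker so downstream recovery is scoreable by id
    chrom_len <- 1 + spec$marker_spacing_bp * (m - 1)
    genes <- data.table::data.table(
      gene_id = sprintf("mgene%04d", seq_len(spec$n_chrom * spec$genes_per_chrom)),
      chrom = rep(chroms, each = spec$genes_per_chrom),
      start_bp = floor(stats::runif(spec$n_chrom * spec$genes_per_chrom, 1,
        chrom_len - spec$gene_len_bp)))
    genes[, `:=`(end_bp = genes$start_bp + spec$gene_len_bp - 1)]
    qtl_chrom <- chrom[spec$qtl_marker]
    qtl_pos <- pos[spec$qtl_marker]
    planted <- genes[genes$chrom == qtl_chrom][["gene_id"]][1]
    genes[genes$gene_id == planted,
      `:=`(start_bp = max(1, qtl_pos - floor(spec$gene_len_bp / 2)),
           end_bp = max(1, qtl_pos - floor(spec$gene_len_bp / 2)) +
             spec$gene_len_bp - 1)]
    data.table::setorder(genes, chrom, start_bp)

    list(markers = markers, genes = genes, geno = geno, pheno = pheno,
      truth = list(qtl_marker = marker_id[spec$qtl_marker],
        chrom = qtl_chrom, pos_bp = qtl_pos, effect = spec$qtl_effect,
        planted_gene = planted))
  })
}

#' Specification for simulated GWAS summary statistics with block LD
#'
#' SNPs come in physically local blocks with exchangeable within-block allele
#' correlation `within_block_r` and independence between blocks. Haplotypes
#' use a copying model (each SNP copies a block ancestral allele with
#' probability `sqrt(within_block_r)`, otherwise draws a fresh allele), which
#' makes the expected allele-level and dosage-level correlation exactly
#' `within_block_r`.
#'
#' @param n_individuals reference-panel / study sample size.
#' @param n_blocks number of LD blocks.
#' @param snps_per_block SNPs per block.
#' @param within_block_r target within-block correlation, in `[0, 1)`.
#' @param causal_gene gene id (must exist in the gene table handed to
#'   [gen_gwas()]) whose nearest SNP carries the phenotype effect.
#' @param causal_beta effect per SD of causal dosage, in phenotype-SD units.
#' @param maf_range allele-frequency interval within `(0, 0.5]`.
#' @param seed integer seed.
#' @return A `gwas_sim_spec` list.
#' @export
gwas_sim_spec <- function(n_individuals = 1000L, n_blocks = 20L,
                          snps_per_block = 10L, within_block_r = 0.6,
                          causal_gene, causal_beta = 0.3,
                          maf_range = c(0.1, 0.5), seed = 1L) {
  stopifnot(n_individuals >= 4, n_blocks >= 1, snps_per_block >= 1,
    within_block_r >= 0, within_block_r < 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2])
  structure(list(n_individuals = as.integer(n_individuals),
    n_blocks = as.integer(n_blocks), snps_per_block = as.integer(snps_per_block),
    within_block_r = within_block_r, causal_gene = causal_gene,
    causal_beta = causal_beta, maf_range = maf_range,
    seed = as.integer(seed)), class = "gwas_sim_spec")
}

#' Simulate GWAS summary statistics and a reference LD panel
#'
#' Blocks are placed at random positions on the chromosomes covered by
#' `genes`; the block containing the causal SNP is centred on the causal
#' gene. A quantitative phenotype is generated from the standardized causal
#' dosage, and each SNP's p-value comes from its marginal simple regression
#' on the phenotype.
#'
#' @param spec a [gwas_sim_spec()].
#' @param genes human gene table (gene_id, chrom, start_bp, end_bp).
#' @param window_bp the SNP-to-gene assignment window the analysis will use;
#'   an error is raised if the causal gene would have no SNP within it.
#' @return A list: `snps` (snp_id, chrom, pos_bp, p), `panel` (individuals x
#'   SNP dosage matrix), `truth` (causal gene and SNP ids, beta).
#' @export
gen_gwas <- function(spec, genes, window_bp = 50000) {
  stopifnot(inherits(spec, "gwas_sim_spec"))
  if (!spec$causal_gene %in% genes$gene_id) {
    stop("causal_gene ", spec$causal_gene, " not present in gene table",
      call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_individuals
    s <- spec$snps_per_block
    r <- spec$within_block_r
    cg <- genes[genes$gene_id == spec$causal_gene]

    # block centres sit on gene midpoints (genic SNP coverage); block 1 is
    # pinned to the causal gene
    pick <- if (spec$n_blocks <= nrow(genes)) {
      sample.int(nrow(genes), spec$n_blocks)
    } else {
      sample.int(nrow(genes), spec$n_blocks, replace = TRUE)
    }
    centers <- data.table::data.table(chrom = genes$chrom[pick],
      center = (genes$start_bp[pick] + genes$end_bp[pick]) / 2)
    centers$chrom[1] <- cg$chrom
    centers$center[1] <- (cg$start_bp + cg$end_bp) / 2
    half_span <- 25000
    pos <- lapply(seq_len(spec$n_blocks), function(b) {
      sort(floor(stats::runif(s, max(1, centers$center[b] - half_span),
        centers$center[b] + half_span)))
    })

    maf <- stats::runif(spec$n_blocks, spec$maf_range[1], spec$maf_range[2])
    panel <- matrix(0L, n, spec$n_blocks * s)
    for (b in seq_len(spec$n_blocks)) {
      dose <- matrix(0L, n, s)
      for (h in 1:2) {
        anc <- stats::rbinom(n, 1, maf[b])
        copy <- matrix(stats::rbinom(n * s, 1, sqrt(r)), n, s)
        fresh <- matrix(stats::rbinom(n * s, 1, maf[b]), n, s)
        dose <- dose + copy * anc + (1L - copy) * fresh
      }
      panel[, (b - 1) * s + seq_len(s)] <- dose
    }
    snp_id <- sprintf("rs%06d", seq_len(ncol(panel)))
    colnames(panel) <- snp_id
    snps <- data.table::data.table(snp_id = snp_id,
      chrom = rep(centers$chrom, each = s), pos_bp = unlist(pos))

    in_window <- snps$chrom == cg$chrom &
      snps$pos_bp >= cg$start_bp - window_bp &
      snps$pos_bp <= cg$end_bp + window_bp
    if (!any(in_window)) {
      stop("causal gene has no SNPs within the +/-", window_bp, " bp window",
        call. = FALSE)
    }
    mid <- (cg$start_bp + cg$end_bp) / 2
    causal_snp <- snps$snp_id[in_window][
      which.min(abs(snps$pos_bp[in_window] - mid))]
    x <- panel[, causal_snp]
    xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    y <- spec$causal_beta * xs + stats::rnorm(n)

    rr <- suppressWarnings(as.vector(stats::cor(panel, y)))
    tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    p[!is.finite(p)] <- 1
    snps$p <- pmin(pmax(p, .Machine$double.xmin), 1)
    data.table::setorder(snps, chrom, pos_bp)

    list(snps = snps, panel = panel,
      truth = list(causal_gene = spec$causal_gene, causal_snp = causal_snp,
        beta = spec$causal_beta))
  })
}

#' Generate a gene annotation table
#'
#' Artifact plumbing shared by both species: `n_genes` genes scattered
#' uniformly over `n_chrom` chromosomes of length `chrom_len_bp`.
#'
#' @param n_genes,n_chrom,chrom_len_bp,gene_len_bp layout parameters.
#' @param prefix gene id prefix.
#' @param seed integer seed.
#' @return data.table: gene_id, chrom, start_bp, end_bp.
#' @export
gen_genes <- function(n_genes, n_chrom = 5L, chrom_len_bp = 8e7,
                      gene_len_bp = 2e4, prefix = "gene", seed = 1L) {
  stopifnot(n_genes >= 1, n_chrom >= 1)
  with_seed(seed, {
    g <- data.table::data.table(
      gene_id = sprintf("%s%05d", prefix, seq_len(n_genes)),
      chrom = as.character(sample.int(n_chrom, n_genes, replace = TRUE)),
      start_bp = floor(stats::runif(n_genes, 1, chrom_len_bp - gene_len_bp)))
    g[, `:=`(end_bp = g$start_bp + gene_len_bp - 1)]
    data.table::setorder(g, chrom, start_bp)
    g[]
  })
}

#' Generate an incomplete one-to-one homology map
#'
#' Maps a random subset of human genes (of size `round(coverage * n)`) to
#' distinct mouse genes. `force_pairs` pins chosen pairs into the map (used to
#' plant a shared causal gene across species).
#'
#' @param genes_h,genes_m human and mouse gene tables.
#' @param coverage fraction of human genes with a homologue, in `(0, 1]`.
#' @param seed integer seed.
#' @param force_pairs optional data.frame(human_gene_id, mouse_gene_id) of
#'   pairs that must appear in the map.
#' @return data.table: human_gene_id, mouse_gene_id (a bijection onto its
#'   image).
#' @export
gen_homology <- function(genes_h, genes_m, coverage = 0.883, seed = 1L,
                         force_pairs = NULL) {
  if (!(coverage > 0 && coverage <= 1)) {
    stop("coverage must lie in (0, 1]", call. = FALSE)
  }
  n_map <- round(coverage * nrow(genes_h))
  if (n_map > nrow(genes_m)) {
    stop("not enough mouse genes for the requested coverage", call. = FALSE)
  }
  with_seed(seed, {
    h_pool <- genes_h$gene_id
    m_pool <- genes_m$gene_id
    out_h <- character(0); out_m <- character(0)
    if (!is.null(force_pairs)) {
      out_h <- as.character(force_pairs$human_gene_id)
      out_m <- as.character(force_pairs$mouse_gene_id)
      stopifnot(all(out_h %in% h_pool), all(out_m %in% m_pool),
        !anyDuplicated(out_h), !anyDuplicated(out_m))
      h_pool <- setdiff(h_pool, out_h)
      m_pool <- setdiff(m_pool, out_m)
    }
    k <- n_map - length(out_h)
    if (k > 0) {
      out_h <- c(out_h, sample(h_pool, k))
      out_m <- c(out_m, sample(m_pool, k))
    }
    map <- data.table::data.table(human_gene_id = out_h, mouse_gene_id = out_m)
    data.table::setorder(map, human_gene_id)
    map[]
  })
}

#' Specification for an exon-array-like expression matrix
#'
#' A planted coexpression module: every concordant probe of a module gene
#' loads on one shared latent factor with loading `sqrt(module_r)`, so any
#' two such probes have expected Pearson correlation `module_r`. The first
#' module gene (the "focal" gene) additionally carries `n_noise_probes`
#' probes independent of the module, emulating the mixture of concordant and
#' non-concordant probes a multi-probe exon array produces for one gene.
#'
#' @param n_strains number of strains (columns); must be >= 4 so correlation
#'   tests are defined.
#' @param n_genes number of genes.
#' @param probes_per_gene length-2 integer range; each gene's concordant
#'   probe count is drawn uniformly from it.
#' @param module_genes character ids (subset of the generated
#'   `gene00001 ...`) forming the planted module; the first is the focal gene.
#' @param module_r target pairwise correlation within the module, in `(0,1)`.
#' @param n_noise_probes extra independent probes for the focal gene.
#' @param seed integer seed.
#' @return An `expr_sim_spec` list.
#' @export
expr_sim_spec <- function(n_strains = 70L, n_genes = 200L,
                          probes_per_gene = c(2L, 6L),
                          module_genes = sprintf("gene%05d", 1:8),
                          module_r = 0.85, n_noise_probes = 11L, seed = 1L) {
  stopifnot(n_genes >= 1, length(probes_per_gene) %in% 1:2,
    all(probes_per_gene >= 1), module_r > 0, module_r < 1,
    n_noise_probes >= 0)
  if (n_strains < 4) stop("n_strains must be >= 4", call. = FALSE)
  if (length(probes_per_gene) == 1) {
    probes_per_gene <- rep(probes_per_gene, 2)
  }
  structure(list(n_strains = as.integer(n_strains),
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    module_genes = as.character(module_genes), module_r = module_r,
    n_noise_probes = as.integer(n_noise_probes), seed = as.integer(seed)),
    class = "expr_sim_spec")
}

#' Simulate the expression matrix and probe annotation
#'
#' @param spec an [expr_sim_spec()].
#' @return A list: `expr` (probes x strains matrix, rows standardized,
#'   rownames = probe ids), `probes` (probe_id, gene_id, target_class with
#'   classes exon/intron/utr5/utr3; noise probes are introns), `truth`
#'   (module gene ids, focal gene id, concordant probe ids of the focal
#'   gene).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  gene_id <- sprintf("gene%05d", seq_len(spec$n_genes))
  if (!all(spec$module_genes %in% gene_id)) {
    stop("module_genes must be a subset of the generated gene ids", call. = FALSE)
  }
  with_seed(spec$seed, {
    rng <- seq(spec$probes_per_gene[1], spec$probes_per_gene[2])
    npg <- if (length(rng) == 1) rep(rng, spec$n_genes) else
      sample(rng, spec$n_genes, replace = TRUE)
    ann <- data.table::data.table(
      probe_id = NA_character_,
      gene_id = rep(gene_id, npg),
      target_class = unlist(lapply(npg, function(k) {
        c("utr5", "exon", "exon", "exon", "exon", "utr3",
          rep("exon", max(0, k - 6)))[seq_len(k)]
      })))
    focal <- spec$module_genes[1]
    if (spec$n_noise_probes > 0) {
      ann <- rbind(ann, data.table::data.table(probe_id = NA_character_,
        gene_id = rep(focal, spec$n_noise_probes), target_class = "intron"))
      data.table::setorder(ann, gene_id)
    }
    ann$probe_id <- sprintf("probe%06d", seq_len(nrow(ann)))

    mod_factor <- stats::rnorm(spec$n_strains)
    lam <- sqrt(spec$module_r)
    concordant <- ann$gene_id %in% spec$module_genes &
      ann$target_class != "intron"
    expr <- matrix(stats::rnorm(nrow(ann) * spec$n_strains), nrow(ann))
    expr[concordant, ] <- lam * matrix(mod_factor, sum(concordant),
      spec$n_strains, byrow = TRUE) +
      sqrt(1 - spec$module_r) * expr[concordant, , drop = FALSE]
    expr <- t(scale(t(expr)))
    rownames(expr) <- ann$probe_id
    colnames(expr) <- sprintf("strain%03d", seq_len(spec$n_strains))

    list(expr = expr, probes = ann,
      truth = list(module_genes = spec$module_genes, focal_gene = focal,
        focal_concordant = ann$probe_id[concordant & ann$gene_id == focal]))
  })
}
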