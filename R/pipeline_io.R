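# Orchestration and file-format handling: TSV tables with mandatory headers,
# GMT gene-set export, table validation diagnostics, a YAML-backed run
# configuration, and the end-to-end driver (simulate -> mouse gene p ->
# human gene p -> cross-species -> coexpression -> report).

#' Write / read a tab-separated table with a header row
#' @param x data.frame or data.table.
#' @param path file path.
#' @return `read_tsv_table` returns a data.table.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  x <- data.table::fread(path, sep = "\t")
  if ("chrom" %in% names(x)) x[, `:=`(chrom = as.character(x$chrom))]
  x[]
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated —
#' the standard input for enrichment tools.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks over the TSV inputs: required columns, p-value
#' ranges, 1-based coordinates with `start <= end`, duplicate ids. Returns
#' machine-readable diagnostics rather than raising.
#'
#' @param paths named list/vector of file paths; recognized names: markers,
#'   genes, snps, homology, probes.
#' @return data.table: file, row, column, message (zero rows when clean).
#' @export
validate_tables <- function(paths) {
  diag <- list()
  note <- function(file, row, column, message) {
    diag[[length(diag) + 1]] <<- data.table::data.table(file = file,
      row = row, column = column, message = message)
  }
  need <- list(
    markers = c("chrom", "pos_bp", "marker_id", "p"),
    genes = c("gene_id", "chrom", "start_bp", "end_bp"),
    snps = c("snp_id", "chrom", "pos_bp", "p"),
    homology = c("human_gene_id", "mouse_gene_id"),
    probes = c("probe_id", "gene_id", "target_class"))
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      note(path, NA_integer_, NA_character_, "file does not exist")
      next
    }
    x <- data.table::fread(path, sep = "\t")
    req <- need[[nm]]
    if (!is.null(req)) {
      for (col in setdiff(req, names(x))) {
        note(path, NA_integer_, col, "required column missing")
      }
      if (!all(req %in% names(x))) next
    }
    if ("p" %in% names(x)) {
      bad <- which(!is.finite(x$p) | x$p <= 0 | x$p > 1)
      for (i in bad) note(path, i, "p", sprintf("p = %g outside (0, 1]", x$p[i]))
    }
    for (col in intersect(c("pos_bp", "start_bp"), names(x))) {
      bad <- which(x[[col]] < 1)
      for (i in bad) note(path, i, col, "coordinate below 1 (1-based expected)")
    }
    if (all(c("start_bp", "end_bp") %in% names(x))) {
      bad <- which(x$end_bp < x$start_bp)
      for (i in bad) note(path, i, "end_bp", "end_bp < start_bp")
    }
    idcol <- intersect(c("marker_id", "gene_id", "snp_id", "probe_id"),
      names(x))[1]
    if (!is.na(idcol) && nm != "probes") {
      bad <- which(duplicated(x[[idcol]]))
      for (i in bad) note(path, i, idcol, paste0("duplicate id ", x[[idcol]][i]))
    }
  }
  if (length(diag) == 0) {
    data.table::data.table(file = character(), row = integer(),
      column = character(), message = character())
  } else {
    data.table::rbindlist(diag)
  }
}

#' Build a run configuration
#'
#' All tunables of the end-to-end run in one nestable structure. `mode`
#' selects simulation, analysis of existing tables, or both. Any field can be
#' overridden; a YAML file with the same structure can be loaded with
#' [load_config()].
#'
#' @param outdir directory for all tables and reports.
#' @param seed global seed (mandatory); every stage derives a substream from
#'   it via [substream_seed()].
#' @param mode `"full"`, `"simulate"` or `"analyze"`.
#' @param plant_shared make the mouse QTL gene and the human causal gene
#'   homologues (the planted cross-species signal); FALSE gives a null run.
#' @param cross,gwas,expr named lists of overrides for [cross_sim_spec()],
#'   [gwas_sim_spec()] and [expr_sim_spec()].
#' @param n_genes_human,coverage human gene count and homology coverage.
#' @param alpha mouse significance threshold and familywise level.
#' @param window_bp SNP-to-gene window.
#' @param n_sims MVN simulations per gene.
#' @param n_perm_lambda,n_perm_rrho,n_perm_overlap,n_perm_eqtl permutation
#'   budgets.
#' @param top_k top-correlate list length.
#' @param r_min probe concordance threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = tempfile("crossgene_run"), seed = 1L,
                       mode = c("full", "simulate", "analyze"),
                       plant_shared = TRUE, cross = list(), gwas = list(),
                       expr = list(), n_genes_human = 120L, coverage = 0.883,
                       alpha = 0.05, window_bp = 50000, n_sims = 2000L,
                       n_perm_lambda = 2000L, n_perm_rrho = 100L,
                       n_perm_overlap = 10000L, n_perm_eqtl = 200L,
                       top_k = 40L, r_min = 0.5) {
  mode <- match.arg(mode)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed), mode = mode,
    plant_shared = isTRUE(plant_shared), cross = cross, gwas = gwas,
    expr = expr, n_genes_human = as.integer(n_genes_human),
    coverage = coverage, alpha = alpha, window_bp = window_bp,
    n_sims = as.integer(n_sims), n_perm_lambda = as.integer(n_perm_lambda),
    n_perm_rrho = as.integer(n_perm_rrho),
    n_perm_overlap = as.integer(n_perm_overlap),
    n_perm_eqtl = as.integer(n_perm_eqtl), top_k = as.integer(top_k),
    r_min = r_min), class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file naming any subset of [run_config()]'s fields.
#' @param ... overrides applied on top of the file.
#' @return A `run_config` list.
#' @export
load_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  do.call(run_config, y)
}

paths_for <- function(outdir) {
  list(markers = file.path(outdir, "markers.tsv"),
    genes_m = file.path(outdir, "genes_mouse.tsv"),
    genes_h = file.path(outdir, "genes_human.tsv"),
    snps = file.path(outdir, "snps.tsv"),
    panel = file.path(outdir, "panel.tsv"),
    expr = file.path(outdir, "expr.tsv"),
    probes = file.path(outdir, "probes.tsv"),
    homology = file.path(outdir, "homology.tsv"),
    geno = file.path(outdir, "geno_mouse.tsv"),
    trait = file.path(outdir, "focal_trait.tsv"),
    truth = file.path(outdir, "truth.json"))
}

simulate_stage <- function(config) {
  pt <- paths_for(config$outdir)
  cr_args <- config$cross
  cr_args$seed <- substream_seed(config$seed, "simulate/cross")
  cross <- gen_cross(do.call(cross_sim_spec, cr_args))

  genes_h <- gen_genes(config$n_genes_human, prefix = "hgene",
    seed = substream_seed(config$seed, "simulate/genes_h"))
  gw_args <- config$gwas
  if (is.null(gw_args$causal_gene)) gw_args$causal_gene <- genes_h$gene_id[1]
  gw_args$seed <- substream_seed(config$seed, "simulate/gwas")
  gwas <- gen_gwas(do.call(gwas_sim_spec, gw_args), genes_h,
    window_bp = config$window_bp)

  force_pairs <- if (config$plant_shared) {
    data.frame(human_gene_id = gwas$truth$causal_gene,
      mouse_gene_id = cross$truth$planted_gene)
  } else NULL
  homology <- gen_homology(genes_h, cross$genes, coverage = config$coverage,
    seed = substream_seed(config$seed, "simulate/homology"),
    force_pairs = force_pairs)

  ex_args <- config$expr
  ex_args$seed <- substream_seed(config$seed, "simulate/expr")
  expr <- gen_expression(do.call(expr_sim_spec, ex_args))

  # a cis-driven expression trait over the cross strains for the eQTL scan:
  # driven by the marker nearest the planted gene
  mk <- cross$markers[cross$markers$chrom == cross$truth$chrom]
  driver <- mk$marker_id[which.min(abs(mk$pos_bp - cross$truth$pos_bp))]
  trait <- with_seed(substream_seed(config$seed, "simulate/trait"),
    cross$geno[, driver] + stats::rnorm(nrow(cross$geno), 0, 0.4))

  write_tsv_table(cross$markers, pt$markers)
  write_tsv_table(cross$genes, pt$genes_m)
  write_tsv_table(genes_h, pt$genes_h)
  write_tsv_table(gwas$snps, pt$snps)
  write_tsv_table(data.table::as.data.table(gwas$panel), pt$panel)
  write_tsv_table(data.table::data.table(probe_id = rownames(expr$expr),
    expr$expr), pt$expr)
  write_tsv_table(expr$probes, pt$probes)
  write_tsv_table(homology, pt$homology)
  write_tsv_table(data.table::data.table(strain = seq_len(nrow(cross$geno)),
    cross$geno), pt$geno)
  write_tsv_table(data.table::data.table(
    strain = seq_len(nrow(cross$geno)), trait = trait), pt$trait)
  truth <- list(cross = cross$truth, gwas = gwas$truth,
    expr = expr$truth, eqtl_driver = driver)
  jsonlite::write_json(truth, pt$truth, auto_unbox = TRUE, digits = NA)
  truth
}

#' Run the full pipeline
#'
#' Stages run in order (simulate, mouse gene p-values, human gene-based test,
#' cross-species tests, coexpression / guilt-by-association, report); every
#' stage writes its outputs before the next stage reads them, so a failed run
#' can be restarted in `analyze` mode. All randomness derives from
#' `config$seed` through named substreams: two runs with the same config and
#' seed produce identical reports up to wall-clock fields.
#'
#' @param config a [run_config()].
#' @return A `RunReport` list (also written to `report.json` in the output
#'   directory): per-stage summaries, package version, config echo, and
#'   wall-clock seconds per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pt <- paths_for(config$outdir)
  stages <- list()
  timing <- list()
  tick <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- fn()
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    stages[[name]] <<- out
    out
  }

  if (config$mode %in% c("full", "simulate")) {
    truth <- tick("simulate", function() simulate_stage(config))
  }
  if (config$mode == "simulate") {
    report <- list(stages = stages, version = as.character(
      utils::packageVersion("crossgene")), config = unclass(config),
      wall_clock_s = timing)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
      auto_unbox = TRUE, digits = 12, pretty = TRUE)
    return(invisible(report))
  }

  for (f in c("markers", "genes_m", "genes_h", "snps", "panel", "homology",
    "expr", "probes", "geno", "trait", "truth")) {
    if (!file.exists(pt[[f]])) {
      stop("analyze mode: missing input file ", pt[[f]], call. = FALSE)
    }
  }
  diags <- validate_tables(list(markers = pt$markers, genes = pt$genes_m,
    snps = pt$snps, homology = pt$homology, probes = pt$probes))
  if (nrow(diags) > 0) {
    stop("input validation failed: ", diags$file[1], " row ", diags$row[1],
      " column ", diags$column[1], ": ", diags$message[1], call. = FALSE)
  }

  markers <- read_tsv_table(pt$markers)
  genes_m <- read_tsv_table(pt$genes_m)
  genes_h <- read_tsv_table(pt$genes_h)
  snps <- read_tsv_table(pt$snps)
  panel <- as.matrix(read_tsv_table(pt$panel))
  homology <- read_tsv_table(pt$homology)
  expr_tab <- read_tsv_table(pt$expr)
  expr <- as.matrix(expr_tab[, -1])
  rownames(expr) <- expr_tab$probe_id
  probes <- read_tsv_table(pt$probes)
  geno_tab <- read_tsv_table(pt$geno)
  geno <- as.matrix(geno_tab[, -1])
  trait <- read_tsv_table(pt$trait)$trait

  mouse <- tick("mouse_gene_p", function() {
    tab <- interpolate_gene_p(markers, genes_m)
    write_tsv_table(tab, file.path(config$outdir, "gene_p_mouse.tsv"))
    sig <- select_significant(tab, config$alpha)
    list(n_genes = nrow(tab), n_significant = length(sig), significant = sig,
      table = tab)
  })
  human <- tick("human_gene_p", function() {
    tab <- gene_based_test(snps, genes_h, panel, window_bp = config$window_bp,
      n_sims = config$n_sims,
      seed = substream_seed(config$seed, "analyze/human"))
    write_tsv_table(tab, file.path(config$outdir, "gene_p_human.tsv"))
    list(n_genes = nrow(tab), n_tested = sum(tab$n_snps > 0), table = tab)
  })

  xs <- tick("xspecies", function() {
    h <- human$table[human$table$n_snps > 0]
    joined <- join_homologs(
      data.table::data.table(gene_id = h$gene_id, p = h$p_emp),
      data.table::data.table(gene_id = mouse$table$gene_id,
        p = mouse$table$p), homology)
    counts <- attr(joined, "counts")
    test_set <- joined$human_gene_id[joined$mouse_gene_id %in%
      mouse$significant]
    lam <- if (length(test_set) >= 2) {
      lambda_perm_test(joined, test_set, n_perm = config$n_perm_lambda,
        seed = substream_seed(config$seed, "analyze/lambda"))
    } else NULL
    sa <- stats::setNames(joined$p_human, joined$human_gene_id)
    sb <- stats::setNames(joined$p_mouse, joined$human_gene_id)
    rr <- rrho_test(sa, sb, n_perm = config$n_perm_rrho,
      seed = substream_seed(config$seed, "analyze/rrho"))
    bon <- bonferroni_overlap(mouse$significant, joined, alpha = config$alpha)
    write_tsv_table(qq_table(joined[joined$mouse_gene_id %in%
      mouse$significant]$p_human), file.path(config$outdir, "qq_human.tsv"))
    list(n_mapped = counts$n_mapped, coverage = counts$coverage,
      n_test_set = length(test_set),
      lambda_obs = if (is.null(lam)) NA else lam$lambda_obs,
      lambda_p_perm = if (is.null(lam)) NA else lam$p_perm,
      rrho_max_logp = rr$max_logp, rrho_p_fwer = rr$p_fwer,
      bonferroni_threshold = bon$threshold,
      hits = bon$hits$human_gene_id,
      hit_pairs = bon$hits)
  })

  cx <- tick("coexpr", function() {
    truth <- jsonlite::read_json(pt$truth, simplifyVector = TRUE)
    focal <- truth$expr$focal_gene
    conc <- probe_concordance(expr, probes, focal, r_min = config$r_min)
    k <- min(config$top_k, nrow(expr) - 1)
    lists <- lapply(conc$probes, function(pid) {
      top_k_correlates(expr, pid, k = k)$probe_id
    })
    inter <- if (length(lists) >= 2) intersect_lists(lists, probes) else
      list(probes = character(), genes = character())
    ov <- if (length(lists) >= 2) {
      multi_list_overlap_p(length(lists), k, nrow(expr),
        length(inter$probes), n_perm = config$n_perm_overlap,
        seed = substream_seed(config$seed, "analyze/overlap"))
    } else NULL
    gene_loc <- genes_m[genes_m$gene_id == truth$cross$planted_gene]
    eq <- eqtl_scan(trait, geno, markers, gene_loc,
      n_perm = config$n_perm_eqtl,
      seed = substream_seed(config$seed, "analyze/eqtl"))
    write_gmt(list(coexpression_module = inter$genes),
      file.path(config$outdir, "coexpr_sets.gmt"),
      descriptions = paste0("probes correlated with all concordant probes of ",
        focal))
    list(focal_gene = focal, concordant_probes = conc$probes,
      n_intersection_probes = length(inter$probes),
      n_intersection_genes = length(inter$genes),
      overlap_p = if (is.null(ov)) NA else ov$p_emp,
      eqtl_class = eq$classification, eqtl_peak = eq$peak_marker)
  })

  report <- list(stages = list(mouse = mouse[c("n_genes", "n_significant",
      "significant")], human = human[c("n_genes", "n_tested")], xspecies =
      xs[setdiff(names(xs), "hit_pairs")], coexpr = cx),
    version = as.character(utils::packageVersion("crossgene")),
    config = unclass(config), wall_clock_s = timing)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
    auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(c(report, list(detail = list(mouse = mouse, human = human,
    xspecies = xs, coexpr = cx))))
}
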