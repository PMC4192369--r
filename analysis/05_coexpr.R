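#!/usr/bin/env Rscript
# Stage 5: guilt-by-association for the focal gene — concordant probe set,
# top-K correlate list per concordant probe, multi-list intersection with
# permutation significance, the two-universe overlap test, and the eQTL scan
# with cis/trans classification.

library(crossgene)

outdir <- "results/run"
expr_tab <- read_tsv_table(file.path(outdir, "expr.tsv"))
expr <- as.matrix(expr_tab[, -1])
rownames(expr) <- expr_tab$probe_id
probes <- read_tsv_table(file.path(outdir, "probes.tsv"))
markers <- read_tsv_table(file.path(outdir, "markers.tsv"))
genes_m <- read_tsv_table(file.path(outdir, "genes_mouse.tsv"))
geno_tab <- read_tsv_table(file.path(outdir, "geno_mouse.tsv"))
geno <- as.matrix(geno_tab[, -1])
trait <- read_tsv_table(file.path(outdir, "focal_trait.tsv"))$trait
truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
  simplifyVector = TRUE)

focal <- truth$expr$focal_gene
conc <- probe_concordance(expr, probes, focal, r_min = 0.5, p_max = 0.05)
cat("Focal gene", focal, "has", sum(probes$gene_id == focal), "probes;",
  length(conc$probes), "are mutually concordant (r >= 0.5, p <= 0.05)\n")

k <- min(40L, nrow(expr) - 1L)
lists <- lapply(conc$probes, function(p) top_k_correlates(expr, p,
  k = k)$probe_id)
inter <- intersect_lists(lists, probes)
cat("Top-", k, " lists of the ", length(lists), " concordant probes share ",
  length(inter$probes), " probes = ", length(inter$genes), " genes\n",
  sep = "")

ov <- multi_list_overlap_p(length(lists), k, nrow(expr),
  length(inter$probes), n_perm = 1e5,
  seed = substream_seed(20260922, "analysis/overlap"))
cat("Multi-list intersection permutation p =", ov$p_emp, "\n")

# how many module genes does the guilt-by-association list recover?
hits <- intersect(inter$genes, truth$expr$module_genes)
two <- two_set_overlap_p(length(inter$genes),
  length(truth$expr$module_genes), length(unique(probes$gene_id)),
  length(hits), n_perm = 1e5,
  seed = substream_seed(20260922, "analysis/two_set"))
cat("Overlap of the", length(inter$genes), "GBA genes with the",
  length(truth$expr$module_genes), "planted module genes:", length(hits),
  "(perm p =", two$p_emp, ", exact p =", signif(two$exact_p, 3), ")\n")

gl <- genes_m[genes_m$gene_id == truth$cross$planted_gene]
eq <- eqtl_scan(trait, geno, markers, gl, n_perm = 1000,
  seed = substream_seed(20260922, "analysis/eqtl"))
cat("eQTL scan of the focal expression trait: peak at", eq$peak_marker,
  "(|t| =", round(eq$peak_stat, 2), ", genome-wide threshold",
  round(eq$threshold, 2), ") ->", eq$classification, "\n")

write_gmt(list(gba_genes = inter$genes,
  planted_module = truth$expr$module_genes),
  file.path(outdir, "coexpr_sets.gmt"),
  descriptions = c("genes correlated with all concordant focal probes",
    "planted coexpression module"))
jsonlite::write_json(list(concordant_probes = conc$probes,
  n_gba_probes = length(inter$probes), n_gba_genes = length(inter$genes),
  multi_list_p = ov$p_emp, module_overlap = length(hits),
  module_overlap_p = two$p_emp, eqtl = eq[c("peak_marker", "peak_stat",
    "threshold", "classification")]),
  file.path(outdir, "coexpr_report.json"), auto_unbox = TRUE, digits = 12)
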