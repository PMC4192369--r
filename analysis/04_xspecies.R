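#!/usr/bin/env Rscript
# Stage 4: cross-species concordance — join the two gene p-value tables
# through the homology map, compute the genomic-control lambda of the
# mouse-significant set with a permutation null, run RRHO, and make the
# Bonferroni-corrected single-gene overlap call.

library(crossgene)

outdir <- "results/run"
mouse <- read_tsv_table(file.path(outdir, "gene_p_mouse.tsv"))
human <- read_tsv_table(file.path(outdir, "gene_p_human.tsv"))
homology <- read_tsv_table(file.path(outdir, "homology.tsv"))
truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
  simplifyVector = TRUE)

tested <- human[human$n_snps > 0]
joined <- join_homologs(
  data.table::data.table(gene_id = tested$gene_id, p = tested$p_emp),
  data.table::data.table(gene_id = mouse$gene_id, p = mouse$p), homology)
counts <- attr(joined, "counts")
cat(counts$n_mapped, "gene pairs joined (",
  round(100 * counts$coverage, 1), "% of tested human genes)\n")

sig <- select_significant(mouse, alpha = 0.05)
test_set <- joined$human_gene_id[joined$mouse_gene_id %in% sig]
lam <- lambda_perm_test(joined, test_set, n_perm = 1e5,
  seed = substream_seed(20260922, "analysis/lambda"))
cat("Mouse-significant set: n =", lam$n_set, ", lambda =",
  round(lam$lambda_obs, 3), ", permutation p =", lam$p_perm, "\n")

rr <- rrho_test(setNames(joined$p_human, joined$human_gene_id),
  setNames(joined$p_mouse, joined$human_gene_id), n_perm = 200,
  seed = substream_seed(20260922, "analysis/rrho"))
cat("RRHO peak -log10 p =", round(rr$max_logp, 2), ", familywise p =",
  round(rr$p_fwer, 3), "\n")

bon <- bonferroni_overlap(sig, joined, alpha = 0.05)
cat("Bonferroni threshold 0.05 /", length(sig), "=",
  signif(bon$threshold, 2), ";", nrow(bon$hits), "hit(s):",
  paste(bon$hits$human_gene_id, collapse = ", "), "\n")
cat("Planted cross-species gene recovered:",
  truth$gwas$causal_gene %in% bon$hits$human_gene_id, "\n")

write_tsv_table(qq_table(joined[joined$mouse_gene_id %in% sig]$p_human),
  file.path(outdir, "qq_human.tsv"))
jsonlite::write_json(list(lambda = lam[c("lambda_obs", "n_set", "p_perm")],
  rrho = list(max_logp = rr$max_logp, p_fwer = rr$p_fwer),
  bonferroni = list(threshold = bon$threshold,
    hits = bon$hits$human_gene_id)),
  file.path(outdir, "xspecies_report.json"), auto_unbox = TRUE, digits = 12)
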