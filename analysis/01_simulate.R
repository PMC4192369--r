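#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — a BXD-like recombinant
# inbred cross with a planted QTL, LD-blocked human GWAS summary statistics
# whose causal gene is the planted mouse gene's homologue, an incomplete
# homology map, an exon-array-like expression matrix with a planted
# coexpression module, and a cis-driven expression trait for the eQTL scan.
# All tables land in results/run/.

library(crossgene)

outdir <- "results/run"
cfg <- run_config(outdir = outdir, seed = 20260922, mode = "simulate",
  gwas = list(n_blocks = 60L, causal_beta = 0.5))
run_pipeline(cfg)

truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
  simplifyVector = TRUE)
markers <- read_tsv_table(file.path(outdir, "markers.tsv"))
snps <- read_tsv_table(file.path(outdir, "snps.tsv"))
cat("Simulated", nrow(markers), "mouse markers;",
  "planted QTL at", truth$cross$qtl_marker, "on chromosome",
  truth$cross$chrom, "\n")
cat("Simulated", nrow(snps), "human SNPs; causal gene",
  truth$gwas$causal_gene, "homologous to mouse", truth$cross$planted_gene,
  "\n")
cat("Expression module genes:",
  paste(truth$expr$module_genes, collapse = ", "), "\n")
cat("Tables written under", outdir, "\n")
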