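---
title: "Methods: cross-species gene prioritization with crossgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species gene prioritization with crossgene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crossgene` asks a simple question of two very different mapping experiments:
do genes that influence a quantitative trait in a mouse cross also influence
the homologous trait in humans? Because the two experiments produce evidence
at different granularities — a sparse marker scan in the mouse, dense SNP
summary statistics in humans — each side first has to be converted to a
common currency, one p-value per gene. This vignette describes each model,
its assumptions, the tunable parameters, and the numerical choices, in the
order the pipeline runs them.

## Mouse: marker-to-gene interpolation

A recombinant-inbred (RI) panel such as BXD is scanned one marker at a time,
so significance is only known at marker positions. `interpolate_gene_p()`
assigns each gene the linear interpolation, **on the raw p scale**, of the
two markers flanking its start position. The halfway case is the defining
example: a gene midway between markers with p = 0.02 and p = 0.04 gets
p = 0.03.

Choices made here, and why:

* **Anchor = gene start**, regardless of strand. The anchor is a single
  point; genes are small relative to RI marker spacing, and strand adds no
  information to a positional lookup.
* **Raw p, not −log10(p).** Interpolating on −log10 would privilege the more
  significant flank; the raw-p rule keeps the halfway property literal. The
  −log10 variant is available (`scale = "log10"`) for sensitivity analysis.
* **Clamping, not extrapolation,** outside the marker range: extrapolation
  can leave (0, 1]. Every gene records its `method`
  (interpolated/at-marker/clamped-left/clamped-right) so downstream users can
  filter on provenance.

The interpolated p is always bounded by the flanking marker p-values
(convexity), and a chromosome whose markers all share p = c maps every gene
to c. These invariants are enforced by property tests.

Interpolated values are *descriptive* — they are not p-values of any test
performed at the gene, and the pipeline never treats them as such: they are
used to rank and select a mouse gene set, whose significance in humans is
then assessed by permutation.

## Human: gene-based association with an LD-aware null

`gene_based_test()` implements the sum-of-chi-squared gene statistic: SNP
p-values within ±50 kb of the gene are converted to upper-tail 1-df
chi-squared quantiles and summed. Under linkage equilibrium the null is
chi-squared with n df; under LD it is not, so the null is simulated: draw
`z ~ MVN(0, R)` with `R` the SNP correlation estimated from a reference
dosage panel, and use `T_sim = Σ z²`. The empirical p uses the
`(r + 1)/(n + 1)` estimator with ties counting against rejection — bounded
away from zero and conservative.

Numerical choices:

* **p floor at 1e-300** before the quantile transform (p = 0 would give an
  infinite statistic).
* **PSD repair** of the sample correlation by eigenvalue clipping at 1e-8
  followed by renormalization to unit diagonal; finite panels with filtered
  SNPs can produce indefinite matrices, and the Cholesky factorization
  requires PSD. Monomorphic SNPs are dropped (recorded) before estimation.
* **Staged simulation** (default 10³ → 10⁴ → 10⁶) escalates only while the
  running estimate is below `10 / n_total` — i.e. while fewer than ~10
  exceedances have been seen, the precision regime where more simulations
  change the answer. Clearly non-significant genes stop cheap. The schedule
  is configurable; the two analytic extremes (identity correlation → n-df
  tail; all-ones correlation → 1-df tail of T/n) are verified by simulation
  in the test suite.

## Cross-species concordance

`join_homologs()` restricts both tables to one-to-one homologous pairs
(duplicates resolved by keeping the smallest human p, a conservative choice
that favours finding signal if any exists; the rest are logged). Three tests
then run at increasing resolution:

* **Set-level inflation.** `genomic_lambda()` uses the median-based
  genomic-control estimator, λ = median(Q(p))/0.45494. The permutation test
  draws random gene sets of the same size from the joined table and counts
  `λ_rand > λ_obs` (strict inequality, divided by the permutation count —
  the classical rule; a `(r+1)/(n+1)` variant is available). λ of the tested
  set near 1 with a non-significant permutation p means the mouse-significant
  set shows no collective human signal.
* **Threshold-free rank association.** `rrho_test()` scans a grid of
  rank-threshold pairs, computing the hypergeometric upper-tail p of the
  overlap of the two top-lists at each pair; the familywise p of the peak
  −log10 p comes from permutations that shuffle one list's ranks while
  holding the other fixed (exchangeability under the null of no rank
  association). Only one list is permuted because the null concerns the
  *association between* the rankings, not either marginal ranking. The step
  defaults to N/100. The familywise p uses `(r+1)/(n+1)` so it can never be
  exactly zero.
* **Single-gene lookup.** `bonferroni_overlap()` tests each
  mouse-significant gene's homologue at `α / |set|` — with 42 mouse genes at
  α = 0.05 the threshold is 0.0012.

## Coexpression and guilt-by-association

Exon arrays carry several probes per gene, not all of which behave like the
gene: `probe_concordance()` keeps the largest set of probes that are
*pairwise* concordant (Pearson r ≥ 0.5 with two-sided t-transform p ≤ 0.05,
n − 2 df). The retained set is a maximal clique of the concordance graph,
greedily grown from the highest-degree probe with ties broken by probe id —
the clique rule reflects what "probes which correlate with each other"
means operationally, and the greedy construction makes the output
deterministic. Single-probe genes are returned flagged untestable.

`top_k_correlates()` ranks by **signed** r (descending): coexpression means
expressing *together*, so negative correlates do not qualify; an absolute-r
mode exists for users who want co-regulation in either direction.
`intersect_lists()` takes the exact intersection and deduplicates probes of
the same gene.

The significance of a multi-list intersection is estimated without ever
materializing the lists: the size of the intersection of j + 1 random
k-subsets, conditional on the current intersection size `I_j`, is
`Hypergeometric(N, I_j, k)`, so `sim_intersection_sizes()` runs one
vectorized `rhyper` chain per replicate batch. This is
distribution-identical to explicit subset sampling (verified by
total-variation distance against brute force on small universes) and makes
one million replicates of the six-list, 1.24-million-probe configuration a
few seconds' work. The two-set overlap test reports both the permutation p
and the exact hypergeometric upper tail; the universe defaults to 19,000
protein-coding genes, and conclusions at the observed effect sizes are
insensitive across 17,787–20,000.

`eqtl_scan()` scans every marker with a Welch two-group comparison of the
expression trait by genotype, and calibrates genome-wide significance by the
max-statistic permutation method (95th percentile of the maximal |t| over
strain-label permutations), which controls the familywise error of the scan
without distributional assumptions. A significant peak within 10 Mb of the
gene is called *cis*, elsewhere *trans*. The 10 Mb window reflects the broad
mapping resolution of RI panels of this size.

Empirical p-value conventions differ deliberately across tests: the
permutation tests that mirror classical divide-by-n definitions
(`lambda_perm_test`, and the `"strict"` convention of the overlap tests)
default to the strict-exceedance rule, while the estimators that feed
downstream decisions (`gene_empirical_p`, `rrho_test`, the `"plus_one"`
default of the overlap tests) use `(r + 1)/(n + 1)` so that reported
p-values are never zero.

## The synthetic-data generators

The generators produce inputs with exactly the statistical structure each
stage assumes, plus a truth record for scoring:

* `gen_cross()`: 37 strains (35 RI lines plus the two parentals) of 0/1
  homozygous genotypes following a Markov chain along each chromosome
  (recombination probability 0.1 per adjacent interval by default), a
  phenotype `effect · g + N(0, σ)`, and a Welch scan per marker. The planted
  QTL's gene is relocated to span the causal marker so recovery is
  scoreable by id. Each strain contributes one observation (strain means are
  the unit of analysis in RI mapping).
* `gen_gwas()`: haplotypes from a copying model — each SNP copies a block
  ancestral allele with probability √r, else draws fresh — giving expected
  allele and dosage correlation exactly r within a block and zero between
  blocks. Blocks are centred on gene midpoints (genic coverage), the causal
  block on the causal gene. Phenotypes regress on the standardized causal
  dosage; p-values come from marginal simple regressions.
* `gen_homology()`: a one-to-one map over a random 88.3% of human genes by
  default, with the option to pin pairs (used to plant the shared causal
  gene).
* `gen_expression()`: all concordant probes of module genes load on one
  latent factor with loading √module_r, so every planted pair correlates at
  module_r in expectation; the focal gene additionally carries independent
  noise probes (with 6 concordant probes and 11 noise probes it reproduces
  the 17-probe mixed structure typical of exon arrays). Rows are
  standardized.

What the generators do **not** emulate: covariate structure and population
stratification on the human side, realistic human LD decay (block
exchangeability only), heteroscedastic expression noise, batch effects, or
many-to-many homology. Passing tests therefore demonstrate the *statistical
machinery* — calibration under the null, recovery under planted signal,
agreement with analytic oracles — not robustness to those real-data
complications.

## Problem sizes and calibration studies

Desk-scale defaults are chosen so a full synthetic study runs in about a
second: 5 mouse chromosomes × 40 markers × 30 genes, 120 human genes with
25–60 LD blocks of 10 SNPs over 1,000 individuals, 200 expression genes ×
70 strains. The test suite's calibration studies use: 200–500 replicates for
uniformity checks (KS at α = 0.01), 200 replicates × 400 permutations for λ
calibration, 200 replicates × 99 permutations (universe 300, step 30) for
RRHO calibration — a universe in which ties of the discrete max statistic
are rare enough not to distort calibration — and 50 replicates for
end-to-end recovery (planted configuration) and null familywise-rate
checks. The two large overlap tests run at their full one-million replicate
counts, since the sequential-hypergeometric simulator makes them cheap. The
eQTL recovery study drives the trait at allele effect 1.0 with residual SD
0.4 — a strongly cis-regulated transcript — and the marker-resolution study
uses loosely linked maps (recombination 0.25) so the causal marker is
statistically separable from its neighbours.

## Reproducibility

Every random draw descends from one global seed through named substreams
(`substream_seed(seed, "stage/name")`, a string-hash offset below 2³¹), so
any stage can be rerun in isolation and reproduce its in-pipeline output.
Reports serialize to JSON at 12 significant digits; two runs with the same
config and seed differ only in wall-clock fields.

## Known limitations

* Interpolated mouse p-values inherit the resolution of the marker map;
  within a broad QTL all nearby genes receive similar p-values, so the mouse
  side selects *regions* more than genes — exactly why the human gene-based
  test and the coexpression evidence are needed to single out a gene.
* The homology join keeps one pair per gene; paralogous families are
  under-served.
* The eQTL scan is a single-marker Welch scan, not interval mapping; it is
  intended for cis/trans classification of a focal transcript, not genome
  QTL discovery.
* RRHO's permutation p is familywise over the threshold grid but conditional
  on the chosen step size.
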