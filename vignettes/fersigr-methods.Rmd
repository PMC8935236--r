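---
title: "Ferroptosis-associated subtyping and the Fersig score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ferroptosis-associated subtyping and the Fersig score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fersigr)
```

## Overview

`fersigr` implements a molecular-classification workflow for bulk tumor
transcriptomes built around ferroptosis biology, together with its
downstream per-patient scoring system. The pipeline has five stages:

1. **Consensus NMF subtyping** of the expression matrix restricted to a
   ferroptosis gene list (drivers, suppressors and markers), with the number
   of clusters chosen by the cophenetic coefficient. In colorectal cohorts
   this classification yields three clusters with immune-desert,
   immune-inflamed and immune-excluded microenvironment profiles.
2. **ssGSEA scoring** of microenvironment and pathway signatures per sample,
   used both descriptively and to identify which cluster is
   immune-activated and which stromal-activated.
3. **Signature derivation**: genes up-regulated in the immune-activated
   cluster (one-vs-rest) intersected with the ferroptosis list form the
   immune-activated signature; likewise for the stromal-activated cluster.
   DEGs shared by all cluster contrasts form the phenotype-related
   signature, which is Cox-filtered for prognostic relevance and partitioned
   into stromal-related (A), immune-related (B) and other (C) gene groups.
4. **Fersig score**: each sample is scored on the first principal component
   of group A and of group B; a univariate Cox model per score decides its
   sign class, and the score is `Fersig = sum(PC1_i) - sum(PC1_j)` with `i`
   the scores whose Cox coefficient is >= 0 and `j` the rest. Samples are
   split at the median into high/low groups; a high score marks a
   stromal-dominant, poor-prognosis, immunotherapy-refractory phenotype.
5. **Single-cell projection**: per-cluster marker sets (derived at a
   natural-log fold-change threshold of 0.5) are scored on single cells with
   binned-control module scores, and every cell is labelled by its maximal
   score.

Every stage is exposed as an exported function returning a tibble (or a
small S3 object with `tidy()`/`glance()`/`autoplot()` methods), and
`run_pipeline()` composes them end to end with a provenance log.

## The synthetic cohort generator

Because the original cohorts (TCGA-COREAD, GEO meta-cohorts, melanoma
immunotherapy cohorts, FerrDb) cannot be redistributed, the package ships a
generator, `sim_config()` + `simulate_*_cohort()`, that emulates the
statistical structure the analysis relies on and returns the ground truth
needed to validate recovery:

* **Expression**: `n_samples = 300` samples, `n_genes = 1500` genes on a
  log2(x+1)-like scale. Three disjoint 80-gene programs (canonical, immune,
  stromal); each sample belongs to one cluster (mixing 50/35/15, echoing the
  published cluster sizes) and its program genes are shifted by
  `delta = 2` log2 units on top of a Uniform(2, 8) per-gene baseline with
  Normal(0, `sigma = 1`) noise, clipped at zero. `delta/sigma = 2` is the
  separation regime the recovery properties are stated at.
* **Ferroptosis list**: 228 genes split 71/61/96 into driver, suppressor and
  marker roles; 25 sit inside the immune program, 25 inside the stromal
  program, 15 inside the canonical program and the rest in the background,
  so activated-signature recovery is a meaningful intersection test.
* **Survival**: exponential event times with hazard
  `lambda0 * exp(beta_cluster)`, `lambda0 = 1/1500` per day and
  `beta = (0, -0.5, +0.8)` for canonical/immune/stromal — the stromal
  cluster dies fastest, the immune cluster slowest. A subject is censored
  with probability 0.3 at a Uniform(0, T) time before its event, keeping the
  censoring mechanism independent of the covariates given the event time.
  Exponential (not Weibull) times keep closed-form checks simple.
* **Stage**: cluster-skewed stage I–IV probabilities (stage IV 15.5% in the
  stromal cluster vs 3.8% in the immune cluster, mirroring the published
  contingency structure).
* **Mutations**: per-gene Bernoulli hits over a 250-gene panel at rate 0.02,
  doubled in the immune cluster, with a realistic mix of variant classes, so
  tumor-mutation-burden contrasts have a planted direction.
* **Single cell**: 2,000 cells in five types (epithelial 40%, T 20%, B 10%,
  myeloid 15%, stromal 15%); negative-binomial counts (size 2, baseline mean
  0.3) with type markers and program genes elevated 4-fold on the mean.
  Epithelial cells split between canonical-program and immune-program
  states; stromal cells over-express the stromal program.
* **Immunotherapy cohort**: `n = 150` samples; response is Bernoulli with
  logit `2 * (z(immune activity) - z(stromal activity))`, and the hazard is
  `lambda0 * exp(-0.5 * response + 0.5 * z(stromal) - 0.3 * z(immune))`:
  responders do better, stromal-dominant tumors do worse — the biology the
  score is supposed to exploit.

What the generator does **not** emulate: batch effects across cohorts,
single-cell dropout and ambient RNA, copy-number structure, correlated
gene-gene noise within programs, and non-proportional hazards. Tests passing
on these cohorts therefore demonstrate that the implementation recovers the
structure it is designed for, not that the biological claims hold on real
data.

One RNG stream per output block (expression / survival / stage / mutations /
single cell / immunotherapy) is derived from the master seed, so adding or
resizing one block never perturbs another and cohorts are bit-reproducible
under a fixed seed.

## Consensus NMF and rank selection

`nmf_factorize()` implements the classic multiplicative updates minimizing
the Kullback–Leibler divergence `D(X || WH)` (the subtyping variant of NMF),
with `W, H` initialized Uniform(0, 1) scaled by `mean(X)`, `tol = 1e-6`
relative objective change and `max_iter = 2000`. The objective trace is
returned and non-increasing — a property the tests assert on every tracked
run. The updates run in compiled code (RcppArmadillo).

`consensus_cluster()` repeats the factorization from `n_runs = 30` random
restarts per candidate rank, hard-assigns each sample by the argmax over the
columns of `H` (ties to the lower component index), and averages the
run-wise connectivity matrices into a consensus matrix `C`. Stability per
rank is the cophenetic coefficient: the Pearson correlation between the
condensed distances `1 - C` and the cophenetic distances of their
average-linkage dendrogram. `select_rank()` takes the argmax with ties
toward the smallest rank, and `assign_clusters()` cuts the dendrogram at the
chosen rank, renaming clusters by descending size so that "cluster 1" is
always the largest.

**Per-run convergence inside the consensus is deliberately bounded**
(`max_iter = 200`, `tol = 1e-4` by default; `nmf_factorize()` on its own
keeps the strict defaults). The consensus matrix estimates clustering
stability from restart-to-restart variability. If every restart is driven to
full objective convergence, restarts collapse onto identical partitions at
*every* candidate rank — on the default synthetic cohort the rank-2
factorization is unimodal (all restarts give the same merged partition), so
the cophenetic coefficient saturates at 1 for rank 2 as well as rank 3 and
rank selection degenerates to the tie-break. This saturation is a known
pathology of cophenetic-based selection (the original consensus-NMF work
already reports a cophenetic of 1 at the wrong rank on well-separated
leukemia classes). A bounded per-run budget leaves the co-clustering of
well-separated samples untouched while keeping genuine restart diversity
visible, which is what makes the coefficient informative across ranks. An
optional connectivity-based stopping rule (stop once hard labels are stable
for a given number of checks) is also available via `conn_stop`.

Genes with zero sum or zero variance are removed before factorization;
an all-ones consensus (every pair always co-clusters) still yields `k`
labels but warns that the consensus is degenerate.

## ssGSEA, module scores, PC1 scores

* **ssGSEA** (`ssgsea_scores()`): per sample, genes are ranked descending
  with average ranks on ties; the enrichment score of a set is the sum over
  all rank positions of the difference between the in-set ECDF weighted by
  `rank^alpha` and the uniform out-of-set ECDF. Defaults `alpha = 0.25` and
  range normalization (divide the whole score matrix by its max − min)
  follow the dominant ssGSEA convention; both are explicit parameters
  because group comparisons can be run on either scale. The implementation
  is checked against a brute-force running-sum oracle to 1e-9 on hundreds of
  random small instances, and its rank-invariance (monotone per-sample
  transforms leave scores unchanged) is asserted directly.
* **Module scores** (`module_scores()`): genes are binned into
  `n_bins = 24` equal-occupancy bins by average expression; each set gene
  draws `n_ctrl = 100` same-bin control genes (without replacement when the
  bin allows, set genes never serve as controls), and the score is mean set
  expression minus mean control-pool expression. The control draw is fixed
  by a mandatory seed. Raw counts are library-size log-normalized first.
  The expected score of a random within-bin set is zero, which the tests
  check within Monte-Carlo error.
* **PC1 signature score** (`pca_signature_score()`): the gene-set submatrix
  is centered per gene (no variance scaling — genes on a common log scale
  should contribute by their actual variation) and samples are projected on
  the leading singular direction. Because an eigenvector's sign is
  arbitrary, the score is oriented to correlate positively with the
  per-sample mean expression of the set; without this rule the sign of the
  downstream Fersig score would depend on the eigensolver. Stored loadings,
  centers and orientation make the score reproducible on new cohorts
  (`apply_fersig()`), with the train/apply identity asserted exactly.

## Differential expression and statistics

One-vs-rest markers use a vectorized Wilcoxon rank-sum test (normal
approximation with tie and continuity corrections, matching
`wilcox.test(exact = FALSE)`), with Welch's t as an option. The continuity
correction matters: on 8-per-group fixtures it brings the approximation
within 0.01–0.02 of the exact permutation p, where the uncorrected
approximation deviates by up to ~0.05. Fold changes are reported on the
natural-log scale (difference of log2 group means times `ln 2`), matching
the convention of the single-cell marker tools whose thresholds (0.25 for
signature derivation, 0.5 for single-cell mapping) the pipeline reuses. The
moderated linear model used for the published bulk contrasts is not
reproduced; a rank test is distribution-robust and dependency-free, and the
signature-recovery properties are insensitive to this choice at the
simulated effect sizes.

Multiple testing is Benjamini–Hochberg throughout. Over-representation is an
upper-tail hypergeometric test against a user-supplied universe — a
deliberate generic stand-in for ontology-portal enrichment, which would
require curated downloads. Tumor mutation burden is a raw nonsilent count by
default (the exome size behind a per-megabase scaling is not part of the
data model); `per_mb = TRUE` divides by a configurable 38 Mb capture.

Survival analysis delegates to the `survival` package: Efron tie handling
for Cox (day-granularity survival data is tie-heavy, and Efron dominates
Breslow there), product-limit KM curves with display-level truncation (tests
run on full follow-up unless truncation is requested), and the k-group
log-rank test. `median_split()` assigns scores strictly above the median to
"high" and median members to "low" — deterministic and conventional.

## Pipeline composition choices

* The phenotype-related signature defaults to the **three-way intersection**
  of the per-cluster DEG lists (significance in every contrast, any
  direction), matching the overlap language of the source analysis; union
  mode is exposed. The prognostic Cox filter keeps genes with Wald
  `p < 0.05`.
* Gene groups A/B/C come from average-linkage clustering of the phenotype
  DEGs on correlation distance, cut at 3; groups are *labelled* by the
  correlation of their mean expression with the stromal- and
  immune-activated ssGSEA scores (A = best stromal correlate, B = best
  immune correlate). Labelling by correlation rather than by GO annotation
  keeps the pipeline self-contained and reproducible offline.
* The immune- and stromal-activated clusters are identified automatically as
  the clusters with the highest immune-reference and stromal-reference
  ssGSEA scores (overridable), since cluster numbering is
  size-canonicalized, not biology-canonicalized.
* A Cox coefficient of exactly 0 is classed into the positive sum `i` — a
  boundary convention, logged in the provenance.
* `run_pipeline()` aborts with the failing stage's name, writes every
  stage's tables through `write_results()` when an output directory is
  given, and records all thresholds, seeds and the selected rank in a
  provenance object; rerunning with identical inputs and seed reproduces
  the outputs byte for byte.

## Problem sizes used by the test-suite

The validation suite exercises the study conditions at sizes chosen to keep
a full run in a few minutes of CPU: rank selection across 50 generator
seeds with 20 restarts per rank; Fersig survival separation and
immunotherapy stratification across 100 seeds each; one 2,000-cell cohort
for the single-cell projection; 200 random instances for the ssGSEA oracle
and 20 fixtures for the Cox grid-search oracle. The end-to-end determinism
check runs a reduced cohort (150 samples, 600 genes, ranks 2–4, 6 restarts)
twice and compares file hashes.

## Known limitations

* Rank selection inherits the cophenetic saturation issue described above;
  cohorts where the rank-2 factorization is genuinely unimodal (a few
  percent of generator seeds) will select rank 2 under the
  ties-toward-smallest rule.
* ssGSEA is the only sample-level scorer; the kernel-CDF GSVA variant,
  CIBERSORT-style deconvolution and CMS classification are out of scope.
* The Wilcoxon marker test does not shrink variances; very small clusters
  (< 3 samples) are rejected rather than moderated.
* `compute_fersig()` requires survival data at training time by
  construction; scoring new cohorts without survival goes through
  `apply_fersig()`.
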