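# fersigr

Ferroptosis-associated molecular subtyping of tumor expression cohorts and
the **Fersig** per-patient score, as an R package.

Colorectal tumors can be stratified by the expression of ferroptosis-related
genes (drivers, suppressors and markers of iron-dependent, lipid-peroxidation
cell death) into subtypes whose tumor microenvironments differ sharply:
immune-desert, immune-inflamed and immune-excluded. `fersigr` implements that
workflow end to end for any genes × samples log-scale expression matrix:

* **Consensus NMF subtyping** on a ferroptosis gene list: Brunet-style
  multiplicative updates minimizing the Kullback–Leibler divergence
  `D(X ‖ WH)`, consensus matrices over random restarts, cophenetic-coefficient
  rank selection, size-canonicalized cluster labels.
* **ssGSEA** per-sample signature scoring (rank-weighted running-sum
  enrichment, `α = 0.25`, optional range normalization) for microenvironment
  and pathway signatures.
* **Signature derivation**: one-vs-rest differential expression
  (Wilcoxon, natural-log fold-change thresholds), immune-/stromal-activated
  ferroptosis signatures, phenotype-related DEGs, univariate-Cox prognostic
  filtering, and gene groups A (stromal) / B (immune) / C (other).
* **Fersig score**: per-sample first-principal-component scores of gene
  groups A and B composed by the sign of their Cox coefficients,

  `Fersig = Σ PC1_i − Σ PC1_j`,

  where `i` indexes signature scores with Cox β ≥ 0 and `j` those with
  β < 0. High Fersig marks a stromal-dominant, poor-prognosis,
  immunotherapy-refractory phenotype; the median split stratifies cohorts
  for survival and response contrasts.
* **Single-cell projection** of bulk subtypes via binned-control module
  scores (24 expression bins, 100 controls per set gene), labelling each
  cell by its maximal cluster-marker score.
* **Synthetic cohorts with ground truth** (`simulate_bulk_cohort()`,
  `simulate_single_cell_cohort()`, `simulate_icb_cohort()`): three latent
  transcriptional programs, a 228-gene ferroptosis list (71/61/96 roles)
  straddling the programs, exponential survival with per-cluster hazards,
  cluster-skewed stage and mutation burden, NB single-cell counts, and a
  response-linked immunotherapy cohort — so the whole pipeline is testable
  offline.

Results come back as tibbles or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(fersigr)

cohort <- simulate_bulk_cohort(sim_config(seed = 7))
res <- run_pipeline(cohort$expr, cohort$sets, cohort$clinical,
                    mutations = cohort$mutations, n_runs = 20, seed = 7)

tidy(res$consensus)          # rank survey
#> # A tibble: 4 × 3
#>    rank cophenetic dispersion
#>   <int>      <dbl>      <dbl>
#> 1     2      0.992      0.809
#> 2     3      0.998      0.865
#> 3     4      0.995      0.765
#> 4     5      0.992      0.709

res$rank                     # cophenetic-selected number of clusters
#> [1] 3

table(res$fac$cluster)       # cluster sizes, 1 = largest
#>   1   2   3
#> 141 115  44

length(res$signatures$immune_activated)   # immune-activated ferroptosis genes
#> [1] 26

glance(res$fersig)
#> # A tibble: 1 × 8
#>       n threshold sign_A sign_B beta_A      p_A  beta_B    p_B
#>   <int>     <dbl> <chr>  <chr>   <dbl>    <dbl>   <dbl>  <dbl>
#> 1   300      4.10 i      j      0.0976 5.95e-10 -0.0155 0.0538

res$contrasts$logrank$p      # survival separation of the Fersig median split
#> [1] 0.007350641
```

The survey shows rank 3 as the most stable clustering; the recovered
clusters match the planted 50/35/15 mixture (141/115/44); 26 of the
derived immune-activated genes cover the 25 planted immune-program
ferroptosis genes. The stromal-related score enters the Fersig sum with a
positive Cox coefficient (higher hazard) and the immune-related score with
a negative one, so `Fersig = PC1_A − PC1_B` here, and the high-Fersig half
of the cohort shows significantly worse survival. `res$contrasts$tests`
additionally holds the Kruskal–Wallis/chi-square contrasts of scores, stage
and TMB between the high and low Fersig groups.

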