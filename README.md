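# igsurv

Intratumoral immunoglobulin isotypes, B-cell receptor clonality, and
overall survival in driver-mutation-defined tumor subgroups.

## What this package is for

Bulk RNA-seq of a solid tumor captures the transcripts of every
infiltrating cell, including the antibodies produced by tumor-infiltrating
B cells and plasma cells. From a gene-level expression table one can
quantify, per sample, how much antibody is being produced (the summed
expression of the nine IGH constant-region genes), which isotype dominates
(e.g. the IgG1 share `IGHG1/IGH`, or the IgA share `(IGHA1+IGHA2)/IGH`),
and — where CDR3-covering reads are deep enough — how clonally focused that
production is. Whether any of these B-cell features matters for prognosis
turns out to depend on the tumor's driver-mutation context: the same
IgG1-skewed antibody response can be strongly protective in a KRAS-mutant
lung adenocarcinoma and irrelevant in a KRAS-wild-type one.

`igsurv` implements that analysis as a tested, reusable pipeline for
anyone with a genes-by-samples expression table, a clinical table, a
mutation-call table, and (optionally) per-sample clonotype tables:

* **Cohort I/O** — readers and validators for the four input tables,
  FPKM→TPM normalization, VEP/SIFT/PolyPhen mutation-call filtering, and
  assignment of each patient to 12 partially overlapping subgroups
  (KRASmut/wt, EGFRmut, TP53mut/wt, STK11mut/wt, PD-L1 high/low by the
  twice-the-cohort-mean CD274 rule, and the PI/PP/TRU transcriptional
  subtypes).
* **Isotype metrics** — per-sample composite expressions and ratios, and
  median dichotomization (ties fall low; missing values are excluded).
* **Repertoire** — coverage filtering (strictly more than 500
  CDR3-covering reads), downsampling to 500 reads by multivariate
  hypergeometric draws, clonality as one minus the normalized
  Shannon–Wiener index

  `clonality = 1 − H / ln S`, with `H = −Σ pᵢ ln pᵢ`,

  IGHV-family × IGHJ-gene usage matrices, and a PCA usage signature
  contrasted between long- and short-survival patients.
* **Survival statistics** — Kaplan–Meier product-limit curves, the
  two-group log-rank test, Cox proportional-hazards fits (Efron ties,
  univariate and covariate-adjusted), Bonferroni adjustment, and Spearman
  correlation of `IGHG1/IGH` with non-silent mutation burden.
* **Synthetic cohorts** — a generator with known ground truth (Dirichlet
  isotype fractions, log-normal expression, Gaussian-copula coupling of
  `IGHG1/IGH` and mutation burden, exponential survival with a hazard
  ratio planted on the median-split indicator inside the KRAS-mutant
  stratum, power-law clone sizes with a planted V–J usage shift), so that
  every stage of the pipeline is verifiable without access to a real
  cohort.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, and `autoplot()` methods for
Kaplan–Meier comparisons and V–J signatures.

## Worked example

Simulate a 442-patient cohort under the default study conditions
(protective hazard ratio 0.36 planted on the IGHG1/IGH median-split
indicator within the KRAS-mutant stratum, target Spearman rho 0.48 with
mutation burden, V–J signature planted in long-survival KRAS-mutant
samples) and run the full analysis:

```r
library(igsurv)

cfg    <- sim_config(n_patients = 442, seed = 7)
bundle <- simulate_cohort_bundle(cfg)
report <- run_full_analysis(
  bundle$expression, bundle$clinical, bundle$mutations,
  clonotypes = bundle$clonotypes, seed = 42
)
report
#> igsurv report: 442 patients; 168 subgroup x metric comparisons
#> Significant after Bonferroni (p.adjusted < 0.05):
#> # A tibble: 1 × 7
#>   subgroup metric         n_high n_low hazard_ratio  p.value p.adjusted
#>   <chr>    <chr>           <int> <int>        <dbl>    <dbl>      <dbl>
#> 1 KRASmut  IGHG1_over_IGH     65    66        0.458 0.000369    0.00443
```

Of the 168 subgroup × metric comparisons, the only one that survives
Bonferroni adjustment is the planted association: a high IgG1 share of
total intratumoral antibody production halves the death hazard
(HR ≈ 0.46, 95% CI 0.29–0.71) in KRAS-mutant patients, and nowhere else.
The multivariable Cox confirmation (stage, gender, smoking, age,
infiltration as `log2(PTPRC + 1)`) agrees (`hr_adjusted` ≈ 0.44). The
planted rank correlation with mutation burden is recovered across the
whole cohort:

```r
dplyr::filter(report$correlation, subgroup == "ALL")
#> # A tibble: 1 × 4
#>   subgroup   rho        p     n
#>   <chr>    <dbl>    <dbl> <int>
#> 1 ALL      0.498 4.86e-29   442
```

and the planted V–J enrichment tops the usage signature computed from the
IgG1 repertoires of KRAS-mutant patients:

```r
glance(report$signature)
#> # A tibble: 1 × 5
#>   n_samples n_features var_explained_pc1 var_explained_pc2 top_feature
#>       <int>      <int>             <dbl>             <dbl> <chr>
#> 1        86         42             0.169             0.108 IGHV6-IGHJ4
```

`autoplot()` on `compare_survival()` results draws the Kaplan–Meier
curves; `plot_screen_forest()` draws a hazard-ratio forest across
subgroups; `write_report(report, dir)` exports all tables plus a manifest
with the seed and configuration hash (identical inputs and seed produce
byte-identical bundles).

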