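# zfpdx

Integrative outcome analysis of acute leukemia xenografts in zebrafish
embryos.

## The problem

Risk stratification of adult acute leukemia from clinical variables alone is
unreliable, especially for patients assigned to the intermediate cytogenetic
risk group. One promising complement is to inject a patient's leukemic cells
into zebrafish embryos (a patient-derived xenograft, PDX) and measure how the
cells behave in a living host — whether they engraft, survive, disperse, and
home to the caudal hematopoietic tissue (CHT), the larval analog of bone
marrow — and to combine those behavioral readouts with a flow-cytometric
quantification of the leukemic stem cell (LSC) compartment and the standard
clinical picture. `zfpdx` implements that full analysis chain as a tested R
package, for lab groups running zebrafish PDX assays and for methodologists
studying how such multi-layer evidence should be fused.

## What the package computes

**LSC gating.** Sequential gates on cytometry events: viability (FSC-A
floor), doublet exclusion (FSC-H/FSC-A ratio band), then the
ALDH<sup>bright</sup>SSC<sup>low</sup> gate with the FITC cutoff placed at a
high quantile (default 0.999) of the DEAB-inhibited control tube, and CD34
positivity within the gate. The combined LSC percentage is the product of the
two gate percentages, `pct_aldh * pct_cd34 / 100`, and each sample is called
ALDH-*numerous* (> 1.9 % bright) or ALDH-*rare*.

**PDX behavior.** Engraftment efficiency (% of injected embryos with ≥ 1
fluorescent focus at 1 dpi); survival as foci counts per scored embryo with a
conjugate Gamma–Poisson posterior, Gamma(a₀ + Σc, b₀ + n), compared between
samples by disjointness of 95 % highest-density intervals (HDIs); mean
migration distances along the anteroposterior and dorsoventral axes with
percentile-bootstrap CIs; a standard deviational ellipse (center = coordinate
means, semi-axes = √(2 λᵢ) from the covariance eigendecomposition) with
bootstrap CIs; and a ten-region tropism profile with a
Dirichlet–multinomial posterior, classified *random* vs *clumped* by
simultaneous marginal-HDI comparisons.

**Integration.** A patient-by-feature matrix (clinical + gating + behavior)
standardized and fed to a from-scratch NIPALS PLS1 discriminant fit of
remission outcome (per component: w ∝ Xᵀy, t = Xw, p = Xᵀt/tᵀt,
q = yᵀt/tᵀt, deflation X ← X − tpᵀ, y ← y − tq), with explained Y-variance,
component-1 variable weights, VIP scores, and nearest-centroid class
prediction. The association tests from the same analysis tradition are
included: the exact two-sided Wilcoxon rank-sum test by full enumeration and
the Yates-corrected chi-square.

**Synthetic studies.** Every layer is generated from controllable ground
truth (`sample_profile`, `gen_study`): per-embryo foci tables, paired
DEAB+/DEAB− flow tubes with debris/doublet contamination, and clinical
records — so the whole pipeline is testable without any external data.

## Worked example

Simulate a study mirroring the reference cohort of seven patients (20,000
flow events per tube here), run the full pipeline, and inspect the results:

```r
library(zfpdx)
cfg    <- study_config(reference_profiles(), n_flow_events = 20000, seed = 42)
report <- run_pipeline(pipeline_config(study_config = cfg,
                                       bootstrap_reps = 999, seed = 42))
report$gate_table
#>   sample_id pct_viable pct_singlet pct_aldh_bright_ssclow pct_cd34_within
#> 1      LPZ6     95.035    97.84816             25.4328422        50.52854
#> 2     LPZ10     95.035    97.93760              5.3451518        29.74874
#> 3     LPZ12     94.905    97.76619              0.3017729        12.50000
#> 4     LPZ13     94.905    97.92424             37.8328940        44.79522
#> 5     LPZ15     94.965    97.89396              1.5704835        28.08219
#> 6     LPZ14     94.770    97.90546              1.7729159        68.38906
#> 7     LPZ21     95.315    98.00661             24.9906332        25.44442
#>   pct_lsc_combined  pattern
#> 1            12.85 numerous
#> 2             1.59 numerous
#> 3             0.04     rare
#> 4            16.95 numerous
#> 5             0.44     rare
#> 6             1.21     rare
#> 7             6.36 numerous
```

The viability gate strips the ~5 % simulated debris, the singlet gate the
~2 % doublets, and the recovered gate percentages track each profile's
generative ground truth (e.g. LPZ6 was simulated at 25.6 % bright with
51.1 % CD34+ within the gate: the product 12.85 % sits within sampling error
of the true 13.08 %). Per-sample behavior:

```r
report$behavior_summaries$LPZ14
#> <behavior_summary> LPZ14 (dpi 1, 202 foci)
#>   engraftment 62.5%, survival mean 29.00 foci/embryo (1 dpi), 19.43 (2 dpi)
#>   mean migration AP 1564 um, DV 266 um
#>   dispersion: clumped; preferred regions: CHT, PCV
```

This sample was generated with a CHT-weighted clump, and the
Dirichlet-posterior classification recovers it, naming CHT and the posterior
cardinal vein as credibly enriched. The integration layer fits the PLS-DA
model on the six outcome-labeled patients:

```r
report$integration$fit
#> <pls_da> NIPALS PLS1, 2 component(s), 6 patients x 25 features
#>   cumulative explained Y-variance: 79.6%, 95.8%
```

With n = 6 this fit is illustrative, not inferential — resubstitution
accuracy and explained variance on six patients are optimistic by
construction. The worked-example statistics of the reference cohort are
exact, however:

```r
wilcoxon_exact(c(60, 66), c(75, 79, 83, 92))$p.value   # 2 of 15 arrangements
#> [1] 0.1333333
chisq_yates(matrix(c(0, 2, 3, 1), 2))
#> <yates_test> Yates chi-square = 0.7500, p = 0.3865 (uncorrected 3.0000, p = 0.0833)
```

A thin command-line front end over the same functions is installed at
`inst/cli/zfpdx` (subcommands `simulate`, `gate`, `behavior`, `run`).

## Limitations

The region atlas is a schematic tiling (the anatomical literature gives no
coordinates); cohort-level published quantities that depend on the original
per-embryo raw data are not reproducible and are not attempted. See the
methods vignette (`vignettes/zfpdx-methods.Rmd`) for the modeling choices,
priors, and the exact study conditions used in the tests.
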