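# celtilr

Translational biomarker analysis for paired-biopsy window-of-opportunity
breast cancer studies.

In a window-of-opportunity trial, patients receive a single dose of a drug
between diagnosis and surgery, with a tumor biopsy at baseline and again
around day 21. The earliest readout of drug activity is not radiological
response but a change in tissue composition: effective treatment reduces
tumor cellularity and draws in lymphocytes. The **CelTIL score** condenses
both into one number per biopsy:

```
CelTIL_raw    = -0.8 x cellularity% + 1.3 x TILs%
CelTIL_scaled = (CelTIL_raw + 80) / 210 x 100        # 0-100 points
```

where cellularity is the percentage of tumor cells in the tumor area and
TILs the percentage of stromal tumor-infiltrating lymphocytes. A sample is
a **CelTIL responder** when the scaled score rises by at least 20 points
from baseline to day 21 (sensitivity cutoffs >0, >=10, >=30, >=40 are also
supported).

`celtilr` implements the full analysis around that endpoint:

- **CelTIL scoring** — raw/scaled scores, paired deltas, response calls,
  cutoff sensitivity scans.
- **Expression panel analysis** — log2 counts normalized against 7
  housekeeping genes (ACTB, MRPL19, GAPD, PSMC4, PUM1, RPLP0, SF3A1),
  nearest-centroid intrinsic subtyping by Spearman correlation,
  weighted-mean signature scores (including a single-gene ERBB2 mRNA
  score), and rank-based tertile grouping that carries reference-cohort
  cutpoints to new samples.
- **Copy-number signatures** — SEG files mapped to genes by maximal
  overlap, per-segment mean signals, linear signature scores
  (`score = sum_k coefficient_k x signal_k`), and Euclidean
  nearest-centroid assignment to four copy-number clusters.
- **Somatic variant filters** — read-support (>= 7 alt reads), assay
  sensitivity (VAF >= 5% SNV / 10% INDEL) and population-frequency
  (gnomAD AF <= 1e-4) filters, mutation frequencies and
  mutation-by-response tables.
- **Association engine** — two-sided Fisher exact tests (2x2 and
  Freeman–Halton r x c), cross-product and logistic odds ratios with Wald
  intervals and separation detection, rank-based ROC AUC, Welch/paired t
  tests, and a full **SAM** (significance analysis of microarrays)
  implementation: moderated d-statistic with a fudge factor s0 chosen on a
  percentile grid, permutation-based expected order statistics, and
  delta-threshold selection at a target FDR.
- **Synthetic cohorts** — a seeded generator producing trial-shaped
  clinical, expression, copy-number and mutation data with planted
  effects (subtype structure, an ERBB2-vs-17q12 correlation, TP53
  enrichment in basal-like tumors, a logistic response model), so every
  pipeline stage is testable without restricted patient data.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and plot helpers (`plot_celtil_change()`, `autoplot()` on SAM
fits).

## Worked example

Score a clinical table and call responders:

```r
library(celtilr)
library(tibble)

biopsies <- tribble(
  ~sample_id, ~timepoint, ~cellularity_pct, ~tils_pct,
  "PT001", "baseline", 80, 5,
  "PT001", "day21",    30, 20,
  "PT002", "baseline", 60, 10,
  "PT002", "day21",    55, 12
)
celtil_pairs(biopsies, cutoff = 20)
#> # A tibble: 2 x 6
#>   sample_id celtil_baseline celtil_day21 delta responder cutoff
#>   <chr>               <dbl>        <dbl> <dbl> <lgl>      <dbl>
#> 1 PT001                10.7         39.0 28.3  TRUE          20
#> 2 PT002                21.4         24.6  3.14 FALSE         20
```

PT001's tumor lost 50 points of cellularity and gained 15 points of TILs,
a 28.3-point CelTIL rise — a responder at the 20-point cutoff. PT002
barely moved.

Run the whole pipeline on a synthetic 77-patient cohort:

```r
bundle <- generate_cohort(cohort_config(), seed = 11)
report <- run_pipeline(bundle, n_permutations = 1000, seed = 11)
report
#> Pipeline run: 77 samples; 26 responders (33.8%) at cutoff 20
#>   mean scaled-CelTIL change: 9.95
#>   SAM significant genes: 33

glance(report$associations$sam)
#> # A tibble: 1 x 7
#>   n_genes n_significant delta    fdr   pi0    s0 n_permutations
#>     <int>         <int> <dbl>  <dbl> <dbl> <dbl>          <int>
#> 1     185            33 0.889 0.0452 0.692     0           1000
```

33 of the 185 panel genes separate CelTIL responders from non-responders
at FDR < 10%; the generator plants response-linked structure in roughly
40 genes (proliferation, luminal, basal-like, immune and ERBB2/GRB7
modules), so at n = 77 SAM recovers most of it. The report also carries
subtype calls, ERBB2-score tertiles, copy-number cluster assignments,
TP53-by-response contingency statistics and the ERBB2-vs-17q12
correlation; `sensitivity_scan(bundle)` repeats the key associations at
every response cutoff.

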