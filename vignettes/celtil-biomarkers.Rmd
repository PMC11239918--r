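---
title: "CelTIL scoring and early-response biomarker methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CelTIL scoring and early-response biomarker methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`celtilr` analyzes paired-biopsy window-of-opportunity breast cancer
studies: one drug dose between baseline and a day-21 biopsy, with early
activity read from the tissue itself. This vignette documents the models
the package implements, the conventions and numerical choices behind
them, what the synthetic cohort generator does and does not emulate, and
the known limitations.

## The CelTIL score

Each biopsy contributes two pathology percentages: tumor cellularity
(tumor cells as a share of tumor area) and stromal tumor-infiltrating
lymphocytes (TILs, scored per the International TILs Working Group
guidelines). The combined score is

$$\mathrm{CelTIL}_{raw} = -0.8\,c + 1.3\,t, \qquad c, t \in [0, 100],$$

so the theoretical range is $[-80, 130]$, and the scaled score maps that
range onto 0–100 points:

$$\mathrm{CelTIL} = \frac{\mathrm{CelTIL}_{raw} + 80}{210} \times 100.$$

Two conventions deserve note.

* **Sign of the TILs coefficient.** Reports of the score sometimes print
  the combination ambiguously ("+ −1.3 × TILs"). The defining property —
  high scores mean heavy immune infiltration with reduced cellularity —
  forces the positive sign, which is what the package uses: the score is
  strictly increasing in TILs and strictly decreasing in cellularity.
* **Scaling constants.** The affine constants are not conventionally
  printed; the package scales by the theoretical raw range (width 210),
  which maps $(-80, 130)$ to $(0, 100)$ exactly. Deltas are computed on
  the scaled score; computing them on raw scores differs only by the
  constant factor $100/210$ and changes no response call once cutoffs are
  expressed on the same scale.

A sample is a responder when the scaled score increases by at least 20
points from baseline to day 21. For the sensitivity set
$\{>0, \ge 10, \ge 20, \ge 30, \ge 40\}$, the zero cutoff is strict
(`delta > 0`) and all others inclusive — so calls at a higher cutoff
always imply calls at lower ones.

## Expression panel analysis

The package models a targeted 192-gene panel: 185 analysis genes plus 7
housekeeping genes (ACTB, MRPL19, GAPD, PSMC4, PUM1, RPLP0, SF3A1).
Counts are normalized per sample as

$$x_g = \log_2(n_g + 1) - \frac{1}{7}\sum_{h}\log_2(n_h + 1),$$

the standard housekeeping-anchored convention for counted panels. The +1
pseudocount keeps zeros finite; normalization is scale-invariant up to
the pseudocount, which matters only at very low counts.

**Subtyping** is nearest-centroid: Spearman correlation between the
normalized profile and each subtype centroid over their shared genes,
argmax wins. Spearman (rather than Pearson) is the common choice for
research-based intrinsic subtyping because it is invariant to any
monotone transform of the profile and thus robust to platform scale;
`assign_subtype(..., method = "pearson")` switches if a user's centroids
were trained on Pearson ranks. The profile must cover at least 90% of
centroid genes (configurable); exact correlation ties break
deterministically by centroid declaration order and are flagged.

**Signature scores** are weighted means over the signature's genes
present in the profile, with weights renormalized to the present genes:
$\sum_g w_g x_g / \sum_g w_g$. A single-gene signature (the ERBB2 mRNA
score) reduces to that gene's normalized value. Renormalization keeps
scores comparable when a panel drops a few genes, at the cost of assuming
the missing genes behave like the observed ones.

**Tertile grouping** carries reference-cohort boundaries to new samples.
With $n$ sorted reference scores, the low group takes ranks
$1..\lceil n/3 \rceil$, the medium group up to $\lceil 2n/3 \rceil$, the
high group the rest; at $n = 77$ this yields 26/26/25. Cutpoints are
midpoints between boundary order statistics, and new values at or below a
cutpoint fall into the lower group, so re-applying a model to its own
reference reproduces the fitted group sizes exactly.

The published centroid and signature weight values are proprietary and
not embedded; the package ships a synthetic model with the same file
schema (`synthetic_expression_model()`, written out by `write_bundle()`)
and accepts user-supplied model files.

## Copy-number signatures and clusters

Segmented copy-number profiles (SEG format; 1-based inclusive
coordinates internally, the reader tolerates the common column
dialects) pass through four stages:

1. **Gene mapping** — each gene receives the `seg.mean` of the segment
   it overlaps most, in base pairs; ties go to the segment with the
   smaller start coordinate. Maximal overlap was chosen over
   length-weighted averaging for determinism and because segment
   boundaries inside a gene are rare at panel scale.
2. **Segment signal** — the mean gene-level value over each model
   segment's member genes; segments with no observed member gene are
   missing and flagged.
3. **Signature scores** — a linear model per signature:
   $s_j = \sum_k \beta_{jk} v_k$ over segment signals $v_k$. Missing
   segments contribute zero; silently renormalizing a linear model would
   distort scores, so instead samples missing more than 20% of segments
   (configurable) raise a quality error, and a per-sample missingness
   report is attached to the result. The full published model has 519
   segments, 150 signatures and 4 cluster centroids; any consistent
   dimensions are accepted.
4. **Cluster assignment** — Euclidean distance to the four cluster
   centroids, nearest wins; ties go to the lowest-numbered cluster and
   are flagged. Whether scores are standardized before distances is
   model-file-driven (optional per-signature means/SDs); the default is
   none, since the reference method does not document standardization.

## Somatic variant filters

A variant survives when all of the following hold (all thresholds
inclusive):

* at least 7 reads support the alternate allele;
* the variant allele frequency meets the assay sensitivity — 5% for
  SNVs, 10% for INDELs (disable with `vaf_filter = FALSE`);
* it is rare in the population: gnomAD AF missing or ≤ 1e-4. The intent
  of the rule is to *remove frequent polymorphisms*; the package
  therefore keeps variants at or below the threshold.

Dropped records are attributed to the first failing rule in that order.
Filtering is idempotent and monotone: tightening any threshold can only
shrink the survivor set. Downstream, mutation frequency is the number of
distinct mutated samples over the cohort size, and
`mutation_response_table()` builds the 2×2 mutation-by-response table
(margins always sum to the cohort), flagging degenerate rows rather than
failing.

## Association statistics

* **Fisher exact tests** use the probability-mass two-sided convention:
  the p-value sums the probabilities of all margin-preserving tables no
  more probable than the observed one. 2×2 tables use the hypergeometric
  distribution, larger tables the Freeman–Halton extension; both are
  verified in the test suite against an independent enumeration oracle.
  Tables with more than 200 observations require the seeded Monte-Carlo
  fallback.
* **Odds ratios** are cross-products with Wald intervals on the log
  scale. Zero cells are flagged; the Haldane–Anscombe 0.5 correction is
  opt-in. For a saturated 2×2 design the univariate logistic MLE equals
  the cross-product ratio, which the tests confirm to six significant
  figures.
* **Logistic regression** is maximum likelihood via IRLS (tolerance
  1e-8, up to 100 iterations), one result row per covariate with
  odds-ratio-scale Wald intervals. Complete or quasi-complete separation
  is detected (non-convergence, runaway coefficients, or fitted
  probabilities saturating) and flagged instead of reported as a bare
  huge estimate.
* **ROC AUC** is the Mann–Whitney rank statistic with midranks for
  ties; for a binary predictor it equals (sensitivity + specificity)/2.
  The p-value is the tie-corrected normal approximation; the interval
  uses the Hanley–McNeil standard error. DeLong variance was not used
  because the package reports the AUC as an effect measure, not for
  paired AUC comparisons.
* **t tests** default to the Welch unpaired variant; pooled-variance and
  paired versions are flags.
* Multiplicity: FDR control applies only within SAM. Contingency and
  logistic p-values are reported raw, matching how such exploratory
  per-biomarker analyses are conventionally presented.

### SAM

The two-class SAM statistic for gene $i$ is

$$d_i = \frac{\bar{x}_{i2} - \bar{x}_{i1}}{s_i + s_0},$$

with $s_i$ the pooled standard error and $s_0$ a fudge factor that
stops low-variance genes from dominating. $s_0$ is chosen on the
percentile grid $0, 0.05, \dots, 1$ of the $s_i$ by minimizing the
coefficient of variation of window-wise $\mathrm{mad}(d)$ across
$s_i$-quantile windows (up to 100 windows, fewer for small panels).
Label permutations (all of them when the design allows fewer than the
requested number, otherwise sampled under the seed) give expected order
statistics $\bar{d}_{(i)}$; for a threshold $\Delta$, walking out from
the origin of the quantile–quantile display, the first departures
$|d_{(i)} - \bar d_{(i)}| \ge \Delta$ set the calling cutoffs, and every
gene beyond them is called.

The FDR at $\Delta$ is estimated as
$\hat\pi_0 \cdot \overline{\#\text{called in permutation}} / \#\text{called}$,
with $\hat\pi_0$ the share of observed $d_i$ inside the central 50% of
the permuted statistics. The package uses the **mean** permutation call
count rather than the median: with only a handful of called genes the
median collapses to zero too easily, and null simulations then show a
realized false-discovery proportion far above the nominal level, while
the mean keeps realized FDR within Monte-Carlo error of nominal (the
acceptance suite measures this on 50 seeded null panels of 200 genes ×
40 samples). $\Delta$ is the smallest grid value whose estimated FDR is
at or below the target (default 10%); per-gene q-values are the smallest
estimated FDR at which each gene is called.

## The synthetic cohort generator

Patient-level trial data are access-restricted, so the package ships a
generator (`generate_cohort()`) whose *defaults are the study
conditions*: they were calibrated once, by Monte Carlo at large n,
against published study-level facts, and are not meant to be tuned per
run.

* 77 patients; intrinsic subtype mixture LumA 0.57, LumB 0.20, HER2-E
  0.12, Basal 0.06, Normal 0.05 (a luminal-heavy HR+/HER2− cohort).
* Expression: per-subtype module means (proliferation, luminal,
  basal-like, immune, ERBB2/GRB7, ERBB3, inert filler) over the
  185-gene panel, gene noise SD 0.5 log2 units, counts formed around a
  housekeeping level of ~500.
* ERBB2 and 17q12: a bivariate normal latent pair with correlation 0.55;
  ERBB2 expression is deliberately subtype-neutral so the correlation is
  not diluted by subtype structure.
* TP53: Bernoulli per subtype (Basal 1.0, LumA 0.107, LumB/HER2-E 0.2,
  Normal 0.1), implying ~19% prevalence — matching the ~18% cohort fact.
* Response: logistic on (proliferation, −ERBB2, TP53) with coefficients
  (1.3, 1.2, log 4) and intercept −1.0, calibrated so the marginal
  CelTIL response rate is ≈ 34%. The effect sizes were set so that a 77-
  patient draw reproduces the published order of magnitude of the
  associations (tens of SAM genes at FDR < 10%, univariate TP53 odds
  ratio in the mid single digits).
* Day-21 biopsies: responders draw a scaled-CelTIL change from
  N(30, 8) truncated to ≥ 20 points, non-responders from N(0, 8)
  truncated below 20; the pair (cellularity, TILs) is then solved from
  the target change, splitting it between a cellularity drop and a TILs
  rise and respecting the [0, 100] box. Biopsy dynamics are
  parameterized directly on the score change because the score is the
  measured endpoint.
* Clinical response: Bernoulli at 0.55 given CelTIL response and 0.22
  otherwise, giving an overall response rate ≈ 33% and a binary-predictor
  AUC ≈ 0.68.
* Copy number: each sample's cluster follows its biology (Basal and
  high-proliferation tumors → cluster 3, HER2-E → cluster 4, luminal →
  clusters 1/2) with a 10% random reassignment, segment signals are the
  cluster's segment-level centroid plus N(0, 0.3) noise, and the 17q12
  segment carries the correlated latent. The synthetic model (40
  segments, 20 signatures, 4 centroids, fixed by its own seed) is
  reduced-scale but schema-identical to the full 519/150/4 model.
* Mutations: background genes (PIK3CA 33%, GATA3 29%, …) independent of
  response; read depths ~Poisson(500), VAFs ~Beta(6, 14); a Poisson(0.5)
  number of artifact records per sample deliberately fail each filter
  rule so the filters are exercised.

What the generator does **not** emulate: inter-gene correlation beyond
the module structure, FFPE degradation and batch effects, realistic
segment-level copy-number noise (no focal amplifications), mutation
co-occurrence patterns, and any link between clinical response and
biology other than through the CelTIL responder state. Passing tests
therefore show that the *methods* behave correctly under the planted
structure, not that the biology of a real cohort is reproduced.

## Numerical choices and degenerate inputs

* Validation errors name the offending field and sample; pairing errors
  (missing/duplicated timepoints) are distinct from range errors.
* Correlation and distance ties break deterministically (declaration
  order / lowest cluster) and are flagged, never random.
* All stochastic procedures (permutations, Monte-Carlo Fisher, the
  generator) take explicit seeds and restore the caller's RNG state.
* Problem sizes in the test suite were chosen to keep the default run
  at a few minutes: SAM null calibration uses 50 panels of 200 genes ×
  40 samples at 200 permutations; exhaustive Fisher verification covers
  every 2×2 table with total ≤ 40; parameter recovery uses 20
  replicates of n = 4000 (at that size the away-from-zero finite-sample
  bias of the logistic MLE is negligible relative to the coefficient
  standard errors, so 95% Wald intervals hold their nominal coverage;
  at n = 2000 the bias already costs 1–2 coverage points).

## Limitations

* The shipped expression and copy-number models are synthetic
  stand-ins; scientific use requires the externally licensed centroid
  and coefficient files, supplied via the documented TSV schemas.
* SAM is implemented for the two-class unpaired design only; multiclass
  designs are out of scope.
* Survival endpoints are out of scope; the package analyzes the paired
  biopsy endpoint and binary response only.
* ROC p-values use the Mann–Whitney normal approximation, which is
  conservative at very small n with heavy ties.
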