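---
title: "ehrkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ehrkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrkit)
```

This vignette documents the statistical procedures implemented in
`ehrkit`, the assumptions behind them, the conventions the package fixes
where several are defensible, and what the synthetic-data generators do
and do not emulate.

## The data model

An `ehrframe` is an annotated observations × variables container:
patient visits are rows of a value matrix `X`, measured quantities are
columns, and aligned tables (`obs`, `var`), named matrices (`layers`,
`obsm`, `varm`), pairwise relations (`obsp`) and a free-form results
store (`uns`) hang off it. The layout mirrors the annotated-matrix
convention widely used for single-cell and, increasingly, clinical data,
and the on-disk store reuses its group names (`X`, `obs`, `var`,
`layers`, `obsm`, `varm`, `obsp`, `uns`).

Two representation choices matter downstream:

* **Missing marker.** A single sentinel, `NA`, in both the numeric and
  the mixed (character-token) matrix. Categorical missingness is an
  absent token, not an explicit "missing" category, until a user encodes
  it otherwise. This gives uniform missingness counting across types.
* **Mixed mode.** While unencoded categorical/boolean/date/text columns
  are present, `X` stores the raw input tokens; it collapses to a
  `double` matrix as soon as every variable is numeric-valued. Numeric
  values written into a token matrix are formatted with 17 significant
  digits, so no precision is lost in transit; the store likewise writes
  `%.17g`, making the write/read round trip bitwise.

Type inference is deliberately simple and configurable: all-parseable →
numeric; a two-token set from {0,1}, {true,false}, {yes,no} → boolean;
ISO dates → datetime; at most `max_categories` (default 100) distinct
tokens → categorical; otherwise text.

## Missing-data mechanisms and Little's test

The package distinguishes the three standard mechanisms: MCAR
(missingness independent of data), MAR (dependent on *observed* data)
and MNAR (dependent on the unobserved value itself). `little_mcar_test()`
tests the MCAR null for a set of numeric variables: observations are
grouped by missingness pattern, the grand mean and covariance are
estimated by EM under a multivariate-normal model (tolerance `1e-6`, at
most 200 iterations, maximum-likelihood `1/n` covariance), and the sum of
pattern-wise Mahalanobis distances of observed-variable means from the
grand mean is referred to a chi-squared distribution with
$\sum_j p_j - p$ degrees of freedom.

Conventions fixed here: rows with no observed value in the selected set
are dropped (they carry no information about the pattern means); all
remaining patterns enter the statistic, including small ones — the
covariance is the EM estimate, not a per-pattern estimate, so small
patterns cause no singularity; a singular observed-submatrix still
errors, naming the pattern. The test is restricted to numeric variables.
Two caveats inherent to the test: multivariate normality is assumed, and
a non-significant result is consistent with MCAR but does not prove it.

The test's operating characteristics are verified by simulation in the
test suite: type-I error within [0.03, 0.08] at α = 0.05 over 500 MCAR
datasets (n = 500, four correlated normals, 20% missing), and power
≥ 0.8 against the default MAR injection at n = 1,000.

## Imputation

Four imputers are provided, all guaranteeing that originally observed
entries are never altered:

* explicit value and per-variable summary statistics (mean/median/mode);
* k-nearest neighbours (default k = 20): distances between incomplete
  rows are Euclidean over the jointly observed coordinates rescaled by
  $\sqrt{p/p_{\text{observed}}}$, neighbours must have the target
  observed, and the imputed value is their unweighted mean. The search
  is exact and $O(n^2)$, which is adequate at cohort sizes where KNN
  imputation is statistically sensible;
* iterative random forests in the MissForest tradition: initialize with
  mean (mode for label-encoded categoricals), loop over variables in
  increasing-missingness order, fit a forest of the variable on all
  others over its originally observed rows, re-predict the originally
  missing rows, and stop when the normalized squared change of the
  imputed values first increases (returning the previous iteration's
  values) or after `max_iter` sweeps. Label-encoded categoricals use
  classification forests. This is single imputation: one completed
  dataset, no between-imputation variance.

Mean imputation under MCAR at rate $r$ leaves the mean unbiased but
shrinks the variance by a factor $1-r$ — the imputed entries contribute
no spread — so the post-imputation standard deviation is
$\sqrt{1-r}$ times the original. Under MAR with a positive driver slope
the observed stratum is no longer exchangeable with the missing one, and
mean imputation biases the location toward the observed stratum while
still shrinking the scale; conditional imputers (KNN, forests) reduce
both distortions. All three statements are asserted on synthetic data in
the test suite.

## Normalization

Eight transforms (`log` = log1p, `maxabs`, `minmax`, Yeo-Johnson `power`
with maximum-likelihood λ followed by standardization, `quantile`
mapping onto the across-variable mean order-statistic profile with
averaged tie ranks, `robust_scale` = (x − median)/IQR, `scale` =
(x − mean)/population sd, and `offset` shifting the lowest negative
value to 0). Missing entries are excluded from fitting and left missing;
fitted parameters are returned in a normalization record and appended to
`uns`. Constant columns under scale-type transforms map to zeros with a
warning rather than erroring, since all-equal lab columns are common in
filtered EHR extracts.

The `group_key` argument fits and applies any transform independently
within groups. That is a modelling decision, not a default: scaling
within groups erases genuine between-group location differences (the
test suite demonstrates a 2-sd shift whose standardized mean difference
drops below 0.05 after group-wise scaling while joint scaling preserves
it). It is the right tool when within-group comparability is wanted and
a masking hazard otherwise.

`log` uses log1p so zeros — ubiquitous in count-like clinical variables —
remain representable; a strictly-positive-log convention can be had by
offsetting first. `scale` uses the population (1/n) standard deviation;
both choices are stated in the function documentation because results
depend on them.

## Value hygiene

Winsorization clamps each variable at the `limits` tail quantiles.
Quantiles use the inverse-empirical-CDF convention (`quantile` type 1),
i.e. order statistics: clamping at an order statistic is exactly
idempotent, whereas clamping at interpolated quantiles moves the clamp
value on re-application. Idempotence is the property a data-cleaning
step should have, so the order-statistic convention was chosen and is
asserted in the tests. `clip_features` clamps at fixed bounds and
reports how many entries moved.

## Patient landscape

`highly_variable_features` flags the top-n features by variance of the
observed values (constant features never qualify). PCA centers but does
not rescale — normalization is an explicit prior step, and silently
rescaling inside PCA would double-transform already-scaled data.
`neighbors` computes the exact k-nearest-neighbour graph (default
k = 15, Euclidean) on a chosen representation, with union-symmetrized
binary connectivities. UMAP (via `uwot`, single-threaded so a seed fixes
the result) embeds the same representation; Leiden community detection
(modularity objective) partitions the connectivity graph, with labels
relabelled contiguously from 0 by decreasing cluster size. On
well-separated groups the graph decomposes into components and Leiden
recovers them exactly at moderate resolution; as resolution → 0 a
connected graph collapses to one community — both behaviours are
exercised in the tests.

## Group feature ranking and survival statistics

`rank_features_groups` tests each group against the union of the others:
Welch t-tests for numeric features (the safer default when clinical
groups have unequal variances; the classical equal-variance t-test is a
special case the data rarely earn), and g-tests
$G = 2\sum O \ln(O/E)$ for raw categorical features, with expected
counts from the margins, observed zeros contributing 0 and
zero-expected categories dropped with a flag. Benjamini–Hochberg
correction is applied within each group across features, matching the
group-vs-rest family structure. BH is monotone (order-preserving) —
note that re-applying BH to already-adjusted values is *not* an
identity, which is why the tests assert oracle agreement and
monotonicity rather than re-application.

Survival analysis wraps the `survival` package: Kaplan–Meier
product-limit curves with Greenwood variance on the log(−log) scale (so
bands stay inside [0, 1]), log-rank tests with the standard
hypergeometric tie handling, and Cox proportional-hazards models with
Wald confidence intervals and per-observation partial hazards. The
concordance index is computed in-package over comparable pairs (the
earlier time must be an observed event; hazard ties count 1/2) with a
percentile bootstrap CI from resampling the (hazard, duration, event)
triples, 1,000 times by default; the `survival` package's concordance
serves as an independent cross-check in the tests, not as the
implementation. The KM estimator is verified exhaustively against a
hand-written product-limit oracle for every event/censor pattern up to
n = 6.

## Causal module

Effects are estimated by backdoor adjustment on a user-supplied DAG.
`backdoor_set` searches candidate sets (non-descendants of the
treatment) in increasing cardinality with lexicographic tie-breaking and
returns the first set d-separating treatment from outcome in the graph
with the treatment's outgoing edges removed; d-separation uses the
moralized-ancestral-graph construction. The estimator is OLS of the
outcome on treatment plus the adjustment set — appropriate for the
linear structural models the synthetic generator produces and the
regime the refuters probe. Six refutation checks are provided; placebo,
dummy-outcome and random-common-cause refuters average the re-estimate
over 20 draws so the refuted value reflects the mechanism rather than
one permutation's noise, and the unobserved-confounder refuter reports
a sensitivity curve over confounder strengths rather than a pass/fail —
no threshold there is principled. Pass tolerances
(`max(0.1·|reference|, 0.05)`) are configurable arguments, not
constants.

## Cohort tracking

A cohort log records, per filtering step, the population count and
distribution snapshots (category counts; numeric mean/sd/quartiles) of
tracked columns, plus a free-text reason. Snapshots deliberately store
distributions rather than row identifiers, keeping logs small and free
of patient-level data. Tracking is restricted to monotone filtering —
a growing observation set errors — because provenance of additive
operations (e.g. imputation) is owned by their own reports. Flow data
(nodes with counts, edges with exclusion counts) conserve the initial
minus final population exactly, and logs round-trip through JSON.

## The synthetic cohort generator

The generators define the study conditions under which every guarantee
in the test suite and acceptance script is evaluated:

* mixed-type cohorts: Gaussian numeric features with optional per-group
  mean shifts, multinomial categoricals, a group label;
* missingness injection: MCAR removes each entry independently at the
  given rate; MAR standardizes a complete driver to mean 0/sd 1
  (population convention), forms p = plogis(scale·z + offset) with
  defaults scale = 1.2, offset = −0.6 (an overall rate near 40%,
  strongly driver-dependent) and samples Bernoulli per row; MNAR applies
  the same logistic rule to the target's own standardized value;
* survival cohorts: exponential event times per group hazard with
  independent exponential censoring calibrated so the expected censored
  fraction equals `censor_rate`;
* linear structural causal models: ancestral sampling in topological
  order, Gaussian noise, optional treatment binarization `1{latent > 0}`
  before children consume it, with the path-product total effect
  recorded for test harnesses.

What the generators emulate: group structure, the three missingness
mechanisms with their stated parameterizations, proportional-hazard
group differences, and linear confounding. What they do not: repeated
irregular time series, non-linear effects, measurement error, coding
drift, or informative censoring. Green tests therefore certify the
statistical machinery under its stated assumptions; they do not certify
robustness to the full messiness of production EHR data.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` use simulation sizes chosen to
make each property measurable with comfortable margins on a single CPU:
500 datasets of n = 500 for Little-test calibration, n = 100,000 for the
variance-shrinkage ratio, 20 replicates of n = 1,500 for the MAR
imputation comparison, 500 replicates for log-rank null uniformity,
n = 2,000 for Cox recovery, n = 5,000 for causal recovery, and 1,000
bootstrap resamples for the concordance CI. EM tolerance is 1e-6; OLS
fits use QR with aliased-column dropping under rank deficiency (with a
warning); Yeo-Johnson λ is fitted by profile likelihood on [−5, 5].
All randomized procedures take explicit seeds and are pure functions of
(inputs, seed).

## Known limitations

* Little's test assumes multivariate normality and numeric variables;
  heavily skewed labs should be transformed first.
* KNN imputation and the neighbour graph are exact but quadratic/linear
  in memory; they target cohort-scale (≤ ~10⁵ rows), not biobank-scale,
  data.
* The causal estimator is linear; non-linear effect estimation and
  instrument/matching designs are out of scope.
* MNAR is generated and discussed but not corrected for: no
  pattern-mixture or shared-parameter models are provided, and
  sensitivity analysis is the recommended tool.
* The on-disk store is a plain-text directory using the annotated-matrix
  group layout; it is exact and diffable, but it is not an HDF5 file.
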