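# ehrkit

Exploratory analysis of electronic health record (EHR) tables in R.

Clinical care produces patient-visit tables that are wide, mixed-type
(labs, vitals, medications, demographics, dates) and riddled with
structured missingness. `ehrkit` organises such a table as an annotated
observations × variables matrix — the `ehrframe`, with rows as patient
visits and columns as measured quantities, plus aligned annotation tables
and named result slots (`layers`, `obsm`, `varm`, `obsp`, `uns`) — and
provides the analysis toolkit around it:

* **Quality control** — per-feature/per-visit missingness, winsorization,
  clipping, bias audits (pairwise correlations, standardized mean
  differences between sensitive groups, value-count deltas, feature
  importance), and **Little's MCAR test**: with observations grouped by
  missingness pattern *j* (mean vector ȳ₍obs,j₎ over the observed
  variables), the statistic

  d² = Σⱼ mⱼ (ȳ₍obs,j₎ − μ̂₍obs,j₎)ᵀ Σ̂₍obs,j₎⁻¹ (ȳ₍obs,j₎ − μ̂₍obs,j₎)

  compares pattern means against the EM-estimated grand mean μ̂ and
  covariance Σ̂; under the null that data are missing completely at random
  it is asymptotically χ² with Σⱼ pⱼ − p degrees of freedom.
* **Encoding** — lossless one-hot and label encoding of categorical and
  boolean variables, with exact `decode()`.
* **Imputation** — explicit value, mean/median/mode, k-nearest-neighbour
  (pairwise-complete distances), and iterative random-forest
  (MissForest-style) imputation.
* **Normalization** — log1p, max-abs, min-max, Yeo-Johnson power,
  quantile, robust, z-scaling and offset transforms, each optionally
  fitted per group, plus OLS covariate residualization (`regress_out`).
* **Patient landscape** — highly variable features, PCA, k-NN graph,
  UMAP embedding, Leiden clustering.
* **Inference** — group feature ranking (Welch t-tests for numeric
  features, g-tests G = 2 Σ O ln(O/E) for categorical ones,
  Benjamini–Hochberg correction), Kaplan–Meier curves Ŝ(t) = Π (1 − dᵢ/nᵢ)
  with Greenwood bands, log-rank tests, Cox proportional hazards
  h(t|x) = h₀(t) exp(xᵀβ), concordance index with a bootstrap CI, GLMs and
  likelihood-ratio model comparison.
* **Causal module** — backdoor adjustment sets by d-separation search on a
  user-supplied DAG, OLS effect estimation, and six refutation checks
  (placebo treatment, dummy outcome, random common cause, data subsets,
  unobserved-confounder sensitivity, bootstrap).
* **Cohort tracking** — an ordered provenance log of filtering steps with
  population counts, tracked-variable distributions, tableone-style
  summaries and consort-style flow data.
* **Synthetic cohorts** — generators for mixed-type cohorts with group
  structure, MCAR/MAR/MNAR missingness injection with stated logistic
  parameterizations, grouped survival cohorts and linear structural causal
  models, so every stage above is testable without any data download.

## Worked example

A synthetic pneumonia-like cohort with a severe phenotype, missingness in
C-reactive protein driven by the white-cell count (missing at random, MAR):

```r
library(ehrkit)
cfg <- cohort_config(
  600,
  numeric = list(
    crp = list(mean = 40, sd = 15, shift = c(severe = 35)),
    wbc = list(mean = 9,  sd = 2,  shift = c(severe = 4)),
    alb = list(mean = 42, sd = 5,  shift = c(severe = -7))),
  categorical = list(antibiotics = list(levels = c("yes", "no"), probs = c(0.6, 0.4))),
  group = list(name = "phenotype", levels = c("mild", "severe"), probs = c(0.7, 0.3)),
  seed = 11)
adata <- make_cohort(cfg)
adata <- inject_mar(adata, "crp", "wbc", seed = 12)

qc_metrics(adata)$var_metrics["crp", "missing_frac"]
#> 0.367
little_mcar_test(adata, variables = c("crp", "wbc", "alb"))
#> Little's MCAR test: d^2 = 154.4708, dof = 2, p = 2.865e-34 (2 patterns)
```

The MAR mechanism is correctly flagged: the missingness is *not* MCAR
(the default injection removes about 36% of entries, preferentially at
high `wbc`). Impute with iterative forests, scale, and rank the features
that characterize each phenotype:

```r
imp <- impute_missforest(encode(adata), seed = 13)
#> imputation report: method=missforest, 220 entries imputed across 1 variables
adata <- normalize(imp$frame, "scale")$frame
rk <- as.data.frame(rank_features_groups(adata, "phenotype"))
head(rk[, c("group", "feature", "test", "statistic", "pvalue", "padj")], 4)
#>   group         feature   test statistic   pvalue     padj
#> 1  mild             wbc t-test    -20.20 2.95e-57 7.38e-57
#> 2  mild             crp t-test    -19.98 1.72e-57 7.38e-57
#> 3  mild             alb t-test     16.72 6.97e-46 1.16e-45
#> 4  mild antibiotics_yes t-test     -1.08 2.81e-01 2.81e-01
```

The inflammatory markers separate the phenotypes (by construction);
antibiotics exposure does not. Survival in a matched cohort with a
hazard ratio of e^1.04 ≈ 2.8 for the severe group:

```r
sc <- simulate_survival_cohort(300, c(mild = 0.5, severe = 1.4),
                               censor_rate = 0.25, seed = 14)
sc$obs$severe <- as.integer(sc$obs$group == "severe")
cox_ph(sc, "duration", "event", "severe")$coefficients
#>   covariate coef    se   hr lower upper  p_value
#> 1    severe 1.04 0.105 2.84 0.839  1.25 2.41e-23
cc <- concordance_ci(cox_ph(sc, "duration", "event", "severe")$partial_hazards,
                     sc$obs$duration, sc$obs$event, n_boot = 1000, seed = 15)
#> C-index 0.622 (95% CI 0.600-0.644)
```

The estimated log hazard ratio (1.04 ± 0.105) covers the simulated
ln(1.4/0.5) ≈ 1.03, and the single binary covariate yields the modest
discrimination a two-group risk score can achieve.

## Documentation

The methods vignette (`vignettes/ehrkit-methods.Rmd`) describes the
statistical procedures, their assumptions, the synthetic-data generators
and the package's numerical conventions. Every exported function carries
roxygen documentation.
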