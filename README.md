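# tilscore

Percentile-based tumor-infiltrating lymphocyte scoring and survival
analysis for early-stage colon cancer cohorts.

## What it is for

In Stage I/II (node-negative) colon cancer, the density of CD3+ and
CD8+ T cells in the center of tumor (CT) and the invasive margin (IM)
carries prognostic information beyond tumor staging. The consensus
Immunoscore turns those four densities into a single score: each density
is converted to a percentile of a reference distribution, the four
percentiles are averaged, and the mean is binned with pre-defined
cut-points —

* IS3: Lo [0, 25], Int (25, 70], Hi (70, 100];
* IS5: I0 [0, 10], I1 (10, 25], I2 (25, 70], I3 (70, 95], I4 (95, 100];
* IS2: Lo [0, 25] vs Int+Hi (25, 100].

`tilscore` is a tidyverse-style reimplementation of that analysis as a
reusable, tested pipeline, for biostatisticians who want to study,
stress-test or extend it without access to patient data:

* slide-level density quantification on synthetic point-pattern slides,
  with the study's QC rules (exclusion on missing regions and on mean
  staining intensity ≤ 152 AU);
* the percentile transform, score and category assignment;
* endpoint construction — time to recurrence (TTR, deaths censor),
  disease-free survival (DFS) and overall survival (OS) — plus the
  Stage II risk-subgroup definitions (high-risk, low-risk, very
  high-risk, T4N0, untreated, MSS);
* a from-first-principles survival battery: Kaplan–Meier with Greenwood
  log(−log) intervals, the log-rank test, center-stratified Cox models
  with Efron ties (Newton–Raphson with step-halving), Harrell's
  concordance with jackknife errors, restricted mean survival time with
  the shortest-follow-up truncation rule, likelihood-ratio model
  comparison and chi-square relative-importance decomposition (the
  `survival` package is used only as a test oracle);
* a calibrated synthetic-cohort generator whose defaults reproduce the
  study conditions (n = 1885 over 14 centers, category proportions
  23.8/47.2/29.0%, per-category 5-year recurrence-free rates
  78.4/88.1/93.4%, censoring solved to a 69.5-month median follow-up,
  52.6% male, mean 19 lymph nodes examined).

The statistical core of the survival analysis is the stratified Cox
partial likelihood with Efron tie handling: for event time `t(j)` with
`d` tied deaths in a stratum,

    L_j(beta) = prod_{l=0}^{d-1} [ exp(sum_D x'beta / d) /
                (sum_{R(t_j)} e^{x'beta} - (l/d) sum_D e^{x'beta}) ]

maximized by Newton iterations; hazard ratios are `exp(beta)` with Wald
intervals, and model comparisons use twice the partial log-likelihood
difference.

## Worked example

```r
library(tilscore)

ref    <- default_reference()                      # packaged synthetic reference
cfg    <- generator_config(n_patients = 1885, seed = 418)
cohort <- generate_cohort(cfg, ref) |>
  qc_cohort() |>                                   # intensity / missing-region QC
  apply_exclusions()
scored <- score_cohort(cohort, ref) |> derive_endpoints()

dplyr::count(scored, is3)
#>   is3       n
#> 1 Lo      445
#> 2 Int     885
#> 3 Hi      555

compare_groups(scored, endpoint = "ttr", grouping = "is3", strata = "center")
#> <til_comparison> endpoint = ttr  grouping = is3  tau = 95.1 months
#> log-rank chi2 = 71.16 (df 2, p = 3.5e-16); C-index 0.643 (0.609-0.678)
#>   level     n   pct  rate rate.low rate.high    hr hr.low hr.high    wald_p
#> 1 Lo      445  23.6  78.0     73.4      81.8 1     NA      NA     NA
#> 2 Int     885  46.9  89.5     87.1      91.5 0.456  0.342   0.607  7.62e- 8
#> 3 Hi      555  29.4  94.2     91.6      96.0 0.239  0.159   0.359  4.57e-12
```

One row per score level: patient count and share, the Kaplan–Meier
recurrence-free rate at 60 months with its Greenwood interval, and the
center-stratified unadjusted hazard ratio against the Lo reference —
here the generator was left at its defaults, so the planted 5-year rates
(78.4/88.1/93.4%) and the implied hazard ratios come back out within
sampling error. Restricted-mean columns (not shown) give each level's
RMST at the common truncation time and its difference versus Lo.

The adjusted analysis and the importance display:

```r
fit <- cox_fit(scored, ttr_time, ttr_event,
               terms = c("is3", "gender", "t_stage", "msi"),
               strata = "center")
tidy(fit, exponentiate = TRUE)
#>   term       estimate std.error statistic  p.value conf.low conf.high
#> 1 is3Int        0.450     0.147    -5.44  5.30e- 8    0.338     0.600
#> 2 is3Hi         0.231     0.207    -7.05  1.74e-12    0.154     0.348
#> 3 gendermale    0.944     0.136    -0.426 6.70e- 1    0.722     1.23
#> ...

chi2_importance(fit)
#>   term    statistic    df importance
#> 1 is3        60.0       2     87.7
#> 2 gender      0.182     1      0.266
#> 3 t_stage     2.72      3      3.98
#> 4 msi         5.48      2      8.02
```

The score carries far more of the model chi-square than the clinical
covariates — the qualitative behavior the analysis is designed to
exhibit. `plot_km()`, `autoplot()` methods and `km_by_group()` provide
figures and curve exports; `run_pipeline()` (or the thin CLI in
`inst/scripts/tilscore-cli.R`) writes every subgroup × endpoint × scheme
block, a run manifest and an exclusion funnel to an output directory.

## Cohort table dictionary

One row per patient, tab-separated (`write_cohort()`/`read_cohort()`):
identifiers (`patient_id`, `cohort`, `center`), clinical covariates
(`gender`, `age`, `stage`, `t_stage`, `n_stage`, `sidedness`, `msi`,
`velipi`, `differentiation`, `perforation`, `ln_examined`,
`chemotherapy`, `preoperative_treatment`), generator ground truth
(`true_category`, `true_mean_percentile`), quantification
(`density_<marker>_<region>` in cells/mm^2, `intensity_cd3`,
`intensity_cd8` in AU), raw outcomes in months (`recurrence_time`,
`recurrence_observed`, `death_time`, `death_observed`, `censor_time`)
and, after scoring/derivation, `pct_*`, `mean_percentile`,
`is2`/`is3`/`is5` and `ttr_*`, `dfs_*`, `os_*`.
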