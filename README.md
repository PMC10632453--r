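# qrmetric

Quantitative response (QR) metric for C-peptide outcomes in type 1
diabetes disease-modifying-therapy trials.

## The problem

Trials in recently diagnosed type 1 diabetes aim to preserve endogenous
insulin secretion, measured as the 2-hour mixed-meal-tolerance-test
C-peptide AUC mean (AUC divided by 120 min, nmol/L). That outcome is
strongly predictable from two baseline covariates — age at entry and
baseline C-peptide — so unadjusted between-arm comparisons waste power
and are vulnerable to chance covariate imbalance, especially in the
small arms (n = 16–111) typical of this field.

The QR metric is a standardized, baseline-adjusted outcome: the
difference between a participant's observed and ANCOVA-predicted
ln-transformed 1-year C-peptide,

```
QR_i = ln(Cp_1year,i + 1) − 0.812 · ln(Cp_0,i + 1) − 0.00638 · Age_i + 0.191
```

QR > 0 means a better-than-expected outcome, QR < 0 worse than
expected. This package is for trial statisticians and translational
researchers who want to compute QR (including interim 3/6/9-month
analogues), refit and validate the underlying ANCOVA on their own
cohorts, classify responders, compare arms on the raw, change, and QR
scales, and run design experiments (power, interim stopping) on a
synthetic multi-trial generator.

## Worked example

```r
library(qrmetric)

d <- read_participants(system.file("extdata", "example_participants.csv",
                                   package = "qrmetric"))
compute_qr(d)
#>   participant_id timepoint predicted_ln observed_ln         qr
#> 1         ex_001        12    0.2843359   0.3364722 0.05213634
#> 2         ex_002        12    0.3587066   0.5187938 0.16008721
#> 3         ex_003        12    0.4604396   0.4762342 0.01579453
```

Participant `ex_001` (age 10, baseline 0.66 nmol/L) kept more C-peptide
at 1 year (0.40 nmol/L) than the natural-history model predicts: QR =
+0.052, slightly better than expected. A teplizumab-like synthetic
trial (44 active vs 19 control, true QR shift 0.156) shows the power
gain from covariate adjustment:

```r
cfg <- trial_config(n_active = 44, n_control = 19,
                    true_qr_shift = 0.156, seed = 7)
trial <- generate_trial(cfg)
treatment_effect(trial[trial$arm == "active", ],
                 trial[trial$arm == "control", ], outcome_scale = "qr")
#> Treatment effect on scale 'qr'
#>   active mean 0.154 (n = 44 ) vs control mean -0.0311 (n = 19 )
#>   difference 0.185 95% CI [ 0.118 , 0.252 ]
#>   Welch t = 5.62 df = 36.4 p = 2.15e-06
```

Refitting the ANCOVA on a synthetic 448-participant placebo cohort
recovers the model family with about half of outcome variance explained
by age and baseline C-peptide:

```r
summary(fit_qr_model(generate_trial(trial_config(n_active = 0,
                                                 n_control = 448), seed = 7)))
#> ANCOVA QR model fit: ln(Cp_12mo + 1) ~ ln(Cp_0mo + 1) + age
#>           estimate std_error
#> intercept  -0.1247    0.0271
#> beta_cp     0.7344    0.0363
#> beta_age    0.0046    0.0010
#> residual SD: 0.1437   R-squared: 0.4896   n: 448
```

Other entry points: `compute_interim_qr()` (3/6/9-month QR),
`validate_qr_model()` and `fit_horizon_grid()` (model transport and
baseline/horizon R² grids), `classify_responders()` and
`responder_bias_analysis()` (five responder definitions and their
age/baseline bias), `qr_percentile()` and `fit_probability_curve()`
(placebo percentiles and the weighted probability-of-effective-therapy
curve), `power_experiment()` and `interim_rule_experiment()` (design
simulations). A thin command-line wrapper lives in
`inst/scripts/qr_tool.R` (subcommands `compute-qr`, `fit-model`,
`simulate`, `power`, ...).

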