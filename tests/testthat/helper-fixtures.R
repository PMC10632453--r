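# Cohort fixtures built in code at test time.

# Placebo-only cohort drawn from the published generative model
null_cohort <- function(n = 100, seed = 1, residual_sd = 0.15, ...) {
  generate_trial(trial_config(n_active = 0, n_control = n,
                              residual_sd = residual_sd, ...),
                 seed = seed)
}

# Single active arm with a true QR shift
shifted_arm <- function(n = 30, seed = 1, shift = 0.15, ...) {
  generate_trial(trial_config(n_active = n, n_control = 0,
                              true_qr_shift = shift, ...),
                 seed = seed)
}

# Deterministic cohort lying exactly on the published ANCOVA plane
noiseless_cohort <- function(n = 60) {
  grid <- expand.grid(cp_0 = seq(0.3, 1.2, length.out = ceiling(n / 6)),
                      age_years = seq(8, 40, length.out = 6))
  grid <- grid[seq_len(n), ]
  pred <- predict(published_qr_model(), baseline_cp = grid$cp_0,
                  age = grid$age_years)
  data.frame(participant_id = sprintf("nl_%03d", seq_len(n)),
             study_id = "noiseless", arm = "control",
             age_years = grid$age_years, cp_0 = grid$cp_0,
             cp_12 = expm1(pred), stringsAsFactors = FALSE)
}

published_formula <- function(cp_0, cp_1y, age) {
  log(cp_1y + 1) - 0.812 * log(cp_0 + 1) - 0.00638 * age + 0.191
}
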