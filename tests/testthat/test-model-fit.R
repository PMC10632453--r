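test_that("noiseless data on the published plane is recovered exactly", {
  fit <- fit_qr_model(noiseless_cohort(60))
  expect_equal(unname(coef(fit)),
               c(-0.191, 0.812, 0.00638), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("fit_ancova matches a normal-equations solve on random data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(12:40, 1)
    d <- data.frame(participant_id = as.character(seq_len(n)),
                    age_years = runif(n, 5, 40),
                    cp_0 = runif(n, 0.1, 1.5),
                    cp_12 = runif(n, 0.05, 1.5))
    fit <- fit_qr_model(d)
    X <- cbind(1, log1p(d$cp_0), d$age_years)
    want <- ols_oracle(X, log1p(d$cp_12))
    expect_equal(unname(coef(fit)), unname(want), tolerance = 1e-8)
    # n - 3 residual divisor
    sse <- sum(residuals(fit)^2)
    expect_equal(fit$residual_sd, sqrt(sse / (n - 3)), tolerance = 1e-10)
    expect_equal(mean(residuals(fit)), 0, tolerance = 1e-10)
  }
})

test_that("degenerate and invalid designs are handled explicitly", {
  d <- noiseless_cohort(20)
  d$cp_12 <- 0.5  # constant outcome
  fit <- fit_qr_model(d)
  expect_equal(fit$r_squared, 0)
  expect_equal(unname(coef(fit)[c("beta_cp", "beta_age")]), c(0, 0))
  d2 <- noiseless_cohort(20)
  d2$age_years <- 12  # constant covariate -> rank deficient
  expect_error(fit_qr_model(d2), "singular")
  expect_error(fit_qr_model(noiseless_cohort(8)), "at least 10")
  d3 <- noiseless_cohort(20)
  d3$participant_id[2] <- d3$participant_id[1]
  expect_error(fit_qr_model(d3), "duplicated")
})

test_that("coefficients are recovered without bias from noisy cohorts", {
  # Monte-Carlo calibration: truth (0.812, 0.00638, -0.191), sigma 0.15,
  # outcomes drawn exactly from the linear model (no non-negativity floor)
  reps <- 50
  est <- t(vapply(seq_len(reps), function(i)
    coef(fit_qr_model(null_cohort(448, seed = 100 + i,
                                  floor_outcome = FALSE))),
    numeric(3)))
  bias <- colMeans(est) - c(-0.191, 0.812, 0.00638)
  expect_lt(abs(bias[1]), 0.01)   # intercept
  expect_lt(abs(bias[2]), 0.01)   # beta_cp
  expect_lt(abs(bias[3]), 0.0005) # beta_age
  # the default trial emulation floors Cp at 0; the truncation attenuates
  # the slope slightly but boundedly
  est_f <- t(vapply(seq_len(20), function(i)
    coef(fit_qr_model(null_cohort(448, seed = 300 + i))), numeric(3)))
  expect_lt(max(abs(colMeans(est_f) - c(-0.191, 0.812, 0.00638))), 0.04)
})

test_that("model validation emulates the cross-cohort workflow", {
  val <- null_cohort(250, seed = 21)
  dev <- null_cohort(300, seed = 22)
  v <- validate_qr_model(published_qr_model(), val, dev)
  expect_gt(v$correlation_new_vs_published_qr, 0.99)
  expect_gt(v$t_test$p_value, 0.001)
  expect_true(v$ks$statistic >= 0 && v$ks$statistic <= 1)
  # identical cohorts: t = 0, D = 0
  self <- validate_qr_model(published_qr_model(), val, val)
  expect_equal(self$t_test$statistic, 0, tolerance = 1e-12)
  expect_equal(self$ks$statistic, 0, tolerance = 1e-12)
  expect_error(validate_qr_model(published_qr_model(), val[1:2, ], dev),
               "at least 3")
})

test_that("KS statistic matches a brute-force empirical-CDF scan", {
  x <- c(0.1, 0.2, 0.3)
  y <- c(0.1, 0.2, 0.9)
  got <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))$statistic
  expect_equal(unname(got), 1 / 3, tolerance = 1e-12)
  expect_equal(ks_oracle(x, y), 1 / 3, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(17)
    b <- rnorm(23, 0.3)
    expect_equal(unname(stats::ks.test(a, b, exact = FALSE)$statistic),
                 ks_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("horizon grid reports R-squared per (baseline, horizon) cell", {
  co <- null_cohort(300, seed = 31)
  g <- fit_horizon_grid(co, baseline_months = 0,
                        horizon_months = c(3, 6, 9, 12))
  # longer horizons are harder to predict from the same baseline
  r2 <- g$r_squared[order(g$horizon_month)]
  expect_true(all(diff(r2) < 0))
  # single-cell grid equals a direct fit
  g1 <- fit_horizon_grid(co, 0, 12)
  expect_equal(g1$r_squared, fit_qr_model(co)$r_squared, tolerance = 1e-12)
  expect_equal(g1$n, fit_qr_model(co)$n_fit)
  # zero-noise cohorts give R-squared 1 in every fitted cell
  nl <- generate_trial(trial_config(n_active = 0, n_control = 40,
                                    residual_sd = 0,
                                    measurement_noise_sd = 0), seed = 5)
  g0 <- fit_horizon_grid(nl, c(0, 6), c(3, 6, 12))
  expect_true(all(abs(g0$r_squared[g0$fitted] - 1) < 1e-10))
  # small cells are flagged, not fit
  tiny <- fit_horizon_grid(co[1:5, ], 0, 12)
  expect_false(tiny$fitted)
  expect_error(fit_horizon_grid(co, 0, -3), "positive")
})

test_that("model JSON round-trips all fields", {
  f <- tempfile(fileext = ".json")
  m <- fit_qr_model(null_cohort(60, seed = 41))
  write_qr_model(m, f)
  m2 <- read_qr_model(f)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(m2$residual_sd, m$residual_sd, tolerance = 1e-12)
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-12)
  expect_identical(m2$provenance, "refit")
  pub <- read_qr_model(published_qr_model_path())
  expect_equal(coef(pub), coef(published_qr_model()))
  expect_identical(pub$provenance, "published")
})
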