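test_that("predicted ln-scale outcome matches the published equation", {
  m <- published_qr_model()
  # frozen from independent evaluation of 0.812*ln(1.73)+0.00638*16.4-0.191
  expect_equal(predict(m, baseline_cp = 0.73, age = 16.4), 0.3587066,
               tolerance = 1e-6)
  # analytic root: zero baseline and age = 0.191/0.00638 cancel exactly
  expect_equal(predict(m, baseline_cp = 0, age = 0.191 / 0.00638), 0,
               tolerance = 1e-12)
  ident <- qr_model(beta_cp = 1, beta_age = 0, intercept = 0)
  expect_equal(predict(ident, baseline_cp = c(0, 0.4, 2), age = c(5, 5, 5)),
               log1p(c(0, 0.4, 2)))
  # back-transform is floored at zero for old/low-C-peptide inputs
  expect_identical(predict(m, baseline_cp = 0, age = 5,
                           type = "cpeptide"), 0)
  expect_error(predict(m, baseline_cp = -0.1, age = 10), "non-negative")
  expect_error(predict(m, baseline_cp = 0.5, age = 0), "positive")
})

test_that("compute_qr reproduces hand-evaluated QR values", {
  d <- data.frame(participant_id = c("a", "b", "c"),
                  age_years = c(10, 16.4, 16.4),
                  cp_0 = c(0.66, 0.73, 0),
                  cp_12 = c(0.40, NA, 0))
  d$cp_12[2] <- expm1(predict(published_qr_model(), baseline_cp = 0.73,
                              age = 16.4))
  res <- compute_qr(d)
  expect_equal(res$qr[1], 0.0521363, tolerance = 1e-6)
  expect_equal(res$qr[2], 0, tolerance = 1e-12)  # observed == predicted
  expect_equal(res$qr[3], 0.191 - 0.00638 * 16.4, tolerance = 1e-12)
  expect_equal(res$observed_ln - res$predicted_ln, res$qr)
})

test_that("compute_qr errors name the missing timepoint", {
  d <- data.frame(participant_id = "a", age_years = 10, cp_0 = 0.5)
  expect_error(compute_qr(d), "month 12")
  d2 <- data.frame(participant_id = "a", age_years = 10, cp_0 = NA_real_,
                   cp_12 = 0.5)
  expect_error(compute_qr(d2), "baseline")
})

test_that("QR agrees with the printed formula on random valid inputs", {
  set.seed(42)
  n <- 1000
  d <- data.frame(participant_id = as.character(seq_len(n)),
                  age_years = runif(n, 3.5, 46.1),
                  cp_0 = runif(n, 0, 2.5),
                  cp_12 = runif(n, 0, 2.5))
  got <- compute_qr(d)$qr
  want <- published_formula(d$cp_0, d$cp_12, d$age_years)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("interim QR interpolates on the ln scale and matches at 12 months", {
  d <- data.frame(participant_id = c("a", "b"), age_years = c(10, 30),
                  cp_0 = c(0.66, 0.9), cp_6 = c(0.55, 0.8),
                  cp_12 = c(0.40, 0.7))
  expect_equal(compute_interim_qr(d, 12)$qr, compute_qr(d)$qr,
               tolerance = 1e-12)
  pred <- predict(published_qr_model(), baseline_cp = 0.66, age = 10)
  want6 <- log(1.55) - (log(1.66) + 0.5 * (pred - log(1.66)))
  expect_equal(compute_interim_qr(d, 6)$qr[1], want6, tolerance = 1e-12)
  # t -> 0: expected value -> observed baseline, so qr -> 0 at cp_t = cp_0
  d3 <- data.frame(participant_id = "a", age_years = 10, cp_0 = 0.66,
                   cp_0.01 = 0.66, cp_12 = 0.40)
  expect_lt(abs(compute_interim_qr(d3, 0.01)$qr), 1e-3)
  expect_error(compute_interim_qr(d, 0), "\\(0, 12\\]")
  expect_error(compute_interim_qr(d, 13), "\\(0, 12\\]")
})

test_that("QR is strictly decreasing in baseline C-peptide and age", {
  cp0 <- seq(0.05, 2, by = 0.05)
  d <- data.frame(participant_id = as.character(seq_along(cp0)),
                  age_years = 15, cp_0 = cp0, cp_12 = 0.5)
  expect_true(all(diff(compute_qr(d)$qr) < 0))
  ages <- seq(4, 45, by = 1)
  d2 <- data.frame(participant_id = as.character(seq_along(ages)),
                   age_years = ages, cp_0 = 0.7, cp_12 = 0.5)
  expect_true(all(diff(compute_qr(d2)$qr) < 0))
})

test_that("counterintuitive rise predictions obey the analytic boundary", {
  m <- published_qr_model()
  expect_false(detect_counterintuitive(m, age = 16.4, baseline_cp = 0.3))
  expect_true(detect_counterintuitive(m, age = 40, baseline_cp = 0.30))
  expect_false(detect_counterintuitive(m, age = 40, baseline_cp = 0.80))
  # below age 0.191/0.00638 = 29.94 the flag is false for every baseline
  grid <- expand.grid(age = seq(3.5, 29.9, length.out = 60),
                      cp = seq(0, 3, length.out = 60))
  expect_false(any(detect_counterintuitive(m, grid$age, grid$cp)))
})

test_that("visit-label matching tolerates a half-month window", {
  d <- data.frame(participant_id = "a", age_years = 10, cp_0 = 0.66,
                  cp_11.7 = 0.40)
  expect_equal(compute_qr(d)$qr, published_formula(0.66, 0.40, 10),
               tolerance = 1e-12)
  d2 <- data.frame(participant_id = "a", age_years = 10, cp_0 = 0.66,
                   cp_10 = 0.40)
  expect_error(compute_qr(d2), "month 12")
})
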