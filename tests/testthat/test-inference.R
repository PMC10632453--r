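test_that("arm summaries follow hand arithmetic", {
  # outcomes equal to model predictions: mean and SD of QR are zero
  d <- noiseless_cohort(10)
  s <- summarize_arm(d)
  expect_equal(s$mean_qr, 0, tolerance = 1e-12)
  expect_equal(s$sd_qr, 0, tolerance = 1e-12)
  # two-participant arm with qr -0.1 and +0.1
  m <- published_qr_model()
  pred <- predict(m, baseline_cp = c(0.7, 0.7), age = c(10, 10))
  d2 <- data.frame(participant_id = c("a", "b"), age_years = 10,
                   cp_0 = 0.7, cp_12 = expm1(pred + c(-0.1, 0.1)))
  s2 <- summarize_arm(d2)
  expect_equal(s2$mean_qr, 0, tolerance = 1e-10)
  expect_equal(s2$sd_qr, 0.1 * sqrt(2), tolerance = 1e-10)
  expect_true(s2$ci95_low <= s2$mean_qr && s2$mean_qr <= s2$ci95_high)
  # t-based CI with n - 1 df
  half <- qt(0.975, 1) * s2$sd_qr / sqrt(2)
  expect_equal(s2$ci95_high, half, tolerance = 1e-10)
  expect_error(summarize_arm(d2[1, , drop = FALSE]), "at least 2")
})

test_that("placebo arms generated from the model centre at QR zero", {
  co <- null_cohort(448, seed = 61)
  s <- summarize_arm(co)
  expect_lt(abs(s$mean_qr), 2 * 0.15 / sqrt(448))
})

test_that("Welch t-test matches the brute-force formula", {
  set.seed(62)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(sample(5:30, 1), 0.3, 1.4)
    want <- welch_oracle(x, y)
    tt <- t.test(x, y, var.equal = FALSE)
    expect_equal(unname(tt$statistic), want$t, tolerance = 1e-10)
    expect_equal(unname(tt$parameter), want$df, tolerance = 1e-10)
    expect_equal(tt$p.value, want$p, tolerance = 1e-10)
  }
})

test_that("treatment_effect compares arms on all three scales", {
  co <- generate_trial(trial_config(n_active = 40, n_control = 30,
                                    true_qr_shift = 0.3), seed = 63)
  act <- co[co$arm == "active", ]
  ctl <- co[co$arm == "control", ]
  for (sc in c("qr", "change_from_baseline", "cp_1y")) {
    eff <- treatment_effect(act, ctl, outcome_scale = sc)
    expect_equal(eff$mean_difference, eff$mean_active - eff$mean_control,
                 tolerance = 1e-12)
    expect_true(eff$welch_df >= min(nrow(act), nrow(ctl)) - 1 &&
                  eff$welch_df <= nrow(act) + nrow(ctl) - 2)
    # agreement with an independent Welch computation
    x <- qrmetric:::outcome_values(act, published_qr_model(), sc)
    y <- qrmetric:::outcome_values(ctl, published_qr_model(), sc)
    want <- welch_oracle(x, y)
    expect_equal(eff$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(eff$p_value, want$p, tolerance = 1e-10)
  }
  # identical arms: t = 0, p = 1
  ctl2 <- ctl
  ctl2$participant_id <- paste0(ctl2$participant_id, "_copy")
  eff0 <- treatment_effect(ctl2, ctl, outcome_scale = "qr")
  expect_equal(eff0$t_statistic, 0, tolerance = 1e-12)
  expect_equal(eff0$p_value, 1, tolerance = 1e-12)
  expect_error(treatment_effect(act, act), "both arms")
})

test_that("one-sample mean-QR test behaves at the degenerate corners", {
  d <- noiseless_cohort(10)
  res <- test_mean_qr_zero(d)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # nonzero constant QR: limiting p of 0 with a flag
  m <- published_qr_model()
  pred <- predict(m, baseline_cp = rep(0.7, 5), age = rep(10, 5))
  d2 <- data.frame(participant_id = letters[1:5], age_years = 10,
                   cp_0 = 0.7, cp_12 = expm1(pred + 0.2))
  res2 <- test_mean_qr_zero(d2)
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)
  # ordinary arm agrees with t.test
  co <- null_cohort(60, seed = 64)
  res3 <- test_mean_qr_zero(co)
  tt <- t.test(compute_qr(co)$qr, mu = 0)
  expect_equal(res3$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("one-sample test holds its type-I error and matches power theory", {
  reps <- 400
  n <- 30
  rej <- vapply(seq_len(reps), function(i)
    test_mean_qr_zero(null_cohort(n, seed = 7000 + i))$p_value < 0.05,
    logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.10)
  # shifted arms: simulated power within MC error of the noncentral-t form
  rej_s <- vapply(seq_len(reps), function(i)
    test_mean_qr_zero(shifted_arm(n, seed = 8000 + i,
                                  shift = -0.072))$p_value < 0.05,
    logical(1))
  ncp <- -0.072 / (0.15 / sqrt(n))
  tcrit <- qt(0.975, n - 1)
  power <- pt(-tcrit, n - 1, ncp) + 1 - pt(tcrit, n - 1, ncp)
  expect_lt(abs(mean(rej_s) - power), 4 * sqrt(power * (1 - power) / reps))
})

test_that("biomarker correlations contrast raw outcome against QR", {
  co <- null_cohort(200, seed = 65)
  qr <- compute_qr(co)$qr
  # biomarker = qr exactly: perfect correlation with QR
  assoc <- biomarker_association(qr, co)
  expect_equal(assoc$r[assoc$association == "qr"], 1, tolerance = 1e-12)
  # age-proxy biomarker: attenuated correlation with QR vs raw outcome
  set.seed(66)
  bm <- -co$age_years + rnorm(nrow(co), 0, 4)
  assoc2 <- biomarker_association(bm, co)
  expect_lt(abs(assoc2$r[assoc2$association == "qr"]),
            abs(assoc2$r[assoc2$association == "ln_cp_1y"]))
  # three-point fixture against the definitional Pearson formula
  d3 <- noiseless_cohort(3)
  bm3 <- c(1, 3, 2)
  a3 <- biomarker_association(bm3, d3)
  expect_equal(a3$r[a3$association == "age"],
               pearson_oracle(bm3, d3$age_years), tolerance = 1e-12)
  expect_error(biomarker_association(rep(1, nrow(co)), co), "constant")
  expect_error(biomarker_association(bm[1:10], co), "one value per")
})

test_that("QR has smaller spread than the ln outcome in every trial", {
  multi <- generate_multi_trial(seed = 67)
  ctl <- multi[multi$arm == "control", ]
  for (sid in unique(ctl$study_id)) {
    arm <- ctl[ctl$study_id == sid, ]
    expect_lt(sd(compute_qr(arm)$qr), sd(log1p(arm$cp_12)), label = sid)
  }
})

test_that("cross-trial summary covers every study x arm cell", {
  multi <- generate_multi_trial(seed = 68)
  tab <- cross_trial_summary(multi)
  expect_equal(nrow(tab), 26)
  expect_true(all(tab$ci95_low <= tab$mean_qr & tab$mean_qr <= tab$ci95_high))
  expect_true(all(!is.na(tab$qr_difference)))
})
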