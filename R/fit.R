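#' Fit an ANCOVA QR model to control-arm data
#'
#' Ordinary-least-squares fit of `ln(Cp_horizon + 1) ~ ln(Cp_baseline + 1)
#' + age`, the model family behind the QR metric. Fitting is intended for
#' placebo/control participants only (the natural-history cohort); pass a
#' control-restricted table. Complete cases for the two required timepoints
#' are used; the residual SD uses an `n - 3` divisor (three estimated
#' parameters).
#'
#' @param data Participant table with `participant_id`, `age_years`,
#'   `cp_<baseline_month>` and `cp_<baseline_month + horizon_month>`
#'   columns.
#' @param baseline_month Month of the baseline covariate measurement
#'   (default 0, treatment initiation).
#' @param horizon_month Months from baseline to the predicted outcome
#'   (default 12).
#' @param min_n Minimum number of complete cases (default 10).
#' @return An object of classes `qr_fit` and `qr_model`: the fitted model
#'   plus `coefficient_standard_errors`, per-participant `residuals`
#'   (named by participant id) and the underlying `lm` fit.
#' @examples
#' cohort <- generate_trial(trial_config(n_active = 0, n_control = 60,
#'                                       seed = 1))
#' fit <- fit_qr_model(cohort)
#' coef(fit)
#' @export
fit_qr_model <- function(data, baseline_month = 0, horizon_month = 12,
                         min_n = 10) {
  if (horizon_month <= 0) stop("horizon_month must be positive", call. = FALSE)
  bcol <- cp_column(data, baseline_month)
  hcol <- cp_column(data, baseline_month + horizon_month)
  if (anyDuplicated(data[["participant_id"]]))
    stop("duplicated participant ids in fitting data", call. = FALSE)
  keep <- !is.na(data[[bcol]]) & !is.na(data[[hcol]]) &
    !is.na(data[["age_years"]])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    stop("need at least ", min_n, " complete cases to fit (have ", n, ")",
         call. = FALSE)
  df_fit <- data.frame(y = log1p(d[[hcol]]), lcp = log1p(d[[bcol]]),
                       age = d[["age_years"]])
  X <- cbind(1, df_fit$lcp, df_fit$age)
  if (qr(X)$rank < 3L)
    stop("singular ANCOVA design (constant covariate?)", call. = FALSE)
  fit <- stats::lm(y ~ lcp + age, data = df_fit)
  # summary.lm warns on exact-fit data (legitimate here: noiseless cohorts)
  sm <- suppressWarnings(summary(fit))
  sst <- sum((df_fit$y - mean(df_fit$y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  cf <- stats::coef(fit)
  # constant outcome: report an exactly-zero-slope model
  if (sst == 0) cf[2:3] <- 0
  m <- qr_model(beta_cp = cf[["lcp"]], beta_age = cf[["age"]],
                intercept = cf[["(Intercept)"]],
                residual_sd = sm$sigma, r_squared = r2, n_fit = n,
                baseline_month = baseline_month,
                horizon_month = horizon_month, provenance = "refit")
  m$coefficient_standard_errors <- sm$coefficients[, "Std. Error"]
  m$residuals <- stats::setNames(stats::residuals(fit),
                                 as.character(d[["participant_id"]]))
  m$lm_fit <- fit
  class(m) <- c("qr_fit", "qr_model")
  m
}

#' @export
residuals.qr_fit <- function(object, ...) object$residuals

#' @export
summary.qr_fit <- function(object, ...) {
  out <- list(coefficients = cbind(
    estimate = object$coefficients,
    std_error = object$coefficient_standard_errors),
    residual_sd = object$residual_sd, r_squared = object$r_squared,
    n = object$n_fit, baseline_month = object$baseline_month,
    horizon_month = object$horizon_month)
  class(out) <- "summary.qr_fit"
  out
}

#' @export
print.summary.qr_fit <- function(x, digits = 4, ...) {
  cat("ANCOVA QR model fit: ln(Cp_", x$baseline_month + x$horizon_month,
      "mo + 1) ~ ln(Cp_", x$baseline_month, "mo + 1) + age\n", sep = "")
  print(round(x$coefficients, digits))
  cat("residual SD:", format(x$residual_sd, digits = digits),
      "  R-squared:", format(x$r_squared, digits = digits),
      "  n:", x$n, "\n")
  invisible(x)
}

#' Validate a published QR model against a new cohort
#'
#' Refits the ANCOVA on the validation cohort's control participants and
#' compares: (i) per-participant Pearson correlation between refit QR and
#' published-model QR in the validation cohort; (ii) Welch two-sample
#' t-test and two-sample Kolmogorov-Smirnov test comparing the
#' published-model QR distributions of the validation and development
#' cohorts. A model transports well when r is near 1 and neither test
#' finds a distributional difference.
#'
#' @param published A [qr_model] to validate (typically
#'   [published_qr_model()]).
#' @param validation_data,development_data Control-arm participant tables.
#' @return A list of class `qr_validation`: `correlation` (refit vs
#'   published QR), `refit` model, `mean_qr_published_model` per cohort,
#'   `t_test` (statistic, Welch df, p) and `ks` (statistic D, p).
#' @export
validate_qr_model <- function(published, validation_data, development_data) {
  if (nrow(validation_data) < 3 || nrow(development_data) < 3)
    stop("need at least 3 participants in each cohort", call. = FALSE)
  refit <- fit_qr_model(validation_data,
                        baseline_month = published$baseline_month,
                        horizon_month = published$horizon_month,
                        min_n = 3)
  qr_pub_val <- compute_qr(validation_data, published)$qr
  qr_new_val <- compute_qr(validation_data, refit)$qr
  qr_pub_dev <- compute_qr(development_data, published)$qr
  r <- stats::cor(qr_new_val, qr_pub_val, use = "complete.obs")
  tt <- welch_or_degenerate(qr_pub_val, qr_pub_dev)
  ks <- suppressWarnings(stats::ks.test(qr_pub_val, qr_pub_dev,
                                        exact = FALSE))
  structure(list(
    correlation_new_vs_published_qr = unname(r),
    refit = refit,
    mean_qr_published_model = c(validation = mean(qr_pub_val, na.rm = TRUE),
                                development = mean(qr_pub_dev, na.rm = TRUE)),
    t_test = tt,
    ks = list(statistic = unname(ks$statistic), p_value = unname(ks$p.value))
  ), class = "qr_validation")
}

# Welch two-sample t-test that degrades gracefully when both samples are
# identical/constant (t = 0, p = 1 by convention).
welch_or_degenerate <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  degenerate = TRUE))
    return(list(statistic = Inf, df = NA_real_, p_value = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), degenerate = FALSE)
}

#' @export
print.qr_validation <- function(x, digits = 3, ...) {
  cat("QR model validation\n")
  cat("  refit-vs-published QR correlation r =",
      format(x$correlation_new_vs_published_qr, digits = digits), "\n")
  cat("  mean published-model QR: validation",
      format(x$mean_qr_published_model[["validation"]], digits = digits),
      "/ development",
      format(x$mean_qr_published_model[["development"]], digits = digits),
      "\n")
  cat("  Welch t =", format(x$t_test$statistic, digits = digits),
      "(df", format(x$t_test$df, digits = digits), "), p =",
      format(x$t_test$p_value, digits = digits), "\n")
  cat("  KS D =", format(x$ks$statistic, digits = digits), ", p =",
      format(x$ks$p_value, digits = digits), "\n")
  invisible(x)
}

#' Fit ANCOVA models over a grid of baseline months and horizons
#'
#' One [fit_qr_model()] per (baseline month, prediction horizon) pair with
#' `horizon > 0`, reporting R-squared and the number of complete cases per
#' cell. Cells with fewer than `min_n` complete cases are flagged and not
#' fitted. Predictions further from the baseline measurement explain less
#' outcome variance, so R-squared decreases as the horizon grows for a
#' fixed baseline.
#'
#' @param data Control-arm participant table with longitudinal
#'   `cp_<month>` columns.
#' @param baseline_months,horizon_months Numeric vectors of months; each
#'   pair is interpreted as covariates at `baseline` predicting the
#'   outcome at `baseline + horizon`.
#' @param min_n Minimum complete cases per cell (default 10).
#' @return A data frame of class `qr_horizon_grid` with columns
#'   `baseline_month`, `horizon_month`, `outcome_month`, `n`, `r_squared`,
#'   `fitted`, and the fitted models in `attr(, "models")`.
#' @export
fit_horizon_grid <- function(data, baseline_months = c(0, 3, 6, 9, 12),
                             horizon_months = c(3, 6, 9, 12, 18, 24),
                             min_n = 10) {
  if (any(horizon_months <= 0))
    stop("prediction horizons must be positive months", call. = FALSE)
  grid <- expand.grid(baseline_month = baseline_months,
                      horizon_month = horizon_months)
  grid$outcome_month <- grid$baseline_month + grid$horizon_month
  grid$n <- NA_integer_
  grid$r_squared <- NA_real_
  grid$fitted <- FALSE
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    b <- grid$baseline_month[i]
    o <- grid$outcome_month[i]
    bcol <- cp_column(data, b, required = FALSE)
    ocol <- cp_column(data, o, required = FALSE)
    if (is.na(bcol) || is.na(ocol)) next
    n <- sum(!is.na(data[[bcol]]) & !is.na(data[[ocol]]) &
               !is.na(data[["age_years"]]))
    grid$n[i] <- n
    if (n < min_n) next
    m <- fit_qr_model(data, baseline_month = b,
                      horizon_month = grid$horizon_month[i], min_n = min_n)
    grid$r_squared[i] <- m$r_squared
    grid$fitted[i] <- TRUE
    models[[i]] <- m
  }
  attr(grid, "models") <- models
  class(grid) <- c("qr_horizon_grid", "data.frame")
  grid
}

#' @export
print.qr_horizon_grid <- function(x, digits = 2, ...) {
  cat("ANCOVA R-squared by baseline month (rows) x horizon month (cols):\n")
  m <- tapply(x$r_squared, list(x$baseline_month, x$horizon_month), mean)
  print(round(m, digits))
  invisible(x)
}

#' Write / read a QR model as a flat JSON file
#'
#' Serialises all model fields (coefficients, residual SD, R-squared, fit
#' n, baseline/horizon months, provenance) as a flat key-value JSON object
#' so a model can be shipped with, or loaded into, an analysis without
#' refitting.
#'
#' @param model A [qr_model].
#' @param path File path.
#' @return `write_qr_model` returns `path` invisibly; `read_qr_model`
#'   returns a [qr_model].
#' @export
write_qr_model <- function(model, path) {
  x <- list(
    beta_cp = model$coefficients[["beta_cp"]],
    beta_age = model$coefficients[["beta_age"]],
    intercept = model$coefficients[["intercept"]],
    residual_sd = model$residual_sd,
    r_squared = model$r_squared,
    n_fit = model$n_fit,
    baseline_month = model$baseline_month,
    horizon_month = model$horizon_month,
    provenance = model$provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_qr_model
#' @export
read_qr_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  qr_model(beta_cp = x$beta_cp, beta_age = x$beta_age,
           intercept = x$intercept, residual_sd = num_or_na(x$residual_sd),
           r_squared = num_or_na(x$r_squared),
           n_fit = if (is.null(x$n_fit)) NA_integer_ else as.integer(x$n_fit),
           baseline_month = x$baseline_month,
           horizon_month = x$horizon_month,
           provenance = x$provenance)
}
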