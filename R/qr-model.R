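#' Construct a QR (quantitative response) model
#'
#' A QR model is an ANCOVA prediction rule for the ln-transformed 1-year
#' 2-hour C-peptide AUC mean (nmol/L):
#' \deqn{\widehat{\ln}(Cp_h + 1) = \beta_{cp} \ln(Cp_0 + 1) + \beta_{age}
#'   \cdot Age + \beta_0}
#' The QR of a participant is the observed minus predicted value on that
#' scale; values above zero indicate a better-than-expected C-peptide
#' outcome, values below zero a worse-than-expected one.
#'
#' @param beta_cp Coefficient on `ln(Cp_baseline + 1)` (dimensionless).
#' @param beta_age Coefficient on age (per year of age at study entry).
#' @param intercept Intercept of the prediction, ln(nmol/L + 1) scale.
#' @param residual_sd Residual standard deviation of the fit on the ln
#'   scale (`NA` if unknown).
#' @param r_squared Fraction of outcome variance explained, in `[0, 1]`.
#' @param n_fit Number of participants the model was fitted on.
#' @param baseline_month Month (from treatment initiation) of the baseline
#'   C-peptide measurement used as covariate.
#' @param horizon_month Month of the predicted outcome, counted from the
#'   baseline measurement.
#' @param provenance `"published"` or `"refit"`.
#'
#' @return An object of class `qr_model`.
#' @seealso [published_qr_model()], [fit_qr_model()], [compute_qr()]
#' @export
qr_model <- function(beta_cp, beta_age, intercept, residual_sd = NA_real_,
                     r_squared = NA_real_, n_fit = NA_integer_,
                     baseline_month = 0, horizon_month = 12,
                     provenance = c("refit", "published")) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(beta_cp), is.numeric(beta_age), is.numeric(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  if (!is.na(residual_sd) && residual_sd < 0)
    stop("residual_sd must be non-negative", call. = FALSE)
  if (horizon_month <= 0)
    stop("horizon_month must be a positive number of months", call. = FALSE)
  structure(
    list(
      coefficients = c(intercept = unname(intercept),
                       beta_cp = unname(beta_cp),
                       beta_age = unname(beta_age)),
      residual_sd = unname(residual_sd),
      r_squared = unname(r_squared),
      n_fit = unname(n_fit),
      baseline_month = baseline_month,
      horizon_month = horizon_month,
      provenance = provenance
    ),
    class = "qr_model"
  )
}

#' The published QR model
#'
#' The ANCOVA model underlying the QR metric as published for recent-onset
#' type 1 diabetes trials:
#' `QR = ln(Cp_1year + 1) - 0.812 * ln(Cp_0 + 1) - 0.00638 * Age + 0.191`,
#' i.e. predicted `ln(Cp_1year + 1) = 0.812 * ln(Cp_0 + 1) +
#' 0.00638 * Age - 0.191`, with baseline within 3 months of diagnosis and a
#' 12-month prediction horizon (development-cohort R-squared 53%).
#'
#' @return A `qr_model` with `provenance = "published"`.
#' @examples
#' m <- published_qr_model()
#' predict(m, baseline_cp = 0.73, age = 16.4)
#' @export
published_qr_model <- function() {
  qr_model(beta_cp = 0.812, beta_age = 0.00638, intercept = -0.191,
           residual_sd = NA_real_, r_squared = 0.53, n_fit = NA_integer_,
           baseline_month = 0, horizon_month = 12, provenance = "published")
}

#' @export
print.qr_model <- function(x, digits = 4, ...) {
  cat("QR model (", x$provenance, ")\n", sep = "")
  cat("  predicted ln(Cp_", x$horizon_month, "mo + 1) = ",
      format(x$coefficients[["beta_cp"]], digits = digits),
      " * ln(Cp_", x$baseline_month, "mo + 1) + ",
      format(x$coefficients[["beta_age"]], digits = digits), " * age ",
      ifelse(x$coefficients[["intercept"]] < 0, "- ", "+ "),
      format(abs(x$coefficients[["intercept"]]), digits = digits), "\n",
      sep = "")
  if (!is.na(x$residual_sd))
    cat("  residual SD (ln scale):", format(x$residual_sd, digits = digits),
        "\n")
  if (!is.na(x$r_squared))
    cat("  R-squared:", format(x$r_squared, digits = digits), "\n")
  if (!is.na(x$n_fit)) cat("  fitted on n =", x$n_fit, "\n")
  invisible(x)
}

#' @export
coef.qr_model <- function(object, ...) object$coefficients

#' Predict the ln-scale (or back-transformed) C-peptide outcome
#'
#' Evaluates the model's linear predictor
#' `beta_cp * ln(baseline_cp + 1) + beta_age * age + intercept`.
#' With `type = "cpeptide"` the prediction is back-transformed with
#' `exp(x) - 1` and floored at 0, since a C-peptide concentration cannot be
#' negative (the floor only affects reporting; QR is always computed on the
#' unfloored ln scale).
#'
#' @param object A [qr_model].
#' @param newdata Optional participant table with columns `age_years` and
#'   `cp_<baseline_month>`; if supplied, `baseline_cp` and `age` are taken
#'   from it.
#' @param baseline_cp Baseline 2-h C-peptide AUC mean, nmol/L (>= 0).
#' @param age Age at study entry in years (> 0).
#' @param type `"ln"` for the ln(Cp + 1)-scale prediction, `"cpeptide"`
#'   for the floored back-transform in nmol/L.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qr_model <- function(object, newdata = NULL, baseline_cp = NULL,
                             age = NULL, type = c("ln", "cpeptide"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    baseline_cp <- newdata[[cp_column(newdata, object$baseline_month)]]
    age <- newdata[["age_years"]]
  }
  check_cp_age(baseline_cp, age)
  b <- object$coefficients
  pred <- b[["beta_cp"]] * log1p(baseline_cp) + b[["beta_age"]] * age +
    b[["intercept"]]
  if (type == "cpeptide") pmax(expm1(pred), 0) else pred
}

check_cp_age <- function(baseline_cp, age) {
  if (is.null(baseline_cp) || is.null(age))
    stop("baseline C-peptide and age are both required", call. = FALSE)
  if (any(baseline_cp < 0, na.rm = TRUE))
    stop("baseline C-peptide must be non-negative (nmol/L)", call. = FALSE)
  if (any(age <= 0, na.rm = TRUE))
    stop("age must be positive (years)", call. = FALSE)
  invisible(TRUE)
}

# Match a nominal month to a cp_<month> column within +/- 0.5 month
# (trial visit windows); error names the timepoint when nothing matches.
cp_column <- function(data, month, tol = 0.5, required = TRUE) {
  nms <- grep("^cp_", names(data), value = TRUE)
  months <- suppressWarnings(as.numeric(sub("^cp_", "", nms)))
  ok <- which(!is.na(months) & abs(months - month) <= tol)
  if (!length(ok)) {
    if (required)
      stop("no C-peptide measurement column for month ", month,
           " (within +/-", tol, " month)", call. = FALSE)
    return(NA_character_)
  }
  nms[ok[which.min(abs(months[ok] - month))]]
}

#' Compute the quantitative response (QR)
#'
#' QR is the observed minus model-predicted ln-transformed C-peptide at the
#' model's prediction horizon:
#' `QR = ln(Cp_horizon + 1) - beta_cp * ln(Cp_0 + 1) - beta_age * Age -
#' intercept`. For the published model this is
#' `ln(Cp_1year + 1) - 0.812 * ln(Cp_0 + 1) - 0.00638 * Age + 0.191`.
#' Positive QR means a better-than-expected outcome.
#'
#' @param data Participant table: one row per participant with columns
#'   `participant_id`, `age_years`, `cp_0` (baseline, nmol/L) and
#'   `cp_<horizon>` (e.g. `cp_12`).
#' @param model A [qr_model]; defaults to the published model.
#' @return A data frame with `participant_id`, `timepoint`, `predicted_ln`,
#'   `observed_ln` and `qr`. Rows with a missing horizon measurement get
#'   `NA` QR (a warning reports how many).
#' @examples
#' d <- data.frame(participant_id = "p1", age_years = 10,
#'                 cp_0 = 0.66, cp_12 = 0.40)
#' compute_qr(d)  # QR = 0.0521
#' @export
compute_qr <- function(data, model = published_qr_model()) {
  bcol <- cp_column(data, model$baseline_month)
  hcol <- cp_column(data, model$baseline_month + model$horizon_month)
  if (any(is.na(data[[bcol]])))
    stop("baseline C-peptide (", bcol, ") is missing for ",
         sum(is.na(data[[bcol]])), " row(s)", call. = FALSE)
  if (any(data[[hcol]] < 0, na.rm = TRUE))
    stop("C-peptide values must be non-negative (", hcol, ")", call. = FALSE)
  predicted <- predict(model, baseline_cp = data[[bcol]],
                       age = data[["age_years"]])
  observed <- log1p(data[[hcol]])
  if (anyNA(observed))
    warning(sum(is.na(observed)), " row(s) missing the month ",
            model$baseline_month + model$horizon_month,
            " measurement; QR set to NA", call. = FALSE)
  data.frame(
    participant_id = as.character(data[["participant_id"]]),
    timepoint = model$baseline_month + model$horizon_month,
    predicted_ln = unname(predicted),
    observed_ln = unname(observed),
    qr = unname(observed - predicted),
    stringsAsFactors = FALSE
  )
}

#' Compute interim QR at a timepoint before the model horizon
#'
#' Because the model is linear on the ln(Cp + 1) scale, the expected value
#' at an interim month `t` is taken as the linear-in-time interpolation
#' between the observed baseline and the model's horizon prediction:
#' `E_t = ln(Cp_0 + 1) + (t / horizon) * (predicted_ln - ln(Cp_0 + 1))`,
#' and interim QR is `ln(Cp_t + 1) - E_t`. At `t = horizon` this equals
#' [compute_qr()] exactly.
#'
#' @inheritParams compute_qr
#' @param timepoint Months from treatment initiation, in
#'   `(0, horizon_month]`.
#' @return A data frame as in [compute_qr()] with `timepoint` set to `t`.
#' @export
compute_interim_qr <- function(data, timepoint, model = published_qr_model()) {
  h <- model$horizon_month
  if (timepoint <= 0 || timepoint > h)
    stop("interim timepoint must lie in (0, ", h, "] months", call. = FALSE)
  bcol <- cp_column(data, model$baseline_month)
  tcol <- cp_column(data, model$baseline_month + timepoint)
  predicted_h <- predict(model, baseline_cp = data[[bcol]],
                         age = data[["age_years"]])
  l0 <- log1p(data[[bcol]])
  expected_t <- l0 + (timepoint / h) * (predicted_h - l0)
  observed <- log1p(data[[tcol]])
  data.frame(
    participant_id = as.character(data[["participant_id"]]),
    timepoint = timepoint,
    predicted_ln = unname(expected_t),
    observed_ln = unname(observed),
    qr = unname(observed - expected_t),
    stringsAsFactors = FALSE
  )
}

#' Flag counterintuitive model predictions
#'
#' The QR model can forecast a (slight) C-peptide rise for older
#' individuals with low baseline C-peptide: the prediction exceeds the
#' baseline on the ln scale whenever
#' `ln(Cp_0 + 1) < (beta_age * age + intercept) / (1 - beta_cp)`.
#' This flags such (age, baseline) pairs; for the published model the flag
#' is provably false for every age below `0.191 / 0.00638` (about 29.94
#' years) whatever the baseline.
#'
#' @param model A [qr_model].
#' @param age Age in years (vectorised).
#' @param baseline_cp Baseline C-peptide, nmol/L (vectorised).
#' @return Logical vector: `TRUE` where the model predicts a rise over
#'   baseline.
#' @export
detect_counterintuitive <- function(model, age, baseline_cp) {
  check_cp_age(baseline_cp, age)
  predict(model, baseline_cp = baseline_cp, age = age) > log1p(baseline_cp)
}
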