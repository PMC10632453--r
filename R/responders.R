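#' Responder definitions for C-peptide preservation
#'
#' The five deterministic responder rules compared by the package. Four
#' are decline-based definitions from the trial literature; the fifth is
#' the QR-based rule.
#'
#' \describe{
#'   \item{intertest_sd}{change from baseline is non-negative, or negative
#'     by no more than one inter-test SD (0.087 nmol/L).}
#'   \item{pct7_5}{C-peptide decline of no more than 7.5\% below baseline.}
#'   \item{pct40}{less than 40\% loss of baseline C-peptide (strict).}
#'   \item{cv}{non-negative change, or negative change with a two-point
#'     duplicate-measurement coefficient of variation below 0.097, where
#'     CV = |Cp_1y - Cp_0| / (sqrt(2) * mean(Cp_0, Cp_1y)).}
#'   \item{qr_positive}{QR strictly greater than 0.}
#' }
#'
#' @return A data frame with columns `name`, `parameter`, `description`.
#' @export
responder_definitions <- function() {
  data.frame(
    name = c("intertest_sd", "pct7_5", "pct40", "cv", "qr_positive"),
    parameter = c(0.087, 0.075, 0.40, 0.097, 0),
    description = c(
      "decline no more than one inter-test SD (0.087 nmol/L)",
      "decline no more than 7.5% of baseline",
      "loss of baseline C-peptide < 40%",
      "non-negative change or two-point CV < 0.097",
      "QR > 0"),
    stringsAsFactors = FALSE
  )
}

#' Classify a participant under one responder definition
#'
#' Vectorised over participants. Decline thresholds are inclusive ("no
#' more than") except the 40\%-loss rule, which is strict ("< 40\% loss");
#' the QR rule requires strictly positive QR. The CV rule's degenerate
#' case `Cp_0 = Cp_1y = 0` is a responder (zero change, no division
#' performed).
#'
#' @param definition One of `"intertest_sd"`, `"pct7_5"`, `"pct40"`,
#'   `"cv"`, `"qr_positive"`.
#' @param cp_0,cp_1y Baseline and outcome C-peptide, nmol/L (>= 0).
#' @param qr QR values (required only for `"qr_positive"`).
#' @return Logical vector of responder calls.
#' @examples
#' classify_responder("intertest_sd", cp_0 = 0.70, cp_1y = 0.62)  # TRUE
#' classify_responder("qr_positive", qr = 0)                      # FALSE
#' @export
classify_responder <- function(definition, cp_0 = NULL, cp_1y = NULL,
                               qr = NULL) {
  definition <- match.arg(definition, responder_definitions()$name)
  if (definition == "qr_positive") {
    if (is.null(qr)) stop("qr values required for the QR>0 definition",
                          call. = FALSE)
    return(qr > 0)
  }
  if (is.null(cp_0) || is.null(cp_1y))
    stop("cp_0 and cp_1y required for definition '", definition, "'",
         call. = FALSE)
  if (any(cp_0 < 0, na.rm = TRUE) || any(cp_1y < 0, na.rm = TRUE))
    stop("C-peptide values must be non-negative", call. = FALSE)
  change <- cp_1y - cp_0
  switch(definition,
    intertest_sd = change >= -0.087,
    pct7_5 = cp_1y >= (1 - 0.075) * cp_0,
    pct40 = cp_1y > (1 - 0.40) * cp_0,
    cv = {
      cv2 <- abs(change) / (sqrt(2) * (cp_0 + cp_1y) / 2)
      change >= 0 | (change < 0 & cv2 < 0.097)
    })
}

#' Classify all participants under all responder definitions
#'
#' @param data Participant table with `participant_id`, `age_years`,
#'   `cp_0` and the model-horizon column (e.g. `cp_12`).
#' @param model A [qr_model] used for the QR-based definition.
#' @param definitions Character vector of definition names (default all
#'   five).
#' @return A tidy data frame: `participant_id`, `definition`, `responder`
#'   (0/1).
#' @export
classify_responders <- function(data, model = published_qr_model(),
                                definitions = responder_definitions()$name) {
  hcol <- cp_column(data, model$baseline_month + model$horizon_month)
  bcol <- cp_column(data, model$baseline_month)
  qr <- compute_qr(data, model)$qr
  out <- lapply(definitions, function(def) {
    data.frame(
      participant_id = as.character(data[["participant_id"]]),
      definition = def,
      responder = as.integer(classify_responder(def, cp_0 = data[[bcol]],
                                                cp_1y = data[[hcol]],
                                                qr = qr)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantify covariate bias of responder definitions
#'
#' For each definition, fits a logit-link binomial GLM
#' `responder ~ age + ln(Cp_0 + 1)` among placebo/control participants,
#' reports per-predictor likelihood-ratio tests (full model vs the model
#' without that predictor) and the benchmark probability of being called a
#' responder for a reference individual (by default the pooled averages:
#' age 16.4 years, ln(Cp_0 + 1) = 0.53) with a delta-method 95\% CI on the
#' logit scale. A definition that truly adjusts for age and baseline shows
#' null LR tests; decline-based definitions are systematically associated
#' with age and/or baseline. No multiplicity adjustment is applied.
#'
#' @param data Control-arm participant table (>= 30 participants
#'   recommended).
#' @param model A [qr_model] for the QR computation.
#' @param definitions Definition names (default all five).
#' @param reference_age,reference_ln_cp Benchmark covariates.
#' @return A data frame of class `qr_bias_report`: one row per definition
#'   with GLM coefficients, LR statistics and p-values for age and
#'   baseline, the benchmark probability with CI, responder count and a
#'   `status` column (`"ok"`, `"separation"`, or `"degenerate"` when all
#'   calls coincide).
#' @export
responder_bias_analysis <- function(data, model = published_qr_model(),
                                    definitions = responder_definitions()$name,
                                    reference_age = 16.4,
                                    reference_ln_cp = 0.53) {
  bcol <- cp_column(data, model$baseline_month)
  calls <- classify_responders(data, model, definitions)
  covars <- data.frame(age = data[["age_years"]],
                       lcp0 = log1p(data[[bcol]]))
  if (stats::sd(covars$age) == 0 || stats::sd(covars$lcp0) == 0)
    stop("both predictors must vary to assess definition bias",
         call. = FALSE)
  rows <- lapply(definitions, function(def) {
    y <- calls$responder[calls$definition == def]
    if (all(y == y[1])) {
      return(data.frame(definition = def, intercept = NA_real_,
                        coef_age = NA_real_, coef_ln_cp0 = NA_real_,
                        lr_age = NA_real_, p_age = NA_real_,
                        lr_cp = NA_real_, p_cp = NA_real_,
                        benchmark_prob = as.numeric(y[1]),
                        benchmark_lo = NA_real_, benchmark_hi = NA_real_,
                        n_responders = sum(y), n = length(y),
                        status = "degenerate", stringsAsFactors = FALSE))
    }
    full <- suppressWarnings(stats::glm(y ~ age + lcp0, data = covars,
                                        family = stats::binomial()))
    no_age <- suppressWarnings(stats::glm(y ~ lcp0, data = covars,
                                          family = stats::binomial()))
    no_cp <- suppressWarnings(stats::glm(y ~ age, data = covars,
                                         family = stats::binomial()))
    sep <- !full$converged ||
      any(full$fitted.values > 1 - 1e-8 | full$fitted.values < 1e-8)
    lr_age <- max(no_age$deviance - full$deviance, 0)
    lr_cp <- max(no_cp$deviance - full$deviance, 0)
    b <- stats::coef(full)
    xref <- c(1, reference_age, reference_ln_cp)
    eta <- sum(b * xref)
    se <- sqrt(drop(t(xref) %*% stats::vcov(full) %*% xref))
    data.frame(definition = def,
               intercept = unname(b[1]), coef_age = unname(b[2]),
               coef_ln_cp0 = unname(b[3]),
               lr_age = lr_age,
               p_age = stats::pchisq(lr_age, df = 1, lower.tail = FALSE),
               lr_cp = lr_cp,
               p_cp = stats::pchisq(lr_cp, df = 1, lower.tail = FALSE),
               benchmark_prob = stats::plogis(eta),
               benchmark_lo = stats::plogis(eta - 1.96 * se),
               benchmark_hi = stats::plogis(eta + 1.96 * se),
               n_responders = sum(y), n = length(y),
               status = if (sep) "separation" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qr_bias_report", "data.frame")
  if (any(out$status == "separation"))
    warning("complete or quasi-complete separation in: ",
            paste(out$definition[out$status == "separation"],
                  collapse = ", "), call. = FALSE)
  out
}

#' @export
print.qr_bias_report <- function(x, digits = 3, ...) {
  cat("Responder-definition covariate bias (logit GLM, responder ~ age +",
      "ln(Cp_0+1))\n")
  cols <- c("definition", "coef_age", "coef_ln_cp0", "p_age", "p_cp",
            "benchmark_prob", "status")
  df <- as.data.frame(x)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write responder calls as a tidy delimited table
#'
#' @param calls Output of [classify_responders()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_responder_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
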