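#' Summarise one trial arm on the QR and C-peptide scales
#'
#' Per-arm mean, SD and two-sided 95\% confidence interval (t distribution,
#' n - 1 df; arms can be as small as 16) of the QR, plus the 1-year
#' C-peptide AUC mean and the raw change from baseline (nmol/L).
#'
#' @param data Participant table for a single arm (n >= 2).
#' @param model A [qr_model].
#' @return A data frame of class `qr_arm_summary` with one row:
#'   `study_id`, `arm`, `n`, `mean_qr`, `sd_qr`, `ci95_low`, `ci95_high`,
#'   `mean_cp_1y`, `sd_cp_1y`, `mean_change`.
#' @export
summarize_arm <- function(data, model = published_qr_model()) {
  if (nrow(data) < 2)
    stop("need at least 2 participants to summarise an arm", call. = FALSE)
  qr <- compute_qr(data, model)$qr
  bcol <- cp_column(data, model$baseline_month)
  hcol <- cp_column(data, model$baseline_month + model$horizon_month)
  n <- sum(!is.na(qr))
  m <- mean(qr, na.rm = TRUE)
  s <- stats::sd(qr, na.rm = TRUE)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  out <- data.frame(
    study_id = if ("study_id" %in% names(data))
      as.character(data$study_id[1]) else NA_character_,
    arm = if ("arm" %in% names(data)) as.character(data$arm[1])
      else NA_character_,
    n = n, mean_qr = m, sd_qr = s,
    ci95_low = m - half, ci95_high = m + half,
    mean_cp_1y = mean(data[[hcol]], na.rm = TRUE),
    sd_cp_1y = stats::sd(data[[hcol]], na.rm = TRUE),
    mean_change = mean(data[[hcol]] - data[[bcol]], na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("qr_arm_summary", "data.frame")
  out
}

#' Between-arm treatment effect on a chosen outcome scale
#'
#' Welch (unequal-variance) two-sided two-sample t-test comparing active
#' vs control on one of three scales: the raw 1-year C-peptide AUC mean
#' (nmol/L), the change from baseline (nmol/L), or the QR. Adjusting for
#' baseline C-peptide and age via QR reduces outcome variance and so
#' typically sharpens the same comparison.
#'
#' @param active_data,control_data Participant tables for the two arms
#'   (each n >= 2, disjoint participant ids).
#' @param model A [qr_model].
#' @param outcome_scale `"qr"`, `"change_from_baseline"` or `"cp_1y"`.
#' @return A list of class `qr_effect`: means per arm, `mean_difference`
#'   (active - control) with 95\% CI, `t_statistic`, `welch_df`,
#'   `p_value`.
#' @export
treatment_effect <- function(active_data, control_data,
                             model = published_qr_model(),
                             outcome_scale = c("qr", "change_from_baseline",
                                               "cp_1y")) {
  outcome_scale <- match.arg(outcome_scale)
  if (nrow(active_data) < 2 || nrow(control_data) < 2)
    stop("each arm needs at least 2 participants", call. = FALSE)
  shared <- intersect(active_data$participant_id,
                      control_data$participant_id)
  if (length(shared))
    stop("participant ids appear in both arms: ",
         paste(utils::head(shared, 3), collapse = ", "), call. = FALSE)
  x <- outcome_values(active_data, model, outcome_scale)
  y <- outcome_values(control_data, model, outcome_scale)
  tt <- welch_or_degenerate(x, y)
  ci <- if (!tt$degenerate) {
    t2 <- stats::t.test(x, y, var.equal = FALSE)
    unname(t2$conf.int)
  } else c(NA_real_, NA_real_)
  structure(list(
    outcome_scale = outcome_scale,
    mean_active = mean(x, na.rm = TRUE),
    mean_control = mean(y, na.rm = TRUE),
    mean_difference = mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE),
    ci95 = ci,
    t_statistic = tt$statistic, welch_df = tt$df, p_value = tt$p_value,
    n_active = sum(!is.na(x)), n_control = sum(!is.na(y))
  ), class = "qr_effect")
}

outcome_values <- function(data, model, scale) {
  bcol <- cp_column(data, model$baseline_month)
  hcol <- cp_column(data, model$baseline_month + model$horizon_month)
  switch(scale,
         qr = compute_qr(data, model)$qr,
         change_from_baseline = data[[hcol]] - data[[bcol]],
         cp_1y = data[[hcol]])
}

#' @export
print.qr_effect <- function(x, digits = 3, ...) {
  cat("Treatment effect on scale '", x$outcome_scale, "'\n", sep = "")
  cat("  active mean", format(x$mean_active, digits = digits),
      "(n =", x$n_active, ") vs control mean",
      format(x$mean_control, digits = digits), "(n =", x$n_control, ")\n")
  cat("  difference", format(x$mean_difference, digits = digits),
      "95% CI [", format(x$ci95[1], digits = digits), ",",
      format(x$ci95[2], digits = digits), "]\n")
  cat("  Welch t =", format(x$t_statistic, digits = digits),
      "df =", format(x$welch_df, digits = digits),
      "p =", format(x$p_value, digits = digits), "\n")
  invisible(x)
}

#' One-sample test of mean QR against zero
#'
#' Two-sided one-sample t-test of the arm's mean QR against 0. A
#' well-calibrated model gives placebo arms mean QR near 0; an active arm
#' with CI entirely above 0 is evidence of effect.
#'
#' @param data Participant table for one arm (n >= 2).
#' @param model A [qr_model].
#' @return A list: `mean_qr`, `t_statistic`, `df`, `p_value`, `ci95`,
#'   `degenerate` (`TRUE` when the QR values have zero variance; p is then
#'   the limiting value 1 for mean 0 and 0 otherwise).
#' @export
test_mean_qr_zero <- function(data, model = published_qr_model()) {
  if (nrow(data) < 2)
    stop("need at least 2 participants", call. = FALSE)
  qr <- compute_qr(data, model)$qr
  qr <- qr[!is.na(qr)]
  if (stats::sd(qr) == 0) {
    return(list(mean_qr = mean(qr), t_statistic = NA_real_,
                df = length(qr) - 1,
                p_value = if (mean(qr) == 0) 1 else 0,
                ci95 = c(mean(qr), mean(qr)), n = length(qr),
                degenerate = TRUE))
  }
  tt <- stats::t.test(qr, mu = 0)
  list(mean_qr = mean(qr), t_statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_value = unname(tt$p.value),
       ci95 = unname(tt$conf.int), n = length(qr), degenerate = FALSE)
}

#' Correlate a biomarker with outcome, QR, and age
#'
#' Pearson correlations (with two-sided p-values) of a per-participant
#' biomarker against (i) the ln-scale 1-year C-peptide, (ii) the QR, and
#' (iii) age. The intended contrast: a biomarker that merely proxies age
#' correlates with the raw outcome but shows an attenuated correlation
#' with QR, which already adjusts for age and baseline C-peptide.
#'
#' @param biomarker Numeric vector aligned with the rows of `data`.
#' @param data Participant table.
#' @param model A [qr_model].
#' @return A data frame with rows `ln_cp_1y`, `qr`, `age` and columns
#'   `r`, `p_value`, `n`.
#' @export
biomarker_association <- function(biomarker, data,
                                  model = published_qr_model()) {
  if (length(biomarker) != nrow(data))
    stop("biomarker must have one value per participant", call. = FALSE)
  if (stats::sd(biomarker, na.rm = TRUE) == 0)
    stop("biomarker is constant; correlation undefined", call. = FALSE)
  hcol <- cp_column(data, model$baseline_month + model$horizon_month)
  targets <- list(ln_cp_1y = log1p(data[[hcol]]),
                  qr = compute_qr(data, model)$qr,
                  age = data[["age_years"]])
  rows <- lapply(names(targets), function(nm) {
    y <- targets[[nm]]
    ok <- !is.na(biomarker) & !is.na(y)
    if (sum(ok) < 3)
      stop("need at least 3 paired non-missing values for ", nm,
           call. = FALSE)
    if (stats::sd(y[ok]) == 0)  # e.g. QR identically 0 on noiseless data
      return(data.frame(association = nm, r = NA_real_,
                        p_value = NA_real_, n = sum(ok),
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(biomarker[ok], y[ok], method = "pearson")
    data.frame(association = nm, r = unname(ct$estimate),
               p_value = unname(ct$p.value), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-trial arm summary table
#'
#' Applies [summarize_arm()] to every study x arm cell of a multi-trial
#' participant table, and appends the between-arm QR difference per study
#' where both arms are present.
#'
#' @param data Multi-trial participant table with `study_id` and `arm`
#'   columns.
#' @param model A [qr_model].
#' @return A data frame: one row per study x arm with the
#'   [summarize_arm()] columns plus `qr_difference`, `diff_p_value` (Welch
#'   test of the QR difference, repeated on both arms' rows).
#' @export
cross_trial_summary <- function(data, model = published_qr_model()) {
  cells <- split(data, list(data$study_id, data$arm), drop = TRUE)
  out <- do.call(rbind, lapply(cells, summarize_arm, model = model))
  out$qr_difference <- NA_real_
  out$diff_p_value <- NA_real_
  for (sid in unique(out$study_id)) {
    a <- data[data$study_id == sid & data$arm == "active", , drop = FALSE]
    c_ <- data[data$study_id == sid & data$arm == "control", , drop = FALSE]
    if (nrow(a) >= 2 && nrow(c_) >= 2) {
      eff <- treatment_effect(a, c_, model, "qr")
      sel <- out$study_id == sid
      out$qr_difference[sel] <- eff$mean_difference
      out$diff_p_value[sel] <- eff$p_value
    }
  }
  rownames(out) <- NULL
  out
}
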