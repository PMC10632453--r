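#' Percentile of a QR value within the placebo distribution
#'
#' Maps a QR value to its empirical percentile among placebo/control QR
#' values, interpolating linearly between the closest order statistics
#' (the convention of quantile box plots: the i-th order statistic of n
#' sits at percentile 100 * (i - 1) / (n - 1)). Queries outside the
#' observed range are clamped to 0 or 100 and flagged via the `"clamped"`
#' attribute.
#'
#' @param placebo_qr Numeric vector of placebo/control QR values (n >= 2;
#'   n >= 10 recommended for stable percentiles).
#' @param query QR value(s) to map.
#' @return Numeric vector of percentiles in `[0, 100]`, with a logical
#'   `"clamped"` attribute.
#' @examples
#' qr_percentile(c(-1, 0, 1), 0)  # 50
#' @export
qr_percentile <- function(placebo_qr, query) {
  placebo_qr <- placebo_qr[!is.na(placebo_qr)]
  n <- length(placebo_qr)
  if (n < 2) stop("need at least 2 placebo QR values", call. = FALSE)
  sx <- sort(placebo_qr)
  p <- 100 * (seq_len(n) - 1) / (n - 1)
  clamped <- query < sx[1] | query > sx[n]
  out <- stats::approx(sx, p, xout = pmin(pmax(query, sx[1]), sx[n]),
                       ties = mean)$y
  if (any(clamped))
    warning(sum(clamped), " query value(s) outside the observed QR range;",
            " clamped to 0/100", call. = FALSE)
  attr(out, "clamped") <- clamped
  out
}

#' Probability-of-effective-therapy curve from QR distributions
#'
#' Fits a logit-link binomial GLM of group membership (active treatment
#' from positive trials = 1, placebo = 0) on QR, with per-observation
#' weights chosen so the two groups are equally represented: the larger
#' group gets weight 1 and the smaller group weight
#' `n_larger / n_smaller` (the target proportion divided by the actual
#' proportion). The fitted curve gives, for any QR value, the probability
#' that an individual with that QR received an effective therapy; the 95\%
#' CI band is computed by the delta method on the linear predictor and
#' back-transformed, keeping it inside `[0, 1]`.
#'
#' @param active_qr QR values of actively treated participants from
#'   positive trials (n >= 10).
#' @param placebo_qr QR values of placebo/control participants (n >= 10).
#' @param grid QR values at which to tabulate the curve.
#' @return An object of class `qr_prob_curve`: `coefficients` (intercept,
#'   slope on QR), `weights` (per group), `n_active`, `n_placebo`,
#'   `separation` flag, and `curve`, a data frame `(qr, probability,
#'   ci_low, ci_high)`.
#' @export
fit_probability_curve <- function(active_qr, placebo_qr,
                                  grid = seq(-0.8, 0.8, by = 0.02)) {
  active_qr <- active_qr[!is.na(active_qr)]
  placebo_qr <- placebo_qr[!is.na(placebo_qr)]
  n_a <- length(active_qr)
  n_p <- length(placebo_qr)
  if (n_a < 10 || n_p < 10)
    stop("need at least 10 QR values in each group", call. = FALSE)
  w <- probability_curve_weights(n_a, n_p)
  df <- data.frame(y = rep(c(1, 0), c(n_a, n_p)),
                   qr = c(active_qr, placebo_qr),
                   w = rep(c(w[["active"]], w[["placebo"]]), c(n_a, n_p)))
  # non-integer weighted binomial counts trigger a spurious glm warning
  fit <- suppressWarnings(stats::glm(y ~ qr, family = stats::binomial(),
                                     data = df, weights = w))
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (sep)
    warning("group separation on QR; probability curve is degenerate",
            call. = FALSE)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  eta <- b[1] + b[2] * grid
  se <- sqrt(V[1, 1] + grid^2 * V[2, 2] + 2 * grid * V[1, 2])
  curve <- data.frame(qr = grid,
                      probability = stats::plogis(eta),
                      ci_low = stats::plogis(eta - 1.96 * se),
                      ci_high = stats::plogis(eta + 1.96 * se))
  structure(list(coefficients = c(intercept = unname(b[1]),
                                  slope = unname(b[2])),
                 vcov = V,
                 weights = w, n_active = n_a, n_placebo = n_p,
                 separation = sep, curve = curve),
            class = "qr_prob_curve")
}

#' Group weights equalising active and placebo representation
#'
#' The larger group gets weight 1; the smaller group gets
#' `n_larger / n_smaller`, i.e. the target proportion (that of the larger
#' group) divided by its actual proportion, so that the weighted group
#' totals are exactly equal.
#'
#' @param n_active,n_placebo Group sizes.
#' @return Named numeric vector `c(active = , placebo = )`.
#' @examples
#' probability_curve_weights(259, 448)  # active weight 448/259
#' @export
probability_curve_weights <- function(n_active, n_placebo) {
  if (n_active >= n_placebo) c(active = 1, placebo = n_active / n_placebo)
  else c(active = n_placebo / n_active, placebo = 1)
}

#' @export
print.qr_prob_curve <- function(x, digits = 3, ...) {
  cat("Probability-of-effective-therapy curve (weighted logistic)\n")
  cat("  logit P(active | QR) =",
      format(x$coefficients[["intercept"]], digits = digits), "+",
      format(x$coefficients[["slope"]], digits = digits), "* QR\n")
  cat("  n active =", x$n_active, "(weight",
      format(x$weights[["active"]], digits = digits), "), n placebo =",
      x$n_placebo, "(weight", format(x$weights[["placebo"]],
                                     digits = digits), ")\n")
  if (x$separation) cat("  WARNING: separation flagged\n")
  invisible(x)
}

#' @export
predict.qr_prob_curve <- function(object, qr, ...) {
  b <- object$coefficients
  eta <- b[["intercept"]] + b[["slope"]] * qr
  se <- sqrt(object$vcov[1, 1] + qr^2 * object$vcov[2, 2] +
               2 * qr * object$vcov[1, 2])
  data.frame(qr = qr, probability = stats::plogis(eta),
             ci_low = stats::plogis(eta - 1.96 * se),
             ci_high = stats::plogis(eta + 1.96 * se))
}

#' @export
plot.qr_prob_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$qr, cv$probability, type = "l", lwd = 2, col = "blue",
                 ylim = c(0, 1), xlab = "QR",
                 ylab = "P(effective therapy)", ...)
  graphics::polygon(c(cv$qr, rev(cv$qr)), c(cv$ci_low, rev(cv$ci_high)),
                    col = grDevices::adjustcolor("blue", 0.2), border = NA)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a probability curve grid as delimited text
#'
#' @param curve A `qr_prob_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_probability_curve <- function(curve, path) {
  utils::write.csv(curve$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
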