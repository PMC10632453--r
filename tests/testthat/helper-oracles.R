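# Independent brute-force oracles used to cross-check the package's
# delegated statistics. Deliberately written from first principles.

# OLS via explicit normal equations
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Welch two-sample t with Welch-Satterthwaite df, from the printed formulas
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Two-sample KS statistic by scanning the empirical CDFs at every data point
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), numeric(1))
  max(d)
}

# Pearson correlation from the definitional sums
pearson_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Logistic regression by hand-rolled IRLS (logit link, canonical weights)
irls_oracle <- function(X, y, tol = 1e-12, maxit = 100, w = rep(1, length(y))) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- drop(solve(crossprod(X, W * X), crossprod(X, W * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}
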