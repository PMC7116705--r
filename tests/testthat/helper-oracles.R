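# Independent reference implementations used to cross-check the package.

# Yule-Walker solution by direct Toeplitz solve (plus-sign convention),
# independent of the Levinson-Durbin recursion.
toeplitz_ar_fit <- function(gamma, p) {
  if (p == 0) return(list(coeffs = numeric(0), innovation_var = gamma[1]))
  G <- stats::toeplitz(gamma[1:p])
  beta <- as.numeric(solve(G, -gamma[2:(p + 1)]))
  list(coeffs = beta,
       innovation_var = gamma[1] + sum(gamma[2:(p + 1)] * beta))
}

# Positive-definite autocovariance sequences: sample autocovariances (divisor
# T) of a random stationary series are positive definite almost surely.
random_acv <- function(max_lag, n = 64) {
  phi <- runif(1, -0.9, 0.9)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  autocovariance(x, max_lag)
}

# Conditional least-squares AR fit on x[start..end] (evaluation range starts
# at start + p when no lags precede `start`), via lm; used to probe
# conditional-likelihood maximality.
cls_fit <- function(x, p, start = 1L, end = length(x)) {
  t0 <- if (start - p >= 1) start else start + p
  idx <- t0:end
  y <- x[idx]
  X <- vapply(seq_len(p), function(j) x[idx - j], numeric(length(idx)))
  fit <- stats::lm.fit(cbind(X), y)
  beta <- -as.numeric(fit$coefficients)
  rss <- sum(fit$residuals^2)
  list(order = p, coeffs = beta, innovation_var = rss / length(idx))
}

quiet_detect <- function(...) suppressWarnings(detect(...))

# deterministic seed for replicate i, stream j of a simulation experiment
sub_seed_pair <- function(master, i, j) {
  as.integer((master * 100003 + i * 613 + j * 7) %% 2147483647)
}

make_profile <- function(values, h, n = 2 * h + length(values) - 1) {
  structure(list(h = as.integer(h),
                 positions = seq.int(h, h + length(values) - 1),
                 values = values,
                 order_used = rep(1L, length(values)),
                 n = as.integer(n)),
            class = "scan_profile")
}
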