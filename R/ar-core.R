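#' Sample autocovariances with divisor T
#'
#' Computes the (biased-form) sample autocovariances
#' \deqn{\hat\gamma(j) = \frac{1}{T}\sum_{t=j+1}^{T} x_t x_{t-j},
#'   \qquad j = 0, \dots, \code{max_lag},}
#' where the divisor is \eqn{T} at every lag, not \eqn{T - j}. This keeps the
#' autocovariance sequence positive semi-definite, which the Levinson-Durbin
#' recursion relies on.
#'
#' The zero-mean form above is the default because series are centred before
#' analysis elsewhere in the pipeline. With `demean = TRUE` every observation
#' is first reduced by `center` (the sample mean when `center` is `NULL`),
#' giving the mean-corrected \eqn{\hat\gamma^*(j)}.
#'
#' @param x numeric vector, the observed series (or segment).
#' @param max_lag maximum lag; must be smaller than `length(x)`.
#' @param demean centre the series before computing moments?
#' @param center value to centre by when `demean = TRUE`; defaults to the
#'   sample mean of `x`.
#' @return numeric vector of length `max_lag + 1`, lags 0 to `max_lag`.
#' @seealso [pooled_autocovariance()], [levinson_durbin()]
#' @examples
#' autocovariance(c(1, -1, 1, -1), 1)  # c(1, -0.75)
#' @export
autocovariance <- function(x, max_lag, demean = FALSE, center = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (max_lag < 0) stop("`max_lag` must be non-negative", call. = FALSE)
  if (max_lag >= n) {
    stop("`max_lag` must be smaller than the series length", call. = FALSE)
  }
  if (demean) x <- x - (if (is.null(center)) mean(x) else center)
  vapply(0:max_lag, function(j) {
    sum(x[(j + 1):n] * x[1:(n - j)]) / n
  }, numeric(1))
}

#' Pooled autocovariances of two segments
#'
#' Combines the lagged moment sums of two segments under the hypothesis that
#' they share one autocovariance structure:
#' \deqn{c(j) = \frac{1}{T_1 + T_2}\Big(\sum_{t=j+1}^{T_1} x_t x_{t-j}
#'   + \sum_{t=j+1}^{T_2} y_t y_{t-j}\Big).}
#' In the mean-corrected variant both segments are centred by the single
#' pooled mean \eqn{\hat\mu = (T_1\hat\mu_X + T_2\hat\mu_Y)/(T_1 + T_2)}
#' before the sums are formed, giving \eqn{c^*(j)}.
#'
#' @param x,y numeric vectors, the two adjacent segments.
#' @param max_lag maximum lag; must be smaller than the shorter segment.
#' @param demean centre both segments by the pooled mean first?
#' @return an object of class `"pooled_cov"`: a list with `values`
#'   (lags 0..`max_lag`), segment lengths `n1`, `n2`, and `pooled_mean`
#'   (`NULL` unless `demean`).
#' @export
pooled_autocovariance <- function(x, y, max_lag, demean = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n1 <- length(x)
  n2 <- length(y)
  if (max_lag < 0 || max_lag >= min(n1, n2)) {
    stop("`max_lag` must be smaller than the shorter segment", call. = FALSE)
  }
  mu <- NULL
  if (demean) {
    mu <- (sum(x) + sum(y)) / (n1 + n2)
    x <- x - mu
    y <- y - mu
  }
  vals <- vapply(0:max_lag, function(j) {
    (sum(x[(j + 1):n1] * x[1:(n1 - j)]) +
       sum(y[(j + 1):n2] * y[1:(n2 - j)])) / (n1 + n2)
  }, numeric(1))
  structure(list(values = vals, n1 = n1, n2 = n2, pooled_mean = mu),
            class = "pooled_cov")
}

#' Levinson-Durbin recursion for Yule-Walker AR estimation
#'
#' Solves the Yule-Walker equations
#' \eqn{\hat\beta_p = -\hat\Gamma_p^{-1}\hat\gamma_p},
#' \eqn{\hat\sigma^2_p = \hat\gamma(0) + \hat\gamma_p'\hat\beta_p}
#' by the \eqn{O(p^2)} Levinson-Durbin recursion rather than a direct
#' Toeplitz solve. Coefficients are returned in the *plus* sign convention
#' \eqn{x_t + \beta_1 x_{t-1} + \dots + \beta_p x_{t-p} = \varepsilon_t};
#' a generative AR coefficient \eqn{\phi} corresponds to \eqn{-\beta}.
#'
#' The recursion yields the innovation variance for every intermediate order,
#' kept in `sigma2_by_order`; this path is monotone non-increasing and is what
#' BIC-based order selection consumes.
#'
#' @param gamma numeric vector of autocovariances at lags 0..`order` or more
#'   (e.g. from [autocovariance()]), or a `"pooled_cov"` object.
#' @param order AR order `p` (non-negative).
#' @return an object of class `"ar_fit"`: list with `order`, `coeffs`
#'   (length `p`, plus-sign convention), `innovation_var`, `autocovariances`
#'   (lags 0..p) and `sigma2_by_order` (orders 0..p).
#' @examples
#' levinson_durbin(c(1, -0.75), 1)  # coeffs 0.75, innovation_var 0.4375
#' @export
levinson_durbin <- function(gamma, order) {
  if (inherits(gamma, "pooled_cov")) gamma <- gamma$values
  gamma <- as.numeric(gamma)
  if (order < 0) stop("`order` must be non-negative", call. = FALSE)
  if (length(gamma) < order + 1) {
    stop("`gamma` must supply lags 0..order", call. = FALSE)
  }
  g0 <- gamma[1]
  if (!is.finite(g0) || g0 <= 0) {
    stop("autocovariance at lag 0 is not positive: degenerate segment",
         call. = FALSE)
  }
  sigma2 <- g0
  s2_path <- numeric(order + 1)
  s2_path[1] <- g0
  phi <- numeric(0)
  if (order > 0) {
    for (k in seq_len(order)) {
      num <- if (k == 1) gamma[2] else gamma[k + 1] - sum(phi * gamma[k:2])
      kappa <- num / sigma2
      phi <- if (k == 1) kappa else c(phi - kappa * rev(phi), kappa)
      sigma2 <- sigma2 * (1 - kappa^2)
      if (!is.finite(sigma2) || sigma2 <= 0) {
        stop("autocovariance sequence is not positive definite ",
             "(degenerate segment at order ", k, ")", call. = FALSE)
      }
      s2_path[k + 1] <- sigma2
    }
  }
  structure(list(order = as.integer(order),
                 coeffs = -phi,
                 innovation_var = sigma2,
                 autocovariances = gamma[seq_len(order + 1)],
                 sigma2_by_order = s2_path),
            class = "ar_fit")
}

#' Conditional Gaussian log-likelihood of an AR fit
#'
#' Evaluates \eqn{\sum_t \log f_\theta(x_t \mid x_{t-1}, \dots, x_{t-p})}
#' over the window `[start, end]`, where each conditional density is Gaussian
#' with mean \eqn{-(\beta_1 x_{t-1} + \dots + \beta_p x_{t-p})} and variance
#' `fit$innovation_var`. When `p` lagged values are available in `x` before
#' `start`, all of `[start, end]` contributes; otherwise the sum conditions
#' on the first `p` observations of the window and starts at `start + p`.
#' This convention makes the log-likelihood additive over a partition of a
#' window at fixed parameters, which is what makes the scan statistic a
#' genuine (non-negative) likelihood ratio.
#'
#' @param x numeric vector containing the window (and any lagged values).
#' @param fit an `"ar_fit"` object (or list with `order`, `coeffs`,
#'   `innovation_var`).
#' @param start,end window bounds, 1-based indices into `x`.
#' @return scalar log-likelihood.
#' @export
ar_conditional_loglik <- function(x, fit, start = 1L, end = length(x)) {
  x <- as.numeric(x)
  p <- fit$order
  if (end > length(x) || start < 1 || end < start) {
    stop("invalid window bounds", call. = FALSE)
  }
  if (end - start + 1 < p + 1) {
    stop("window too short for AR order ", p, call. = FALSE)
  }
  t0 <- if (start - p >= 1) start else start + p
  idx <- t0:end
  resid <- x[idx]
  if (p > 0) {
    for (j in seq_len(p)) resid <- resid + fit$coeffs[j] * x[idx - j]
  }
  s2 <- fit$innovation_var
  -0.5 * length(idx) * log(2 * pi * s2) - sum(resid^2) / (2 * s2)
}

#' Fixed AR order for the discrimination test
#'
#' The autoregressive-approximation order used by the segment comparison
#' test: \eqn{p = \lfloor (\log T_{\min})^\upsilon \rfloor} with
#' \eqn{\upsilon > 1}. The defaults use the base-10 logarithm with
#' \eqn{\upsilon = 2}; e.g. segments of minimum length 128 give
#' \eqn{\lfloor 2.107^2 \rfloor = 4}, hence a chi-square reference with
#' 5 degrees of freedom in the zero-mean variant. Both the base and the
#' exponent are configurable.
#'
#' @param t_min length of the shorter segment (at least 2).
#' @param upsilon exponent (> 1); default 2.
#' @param log_base logarithm base; default 10.
#' @return integer order.
#' @examples
#' fixed_order(128)  # 4
#' @export
fixed_order <- function(t_min, upsilon = 2, log_base = 10) {
  if (t_min < 2) stop("`t_min` must be at least 2", call. = FALSE)
  as.integer(floor(log(t_min, base = log_base)^upsilon))
}

# BIC order selection on an autocovariance sequence: n*log(sigma2_m) + m*log(n)
# over m = 0..order_max, using the Levinson-Durbin variance path. Orders whose
# recursion breaks down (non-PD) are skipped.
bic_order <- function(gamma, n, order_max) {
  if (inherits(gamma, "pooled_cov")) gamma <- gamma$values
  order_max <- min(order_max, length(gamma) - 1)
  best <- 0L
  best_bic <- Inf
  for (m in 0:order_max) {
    s2 <- tryCatch(levinson_durbin(gamma, m)$innovation_var,
                   error = function(e) NA_real_)
    if (!is.finite(s2) || s2 <= 0) break
    bic <- n * log(s2) + m * log(n)
    if (bic < best_bic - 1e-12) {
      best_bic <- bic
      best <- m
    }
  }
  best
}
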