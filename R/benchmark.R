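#' Monte Carlo benchmark of the detection pipeline
#'
#' Simulates `reps` replicates of a library model ([model_library()]), runs
#' [detect()] on each, and tabulates (i) the distribution of the estimated
#' number of change points \eqn{\hat N}, binned around the true number
#' \eqn{N} the way detection-rate tables are usually reported
#' (\eqn{\{\le N-1, N, \ge N+1\}}, with \eqn{\{0, 1, \ge 2\}} when
#' \eqn{N \le 1}); (ii) the exact detection rate, the proportion of
#' replicates with \eqn{\hat N = N}; (iii) the mean chi-square degrees of
#' freedom across all validation tests; and (iv) per-replicate signed
#' location errors \eqn{\hat k_i - k_i} for the replicates with
#' \eqn{\hat N = N}.
#'
#' Replicate `i` uses a deterministic sub-seed of `(seed, i)`, so results are
#' reproducible and independent of `reps`.
#'
#' @param model model name `"A"`..`"I"`.
#' @param beta AR(1) coefficient, Model A only.
#' @param method `"bh"` or `"bonferroni"`.
#' @param r scan radius multiplier; `h = window_radius(T, r)` unless `h` is
#'   given directly.
#' @param reps number of replicates (default 100).
#' @param seed master seed.
#' @param h optional explicit window radius (overrides `r`).
#' @param alpha significance / FDR level.
#' @param variant discrimination-test variant.
#' @return an object of class `"mcp2_benchmark"`: list with `model`,
#'   `method`, `h`, `reps`, `true_change_points`, `dist_nhat` (named
#'   proportions), `exact_rate`, `mean_df`, `nhat` (per replicate),
#'   `location_errors` (matrix, one row per exact-count replicate) and
#'   `seed`.
#' @examples
#' \donttest{
#' b <- run_benchmark("I", method = "bh", r = 1, reps = 20, seed = 1)
#' b$exact_rate
#' }
#' @export
run_benchmark <- function(model, beta = NULL, method = c("bh", "bonferroni"),
                          r = 2, reps = 100, seed = 1, h = NULL,
                          alpha = 0.05,
                          variant = c("zero_mean", "mean_corrected",
                                      "known_order")) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  spec <- model_library(model, beta = beta)
  T <- spec$total_length
  if (is.null(h)) h <- window_radius(T, r)
  truth <- spec$change_points
  q <- length(truth)

  nhat <- integer(reps)
  dfs <- list()
  loc_err <- list()
  for (i in seq_len(reps)) {
    sim <- simulate_piecewise(spec, sub_seed(seed, 100000 + i))
    res <- suppressWarnings(
      detect(sim$values, h = h, method = method, variant = variant,
             alpha = alpha))
    est <- res$change_points
    nhat[i] <- length(est)
    dfs[[i]] <- res$df[!is.na(res$df)]
    if (length(est) == q && q > 0) loc_err[[length(loc_err) + 1]] <- est - truth
  }

  # bins {<= q-1, q, >= q+1}, reported as {0, 1, >= 2} when q <= 1
  if (q == 0) {
    dist <- c(mean(nhat == 0), mean(nhat == 1), mean(nhat >= 2))
    names(dist) <- c("0", "1", ">=2")
  } else {
    dist <- c(mean(nhat <= q - 1), mean(nhat == q), mean(nhat >= q + 1))
    names(dist) <- c(if (q == 1) "0" else paste0("<=", q - 1),
                     as.character(q), paste0(">=", q + 1))
  }

  structure(list(model = spec$name,
                 method = if (method == "bh") "mcp2_bh" else "mcp2_wright",
                 h = as.integer(h),
                 reps = as.integer(reps),
                 true_change_points = truth,
                 dist_nhat = dist,
                 exact_rate = mean(nhat == q),
                 mean_df = if (length(unlist(dfs))) mean(unlist(dfs)) else NA_real_,
                 nhat = nhat,
                 location_errors = if (length(loc_err))
                   do.call(rbind, loc_err) else
                   matrix(integer(0), 0, q),
                 seed = seed),
            class = "mcp2_benchmark")
}

#' Summarise change point location errors
#'
#' Per true change point, the median and interquartile range of the signed
#' location error \eqn{\hat k - k} over the replicates that recovered the
#' correct number of change points.
#'
#' @param result an `"mcp2_benchmark"` from [run_benchmark()].
#' @return data frame with columns `change_point`, `n`, `median_error`,
#'   `iqr`, `q1`, `q3`; zero rows (with a message) when no replicate had the
#'   exact count.
#' @export
location_error_summary <- function(result) {
  if (!inherits(result, "mcp2_benchmark")) {
    stop("`result` must be an mcp2_benchmark", call. = FALSE)
  }
  err <- result$location_errors
  empty <- data.frame(change_point = integer(0), n = integer(0),
                      median_error = numeric(0), iqr = numeric(0),
                      q1 = numeric(0), q3 = numeric(0))
  if (!length(result$true_change_points)) {
    message("model has no true change points; nothing to summarise")
    return(empty)
  }
  if (!nrow(err)) {
    message("no replicate recovered the exact number of change points")
    return(empty)
  }
  qs <- apply(err, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(change_point = result$true_change_points,
             n = nrow(err),
             median_error = qs[2, ],
             iqr = qs[3, ] - qs[1, ],
             q1 = qs[1, ],
             q3 = qs[3, ])
}

#' @export
print.mcp2_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark: model %s, %s, h = %d, %d replicates\n",
              x$model, toupper(sub("mcp2_", "", x$method)), x$h, x$reps))
  cat(sprintf("  exact detection rate (Nhat = N): %.2f; mean test df: %s\n",
              x$exact_rate,
              if (is.na(x$mean_df)) "NA" else sprintf("%.2f", x$mean_df)))
  cat("  Nhat distribution: ",
      paste(sprintf("%s: %.2f", names(x$dist_nhat), x$dist_nhat),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
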