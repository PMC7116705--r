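#' Detect and validate multiple change points
#'
#' The full MCP2 pipeline in three stages: (1) a likelihood-ratio scan
#' ([scan_profile()]) proposes candidate change points as local maxima of the
#' scan statistic ([select_candidates()]); (2) each candidate is tested by
#' the spectral discrimination likelihood-ratio test on the two segments it
#' separates ([validate_candidates()]); (3) a multiple-testing procedure —
#' Benjamini-Hochberg FDR or Bonferroni (Wright) — is applied once to the
#' candidate p-values and the surviving candidates form the final change
#' point set ([finalize()]).
#'
#' The series is mean-corrected globally before scanning, and each tested
#' segment is re-centred individually under the default `"zero_mean"`
#' variant; level shifts are therefore not treated as change points (use
#' `variant = "mean_corrected"` if they should be).
#'
#' @param x numeric series (finite values, length `> 2h`).
#' @param h scanning window radius; when `NULL`, uses `window_radius(T, r)`
#'   if `r` is given, otherwise the rule-of-thumb [default_window()].
#' @param r radius multiplier, used only when `h` is `NULL`.
#' @param method multiple-testing procedure, `"bh"` or `"bonferroni"`.
#' @param variant discrimination-test variant; see [discrimination_test()].
#' @param alpha significance / FDR level (default 0.05).
#' @param upsilon,log_base fixed-order rule parameters; see [fixed_order()].
#' @param order_max cap on the scan-window AR order; see [scan_profile()].
#' @return an `"mcp2_result"` (see [finalize()]) with the scan `profile` and
#'   a `settings` echo attached. `$change_points` holds the validated set,
#'   1-based, each entry the last index of its segment.
#' @examples
#' sim <- simulate_piecewise(model_library("C"), seed = 42)
#' res <- detect(sim$values, h = 96, method = "bonferroni")
#' res$change_points  # near the true 400, 612
#' @export
detect <- function(x, h = NULL, r = NULL,
                   method = c("bh", "bonferroni"),
                   variant = c("zero_mean", "mean_corrected", "known_order"),
                   alpha = 0.05, upsilon = 2, log_base = 10,
                   order_max = NULL) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("series contains missing or non-finite values", call. = FALSE)
  }
  T <- length(x)
  if (is.null(h)) {
    h <- if (!is.null(r)) window_radius(T, r) else default_window(T)
  }
  h <- as.integer(h)
  if (2 * h >= T) {
    stop(sprintf("no scanning positions: need 2h < T (h = %d, T = %d)", h, T),
         call. = FALSE)
  }
  if (T < 4 * h) {
    warning("series shorter than 4h; changes in short segments may be undetectable",
            call. = FALSE)
  }
  xc <- x - mean(x)
  profile <- scan_profile(xc, h, order_max = order_max, center = FALSE)
  cand <- select_candidates(profile)
  tests <- validate_candidates(xc, cand, variant = variant,
                               upsilon = upsilon, log_base = log_base)
  out <- finalize(cand, tests, method = method, alpha = alpha)
  out$profile <- profile
  out$settings <- list(h = h, method = method, variant = variant,
                       alpha = alpha, upsilon = upsilon, log_base = log_base)
  out
}
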