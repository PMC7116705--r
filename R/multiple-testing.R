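#' Benjamini-Hochberg step-up decisions
#'
#' Orders the p-values \eqn{P_{(1)} \le \dots \le P_{(q)}}, finds the largest
#' \eqn{i} with \eqn{P_{(i)} \le (i/q)\alpha}, and rejects the hypotheses with
#' the \eqn{i} smallest p-values (controlling the false discovery rate at
#' \eqn{\alpha}). Tied p-values are rejected or retained together. Decisions
#' are returned in the original candidate order.
#'
#' @param p_values numeric vector of unadjusted p-values in `[0, 1]`.
#' @param alpha target FDR level in `(0, 1)`.
#' @return logical vector, `TRUE` where rejected.
#' @examples
#' bh_procedure(c(0.001, 0.02, 0.04, 0.2), 0.05)  # TRUE TRUE FALSE FALSE
#' @export
bh_procedure <- function(p_values, alpha = 0.05) {
  check_pvalues(p_values, alpha)
  q <- length(p_values)
  if (q == 0L) return(logical(0))
  sorted <- sort(p_values)
  ok <- sorted <= (seq_len(q) / q) * alpha
  if (!any(ok)) return(rep(FALSE, q))
  p_values <= sorted[max(which(ok))]
}

#' Bonferroni (Wright) adjusted p-value decisions
#'
#' Rejects hypothesis \eqn{i} when \eqn{q \cdot p_i \le \alpha}, where `q` is
#' the number of hypotheses — the adjusted p-value rule controlling the
#' family-wise error rate. More conservative than [bh_procedure()]: its
#' rejections are always a subset of the BH rejections at the same `alpha`.
#'
#' @inheritParams bh_procedure
#' @return logical vector, `TRUE` where rejected.
#' @examples
#' bonferroni_procedure(c(0.001, 0.02, 0.04, 0.2), 0.05)  # TRUE FALSE FALSE FALSE
#' @export
bonferroni_procedure <- function(p_values, alpha = 0.05) {
  check_pvalues(p_values, alpha)
  if (!length(p_values)) return(logical(0))
  length(p_values) * p_values <= alpha
}

check_pvalues <- function(p_values, alpha) {
  if (length(p_values) && (anyNA(p_values) ||
                           any(p_values < 0) || any(p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the final change point set
#'
#' Applies the chosen multiple-testing procedure once to the unadjusted
#' p-values of the candidate validation tests (a single pass over the stage-1
#' segmentation; no iterative re-merging) and keeps the candidates whose null
#' hypotheses are rejected.
#'
#' @param candidates a `"candidate_set"`.
#' @param results list of `"mcp2_test"` results, one per candidate (from
#'   [validate_candidates()]).
#' @param method `"bh"` or `"bonferroni"`.
#' @param alpha significance / FDR level; default 0.05.
#' @return an object of class `"mcp2_result"`: list with `candidates`
#'   (integer positions), `p_values`, `lambda`, `df`, `method`, `alpha`,
#'   `rejected` (logical) and `change_points` (the validated set, order
#'   preserved).
#' @export
finalize <- function(candidates, results, method = c("bh", "bonferroni"),
                     alpha = 0.05) {
  method <- match.arg(method)
  k <- if (inherits(candidates, "candidate_set")) candidates$change_points
       else as.integer(candidates)
  if (length(results) != length(k)) {
    stop("one test result is required per candidate", call. = FALSE)
  }
  p <- vapply(results, function(r) r$p_value, numeric(1))
  rejected <- switch(method,
                     bh = bh_procedure(p, alpha),
                     bonferroni = bonferroni_procedure(p, alpha))
  structure(list(candidates = k,
                 p_values = p,
                 lambda = vapply(results, function(r) r$lambda, numeric(1)),
                 df = vapply(results, function(r) as.integer(r$df), integer(1)),
                 method = method,
                 alpha = alpha,
                 rejected = rejected,
                 change_points = k[rejected],
                 tests = results),
            class = "mcp2_result")
}

#' @export
print.mcp2_result <- function(x, ...) {
  q <- length(x$candidates)
  cat(sprintf("MCP2 detection (%s, alpha = %g): %d candidate(s), %d validated\n",
              toupper(x$method), x$alpha, q, sum(x$rejected)))
  if (q) {
    print(data.frame(position = x$candidates,
                     lambda = round(x$lambda, 3),
                     df = x$df,
                     p_value = signif(x$p_values, 4),
                     rejected = x$rejected),
          row.names = FALSE)
  }
  cat("Final change points:",
      if (length(x$change_points)) paste(x$change_points, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
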