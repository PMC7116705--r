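#' Specify one stationary AR/ARMA segment
#'
#' A segment is a stationary, zero-mean Gaussian ARMA(p, q) process
#' \eqn{x_t = \phi_1 x_{t-1} + \dots + \phi_p x_{t-p}
#'   + \varepsilon_t + \theta_1\varepsilon_{t-1} + \dots},
#' \eqn{\varepsilon_t \sim N(0, \code{sd}^2)}. Coefficients are in the
#' *generative* sign convention (the estimation side of the package uses the
#' opposite sign; see [levinson_durbin()]).
#'
#' The AR polynomial must be causal: all roots of
#' \eqn{1 - \phi_1 z - \dots - \phi_p z^p} strictly outside the unit circle.
#' Near-unit-root segments (e.g. \eqn{\phi = 0.999}) are allowed as long as
#' that holds.
#'
#' @param ar numeric vector of AR coefficients \eqn{\phi_1..\phi_p} (may be
#'   empty).
#' @param ma numeric vector of MA coefficients \eqn{\theta_1..\theta_q} (may
#'   be empty).
#' @param sd innovation standard deviation (> 0).
#' @param length number of observations in the segment (>= 1).
#' @return an object of class `"segment_spec"`.
#' @examples
#' segment_spec(ar = 0.7, length = 256)
#' @export
segment_spec <- function(ar = numeric(), ma = numeric(), sd = 1, length) {
  ar <- as.numeric(ar)
  ma <- as.numeric(ma)
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0) {
    stop("`sd` must be a positive scalar", call. = FALSE)
  }
  n <- as.integer(length)
  if (is.na(n) || n < 1) stop("`length` must be a positive integer", call. = FALSE)
  if (base::length(ar) > 0) {
    mods <- Mod(polyroot(c(1, -ar)))
    if (any(mods <= 1 + 1e-8)) {
      stop(sprintf(
        "non-stationary AR polynomial: root modulus %.6f is not outside the unit circle",
        min(mods)), call. = FALSE)
    }
  }
  structure(list(ar = ar, ma = ma, sd = sd, length = n),
            class = "segment_spec")
}

#' Specify a piecewise stationary process
#'
#' An ordered list of independent stationary segments. The true change points
#' are the cumulative segment endpoints: with segment lengths
#' \eqn{n_1, \dots, n_{q+1}}, change point \eqn{k_i = n_1 + \dots + n_i}
#' (1-based, the last observation of segment i), for \eqn{i = 1..q}.
#'
#' @param segments list of [segment_spec()] objects.
#' @param name optional label.
#' @return an object of class `"piecewise_spec"` with elements `segments`,
#'   `name`, `lengths`, `total_length` and `change_points`.
#' @export
piecewise_spec <- function(segments, name = NULL) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  if (!length(segments) || !all(vapply(segments, inherits, logical(1), "segment_spec"))) {
    stop("`segments` must be a non-empty list of segment_spec objects",
         call. = FALSE)
  }
  lens <- vapply(segments, function(s) s$length, integer(1))
  cps <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0)
  structure(list(segments = segments, name = name, lengths = lens,
                 total_length = sum(lens),
                 change_points = as.integer(cps)),
            class = "piecewise_spec")
}

# Deterministic 32-bit sub-seed for stream index i under master `seed`.
# Exact in double arithmetic (products stay below 2^53); independent of how
# many other streams exist, so adding a segment/replicate never perturbs
# earlier ones.
sub_seed <- function(seed, i) {
  v <- (abs(as.double(seed)) %% 2147483647) * 48271 + as.double(i) * 1299709
  as.integer(v %% 2147483647)
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one stationary segment
#'
#' Draws `spec$length` observations from the segment's Gaussian ARMA process.
#' A burn-in of `500 + 10 * (p + q)` samples is generated and discarded so the
#' retained stretch is approximately stationary. The same `(spec, seed)` pair
#' always returns bit-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [segment_spec()].
#' @param seed integer seed for this segment.
#' @return numeric vector of length `spec$length`.
#' @export
simulate_segment <- function(spec, seed) {
  if (!inherits(spec, "segment_spec")) {
    stop("`spec` must be a segment_spec", call. = FALSE)
  }
  p <- length(spec$ar)
  q <- length(spec$ma)
  burn <- 500 + 10 * (p + q)
  model <- list()
  if (p > 0) model$ar <- spec$ar
  if (q > 0) model$ma <- spec$ma
  with_local_seed(seed, {
    as.numeric(stats::arima.sim(model = model, n = spec$length,
                                n.start = burn, sd = spec$sd))
  })
}

#' Simulate a piecewise stationary series with known change points
#'
#' Concatenates independently simulated segments. Segment `i` uses the
#' deterministic sub-seed derived from `(seed, i)`, so segments are mutually
#' independent and adding a segment to the spec does not perturb the draws of
#' earlier segments.
#'
#' @param spec a [piecewise_spec()].
#' @param seed integer master seed.
#' @return list with `values` (numeric vector of length `spec$total_length`),
#'   `change_points` (1-based indices of the last observation of each
#'   non-final segment) and `model` (the spec's name).
#' @examples
#' sim <- simulate_piecewise(model_library("D"), seed = 1)
#' sim$change_points  # 50
#' @export
simulate_piecewise <- function(spec, seed) {
  if (!inherits(spec, "piecewise_spec")) {
    stop("`spec` must be a piecewise_spec", call. = FALSE)
  }
  values <- unlist(lapply(seq_along(spec$segments), function(i) {
    simulate_segment(spec$segments[[i]], sub_seed(seed, i))
  }), use.names = FALSE)
  list(values = values,
       change_points = spec$change_points,
       model = spec$name)
}

#' Benchmark model library (Models A-I)
#'
#' Returns the generating specification of one of the nine benchmark models
#' used throughout the package's simulation study: piecewise AR, near-unit-root,
#' variance-change, ARMA and pure-MA configurations on series of length 1024
#' (Models A-H) or 256 (Model I). All innovations are Gaussian with unit
#' standard deviation except where noted (Models E and F have a middle segment
#' with sd 1.5).
#'
#' * **A** (`beta` required): stationary AR(1), no change point, T = 1024.
#' * **B**: AR segments (0.9), (1.69, -0.81), (1.32, -0.81); changes at 512, 768.
#' * **C**: AR(1) 0.4 / -0.6 / 0.5; changes at 400, 612.
#' * **D**: AR(1) 0.75 / -0.5; one change at 50 (short first segment).
#' * **E**: near-unit-root AR(1) 0.999 throughout; innovation sd 1, 1.5, 1;
#'   changes at 400, 750.
#' * **F**: AR (1.399, -0.4) / 0.999 (sd 1.5) / (0.699, 0.3); changes at 400, 750.
#' * **G**: AR(1) 0.7 / 0.3 / 0.9 / 0.1; changes at 125, 532, 704.
#' * **H**: ARMA(1,1) segments (0.7; 0.6), (0.3; 0.3), (0.9; -), (0.1; -0.5);
#'   changes at 125, 532, 704.
#' * **I**: MA segments (0.8) and (1.68, -0.81), T = 256; one change at 128.
#'
#' @param name one of `"A"`..`"I"`.
#' @param beta AR(1) coefficient for Model A (ignored otherwise).
#' @return a [piecewise_spec()].
#' @examples
#' model_library("G")$change_points  # 125 532 704
#' @export
model_library <- function(name, beta = NULL) {
  name <- toupper(as.character(name))
  seg <- function(ar = numeric(), ma = numeric(), sd = 1, n) {
    segment_spec(ar = ar, ma = ma, sd = sd, length = n)
  }
  segments <- switch(name,
    A = {
      if (is.null(beta)) stop("Model A requires `beta`", call. = FALSE)
      list(seg(ar = beta, n = 1024))
    },
    B = list(seg(ar = 0.9, n = 512),
             seg(ar = c(1.69, -0.81), n = 256),
             seg(ar = c(1.32, -0.81), n = 256)),
    C = list(seg(ar = 0.4, n = 400),
             seg(ar = -0.6, n = 212),
             seg(ar = 0.5, n = 412)),
    D = list(seg(ar = 0.75, n = 50),
             seg(ar = -0.5, n = 974)),
    E = list(seg(ar = 0.999, sd = 1, n = 400),
             seg(ar = 0.999, sd = 1.5, n = 350),
             seg(ar = 0.999, sd = 1, n = 274)),
    F = list(seg(ar = c(1.399, -0.4), sd = 1, n = 400),
             seg(ar = 0.999, sd = 1.5, n = 350),
             seg(ar = c(0.699, 0.3), sd = 1, n = 274)),
    G = list(seg(ar = 0.7, n = 125),
             seg(ar = 0.3, n = 407),
             seg(ar = 0.9, n = 172),
             seg(ar = 0.1, n = 320)),
    H = list(seg(ar = 0.7, ma = 0.6, n = 125),
             seg(ar = 0.3, ma = 0.3, n = 407),
             seg(ar = 0.9, n = 172),
             seg(ar = 0.1, ma = -0.5, n = 320)),
    I = list(seg(ma = 0.8, n = 128),
             seg(ma = c(1.68, -0.81), n = 128)),
    stop("unknown model '", name, "' (expected one of A-I)", call. = FALSE)
  )
  label <- if (name == "A") sprintf("A(beta=%g)", beta) else name
  piecewise_spec(segments, name = label)
}
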