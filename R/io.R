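#' Read a univariate series from a single-column text file
#'
#' One value per line; an optional single header line is auto-detected (a
#' first line that does not parse as a number is skipped). Blank lines are
#' ignored. Missing or non-numeric values anywhere else are rejected.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_series <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty series file: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(lines) > 1) {
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (anyNA(vals)) {
    stop("series file contains missing or non-numeric values: ", path,
         call. = FALSE)
  }
  vals
}

#' Read a piecewise process specification from a key-value text file
#'
#' The file lists one block per segment. A line consisting of `segment`
#' starts a new block; within a block, `key = value` lines set `ar`, `ma`
#' (comma-separated coefficient lists), `sd` and `length`. Blank lines and
#' lines starting with `#` are ignored.
#'
#' ```
#' # two-segment example
#' segment
#' ar = 0.9
#' length = 512
#' segment
#' ar = 1.69, -0.81
#' sd = 1
#' length = 256
#' ```
#'
#' @param path file path.
#' @return a [piecewise_spec()].
#' @export
read_piecewise_spec <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  current <- NULL
  for (ln in lines) {
    if (tolower(ln) == "segment") {
      if (!is.null(current)) blocks[[length(blocks) + 1]] <- current
      current <- list(ar = numeric(), ma = numeric(), sd = 1, length = NA)
      next
    }
    if (is.null(current)) {
      stop("spec file must start with a `segment` line: ", path, call. = FALSE)
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed line in spec file: ", ln, call. = FALSE)
    key <- tolower(trimws(kv[1]))
    val <- as.numeric(trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(val)) stop("non-numeric value in spec file: ", ln, call. = FALSE)
    if (!key %in% c("ar", "ma", "sd", "length")) {
      stop("unknown key in spec file: ", key, call. = FALSE)
    }
    current[[key]] <- val
  }
  if (!is.null(current)) blocks[[length(blocks) + 1]] <- current
  if (!length(blocks)) stop("no segments in spec file: ", path, call. = FALSE)
  piecewise_spec(lapply(blocks, function(b) {
    if (is.na(b$length[1])) stop("segment is missing `length`", call. = FALSE)
    segment_spec(ar = b$ar, ma = b$ma, sd = b$sd[1], length = b$length[1])
  }), name = basename(path))
}

#' Write a univariate series to a single-column text file
#'
#' @param x numeric vector.
#' @param path file path.
#' @param header optional column name written as a first line.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, header = NULL) {
  lines <- format(as.numeric(x), trim = TRUE, digits = 15)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  invisible(path)
}
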