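#' @keywords internal
"_PACKAGE"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible substream seed
#'
#' Counter-based splitting of one global seed into independent substreams,
#' so that e.g. series `i` of a synthetic dataset gets the same random
#' stream regardless of how many other series are generated. All arithmetic
#' stays below 2^53 so the result is exact in doubles and below 2^31 so it
#' is a valid R seed.
#'
#' @param seed integer global seed.
#' @param ... one or more non-negative integer counters (stream indices).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (k in list(...)) {
    h <- (h * 1103 + as.numeric(k) * 12347 + 7) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
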