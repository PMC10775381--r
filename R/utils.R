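# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Percentages in IHC co-expression tables are conventionally reported with
#' ties rounded up (23/304 -> 8%, 3/71 -> 4.2%). Base [round()] rounds half
#' to even, which disagrees with that convention at .5 ties, so reporting
#' functions use this variant.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round_half_up(c(76.64, 0.5, 4.225), 0)
#' round_half_up(4.225, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Typed condition constructor: all package errors carry a subclass so callers
# (and tests) can distinguish schema, integrity, vocabulary, configuration
# and degeneracy failures.
tma_stop <- function(subclass, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "tmahet_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG state: seeds the generator, restores the
# caller's .Random.seed on exit. Every stochastic operation in the package
# funnels through this so that a recorded seed fully reproduces its output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable format of a numeric for TSV output (avoids scientific notation and
# locale effects; used by write_cohort and the pipeline writers).
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}
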