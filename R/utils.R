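#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive the k-th child seed from a user seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k) * 7919L) %% 2147483587L
}

#' Percentile with the package-wide convention
#'
#' All percentiles in this package (interdecile range of beat intervals,
#' interquartile dispersion of sarcomere angles) use linear interpolation
#' between order statistics at plotting positions p_k = (k-1)/(n-1),
#' i.e. `stats::quantile(type = 7)`. The convention is frozen by tests.
#'
#' @param x numeric vector.
#' @param p probabilities in \[0, 1\].
#' @return numeric vector of percentiles.
#' @export
eht_percentile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

stop_param <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
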