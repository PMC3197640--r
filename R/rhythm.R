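#' Interdecile range (RR-scatter)
#'
#' Beat-to-beat interval scatter: the length between the 10th and 90th
#' percentile of the interval distribution (interdecile range, IDR).
#' Interval lengths within a recording are typically non-normal, which is
#' why a rank-based scatter measure is used. Percentiles follow the
#' package-wide convention ([eht_percentile()], type-7 linear
#' interpolation).
#'
#' @param values numeric vector (beat intervals, s), length >= 2.
#' @return list of class `scatter_result`: `idr`, `n`, `decile_10`,
#'   `decile_90`.
#' @export
interdecile_range <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values))) {
    stop_param("interdecile_range needs >= 2 finite values")
  }
  q <- eht_percentile(values, c(0.1, 0.9))
  structure(
    list(idr = q[2] - q[1], n = length(values),
         decile_10 = q[1], decile_90 = q[2]),
    class = "scatter_result"
  )
}

#' Poincare pairs of a beat-interval series
#'
#' Each beat contributes the pair (interval to the previous twitch,
#' interval to the following twitch); perfectly regular beating puts every
#' pair on the identity diagonal, while irregular beating spreads the
#' cloud. With fewer than two intervals an empty pairing is returned with
#' attribute `insufficient = TRUE`.
#'
#' @param intervals numeric vector of successive beat intervals, s (> 0).
#' @return data.frame with columns `previous`, `following`;
#'   `nrow = length(intervals) - 1`.
#' @export
poincare_pairs <- function(intervals) {
  stopifnot(is.numeric(intervals))
  if (any(intervals <= 0)) stop_param("intervals must be > 0")
  n <- length(intervals)
  if (n < 2) {
    out <- data.frame(previous = numeric(), following = numeric())
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  data.frame(previous = intervals[-n], following = intervals[-1])
}

# Null distribution of the rank-sum of group A over all C(n, na) group
# assignments of the pooled midranks (exact, valid under ties).
mw_exact_dist <- function(ranks, na) {
  combos <- utils::combn(length(ranks), na)
  colSums(matrix(ranks[combos], nrow = na))
}

#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' Rank-sum test comparing two groups of biological replicates. In exact
#' mode the two-sided p-value is obtained by full enumeration of all
#' `choose(na+nb, na)` group assignments of the pooled midranks, so it is
#' valid at the very small group sizes (n = 4 per group) used for
#' replicate comparisons, including ties. `mode = "auto"` enumerates
#' whenever both groups have at most 8 observations. The normal mode uses
#' the tie-corrected large-sample z with continuity correction. Two-sided
#' p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list of class `mw_test`: `U` (statistic of group A),
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b)) {
    stop_param("both groups must be non-empty")
  }
  na <- length(group_a); nb <- length(group_b)
  if (mode == "auto") mode <- if (na <= 8 && nb <= 8) "exact" else "normal"
  ranks <- rank(c(group_a, group_b))  # midranks under ties
  u <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "exact") {
    dist <- mw_exact_dist(ranks, na) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(dist <= u), mean(dist >= u)))
  } else {
    nn <- na + nb
    ties <- table(ranks)
    sigma2 <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    mu <- na * nb / 2
    z <- u - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity corr.
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(U = u, p_value = p, method = mode), class = "mw_test")
}
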