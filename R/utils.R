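# Internal helpers shared across modules: interval arithmetic on
# per-day windows, classed error constructors, and a paired Wilcoxon
# wrapper with a fixed exact/approximate policy.

dt_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dyadtempo_error")))
}

#' Merge a set of intervals into disjoint sorted intervals
#' @param start,end numeric vectors of interval endpoints (start <= end)
#' @return data.frame with columns start, end; disjoint, sorted
#' @keywords internal
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  keep <- end > start | end == start
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  rs <- numeric(0); re <- numeric(0)
  ms <- start[1]; me <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        rs <- c(rs, ms); re <- c(re, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(rs, ms), end = c(re, me))
}

#' Intersect one interval set with another (both within one day)
#' @return data.frame(start, end) of non-empty intersections, merged
#' @keywords internal
clip_intervals <- function(ints, windows) {
  if (!nrow(ints) || !nrow(windows)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  out_s <- numeric(0); out_e <- numeric(0)
  for (w in seq_len(nrow(windows))) {
    s <- pmax(ints$start, windows$start[w])
    e <- pmin(ints$end, windows$end[w])
    keep <- e > s
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  merge_intervals(out_s, out_e)
}

#' Total overlap length between an interval [s, e] and a window set
#' @keywords internal
overlap_length <- function(s, e, wstart, wend) {
  sum(pmax(0, pmin(e, wend) - pmax(s, wstart)))
}

#' Force a sorted numeric vector to be strictly increasing
#'
#' Exact ties (e.g. two animals coded with the same onset) are broken by
#' stable input order with a forward perturbation of `eps` seconds, so
#' downstream gap-based algorithms see strictly positive gaps.
#' @keywords internal
make_strictly_increasing <- function(t, eps = 1e-6) {
  if (length(t) < 2) return(t)
  for (i in 2:length(t)) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + eps
  t
}

#' Paired Wilcoxon signed-rank test with a fixed policy
#'
#' Zero differences are dropped (signed-rank convention). The exact
#' distribution is used for up to `exact_max` informative pairs when the
#' absolute differences are untied; otherwise the normal approximation
#' with tie correction is used. All-zero differences give p = 1 with a
#' note rather than an error.
#'
#' @param x,y paired numeric vectors (NA pairs dropped)
#' @param exact_max largest n for which the exact distribution is used
#' @return list(V, p, n, note)
#' @export
paired_wilcoxon <- function(x, y, exact_max = 25) {
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(V = 0, p = 1, n = 0L, note = "no informative pairs"))
  }
  exact <- n <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact))
  list(V = unname(ht$statistic), p = ht$p.value, n = n, note = NA_character_)
}

#' Derive a bounded child seed from a master seed and a stream index
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}
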