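# Kleinberg burst detection on onset series. The infinite-state automaton
# is truncated to a finite cap: states whose expected gap falls below the
# minimum observed gap can never be optimal. Gaps x_1..x_{n-1} between n
# onsets are modelled as exponential with state-dependent rate
# alpha_i = (n/T) * s^i (T = span of the series); moving up j - i states
# costs gamma * (j - i) * ln(n), moving down is free. The minimum-cost
# state path is found by dynamic programming (Viterbi), with ties broken
# toward the lower state for deterministic, burst-sparing output.

#' Optimal Kleinberg state sequence for an onset series
#'
#' @param times strictly increasing numeric vector of onset times
#'   (seconds); pass a single day's onsets
#' @param gamma state-increase penalty coefficient (default 0.3)
#' @param s rate ratio between adjacent states (default 2)
#' @param max_states optional cap on the number of automaton states
#'   (including state 0); default: smallest k with expected gap of state
#'   k below the minimum observed gap, plus one (i.e. states 0..k)
#' @return integer vector of per-gap optimal states (length
#'   `length(times) - 1`), with attributes `cost` (total path cost) and
#'   `n_states`; length-0 for fewer than 2 onsets
#' @export
kleinberg_states <- function(times, gamma = 0.3, s = 2, max_states = NULL) {
  n <- length(times)
  if (n < 2) {
    return(structure(integer(0), cost = 0, n_states = 1L))
  }
  gaps <- diff(times)
  if (any(gaps <= 0)) {
    dt_error("onset times must be strictly increasing", "dt_validation_error")
  }
  if (gamma <= 0 || s <= 1) {
    dt_error("require gamma > 0 and s > 1", "dt_validation_error")
  }
  span <- times[n] - times[1]
  dmin <- min(gaps)
  k <- 0L
  while (span / (n * s^k) >= dmin) k <- k + 1L
  S <- k + 1L
  if (!is.null(max_states)) S <- min(S, as.integer(max_states))
  S <- max(S, 1L)
  alpha <- (n / span) * s^(0:(S - 1))
  logn <- log(n)
  # emission[j, t]: cost of gap t in state j-1
  emis <- outer(-log(alpha), rep(1, n - 1)) + outer(alpha, gaps)
  # tau[i, j]: transition cost from state i-1 to state j-1
  tau <- matrix(0, S, S)
  for (i in 1:S) for (j in 1:S) {
    if (j > i) tau[i, j] <- gamma * (j - i) * logn
  }
  C <- matrix(Inf, n - 1, S)
  B <- matrix(0L, n - 1, S)
  C[1, ] <- tau[1, ] + emis[, 1]  # path starts in state 0
  if (n - 1 >= 2) {
    for (t in 2:(n - 1)) {
      for (j in 1:S) {
        tot <- C[t - 1, ] + tau[, j]
        i <- which.min(tot)  # first minimum = lowest previous state
        C[t, j] <- tot[i] + emis[j, t]
        B[t, j] <- i
      }
    }
  }
  j <- which.min(C[n - 1, ])
  states <- integer(n - 1)
  states[n - 1] <- j - 1L
  if (n - 1 >= 2) {
    for (t in (n - 1):2) {
      j <- B[t, j]
      states[t - 1] <- j - 1L
    }
  }
  structure(states, cost = min(C[n - 1, ]), n_states = S)
}

#' Total path cost of a given state sequence under the Kleinberg model
#'
#' Utility used for optimality checks; shares the model definition with
#' [kleinberg_states()] but evaluates an arbitrary path.
#' @param states integer vector of per-gap states
#' @param times onset times (length `length(states) + 1`)
#' @inheritParams kleinberg_states
#' @return total cost (numeric)
#' @export
kleinberg_path_cost <- function(states, times, gamma = 0.3, s = 2) {
  n <- length(times)
  stopifnot(length(states) == n - 1)
  gaps <- diff(times)
  span <- times[n] - times[1]
  alpha <- function(i) (n / span) * s^i
  prev <- 0L
  cost <- 0
  for (t in seq_along(states)) {
    j <- states[t]
    if (j > prev) cost <- cost + gamma * (j - prev) * log(n)
    a <- alpha(j)
    cost <- cost + (-log(a) + a * gaps[t])
    prev <- j
  }
  cost
}

#' Extract burst intervals of a given order from a state sequence
#'
#' Maximal runs of gaps with state >= `level` become intervals spanning
#' from the onset that begins the first qualifying gap to the onset that
#' ends the last one. Onsets exactly at an endpoint count as inside.
#'
#' @param states per-gap state labels from [kleinberg_states()]
#' @param times the onset times the states were computed from
#' @param level burst order to extract (default 2)
#' @return data.frame(start, end, level) sorted by start
#' @export
extract_bursts <- function(states, times, level = 2) {
  empty <- data.frame(start = numeric(0), end = numeric(0), level = integer(0))
  if (!length(states)) return(empty)
  stopifnot(length(states) == length(times) - 1)
  q <- states >= level
  if (!any(q)) return(empty)
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = times[starts[keep]],
             end = times[ends[keep] + 1],
             level = as.integer(level))
}

#' Detect agonistic bursts for one dyad across days
#'
#' Pools the onsets of all aggressive and subordinate behaviors by either
#' subject, per day, runs burst detection independently on each day's
#' series, and numbers the resulting intervals cumulatively across days
#' in (day, start) order. A burst never spans days. Days with fewer than
#' two agonistic onsets contribute no bursts.
#'
#' @param log an event log
#' @param dyad dyad id
#' @param eth an ethogram
#' @inheritParams kleinberg_states
#' @param level burst order to extract (default 2, "second-order bursts")
#' @return data.frame(dyad_id, day, index, start, end, level)
#' @export
detect_dyad_bursts <- function(log, dyad, eth = default_ethogram(),
                               gamma = 0.3, s = 2, level = 2) {
  series <- extract_onsets(log, dyad, behaviors = agonistic_behaviors(eth))
  out <- NULL
  for (d in sort(unique(series$times$day))) {
    t <- series$times$t[series$times$day == d]
    if (length(t) < 2) next
    st <- kleinberg_states(t, gamma = gamma, s = s)
    b <- extract_bursts(st, t, level = level)
    if (nrow(b)) out <- rbind(out, cbind(day = d, b))
  }
  if (is.null(out)) {
    return(data.frame(dyad_id = character(0), day = integer(0),
                      index = integer(0), start = numeric(0),
                      end = numeric(0), level = integer(0)))
  }
  out <- out[order(out$day, out$start), , drop = FALSE]
  data.frame(dyad_id = dyad, day = as.integer(out$day),
             index = seq_len(nrow(out)), start = out$start, end = out$end,
             level = out$level, row.names = NULL)
}

#' Descriptive burst statistics per dyad-day and across dyads
#'
#' Per dyad-day: burst count, burst durations, and the proportion of
#' aggressive (and, separately, subordinate) onsets falling inside a
#' burst (onsets exactly at a burst endpoint count as inside). Days with
#' zero onsets of a state report the proportion as missing. Across-dyad
#' medians and IQRs are summarised per day and overall.
#'
#' @param log an event log
#' @param bursts burst table as returned by [detect_dyad_bursts()]
#'   (possibly several dyads row-bound)
#' @param eth an ethogram
#' @return list with `per_dyad_day` (dyad_id, day, n_bursts,
#'   median_duration, prop_aggressive_in, prop_subordinate_in) and
#'   `summary` (per-day and overall medians with IQRs)
#' @export
burst_summary <- function(log, bursts, eth = default_ethogram()) {
  agg <- behaviors_of_state(eth, "Aggressive")
  sub <- behaviors_of_state(eth, "Subordinate")
  dyads <- sort(unique(log$dyad_id))
  rows <- NULL
  for (dy in dyads) {
    ld <- log[log$dyad_id == dy, , drop = FALSE]
    for (d in sort(unique(ld$day))) {
      ldd <- ld[ld$day == d, , drop = FALSE]
      bb <- bursts[bursts$dyad_id == dy & bursts$day == d, , drop = FALSE]
      inside <- function(t) {
        if (!nrow(bb) || !length(t)) return(logical(length(t)))
        vapply(t, function(ti) any(ti >= bb$start & ti <= bb$end), logical(1))
      }
      ta <- ldd$onset_s[ldd$behavior %in% agg]
      ts <- ldd$onset_s[ldd$behavior %in% sub]
      rows <- rbind(rows, data.frame(
        dyad_id = dy, day = d, n_bursts = nrow(bb),
        median_duration = if (nrow(bb)) stats::median(bb$end - bb$start) else NA_real_,
        prop_aggressive_in = if (length(ta)) mean(inside(ta)) else NA_real_,
        prop_subordinate_in = if (length(ts)) mean(inside(ts)) else NA_real_
      ))
    }
  }
  qfun <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  }
  summarise <- function(sel, label) {
    f <- qfun(sel$n_bursts); du <- qfun(sel$median_duration)
    pa <- qfun(sel$prop_aggressive_in); ps <- qfun(sel$prop_subordinate_in)
    data.frame(day = label,
               burst_frequency = f[1], freq_q1 = f[2], freq_q3 = f[3],
               burst_duration = du[1], dur_q1 = du[2], dur_q3 = du[3],
               prop_aggressive_in = pa[1], agg_q1 = pa[2], agg_q3 = pa[3],
               prop_subordinate_in = ps[1], sub_q1 = ps[2], sub_q3 = ps[3])
  }
  summ <- NULL
  for (d in sort(unique(rows$day))) {
    summ <- rbind(summ, summarise(rows[rows$day == d, ], as.character(d)))
  }
  # overall: total bursts per dyad over all days, pooled proportions
  per_dyad <- do.call(rbind, lapply(split(rows, rows$dyad_id), function(g) {
    data.frame(n_bursts = sum(g$n_bursts),
               median_duration = stats::median(g$median_duration, na.rm = TRUE),
               prop_aggressive_in = stats::median(g$prop_aggressive_in, na.rm = TRUE),
               prop_subordinate_in = stats::median(g$prop_subordinate_in, na.rm = TRUE))
  }))
  summ <- rbind(summ, summarise(per_dyad, "all"))
  list(per_dyad_day = rows, summary = summ)
}
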