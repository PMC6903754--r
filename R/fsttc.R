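# Directional timed-window cross-correlation between two event trains.
# The Forward Spike Time Tiling Coefficient (FSTTC) of A -> B is
#   1/2 * ((P - T_B) / (1 - P * T_B) + (P - T_A) / (1 - P * T_A))
# where P is the proportion of B onsets lying within dt after any A
# onset, and T_A (T_B) is the proportion of total observation time lying
# within dt after any A (B) onset. It is frequency-insensitive: chance
# coincidence is absorbed by the tiling terms, giving 0 at independence,
# +1 when every B onset follows an A onset within dt, and negative
# values below chance. Window conventions: an onset pair counts when
# b - a lies in [0, dt] (co-initiation counts); tiles are (t, t + dt]
# clipped at observation-window ends; onsets and time in different days
# never interact.

#' Proportion of observation time tiled by forward dt-windows
#'
#' Union of the intervals (t, t + dt] after each onset, clipped to the
#' observation windows (per day), merged where overlapping, divided by
#' the total window length.
#'
#' @param os an [onset_series()]
#' @param dt window length in seconds (default 2)
#' @return proportion in `[0, 1]`; NA when total observation time is 0
#' @export
tiled_time <- function(os, dt = 2) {
  if (os$total_time <= 0) return(NA_real_)
  covered <- 0
  for (d in unique(os$windows$day)) {
    w <- os$windows[os$windows$day == d, c("start", "end"), drop = FALSE]
    t <- os$times$t[os$times$day == d]
    if (!length(t)) next
    tiles <- clip_intervals(data.frame(start = t, end = t + dt), w)
    covered <- covered + sum(tiles$end - tiles$start)
  }
  covered / os$total_time
}

#' Proportion of B onsets within dt after any A onset
#'
#' An onset b of B counts when some onset a of A on the same day
#' satisfies 0 <= b - a <= dt.
#'
#' @param A,B [onset_series()] objects sharing observation windows
#' @param dt window length in seconds (default 2)
#' @return proportion in `[0, 1]`; NA when B has no onsets
#' @export
forward_proportion <- function(A, B, dt = 2) {
  nb <- nrow(B$times)
  if (nb == 0) return(NA_real_)
  hit <- 0L
  for (d in unique(B$times$day)) {
    b <- B$times$t[B$times$day == d]
    a <- sort(A$times$t[A$times$day == d])
    if (!length(a)) next
    ia <- findInterval(b, a)
    hit <- hit + sum(ia > 0 & (b - a[pmax(ia, 1)]) <= dt)
  }
  hit / nb
}

#' Forward Spike Time Tiling Coefficient of A -> B
#'
#' @param A onset series of the actor's given behavior
#' @param B onset series of the responder's target behavior (same
#'   observation windows)
#' @param dt window length in seconds (default 2)
#' @return list of class `"fsttc_result"`: `value`, `P`, `T_A`, `T_B`,
#'   `n_A`, `n_B`, `defined`. Undefined (value NA, `defined = FALSE`)
#'   when either train is empty, total time is zero, or a denominator
#'   vanishes -- never silently zero.
#' @export
forward_sttc <- function(A, B, dt = 2) {
  n_A <- nrow(A$times); n_B <- nrow(B$times)
  res <- list(value = NA_real_, P = NA_real_, T_A = NA_real_, T_B = NA_real_,
              n_A = n_A, n_B = n_B, defined = FALSE)
  class(res) <- "fsttc_result"
  if (n_A == 0 || n_B == 0 || A$total_time <= 0) return(res)
  P <- forward_proportion(A, B, dt)
  T_A <- tiled_time(A, dt)
  T_B <- tiled_time(B, dt)
  res$P <- P; res$T_A <- T_A; res$T_B <- T_B
  if (1 - P * T_B == 0 || 1 - P * T_A == 0) return(res)
  res$value <- 0.5 * ((P - T_B) / (1 - P * T_B) + (P - T_A) / (1 - P * T_A))
  res$defined <- TRUE
  res
}

#' @export
print.fsttc_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<fsttc> %.4f (P=%.3f, T_A=%.3f, T_B=%.3f, n_A=%d, n_B=%d)\n",
                x$value, x$P, x$T_A, x$T_B, x$n_A, x$n_B))
  } else {
    cat("<fsttc> undefined (n_A=", x$n_A, ", n_B=", x$n_B, ")\n", sep = "")
  }
  invisible(x)
}

#' Symmetric Spike Time Tiling Coefficient (cross-check utility)
#'
#' The original symmetric coefficient with two-sided tiles of half-width
#' dt; provided for comparison only.
#' @inheritParams forward_sttc
#' @return numeric value or NA
#' @export
sttc <- function(A, B, dt = 2) {
  n_A <- nrow(A$times); n_B <- nrow(B$times)
  if (n_A == 0 || n_B == 0 || A$total_time <= 0) return(NA_real_)
  two_sided_tiled <- function(os) {
    covered <- 0
    for (d in unique(os$windows$day)) {
      w <- os$windows[os$windows$day == d, c("start", "end"), drop = FALSE]
      t <- os$times$t[os$times$day == d]
      if (!length(t)) next
      tiles <- clip_intervals(data.frame(start = t - dt, end = t + dt), w)
      covered <- covered + sum(tiles$end - tiles$start)
    }
    covered / os$total_time
  }
  near <- function(X, Y) {
    # proportion of X onsets within +/- dt of some Y onset (same day)
    nx <- nrow(X$times)
    hit <- 0L
    for (d in unique(X$times$day)) {
      x <- X$times$t[X$times$day == d]
      y <- sort(Y$times$t[Y$times$day == d])
      if (!length(y) || !length(x)) next
      ix <- findInterval(x, y)
      lo <- pmax(ix, 1)
      hi <- pmin(ix + 1, length(y))
      hit <- hit + sum(abs(x - y[lo]) <= dt | abs(x - y[hi]) <= dt)
    }
    hit / nx
  }
  TA <- two_sided_tiled(A); TB <- two_sided_tiled(B)
  PA <- near(A, B); PB <- near(B, A)
  if (1 - PA * TB == 0 || 1 - PB * TA == 0) return(NA_real_)
  0.5 * ((PA - TB) / (1 - PA * TB) + (PB - TA) / (1 - PB * TA))
}

#' Default behavior groupings for FSTTC contingencies
#'
#' Biting and lunging pooled, tail rattling separate, the subordinate
#' behaviors pooled, plus each full ethogram state.
#' @param eth an ethogram
#' @return named list of behavior-label vectors
#' @export
default_fsttc_groups <- function(eth = default_ethogram()) {
  g <- list(
    lunge_bite = intersect(c("lunge", "bite"), names(eth)),
    tail_rattle = intersect("tail_rattle", names(eth)),
    subordinate = behaviors_of_state(eth, "Subordinate")
  )
  for (s in setdiff(unique(unclass(eth)), c("Aggressive", "Subordinate"))) {
    g[[tolower(s)]] <- behaviors_of_state(eth, s)
  }
  g
}

#' FSTTC contingency table for one dyad
#'
#' For each phase (pre and post by default), each ordered pair of
#' behavior groups and each direction (DOM->SUB: the dominant's given
#' behavior against the subordinate's target behavior; SUB->DOM vice
#' versa), computes the FSTTC on onsets restricted to that phase's
#' windows. Undefined cells are recorded with `fsttc = NA`.
#'
#' @param log an event log
#' @param dyad dyad id
#' @param phases phase table from [segment_phases()]
#' @param roles list(dom =, sub =)
#' @param eth an ethogram
#' @param groupings named list of behavior-label vectors (default
#'   [default_fsttc_groups()])
#' @param dt window length in seconds (default 2)
#' @param phase_set phases to evaluate (default pre and post)
#' @return data.frame(dyad_id, phase, direction, given_group,
#'   target_group, P, T_A, T_B, fsttc, n_A, n_B)
#' @export
dyad_fsttc_table <- function(log, dyad, phases, roles,
                             eth = default_ethogram(),
                             groupings = default_fsttc_groups(eth), dt = 2,
                             phase_set = c("pre", "post")) {
  ph <- phases[phases$dyad_id == dyad, , drop = FALSE]
  out <- NULL
  for (pname in phase_set) {
    w <- ph[ph$phase == pname, c("day", "start", "end"), drop = FALSE]
    if (!nrow(w)) next
    # cache onset series per (subject, group)
    cache <- list()
    get_os <- function(subject, group) {
      key <- paste(subject, group)
      if (is.null(cache[[key]])) {
        cache[[key]] <<- extract_onsets(log, dyad,
                                        behaviors = groupings[[group]],
                                        subjects = subject, windows = w)
      }
      cache[[key]]
    }
    for (dir in c("DOM->SUB", "SUB->DOM")) {
      actor <- if (dir == "DOM->SUB") roles$dom else roles$sub
      responder <- if (dir == "DOM->SUB") roles$sub else roles$dom
      for (gg in names(groupings)) {
        for (tg in names(groupings)) {
          r <- forward_sttc(get_os(actor, gg), get_os(responder, tg), dt = dt)
          out <- rbind(out, data.frame(
            dyad_id = dyad, phase = pname, direction = dir,
            given_group = gg, target_group = tg,
            P = r$P, T_A = r$T_A, T_B = r$T_B,
            fsttc = r$value, n_A = r$n_A, n_B = r$n_B, row.names = NULL))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(dyad_id = character(0), phase = character(0),
                      direction = character(0), given_group = character(0),
                      target_group = character(0), P = numeric(0),
                      T_A = numeric(0), T_B = numeric(0), fsttc = numeric(0),
                      n_A = integer(0), n_B = integer(0))
  }
  out
}

#' Paired comparison of FSTTC directions across dyads
#'
#' For each (given group, target group, phase): a paired Wilcoxon
#' signed-rank test of DOM->SUB against SUB->DOM FSTTC values across
#' dyads. Dyads with an undefined direction are dropped pairwise;
#' undefined values are never imputed as zero. Cells without complete
#' pairs are marked untestable.
#'
#' @param tab row-bound [dyad_fsttc_table()] outputs over dyads
#' @return data.frame(given_group, target_group, phase, n_pairs,
#'   median_dom_sub, median_sub_dom, V, p, testable)
#' @export
compare_directions <- function(tab) {
  out <- NULL
  combos <- unique(tab[c("given_group", "target_group", "phase")])
  for (i in seq_len(nrow(combos))) {
    gg <- combos$given_group[i]; tg <- combos$target_group[i]
    pn <- combos$phase[i]
    sel <- tab[tab$given_group == gg & tab$target_group == tg &
                 tab$phase == pn, , drop = FALSE]
    ds <- sel$fsttc[sel$direction == "DOM->SUB"][
      match(unique(sel$dyad_id), sel$dyad_id[sel$direction == "DOM->SUB"])]
    sd <- sel$fsttc[sel$direction == "SUB->DOM"][
      match(unique(sel$dyad_id), sel$dyad_id[sel$direction == "SUB->DOM"])]
    ok <- is.finite(ds) & is.finite(sd)
    if (!any(ok)) {
      out <- rbind(out, data.frame(
        given_group = gg, target_group = tg, phase = pn, n_pairs = 0L,
        median_dom_sub = NA_real_, median_sub_dom = NA_real_,
        V = NA_real_, p = NA_real_, testable = FALSE, row.names = NULL))
      next
    }
    wt <- paired_wilcoxon(ds[ok], sd[ok])
    out <- rbind(out, data.frame(
      given_group = gg, target_group = tg, phase = pn, n_pairs = sum(ok),
      median_dom_sub = stats::median(ds[ok]),
      median_sub_dom = stats::median(sd[ok]),
      V = wt$V, p = wt$p, testable = TRUE, row.names = NULL))
  }
  out
}
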