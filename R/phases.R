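# Phase segmentation and phase-wise behavior comparison. The
# pre-resolution phase is all session time strictly before the START of
# the burst at which the lenient difference criterion first resolves;
# the post-resolution phase is all session time strictly after the END
# of the burst at which the stringent phi criterion resolves; the middle
# phase (including both boundary bursts) is everything in between.
# Phases are sets of per-day windows -- days are physically separate
# sessions and are never concatenated onto one clock, but phase
# boundaries are located on the cumulative session clock
# (day - 1) * session_length + t.

#' Segment a dyad's observation time into pre / middle / post phases
#'
#' @param bursts burst table for the dyad
#' @param res_diff resolution result of the difference method (must be
#'   resolved)
#' @param res_phi resolution result of the phi method; if unresolved the
#'   post phase is empty and the middle phase extends to the study end
#' @param days integer vector of observed days (each contributes a full
#'   `[0, session_length]` window)
#' @param session_length seconds per session
#' @param dyad_id optional id copied into the output
#' @return data.frame(dyad_id, day, start, end, phase) partitioning each
#'   day's session; zero-length windows are dropped
#' @export
segment_phases <- function(bursts, res_diff, res_phi,
                           days = sort(unique(bursts$day)),
                           session_length = 1200, dyad_id = NA_character_) {
  if (!isTRUE(res_diff$resolved)) {
    dt_error("difference method unresolved: phases undefined",
             "dt_phase_error")
  }
  cum <- function(day, t) (day - 1) * session_length + t
  bd <- bursts[bursts$index == res_diff$resolution_burst_index, , drop = FALSE]
  cum0 <- cum(bd$day, bd$start)
  total <- max(days) * session_length
  if (isTRUE(res_phi$resolved)) {
    bp <- bursts[bursts$index == res_phi$resolution_burst_index, , drop = FALSE]
    cum1 <- cum(bp$day, bp$end)
    if (cum0 > cum1) {
      dt_error("difference-method burst starts after phi-method burst ends",
               "dt_phase_order_error")
    }
  } else {
    cum1 <- total
  }
  rows <- NULL
  for (d in sort(days)) {
    lo <- (d - 1) * session_length
    cuts <- sort(unique(pmin(pmax(c(cum0, cum1), lo), lo + session_length)))
    edges <- unique(c(lo, cuts, lo + session_length))
    for (i in seq_len(length(edges) - 1)) {
      s <- edges[i]; e <- edges[i + 1]
      if (e <= s) next
      mid <- (s + e) / 2
      phase <- if (mid < cum0) "pre" else if (mid <= cum1) "middle" else "post"
      rows <- rbind(rows, data.frame(dyad_id = dyad_id, day = d,
                                     start = s - lo, end = e - lo,
                                     phase = phase))
    }
  }
  rows
}

#' Proportion of phase time spent in each behavior
#'
#' For each subject, phase and behavior: the summed bout duration clipped
#' to the phase's windows, divided by the total phase duration. Phases
#' with zero total duration are omitted.
#'
#' @param log an event log (one dyad, or filter beforehand)
#' @param phases phase table from [segment_phases()] (may cover several
#'   dyads)
#' @param behaviors behaviors to tabulate (default: the ethogram's)
#' @param eth an ethogram
#' @return data.frame(dyad_id, subject_id, phase, behavior, proportion,
#'   phase_duration)
#' @export
phase_proportions <- function(log, phases, behaviors = NULL,
                              eth = default_ethogram()) {
  if (is.null(behaviors)) behaviors <- names(eth)
  out <- NULL
  for (dy in sort(unique(phases$dyad_id))) {
    ph <- phases[phases$dyad_id == dy, , drop = FALSE]
    ld <- log[log$dyad_id == dy, , drop = FALSE]
    subjects <- sort(unique(ld$subject_id))
    for (pname in c("pre", "middle", "post")) {
      w <- ph[ph$phase == pname, , drop = FALSE]
      tot <- sum(w$end - w$start)
      if (tot <= 0) next
      for (subj in subjects) {
        ls <- ld[ld$subject_id == subj & ld$behavior %in% behaviors, , drop = FALSE]
        dur <- stats::setNames(numeric(length(behaviors)), behaviors)
        for (i in seq_len(nrow(ls))) {
          wd <- w[w$day == ls$day[i], , drop = FALSE]
          if (!nrow(wd)) next
          ov <- overlap_length(ls$onset_s[i], ls$offset_s[i], wd$start, wd$end)
          dur[ls$behavior[i]] <- dur[ls$behavior[i]] + ov
        }
        out <- rbind(out, data.frame(
          dyad_id = dy, subject_id = subj, phase = pname,
          behavior = behaviors, proportion = unname(dur) / tot,
          phase_duration = tot, row.names = NULL))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(dyad_id = character(0), subject_id = character(0),
                      phase = character(0), behavior = character(0),
                      proportion = numeric(0), phase_duration = numeric(0))
  }
  out
}

#' Paired dominant-vs-subordinate comparison of phase proportions
#'
#' For every (phase, behavior), a paired Wilcoxon signed-rank test of the
#' dominant's against the subordinate's proportion across dyads. Dyads
#' missing a phase are dropped pairwise. All-zero differences report
#' p = 1 with a note.
#'
#' @param tab output of [phase_proportions()] covering several dyads
#' @param roles data.frame(dyad_id, subject_id, role) with role in
#'   `"dom"`/`"sub"`
#' @return data.frame(phase, behavior, n_pairs, median_dom, median_sub,
#'   V, p, note)
#' @export
compare_phase_behaviors <- function(tab, roles) {
  tab <- merge(tab, roles, by = c("dyad_id", "subject_id"))
  out <- NULL
  for (pname in intersect(c("pre", "middle", "post"), unique(tab$phase))) {
    for (beh in sort(unique(tab$behavior))) {
      sel <- tab[tab$phase == pname & tab$behavior == beh, , drop = FALSE]
      wd <- stats::reshape(sel[c("dyad_id", "role", "proportion")],
                           idvar = "dyad_id", timevar = "role",
                           direction = "wide")
      x <- wd$proportion.dom; y <- wd$proportion.sub
      wt <- paired_wilcoxon(x, y)
      out <- rbind(out, data.frame(
        phase = pname, behavior = beh,
        n_pairs = sum(is.finite(x) & is.finite(y)),
        median_dom = stats::median(x, na.rm = TRUE),
        median_sub = stats::median(y, na.rm = TRUE),
        V = wt$V, p = wt$p, note = wt$note, row.names = NULL))
    }
  }
  out
}
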