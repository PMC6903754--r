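# Relationship-resolution criteria. For every burst a 2x2 agonistic
# matrix (a, b, c, d) is tallied: aggressive/subordinate onset counts by
# the eventual dominant (a, b) and eventual subordinate (c, d). The
# phi-coefficient phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)) measures
# role separation within the burst (+1 = dominant exclusively aggressive
# and subordinate exclusively subordinate); its significance uses
# X^2 = N * phi^2 against chi-square with 1 df. The stringent phi
# criterion and the lenient difference criterion (a - c) >= (b - d) each
# locate the earliest burst from which every later burst stays
# role-consistent.

#' Per-burst 2x2 agonistic matrices
#'
#' @param log an event log
#' @param bursts burst table for one dyad ([detect_dyad_bursts()])
#' @param roles list(dom = subject_id, sub = subject_id)
#' @param eth an ethogram
#' @return data.frame(index, day, a, b, c, d, N) ordered by burst index;
#'   onsets exactly at a burst endpoint count as inside
#' @export
agonistic_matrices <- function(log, bursts, roles, eth = default_ethogram()) {
  agg <- behaviors_of_state(eth, "Aggressive")
  sub <- behaviors_of_state(eth, "Subordinate")
  ld <- log[log$dyad_id %in% unique(bursts$dyad_id), , drop = FALSE]
  count_in <- function(b, subject, behaviors) {
    sel <- ld$day == b$day & ld$subject_id == subject &
      ld$behavior %in% behaviors &
      ld$onset_s >= b$start & ld$onset_s <= b$end
    sum(sel)
  }
  bursts <- bursts[order(bursts$index), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(bursts)), function(i) {
    b <- bursts[i, ]
    a <- count_in(b, roles$dom, agg); bb <- count_in(b, roles$dom, sub)
    cc <- count_in(b, roles$sub, agg); d <- count_in(b, roles$sub, sub)
    data.frame(index = b$index, day = b$day, a = a, b = bb, c = cc, d = d,
               N = a + bb + cc + d)
  }))
  if (is.null(out)) {
    out <- data.frame(index = integer(0), day = integer(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      N = integer(0))
  }
  out
}

#' Phi-coefficient of 2x2 agonistic matrices
#'
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)), with X^2 = N * phi^2
#' (exact identity) and an upper-tail chi-square(1) p-value (no
#' continuity correction). A burst is flagged `excluded` when it has
#' fewer than `min_events` behavior instances or any margin is zero (the
#' denominator vanishes, so phi is undefined).
#'
#' @param m data.frame with columns a, b, c, d (one row per burst), or a
#'   numeric vector c(a, b, c, d)
#' @param min_events minimum behavior instances for a burst to be
#'   evaluable (default 6)
#' @return data.frame(phi, chi_sq, p, N, excluded)
#' @export
phi_coefficient <- function(m, min_events = 6) {
  if (is.numeric(m) && is.null(dim(m))) {
    m <- as.data.frame(as.list(stats::setNames(m, c("a", "b", "c", "d"))))
  }
  a <- m$a; b <- m$b; cc <- m$c; d <- m$d
  N <- a + b + cc + d
  denom2 <- (a + b) * (cc + d) * (a + cc) * (b + d)
  phi <- ifelse(denom2 > 0, (a * d - b * cc) / sqrt(denom2), NA_real_)
  chi_sq <- N * phi^2
  p <- ifelse(is.na(phi), NA_real_,
              stats::pchisq(chi_sq, df = 1, lower.tail = FALSE))
  excluded <- (N < min_events) | denom2 == 0
  data.frame(phi = phi, chi_sq = chi_sq, p = p, N = N, excluded = excluded)
}

#' Assign the eventual dominant from the last two bursts
#'
#' The subject with the higher share of aggressive onsets and the lower
#' share of subordinate onsets pooled over the last two bursts (the last
#' burst only, if just one exists) is the eventual dominant. Both
#' comparisons must agree; a tie on both, or a conflict, raises a
#' role-ambiguity error (class `dt_role_ambiguity`) unless `force` is
#' supplied.
#'
#' @param log an event log
#' @param bursts burst table for one dyad
#' @param eth an ethogram
#' @param force optional list(dom =, sub =) to bypass the rule
#' @return list(dom = subject_id, sub = subject_id)
#' @export
assign_eventual_dominant <- function(log, bursts, eth = default_ethogram(),
                                     force = NULL) {
  if (!is.null(force)) return(force)
  if (!nrow(bursts)) dt_error("no bursts to assign roles from", "dt_role_ambiguity")
  dy <- unique(bursts$dyad_id)
  subjects <- sort(unique(log$subject_id[log$dyad_id == dy]))
  if (length(subjects) != 2) {
    dt_error("dyad must have exactly two subjects", "dt_validation_error")
  }
  last2 <- utils::tail(bursts[order(bursts$index), , drop = FALSE], 2)
  agg <- behaviors_of_state(eth, "Aggressive")
  sub <- behaviors_of_state(eth, "Subordinate")
  ld <- log[log$dyad_id == dy, , drop = FALSE]
  cnt <- function(subject, behaviors) {
    s <- 0L
    for (i in seq_len(nrow(last2))) {
      b <- last2[i, ]
      s <- s + sum(ld$day == b$day & ld$subject_id == subject &
                     ld$behavior %in% behaviors &
                     ld$onset_s >= b$start & ld$onset_s <= b$end)
    }
    s
  }
  a1 <- cnt(subjects[1], agg); a2 <- cnt(subjects[2], agg)
  s1 <- cnt(subjects[1], sub); s2 <- cnt(subjects[2], sub)
  by_agg <- if (a1 > a2) 1L else if (a2 > a1) 2L else NA_integer_
  by_sub <- if (s1 < s2) 1L else if (s2 < s1) 2L else NA_integer_
  cand <- stats::na.omit(c(by_agg, by_sub))
  if (!length(cand) || length(unique(cand)) > 1) {
    dt_error(sprintf(
      "ambiguous roles for dyad %s (agg %d vs %d, sub %d vs %d)",
      dy, a1, a2, s1, s2), "dt_role_ambiguity")
  }
  dom <- subjects[cand[1]]
  list(dom = dom, sub = setdiff(subjects, dom))
}

.resolution_result <- function(method, k, mats, bursts, session_length) {
  if (is.na(k)) {
    return(structure(list(method = method, resolved = FALSE,
                          resolution_burst_index = NA_integer_,
                          resolution_day = NA_integer_,
                          cumulative_interaction_s = NA_real_),
                     class = "resolution_result"))
  }
  idx <- mats$index[k]
  day <- mats$day[k]
  cum <- NA_real_
  if (!is.null(bursts)) {
    b <- bursts[bursts$index == idx, , drop = FALSE]
    if (nrow(b) == 1) cum <- (b$day - 1) * session_length + b$end
  }
  structure(list(method = method, resolved = TRUE,
                 resolution_burst_index = as.integer(idx),
                 resolution_day = as.integer(day),
                 cumulative_interaction_s = cum),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution_result> method:", x$method,
      if (x$resolved) sprintf("resolved at burst %d (day %d, %.0f s cumulative)",
                              x$resolution_burst_index, x$resolution_day,
                              x$cumulative_interaction_s)
      else "unresolved", "\n")
  invisible(x)
}

#' Phi-coefficient resolution criterion
#'
#' The relationship is resolved at the earliest burst k such that k and
#' every later burst satisfy phi > 0 and p < alpha, where bursts flagged
#' excluded (fewer than `min_events` instances, or undefined phi) are
#' skipped entirely when evaluating the criterion. With one or two
#' evaluable bursts remaining the rule degenerates to requiring the final
#' one or two to satisfy it. Unresolved if no such burst exists (in
#' particular if the final evaluable burst fails) or no burst is
#' evaluable.
#'
#' @param mats data.frame(index, day, a, b, c, d) from
#'   [agonistic_matrices()], ordered by index
#' @param bursts optional burst table (for cumulative interaction time)
#' @param alpha significance threshold (default 0.1)
#' @param min_events phi exclusion threshold (default 6)
#' @param session_length seconds per session (default 1200)
#' @return list of class `"resolution_result"`; `$detail` holds the
#'   per-burst phi table
#' @export
resolve_phi <- function(mats, bursts = NULL, alpha = 0.1, min_events = 6,
                        session_length = 1200) {
  ph <- phi_coefficient(mats, min_events = min_events)
  ok <- !ph$excluded & !is.na(ph$phi) & ph$phi > 0 & ph$p < alpha
  evaluable <- which(!ph$excluded & !is.na(ph$phi))
  k <- NA_integer_
  for (i in evaluable) {
    later <- evaluable[evaluable >= i]
    if (all(ok[later])) { k <- i; break }
  }
  res <- .resolution_result("phi", k, mats, bursts, session_length)
  res$detail <- cbind(mats[c("index", "day")], ph)
  res
}

#' Difference-method resolution criterion
#'
#' The relationship is resolved at the earliest burst k such that
#' (a - c) >= (b - d) holds for k and every later burst. All bursts are
#' evaluated (no minimum-instance exclusion); ties satisfy the
#' criterion literally. Unresolved if no such burst exists.
#'
#' @inheritParams resolve_phi
#' @return list of class `"resolution_result"`
#' @export
resolve_difference <- function(mats, bursts = NULL, session_length = 1200) {
  ok <- (mats$a - mats$c) >= (mats$b - mats$d)
  k <- NA_integer_
  n <- nrow(mats)
  if (n) {
    suffix_all <- rev(cumprod(rev(ok))) == 1
    if (any(suffix_all)) k <- which(suffix_all)[1]
  }
  res <- .resolution_result("difference", k, mats, bursts, session_length)
  res$detail <- cbind(mats[c("index", "day")],
                      diff_agg = mats$a - mats$c, diff_sub = mats$b - mats$d,
                      ok = ok)
  res
}
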