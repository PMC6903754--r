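# Event-log data model and IO. The universal input is a tidy long table:
# one row per behavior bout, columns dyad_id, day, subject_id, behavior,
# onset_s, offset_s, with times in seconds relative to the start of that
# day's session (default 20-minute = 1200 s sessions). Cross-day
# timelines are never concatenated onto one clock; all interval logic is
# per (dyad, day).

.DT_COLS <- c("dyad_id", "day", "subject_id", "behavior", "onset_s", "offset_s")

#' Construct a validated event log
#'
#' @param df data.frame with columns dyad_id, day, subject_id, behavior,
#'   onset_s, offset_s
#' @param session_length session duration in seconds (default 1200)
#' @param normalize normalize behavior labels via [normalize_label()]
#' @return data.frame of class `"event_log"`, sorted by
#'   (dyad_id, day, onset_s), with attribute `session_length`
#' @export
event_log <- function(df, session_length = 1200, normalize = TRUE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.DT_COLS, names(df))
  if (length(missing_cols)) {
    dt_error(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
             "dt_format_error")
  }
  df <- df[.DT_COLS]
  df$dyad_id <- as.character(df$dyad_id)
  df$subject_id <- as.character(df$subject_id)
  df$day <- as.integer(df$day)
  df$behavior <- if (normalize) normalize_label(df$behavior) else as.character(df$behavior)
  for (cc in c("onset_s", "offset_s")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) {
      dt_error(paste0("unparseable ", cc, " at row(s): ",
                      paste(utils::head(bad, 10), collapse = ", ")),
               "dt_format_error")
    }
    df[[cc]] <- v
  }
  bad <- which(df$offset_s < df$onset_s)
  if (length(bad)) {
    dt_error(paste0("offset_s < onset_s at row(s): ",
                    paste(utils::head(bad, 10), collapse = ", ")),
             "dt_validation_error")
  }
  if (any(df$onset_s < 0, na.rm = TRUE)) {
    dt_error("negative onset_s", "dt_validation_error")
  }
  df <- df[order(df$dyad_id, df$day, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "session_length") <- session_length
  class(df) <- c("event_log", "data.frame")
  df
}

#' Session length of an event log
#' @param log an event log
#' @export
session_length <- function(log) {
  sl <- attr(log, "session_length")
  if (is.null(sl)) 1200 else sl
}

#' Read an event log from CSV/TSV
#'
#' @param path file path
#' @param dialect optional named character vector mapping standard column
#'   names to the file's header names, e.g.
#'   `c(dyad_id = "Pair", onset_s = "Start")`; unmapped columns are
#'   looked up under their standard names
#' @param session_length session duration in seconds
#' @return an [event_log()]
#' @export
read_event_log <- function(path, dialect = NULL, session_length = 1200) {
  if (!file.exists(path)) {
    dt_error(paste0("file not found: ", path), "dt_format_error")
  }
  raw <- data.table::fread(path, data.table = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      src <- dialect[[std]]
      if (!src %in% names(raw)) {
        dt_error(paste0("dialect column not found in file: ", src),
                 "dt_format_error")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  event_log(raw, session_length = session_length)
}

#' Write an event log to CSV
#' @param log an event log
#' @param path output path
#' @export
write_event_log <- function(log, path) {
  data.table::fwrite(as.data.frame(log)[.DT_COLS], path)
  invisible(path)
}

#' Validate an event log against an ethogram
#'
#' Report-based validation: unknown behavior labels, times outside
#' `[0, session_length]`, and dyads without exactly two subjects are
#' listed; the log is flagged clean iff all lists are empty.
#'
#' @param log an event log
#' @param eth an ethogram
#' @return list of class `"validation_report"` with elements
#'   `unknown_behaviors`, `out_of_session`, `bad_structure`, `clean`
#' @export
validate_events <- function(log, eth = default_ethogram()) {
  sl <- session_length(log)
  unk <- sort(unique(log$behavior[!log$behavior %in% names(eth)]))
  oos <- which(log$onset_s < 0 | log$onset_s > sl |
                 log$offset_s < 0 | log$offset_s > sl)
  ns <- tapply(log$subject_id, log$dyad_id, function(s) length(unique(s)))
  bad_dyads <- names(ns)[ns != 2]
  rep <- list(
    unknown_behaviors = unk,
    out_of_session = data.frame(row = oos,
                                dyad_id = log$dyad_id[oos],
                                day = log$day[oos],
                                onset_s = log$onset_s[oos],
                                offset_s = log$offset_s[oos]),
    bad_structure = data.frame(dyad_id = bad_dyads,
                               n_subjects = as.integer(ns[bad_dyads])),
    clean = length(unk) == 0 && length(oos) == 0 && length(bad_dyads) == 0
  )
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> clean:", x$clean, "\n")
  if (length(x$unknown_behaviors)) {
    cat("  unknown behaviors:", paste(x$unknown_behaviors, collapse = ", "), "\n")
  }
  if (nrow(x$out_of_session)) {
    cat("  out-of-session rows:", nrow(x$out_of_session), "\n")
  }
  if (nrow(x$bad_structure)) {
    cat("  dyads without exactly 2 subjects:",
        paste(x$bad_structure$dyad_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation report as JSON
#' @param report a validation report
#' @param path output path
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct an onset series
#'
#' A set of strictly increasing onset times lying inside disjoint
#' observation windows. Windows and times carry a day index; times in
#' different days never interact in downstream gap or tiling logic.
#'
#' @param times data.frame(day, t) or numeric vector (day taken as 1)
#' @param windows data.frame(day, start, end) or data.frame(start, end)
#' @return list of class `"onset_series"` with elements `times`,
#'   `windows`, `total_time`
#' @export
onset_series <- function(times, windows) {
  if (is.numeric(times)) {
    times <- data.frame(day = rep(1L, length(times)), t = times)
  }
  if (!"day" %in% names(windows)) windows <- cbind(day = 1L, windows)
  windows <- windows[order(windows$day, windows$start), , drop = FALSE]
  times <- times[order(times$day, times$t), , drop = FALSE]
  rownames(times) <- rownames(windows) <- NULL
  structure(list(times = times, windows = windows,
                 total_time = sum(windows$end - windows$start)),
            class = "onset_series")
}

#' @export
print.onset_series <- function(x, ...) {
  cat("<onset_series> ", nrow(x$times), " onsets over ",
      nrow(x$windows), " window(s), total ", x$total_time, " s\n", sep = "")
  invisible(x)
}

#' Extract an onset series from an event log
#'
#' Onset times of the selected behaviors by the selected subjects,
#' clipped to the supplied observation windows. Exact onset ties are kept
#' (distinct records) and perturbed forward by 1e-6 s so the series is
#' strictly increasing within each day.
#'
#' @param log an event log
#' @param dyad dyad id
#' @param behaviors character vector of behavior labels to keep
#' @param subjects subject ids to keep (default: both)
#' @param windows data.frame(day, start, end); default: the full session
#'   on every day the dyad was observed
#' @return an [onset_series()]
#' @export
extract_onsets <- function(log, dyad, behaviors, subjects = NULL,
                           windows = NULL) {
  sl <- session_length(log)
  sub <- log[log$dyad_id == dyad, , drop = FALSE]
  if (is.null(windows)) {
    days <- sort(unique(sub$day))
    windows <- data.frame(day = days, start = rep(0, length(days)),
                          end = rep(sl, length(days)))
  }
  if (!is.null(subjects)) sub <- sub[sub$subject_id %in% subjects, , drop = FALSE]
  sub <- sub[sub$behavior %in% behaviors, , drop = FALSE]
  out <- NULL
  for (d in sort(unique(windows$day))) {
    w <- windows[windows$day == d, , drop = FALSE]
    t <- sub$onset_s[sub$day == d]
    keep <- vapply(t, function(ti) any(ti >= w$start & ti <= w$end), logical(1))
    t <- sort(t[keep])
    t <- make_strictly_increasing(t)
    if (length(t)) out <- rbind(out, data.frame(day = d, t = t))
  }
  if (is.null(out)) out <- data.frame(day = integer(0), t = numeric(0))
  onset_series(out, windows)
}

#' Collapse a subject's events to a no-repeat behavior sequence
#'
#' Behaviors of the subject whose onsets fall inside the windows, ordered
#' by (day, onset), with consecutive duplicate labels collapsed to one.
#'
#' @param log an event log
#' @param subject subject id
#' @param dyad optional dyad id filter
#' @param windows data.frame(day, start, end); default full sessions
#' @return character vector of class `"behavior_sequence"` with no
#'   adjacent duplicates
#' @export
collapse_to_sequence <- function(log, subject, dyad = NULL, windows = NULL) {
  sl <- session_length(log)
  sub <- log[log$subject_id == subject, , drop = FALSE]
  if (!is.null(dyad)) sub <- sub[sub$dyad_id == dyad, , drop = FALSE]
  if (is.null(windows)) {
    days <- sort(unique(sub$day))
    windows <- data.frame(day = days, start = rep(0, length(days)),
                          end = rep(sl, length(days)))
  }
  labs <- character(0)
  for (d in sort(unique(windows$day))) {
    w <- windows[windows$day == d, , drop = FALSE]
    sd <- sub[sub$day == d, , drop = FALSE]
    keep <- vapply(sd$onset_s,
                   function(ti) any(ti >= w$start & ti <= w$end), logical(1))
    sd <- sd[keep, , drop = FALSE]
    labs <- c(labs, sd$behavior[order(sd$onset_s)])
  }
  if (length(labs)) labs <- rle(labs)$values
  structure(labs, class = "behavior_sequence", subject = subject)
}
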