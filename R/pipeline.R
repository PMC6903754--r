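# End-to-end orchestration: events -> bursts -> roles -> per-burst
# matrices -> resolution (both criteria) -> phases -> phase statistics,
# Markov transition analysis, and FSTTC contingencies, with CSV/JSON
# outputs and a run manifest. Per-dyad failures (unresolved
# relationships, ambiguous roles, too-short sequences) are propagated as
# flags, not crashes.

#' Run the full dyadic analysis pipeline
#'
#' @param log an [event_log()] (or a file path readable by
#'   [read_event_log()])
#' @param out_dir output directory; created if missing. Set to NULL to
#'   skip writing files.
#' @param gamma,s,level Kleinberg parameters
#' @param alpha,min_events phi-resolution parameters
#' @param n_perm,p_thresh,prob_thresh,min_transitions Markov parameters
#' @param dt FSTTC window (seconds)
#' @param fsttc_groups FSTTC behavior groupings (default
#'   [default_fsttc_groups()])
#' @param seed manifest seed; all stage randomness derives from it
#' @param eth ethogram
#' @param run_markov,run_fsttc toggle the expensive stages
#' @return invisible list with elements `bursts`, `roles`, `resolution`,
#'   `phases`, `phase_stats`, `markov`, `fsttc`, `fsttc_tests`, `flags`,
#'   `manifest`
#' @export
run_pipeline <- function(log, out_dir = NULL,
                         gamma = 0.3, s = 2, level = 2,
                         alpha = 0.1, min_events = 6,
                         n_perm = 1000, p_thresh = 0.01, prob_thresh = 0.075,
                         min_transitions = 10, dt = 2,
                         fsttc_groups = NULL,
                         seed = 1, eth = default_ethogram(),
                         run_markov = TRUE, run_fsttc = TRUE) {
  if (is.character(log)) log <- read_event_log(log)
  if (is.null(fsttc_groups)) fsttc_groups <- default_fsttc_groups(eth)
  sl <- session_length(log)
  report <- validate_events(log, eth)
  dyads <- sort(unique(log$dyad_id))

  flags <- list()
  flag <- function(dyad, stage, msg) {
    flags[[length(flags) + 1]] <<- data.frame(dyad_id = dyad, stage = stage,
                                              message = msg)
  }

  all_bursts <- NULL; roles_df <- NULL; res_rows <- NULL
  phases_all <- NULL; markov_results <- list(); markov_group <- NULL
  roles_by_dyad <- list()
  fsttc_all <- NULL

  for (dy in dyads) {
    bursts <- detect_dyad_bursts(log, dy, eth, gamma = gamma, s = s,
                                 level = level)
    all_bursts <- rbind(all_bursts, bursts)
    if (!nrow(bursts)) {
      flag(dy, "bursts", "no bursts detected")
      next
    }
    roles <- tryCatch(assign_eventual_dominant(log, bursts, eth),
                      error = function(e) e)
    if (inherits(roles, "error")) {
      flag(dy, "roles", conditionMessage(roles))
      next
    }
    roles_by_dyad[[dy]] <- roles
    roles_df <- rbind(roles_df,
                      data.frame(dyad_id = dy,
                                 subject_id = c(roles$dom, roles$sub),
                                 role = c("dom", "sub")))
    mats <- agonistic_matrices(log, bursts, roles, eth)
    rphi <- resolve_phi(mats, bursts, alpha = alpha, min_events = min_events,
                        session_length = sl)
    rdiff <- resolve_difference(mats, bursts, session_length = sl)
    first_phi <- if (nrow(mats)) phi_coefficient(mats[1, ],
                                                 min_events = min_events)$phi
                 else NA_real_
    res_rows <- rbind(res_rows, data.frame(
      dyad_id = dy, method = c("phi", "difference"),
      resolved = c(rphi$resolved, rdiff$resolved),
      resolution_burst_index = c(rphi$resolution_burst_index,
                                 rdiff$resolution_burst_index),
      resolution_day = c(rphi$resolution_day, rdiff$resolution_day),
      cumulative_interaction_s = c(rphi$cumulative_interaction_s,
                                   rdiff$cumulative_interaction_s),
      first_burst_phi = first_phi))
    if (!rdiff$resolved) {
      flag(dy, "phases", "difference method unresolved; phases undefined")
      next
    }
    if (!rphi$resolved) {
      flag(dy, "resolution", "phi method unresolved; post phase empty")
    }
    ph <- tryCatch(
      segment_phases(bursts, rdiff, rphi, days = sort(unique(log$day)),
                     session_length = sl, dyad_id = dy),
      error = function(e) e)
    if (inherits(ph, "error")) {
      flag(dy, "phases", conditionMessage(ph))
      next
    }
    phases_all <- rbind(phases_all, ph)
  }

  phase_stats <- NULL
  if (!is.null(phases_all) && !is.null(roles_df)) {
    props <- phase_proportions(log, phases_all, eth = eth)
    phase_stats <- compare_phase_behaviors(props, roles_df)
  }

  grouping <- character(0)
  if (run_markov && !is.null(phases_all)) {
    mseed <- derive_seed(seed, 1)
    i <- 0L
    for (dy in names(roles_by_dyad)) {
      ph <- phases_all[phases_all$dyad_id == dy, , drop = FALSE]
      if (!nrow(ph)) next
      roles <- roles_by_dyad[[dy]]
      for (role in c("dom", "sub")) {
        subj <- roles[[role]]
        for (pname in c("pre", "post")) {
          w <- ph[ph$phase == pname, c("day", "start", "end"), drop = FALSE]
          if (!nrow(w)) next
          sq <- collapse_to_sequence(log, subj, dyad = dy, windows = w)
          i <- i + 1L
          r <- tryCatch(
            permutation_transition_test(sq, n_perm = n_perm,
                                        seed = derive_seed(mseed, i),
                                        min_transitions = min_transitions),
            error = function(e) e)
          if (inherits(r, "error")) {
            flag(dy, "markov", paste0(subj, " ", pname, ": ",
                                      conditionMessage(r)))
            next
          }
          id <- paste(subj, pname, sep = ".")
          markov_results[[id]] <- r
          grouping[id] <- paste(role, pname, sep = "_")
        }
      }
    }
    if (length(markov_results)) {
      markov_group <- group_transition_summary(markov_results, grouping,
                                               p_thresh = p_thresh,
                                               prob_thresh = prob_thresh)
    }
  }

  fsttc_tests <- NULL
  if (run_fsttc && !is.null(phases_all)) {
    for (dy in names(roles_by_dyad)) {
      ph <- phases_all[phases_all$dyad_id == dy, , drop = FALSE]
      if (!nrow(ph)) next
      fsttc_all <- rbind(fsttc_all,
                         dyad_fsttc_table(log, dy, ph, roles_by_dyad[[dy]],
                                          eth, groupings = fsttc_groups,
                                          dt = dt))
    }
    if (!is.null(fsttc_all)) fsttc_tests <- compare_directions(fsttc_all)
  }

  flags_df <- if (length(flags)) do.call(rbind, flags) else
    data.frame(dyad_id = character(0), stage = character(0),
               message = character(0))
  manifest <- list(
    package = "dyadtempo",
    version = as.character(utils::packageVersion("dyadtempo")),
    seed = seed,
    params = list(gamma = gamma, s = s, level = level, alpha = alpha,
                  min_events = min_events, n_perm = n_perm,
                  p_thresh = p_thresh, prob_thresh = prob_thresh,
                  min_transitions = min_transitions, dt = dt,
                  session_length = sl),
    counts = list(dyads = length(dyads),
                  events = nrow(log),
                  bursts = if (is.null(all_bursts)) 0L else nrow(all_bursts),
                  flagged = nrow(flags_df)),
    clean_input = report$clean
  )

  out <- list(bursts = all_bursts, roles = roles_df, resolution = res_rows,
              phases = phases_all, phase_stats = phase_stats,
              markov = list(per_individual = markov_results,
                            grouping = grouping, group = markov_group),
              fsttc = fsttc_all, fsttc_tests = fsttc_tests,
              flags = flags_df, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df) && nrow(df)) {
        data.table::fwrite(df, file.path(out_dir, name))
      }
    }
    wr(all_bursts, "bursts.csv")
    wr(roles_df, "roles.csv")
    wr(res_rows, "resolution.csv")
    wr(phases_all, "phases.csv")
    wr(phase_stats, "phase_stats.csv")
    wr(fsttc_all, "fsttc.csv")
    wr(fsttc_tests, "fsttc_tests.csv")
    wr(flags_df, "flags.csv")
    if (!is.null(markov_group)) {
      mdir <- file.path(out_dir, "markov")
      dir.create(mdir, showWarnings = FALSE)
      data.table::fwrite(markov_group, file.path(mdir, "group_transitions.csv"))
      per <- do.call(rbind, lapply(names(markov_results), function(id) {
        cbind(individual = id, group = grouping[[id]], markov_results[[id]])
      }))
      data.table::fwrite(per, file.path(mdir, "individual_transitions.csv"))
      export_kinetogram(markov_group, mdir)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Cohort-level resolution summary
#'
#' Counts of resolved dyads per method and per day, an exact binomial
#' test of the resolution success rate (null p0 = 0.5 by default), a
#' Wilcoxon signed-rank test of the first-burst phi-coefficients against
#' zero, and the median cumulative seconds of interaction to resolution
#' per method.
#'
#' @param resolution the `resolution` table from [run_pipeline()]
#' @param p0 binomial null success probability (default 0.5)
#' @return list(per_method, per_day, binomial, first_phi_test)
#' @export
summarize_resolution <- function(resolution, p0 = 0.5) {
  per_method <- do.call(rbind, lapply(split(resolution, resolution$method),
                                      function(g) {
    data.frame(method = g$method[1],
               n = nrow(g),
               n_resolved = sum(g$resolved),
               median_cumulative_s = stats::median(
                 g$cumulative_interaction_s[g$resolved], na.rm = TRUE))
  }))
  per_day <- stats::aggregate(resolved ~ method + resolution_day,
                              data = resolution[resolution$resolved, ],
                              FUN = length)
  names(per_day)[names(per_day) == "resolved"] <- "n_resolved"
  phis <- resolution$first_burst_phi[resolution$method == "phi"]
  phis <- phis[is.finite(phis)]
  first_phi_test <- if (length(phis[phis != 0])) {
    ht <- suppressWarnings(
      stats::wilcox.test(phis, mu = 0,
                         exact = length(phis) <= 25 && !anyDuplicated(abs(phis[phis != 0]))))
    list(V = unname(ht$statistic), p = ht$p.value, n = length(phis))
  } else list(V = 0, p = 1, n = length(phis))
  nphi <- sum(resolution$method == "phi")
  kphi <- sum(resolution$resolved[resolution$method == "phi"])
  binom <- stats::binom.test(kphi, nphi, p = p0)
  list(per_method = per_method, per_day = per_day,
       binomial = list(k = kphi, n = nphi, p0 = p0, p = binom$p.value),
       first_phi_test = first_phi_test)
}
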