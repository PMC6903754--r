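# Synthetic dyad generator with planted ground truth. Each simulated
# dyad emulates the stated study structure: two subjects interacting for
# n_days daily 1200 s sessions, agonistic behavior concentrated in a
# small number of planted bursts per day (counts decreasing over days,
# durations 15-25 s), symmetric aggressive/subordinate mixing before a
# planted resolution burst k* and role-differentiated behavior after it,
# continuous non-agonistic filler behavior driven by a no-repeat
# first-order transition kernel, and optionally planted forward
# contingency: with probability theta a partner response onset is
# inserted shortly after a given onset (a directional, not symmetric,
# dependency).

#' Uniform no-repeat transition kernel over a label set
#' @param labels character vector
#' @return row-stochastic matrix with zero diagonal
#' @export
uniform_kernel <- function(labels) {
  k <- length(labels)
  m <- matrix(1 / (k - 1), k, k, dimnames = list(labels, labels))
  diag(m) <- 0
  m
}

#' Multiply one transition's kernel weight and renormalize its row
#' @param kernel a no-repeat kernel
#' @param from,to labels of the boosted transition
#' @param factor multiplicative boost (default 5)
#' @export
boost_kernel <- function(kernel, from, to, factor = 5) {
  kernel[from, to] <- kernel[from, to] * factor
  kernel[from, ] <- kernel[from, ] / sum(kernel[from, ])
  kernel
}

#' Simulate a no-repeat first-order Markov label sequence
#' @param kernel row-stochastic kernel with zero diagonal (dimnames =
#'   labels)
#' @param n sequence length
#' @param seed optional RNG seed
#' @return character vector of length n with no adjacent duplicates
#' @export
simulate_markov_sequence <- function(kernel, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- rownames(kernel)
  out <- character(n)
  if (!n) return(out)
  out[1] <- sample(labels, 1)
  for (i in seq_len(n - 1)) {
    out[i + 1] <- sample(labels, 1, prob = kernel[out[i], ])
  }
  out
}

#' Configuration for the synthetic dyad generator
#'
#' Defaults state the emulated world: 21 dyads, 5 days of 1200 s
#' sessions; planted agonistic bursts per day decreasing 6, 3, 2, 2, 1
#' with durations 15-25 s; agonistic onset rate 0.5 events/s per subject
#' inside bursts against 0.005 events/s outside (rate ratio far above
#' the detection floor); role differentiation from cumulative burst
#' index `resolution_burst` (default 6, the first burst of day 2) with
#' symmetric mixing (`pre_mix` = 0.5) before it and role fidelity 0.95
#' after; continuous non-agonistic filler at 0.25 events/s per subject
#' (hundreds of events per subject-day).
#'
#' @param n_dyads,n_days,session_length cohort shape
#' @param baseline_event_rate filler events/s per subject
#' @param bursts_per_day integer vector, recycled/truncated to n_days
#' @param burst_duration_range c(min, max) seconds on day 1
#' @param burst_duration_day_slope seconds added to both bounds per
#'   elapsed day (default 2: day-5 bursts run 23-33 s), emulating the
#'   observed lengthening of bursts as counts fall
#' @param burst_agonistic_rate agonistic events/s per subject in bursts
#' @param quiescent_agonistic_rate same, outside bursts
#' @param resolution_burst planted k* (cumulative burst index)
#' @param pre_mix P(agonistic event is aggressive) before k*, both roles
#' @param post_dom_aggressive P(dominant's agonistic event is
#'   aggressive) from k* on
#' @param post_sub_subordinate P(subordinate's agonistic event is
#'   subordinate) from k* on
#' @param bout_duration_meanlog,bout_duration_sdlog lognormal filler
#'   bout durations
#' @param agonistic_bout_meanlog,agonistic_bout_sdlog lognormal
#'   agonistic bout durations
#' @param transition_kernel NULL (uniform over non-agonistic behaviors),
#'   a single kernel, or a list with elements dom_pre, dom_post,
#'   sub_pre, sub_post
#' @param theta NULL or data.frame(given_group, target_group, direction,
#'   prob) of planted forward-contingency probabilities
#' @param theta_window c(lo, hi) seconds: planted response lag window
#' @param eth ethogram
#' @return list of class `"synthetic_config"`
#' @export
synthetic_config <- function(n_dyads = 21, n_days = 5, session_length = 1200,
                             baseline_event_rate = 0.25,
                             bursts_per_day = c(6, 3, 2, 2, 1),
                             burst_duration_range = c(15, 25),
                             burst_duration_day_slope = 2,
                             burst_agonistic_rate = 0.5,
                             quiescent_agonistic_rate = 0.005,
                             resolution_burst = 6,
                             pre_mix = 0.5,
                             post_dom_aggressive = 0.95,
                             post_sub_subordinate = 0.95,
                             bout_duration_meanlog = log(1.5),
                             bout_duration_sdlog = 0.6,
                             agonistic_bout_meanlog = log(0.8),
                             agonistic_bout_sdlog = 0.5,
                             transition_kernel = NULL,
                             theta = NULL,
                             theta_window = c(0.1, 2),
                             eth = default_ethogram()) {
  cfg <- list(n_dyads = n_dyads, n_days = n_days,
              session_length = session_length,
              baseline_event_rate = baseline_event_rate,
              bursts_per_day = rep_len(bursts_per_day, n_days),
              burst_duration_range = burst_duration_range,
              burst_duration_day_slope = burst_duration_day_slope,
              burst_agonistic_rate = burst_agonistic_rate,
              quiescent_agonistic_rate = quiescent_agonistic_rate,
              resolution_burst = resolution_burst,
              pre_mix = pre_mix,
              post_dom_aggressive = post_dom_aggressive,
              post_sub_subordinate = post_sub_subordinate,
              bout_duration_meanlog = bout_duration_meanlog,
              bout_duration_sdlog = bout_duration_sdlog,
              agonistic_bout_meanlog = agonistic_bout_meanlog,
              agonistic_bout_sdlog = agonistic_bout_sdlog,
              transition_kernel = transition_kernel,
              theta = theta, theta_window = theta_window, eth = eth)
  stopifnot(baseline_event_rate > 0, burst_agonistic_rate > 0,
            quiescent_agonistic_rate >= 0,
            pre_mix >= 0, pre_mix <= 1,
            post_dom_aggressive >= 0, post_dom_aggressive <= 1,
            post_sub_subordinate >= 0, post_sub_subordinate <= 1)
  probs_ok <- is.null(theta) || all(theta$prob >= 0 & theta$prob <= 1)
  if (!probs_ok) dt_error("theta probabilities outside [0, 1]", "dt_config_error")
  if (!is.null(transition_kernel)) {
    ks <- if (is.matrix(transition_kernel)) list(transition_kernel)
          else transition_kernel
    for (kk in ks) {
      if (any(diag(kk) != 0) || any(abs(rowSums(kk) - 1) > 1e-8)) {
        dt_error("transition kernels must be row-stochastic with zero diagonal",
                 "dt_config_error")
      }
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

.get_kernel <- function(cfg, role, phase) {
  tk <- cfg$transition_kernel
  if (is.null(tk)) {
    filler <- setdiff(names(cfg$eth), agonistic_behaviors(cfg$eth))
    return(uniform_kernel(filler))
  }
  if (is.matrix(tk)) return(tk)
  tk[[paste(role, phase, sep = "_")]]
}

.place_bursts <- function(n_b, dur_range, L, margin = 30, min_gap = 60) {
  if (n_b == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  dur <- stats::runif(n_b, dur_range[1], dur_range[2])
  slack <- (L - 2 * margin) - sum(dur) - min_gap * (n_b - 1)
  if (slack < 0) {
    dt_error("burst schedule does not fit in the session", "dt_config_error")
  }
  extra <- stats::runif(n_b + 1)
  extra <- extra / sum(extra) * slack
  starts <- numeric(n_b)
  pos <- margin
  for (i in seq_len(n_b)) {
    pos <- pos + extra[i]
    starts[i] <- pos
    pos <- pos + dur[i] + min_gap
  }
  data.frame(start = starts, end = starts + dur)
}

.sample_outside <- function(n, bursts, L) {
  if (!n) return(numeric(0))
  comp <- data.frame(start = c(0, bursts$end), end = c(bursts$start, L))
  comp <- comp[comp$end > comp$start, , drop = FALSE]
  len <- comp$end - comp$start
  w <- sample.int(nrow(comp), n, replace = TRUE, prob = len)
  comp$start[w] + stats::runif(n) * len[w]
}

#' Simulate one dyad's event log with ground truth
#'
#' @param cfg a [synthetic_config()]
#' @param dyad_id dyad identifier
#' @param seed optional RNG seed (deterministic output under a fixed
#'   seed)
#' @return list(log = [event_log()], truth = list(dyad_id, roles,
#'   bursts, k_star, theta))
#' @export
simulate_dyad <- function(cfg, dyad_id = "D01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eth <- cfg$eth
  L <- cfg$session_length
  agg_b <- behaviors_of_state(eth, "Aggressive")
  sub_b <- behaviors_of_state(eth, "Subordinate")
  subjects <- paste0(dyad_id, c("_1", "_2"))
  dom <- sample(subjects, 1)
  roles <- list(dom = dom, sub = setdiff(subjects, dom))
  k_star <- cfg$resolution_burst

  kernels <- list()
  for (ro in c("dom", "sub")) for (phz in c("pre", "post")) {
    kernels[[paste(ro, phz, sep = "_")]] <- .get_kernel(cfg, ro, phz)
  }

  truth_bursts <- NULL
  ev <- list()
  burst_counter <- 0L
  kstar_clock <- NA_real_  # cumulative clock time at which roles switch

  for (d in seq_len(cfg$n_days)) {
    bd <- .place_bursts(cfg$bursts_per_day[d],
                        cfg$burst_duration_range +
                          cfg$burst_duration_day_slope * (d - 1), L)
    if (nrow(bd)) {
      idx <- burst_counter + seq_len(nrow(bd))
      truth_bursts <- rbind(truth_bursts,
                            data.frame(day = d, index = idx, bd))
      if (is.na(kstar_clock) && any(idx == k_star)) {
        kstar_clock <- (d - 1) * L + bd$start[idx == k_star]
      }
    }
    day_rows <- NULL
    for (subj in subjects) {
      is_dom <- subj == roles$dom
      # agonistic events inside bursts
      for (i in seq_len(nrow(bd))) {
        kb <- burst_counter + i
        durb <- bd$end[i] - bd$start[i]
        n <- stats::rpois(1, cfg$burst_agonistic_rate * durb)
        if (!n) next
        t <- sort(stats::runif(n, bd$start[i], bd$end[i]))
        p_agg <- if (kb < k_star) cfg$pre_mix else {
          if (is_dom) cfg$post_dom_aggressive else 1 - cfg$post_sub_subordinate
        }
        is_agg <- stats::runif(n) < p_agg
        beh <- ifelse(is_agg, sample(agg_b, n, replace = TRUE),
                      sample(sub_b, n, replace = TRUE))
        durs <- stats::rlnorm(n, cfg$agonistic_bout_meanlog,
                              cfg$agonistic_bout_sdlog)
        day_rows <- rbind(day_rows, data.frame(
          subject_id = subj, behavior = beh, onset_s = t,
          offset_s = pmin(t + durs, L)))
      }
      # sparse agonistic events outside bursts
      out_len <- L - sum(bd$end - bd$start)
      n <- stats::rpois(1, cfg$quiescent_agonistic_rate * out_len)
      if (n) {
        t <- .sample_outside(n, bd, L)
        clock <- (d - 1) * L + t
        post <- !is.na(kstar_clock) & clock >= kstar_clock
        p_agg <- ifelse(post,
                        if (is_dom) cfg$post_dom_aggressive
                        else 1 - cfg$post_sub_subordinate,
                        cfg$pre_mix)
        is_agg <- stats::runif(n) < p_agg
        beh <- ifelse(is_agg, sample(agg_b, n, replace = TRUE),
                      sample(sub_b, n, replace = TRUE))
        durs <- stats::rlnorm(n, cfg$agonistic_bout_meanlog,
                              cfg$agonistic_bout_sdlog)
        day_rows <- rbind(day_rows, data.frame(
          subject_id = subj, behavior = beh, onset_s = t,
          offset_s = pmin(t + durs, L)))
      }
      # continuous non-agonistic filler via no-repeat kernel
      n <- stats::rpois(1, cfg$baseline_event_rate * L)
      if (n) {
        t <- sort(stats::runif(n, 0, L))
        clock <- (d - 1) * L + t
        role <- if (is_dom) "dom" else "sub"
        phase <- ifelse(!is.na(kstar_clock) & clock >= kstar_clock,
                        "post", "pre")
        beh <- character(n)
        prev <- NA_character_
        for (i in seq_len(n)) {
          kern <- kernels[[paste(role, phase[i], sep = "_")]]
          labs <- rownames(kern)
          beh[i] <- if (is.na(prev) || !(prev %in% labs)) sample(labs, 1)
                    else sample(labs, 1, prob = kern[prev, ])
          prev <- beh[i]
        }
        durs <- stats::rlnorm(n, cfg$bout_duration_meanlog,
                              cfg$bout_duration_sdlog)
        day_rows <- rbind(day_rows, data.frame(
          subject_id = subj, behavior = beh, onset_s = t,
          offset_s = pmin(t + durs, L)))
      }
    }
    # planted forward contingency: insert responder onsets after given
    # onsets with probability theta, displacing the responder's next bout
    if (!is.null(cfg$theta) && nrow(day_rows)) {
      groups <- default_fsttc_groups(eth)
      for (r in seq_len(nrow(cfg$theta))) {
        th <- cfg$theta[r, ]
        if (th$prob <= 0) next
        actor <- if (th$direction == "DOM->SUB") roles$dom else roles$sub
        responder <- setdiff(subjects, actor)
        given <- day_rows$onset_s[day_rows$subject_id == actor &
                                    day_rows$behavior %in%
                                    groups[[th$given_group]]]
        for (g0 in given) {
          if (stats::runif(1) >= th$prob) next
          rt <- g0 + stats::runif(1, cfg$theta_window[1], cfg$theta_window[2])
          if (rt > L) next
          # displace the responder's next scheduled bout, if any
          nxt <- which(day_rows$subject_id == responder &
                         day_rows$onset_s > rt)
          if (length(nxt)) {
            nxt <- nxt[which.min(day_rows$onset_s[nxt])]
            day_rows <- day_rows[-nxt, , drop = FALSE]
          }
          tb <- groups[[th$target_group]]
          day_rows <- rbind(day_rows, data.frame(
            subject_id = responder,
            behavior = if (length(tb) == 1) tb else sample(tb, 1),
            onset_s = rt,
            offset_s = pmin(rt + stats::rlnorm(1, cfg$agonistic_bout_meanlog,
                                               cfg$agonistic_bout_sdlog), L)))
        }
      }
    }
    if (!is.null(day_rows) && nrow(day_rows)) {
      ev[[d]] <- cbind(dyad_id = dyad_id, day = d, day_rows)
    }
    burst_counter <- burst_counter + nrow(bd)
  }
  log <- event_log(do.call(rbind, ev), session_length = L)
  list(log = log,
       truth = list(dyad_id = dyad_id, roles = roles,
                    bursts = truth_bursts, k_star = k_star,
                    theta = cfg$theta))
}

#' Simulate a cohort of independent dyads
#'
#' Per-dyad seeds are derived from the master seed and the dyad index,
#' so each dyad's log is independent of cohort ordering.
#'
#' @param cfg a [synthetic_config()]
#' @param seed master seed
#' @return list(log = combined [event_log()], truth = per-dyad list)
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  logs <- list(); truths <- list()
  for (i in seq_len(cfg$n_dyads)) {
    id <- sprintf("D%02d", i)
    sim <- simulate_dyad(cfg, dyad_id = id, seed = derive_seed(seed, i))
    logs[[i]] <- as.data.frame(sim$log)
    truths[[id]] <- sim$truth
  }
  list(log = event_log(do.call(rbind, logs),
                       session_length = cfg$session_length),
       truth = truths)
}

#' Write a cohort to a tidy CSV plus a ground-truth JSON
#' @param cohort output of [simulate_cohort()]
#' @param events_path CSV path for the event log
#' @param truth_path JSON path for the ground truth
#' @export
write_cohort <- function(cohort, events_path, truth_path) {
  write_event_log(cohort$log, events_path)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(events = events_path, truth = truth_path))
}
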