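# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different computational route from the
# implementation it checks (exhaustive enumeration, rasterization,
# stats::loglin, direct formulas).

mk_log <- function(subject, behavior, onset, offset = onset + 0.5,
                   day = 1, dyad = "d1", session_length = 1200) {
  event_log(data.frame(dyad_id = dyad, day = day, subject_id = subject,
                       behavior = behavior, onset_s = onset,
                       offset_s = offset),
            session_length = session_length)
}

random_log <- function(n = 50, dyad = "d1", session_length = 1200) {
  beh <- names(default_ethogram())
  on <- round(runif(n, 0, session_length - 10), 3)
  data.frame(dyad_id = dyad,
             day = sample(1:3, n, replace = TRUE),
             subject_id = sample(paste0(dyad, c("_1", "_2")), n, replace = TRUE),
             behavior = sample(beh, n, replace = TRUE),
             onset_s = on,
             offset_s = round(on + runif(n, 0.1, 8), 3))
}

make_unique_times <- function(t, eps = 1e-4) {
  t <- sort(t)
  for (i in seq_along(t)[-1]) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + eps
  t
}

# exhaustive minimum-cost search over all state sequences (states capped)
kleinberg_brute <- function(times, gamma = 0.3, s = 2, max_states = 4) {
  n <- length(times); g <- n - 1
  gaps <- diff(times); span <- times[n] - times[1]; dmin <- min(gaps)
  k <- 0
  while (span / (n * s^k) >= dmin) k <- k + 1
  S <- max(min(k + 1, max_states), 1)
  alpha <- (n / span) * s^(0:(S - 1))
  emis <- outer(0:(S - 1), 1:g,
                function(j, t) -log(alpha[j + 1]) + alpha[j + 1] * gaps[t])
  total <- S^g
  idx <- seq_len(total) - 1L
  cost <- numeric(total)
  prev <- integer(total)
  Sl <- 1
  logn <- log(n)
  for (t in 1:g) {
    digit <- (idx %/% Sl) %% S
    up <- digit - prev; up[up < 0] <- 0L
    cost <- cost + gamma * logn * up + emis[cbind(digit + 1, t)]
    prev <- digit
    Sl <- Sl * S
  }
  best <- which.min(cost)
  states <- integer(g); b <- best - 1L
  for (t in 1:g) { states[t] <- b %% S; b <- b %/% S }
  list(min_cost = min(cost), states = states, S = S)
}

# brute-force scan for the earliest index from which all later evaluable
# bursts satisfy the criterion
resolve_phi_oracle <- function(mats, alpha = 0.1, min_events = 6) {
  ph <- phi_coefficient(mats, min_events = min_events)
  ev <- which(!ph$excluded & !is.na(ph$phi))
  ok <- !is.na(ph$phi) & ph$phi > 0 & ph$p < alpha
  for (k in ev) {
    later <- ev[ev >= k]
    good <- TRUE
    for (j in later) if (!ok[j]) { good <- FALSE; break }
    if (good) return(mats$index[k])
  }
  NA_integer_
}

resolve_difference_oracle <- function(mats) {
  n <- nrow(mats)
  for (k in seq_len(n)) {
    good <- TRUE
    for (j in k:n) {
      if (!((mats$a[j] - mats$c[j]) >= (mats$b[j] - mats$d[j]))) {
        good <- FALSE; break
      }
    }
    if (good) return(mats$index[k])
  }
  NA_integer_
}

# rasterized forward-tile coverage: fraction of 1 ms grid midpoints
# (within the windows) lying in some (t, t + dt] tile
tiled_time_raster <- function(times, windows, dt, step = 0.001) {
  pts <- unlist(lapply(seq_len(nrow(windows)), function(i) {
    seq(windows$start[i] + step / 2, windows$end[i], by = step)
  }))
  covered <- vapply(pts, function(p) any(p > times & p <= times + dt),
                    logical(1))
  mean(covered)
}

# rasterized proportion of phase time a subject spends in a behavior
phase_prop_raster <- function(log, windows, subject, behavior, step = 0.01) {
  tot <- 0; hit <- 0
  bouts <- log[log$subject_id == subject & log$behavior == behavior, ]
  for (i in seq_len(nrow(windows))) {
    pts <- seq(windows$start[i] + step / 2, windows$end[i], by = step)
    bd <- bouts[bouts$day == windows$day[i], ]
    tot <- tot + length(pts)
    if (nrow(bd)) {
      hit <- hit + sum(vapply(pts, function(p) {
        any(p >= bd$onset_s & p < bd$offset_s)
      }, logical(1)))
    }
  }
  hit / tot
}

# quasi-independence expected counts via stats::loglin with a
# structural-zero start (independent code path from the package IPF)
ipf_oracle <- function(O) {
  start <- matrix(1, nrow(O), ncol(O))
  diag(start) <- 0
  fit <- suppressWarnings(
    stats::loglin(O, margin = list(1, 2), start = start, fit = TRUE,
                  eps = 1e-12, iter = 50000, print = FALSE))
  fit$fit
}

# random burst-matrix sequences with a realistic mix of small (excluded)
# and decisive bursts
mk_mats_random <- function(n) {
  a <- rpois(n, 3); b <- rpois(n, 1.5); cc <- rpois(n, 1.5); d <- rpois(n, 3)
  data.frame(index = seq_len(n), day = 1L, a = a, b = b, c = cc, d = d,
             N = a + b + cc + d)
}

fsttc_formula <- function(P, TA, TB) {
  0.5 * ((P - TB) / (1 - P * TB) + (P - TA) / (1 - P * TA))
}
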