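# Within-individual first-order transition analysis. Because no-repeat
# sequences forbid self-transitions, the transition table has structural
# zeros on its diagonal; expected counts under quasi-independence are
# obtained by iterative proportional fitting (alternating row/column
# scaling of an off-diagonal seed), the global likelihood-ratio G^2 test
# uses degrees of freedom (k-1)^2 - k adjusted for the structural
# diagonal, and per-transition significance comes from permutation nulls
# that preserve the no-adjacent-repeat property.

#' First-order transition counts of a no-repeat sequence
#'
#' @param seq character vector (behavior sequence with no adjacent
#'   duplicates)
#' @param min_transitions minimum transitions required (default 2);
#'   shorter sequences raise a `dt_sequence_too_short` error
#' @return list of class `"transition_matrix"`: `labels`, `observed`
#'   (k x k integer matrix, structural-zero diagonal), `expected`
#'   (NULL until fitted), `total`
#' @export
transition_counts <- function(seq, min_transitions = 2) {
  seq <- as.character(seq)
  n <- length(seq)
  if (n >= 2 && any(seq[-1] == seq[-n])) {
    dt_error("sequence has adjacent duplicate labels", "dt_validation_error")
  }
  if (n - 1 < min_transitions) {
    dt_error(sprintf("sequence too short: %d transitions (< %d)",
                     max(n - 1, 0), min_transitions),
             "dt_sequence_too_short")
  }
  labels <- sort(unique(seq))
  k <- length(labels)
  idx <- match(seq, labels)
  counts <- tabulate((idx[-n] - 1L) * k + idx[-1], nbins = k * k)
  # bin index is (from - 1) * k + to, i.e. row-major by 'from'
  O <- matrix(counts, k, k, byrow = TRUE, dimnames = list(labels, labels))
  structure(list(labels = labels, observed = O, expected = NULL,
                 total = sum(O)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", length(x$labels), " labels, ",
      x$total, " transitions", if (!is.null(x$expected)) ", fitted" else "",
      "\n", sep = "")
  invisible(x)
}

#' Quasi-independence expected counts via iterative proportional fitting
#'
#' Fits expected counts E with zero diagonal whose row and column sums
#' match the observed table, starting from a seed of ones off the
#' diagonal and alternating row and column scaling. Rows or columns with
#' zero observed margin are dropped from the fit (their E set to zero)
#' and reduce the degrees of freedom.
#'
#' @param tm a transition matrix from [transition_counts()]
#' @param tol maximum allowed margin discrepancy (default 1e-10)
#' @param max_iter iteration cap (default 10000)
#' @return the transition matrix with `expected` filled and attributes
#'   `iterations` and `discrepancy`
#' @export
quasi_independence_expected <- function(tm, tol = 1e-10, max_iter = 10000) {
  O <- tm$observed
  k <- nrow(O)
  rs <- rowSums(O); cs <- colSums(O)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2) {
    dt_error("need at least 2 nonzero rows and columns", "dt_validation_error")
  }
  E <- matrix(1, k, k, dimnames = dimnames(O))
  diag(E) <- 0
  E[rs == 0, ] <- 0
  E[, cs == 0] <- 0
  disc <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    er <- rowSums(E)
    sc <- ifelse(er > 0, rs / er, 0)
    E <- E * sc
    ec <- colSums(E)
    sc <- ifelse(ec > 0, cs / ec, 0)
    E <- sweep(E, 2, sc, `*`)
    disc <- max(abs(rowSums(E) - rs), abs(colSums(E) - cs))
    if (disc < tol) break
  }
  if (disc >= tol) {
    dt_error(sprintf("IPF did not converge: discrepancy %.3g after %d iterations",
                     disc, it), "dt_convergence_error")
  }
  tm$expected <- E
  attr(tm$expected, "iterations") <- it
  attr(tm$expected, "discrepancy") <- disc
  tm
}

#' Likelihood-ratio G^2 test of a fitted transition matrix
#'
#' G^2 = 2 * sum over cells with O > 0 of O * ln(O / E); df =
#' (k - 1)^2 - k for a full k x k table with k structural diagonal
#' zeros, reduced by one per additional structurally empty row or
#' column. df <= 0 (e.g. k = 2) yields a test-not-defined result.
#'
#' @param tm a fitted transition matrix
#' @return list(g2, df, p, defined)
#' @export
g2_test <- function(tm) {
  if (is.null(tm$expected)) {
    dt_error("expected counts not fitted; call quasi_independence_expected()",
             "dt_validation_error")
  }
  O <- tm$observed; E <- tm$expected
  k <- nrow(O)
  pos <- O > 0
  g2 <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  n_empty <- sum(rowSums(O) == 0) + sum(colSums(O) == 0)
  df <- (k - 1)^2 - k - n_empty
  if (df < 1) {
    return(list(g2 = g2, df = df, p = NA_real_, defined = FALSE))
  }
  list(g2 = g2, df = df,
       p = stats::pchisq(g2, df = df, lower.tail = FALSE), defined = TRUE)
}

#' Random no-adjacent-repeat rearrangement of a label multiset
#'
#' Primary sampler: Fisher-Yates shuffles with rejection of arrangements
#' containing adjacent duplicates (unbiased when feasible), capped at
#' `max_attempts`. Rejection is skipped outright when it is provably
#' hopeless -- a uniform shuffle avoids adjacent repeats with
#' probability about exp(-(n-1) * sum(p_i^2)), so when even
#' `max_attempts` draws have under a 1% chance of a single success the
#' sampler goes straight to the fallback. The fallback places labels one
#' at a time among feasibility-preserving candidates weighted by
#' remaining multiplicity (slightly biased; documented). Infeasible
#' multisets (one label occurring more than ceiling(n/2) times) raise a
#' `dt_infeasible` error.
#'
#' @param labels character vector (the sequence to permute)
#' @param max_attempts rejection cap before the constructive fallback
#' @return a permutation of `labels` with no adjacent duplicates
#' @export
permute_no_repeats <- function(labels, max_attempts = 10000) {
  n <- length(labels)
  if (n < 2) return(labels)
  ulab <- unique(labels)
  k <- length(ulab)
  cnt0 <- tabulate(match(labels, ulab), k)
  if (max(cnt0) > ceiling(n / 2)) {
    dt_error("no arrangement without adjacent repeats exists", "dt_infeasible")
  }
  exp_coll <- (n - 1) * sum((cnt0 / n)^2)
  hopeless <- max_attempts * exp(-exp_coll) < 0.01
  if (!hopeless) {
    for (a in seq_len(max_attempts)) {
      x <- labels[sample.int(n)]
      if (!any(x[-1] == x[-n])) return(x)
    }
  }
  # constructive sampler (integer-indexed for speed)
  cnt <- cnt0
  res <- integer(n)
  prev <- 0L
  for (pos in seq_len(n)) {
    rem <- n - pos + 1L
    w <- cnt
    if (prev > 0L) w[prev] <- 0L
    if (2L * max(cnt) >= rem) {
      # near-critical multiset: drop feasibility-breaking candidates
      for (cc in which(w > 0L)) {
        cnt[cc] <- cnt[cc] - 1L
        m <- max(cnt); r <- rem - 1L
        ok <- m <= (r + 1L) %/% 2L &&
          !(r %% 2L == 1L && cnt[cc] == (r + 1L) %/% 2L)
        cnt[cc] <- cnt[cc] + 1L
        if (!ok) w[cc] <- 0L
      }
    }
    pick <- if (sum(w > 0L) == 1L) which(w > 0L) else sample.int(k, 1L, prob = w)
    res[pos] <- pick
    cnt[pick] <- cnt[pick] - 1L
    prev <- pick
  }
  ulab[res]
}

#' Permutation test of first-order transitions
#'
#' The observed sequence is rearranged `n_perm` times under the
#' no-adjacent-repeat constraint; for every ordered pair of labels the
#' p-value is the fraction of rearrangements in which that transition
#' occurred strictly more often than observed (`ge = TRUE` switches to
#' the (count >= observed occurrences + 1)/(n_perm + 1) convention).
#' Transition probability is observed count / total transitions.
#'
#' @param seq a no-repeat behavior sequence
#' @param n_perm number of permutations (default 1000)
#' @param seed optional RNG seed
#' @param ge use the greater-or-equal p-value convention
#' @param min_transitions passed to [transition_counts()]
#' @return data.frame(from, to, observed, probability, p) over all
#'   ordered label pairs (diagonal excluded), with attributes `n_perm`,
#'   `total`, and `label_freq` (relative label frequencies in `seq`)
#' @export
permutation_transition_test <- function(seq, n_perm = 1000, seed = NULL,
                                        ge = FALSE, min_transitions = 2) {
  if (!is.null(seed)) set.seed(seed)
  tm <- transition_counts(seq, min_transitions = min_transitions)
  labels <- tm$labels
  k <- length(labels)
  n <- length(seq)
  idx <- match(as.character(seq), labels)
  bin <- function(ix) tabulate((ix[-n] - 1L) * k + ix[-1], nbins = k * k)
  obs <- bin(idx)
  exceed <- integer(k * k)
  for (r in seq_len(n_perm)) {
    px <- match(permute_no_repeats(as.character(seq)), labels)
    cnt <- bin(px)
    if (ge) exceed <- exceed + (cnt >= obs) else exceed <- exceed + (cnt > obs)
  }
  p <- if (ge) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  from <- rep(labels, each = k)
  to <- rep(labels, k)
  keep <- from != to
  out <- data.frame(from = from[keep], to = to[keep],
                    observed = obs[keep],
                    probability = obs[keep] / tm$total,
                    p = p[keep], row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "total") <- tm$total
  attr(out, "label_freq") <- table(factor(seq, levels = labels)) / n
  out
}

#' Group-level transition summary
#'
#' Medians of per-individual permutation p-values and transition
#' probabilities within each group. Individuals lacking a transition
#' contribute probability 0 and p = 1, so medians are over all
#' individuals in the group. A transition is flagged `significant` when
#' its median p <= `p_thresh` and `meaningful` when its median
#' probability >= `prob_thresh`.
#'
#' @param results named list of [permutation_transition_test()] outputs,
#'   one per individual
#' @param grouping named character vector: group label per individual
#'   (names matching `results`)
#' @param p_thresh significance threshold on the median p (default 0.01)
#' @param prob_thresh meaningfulness threshold on the median probability
#'   (default 0.075)
#' @return data.frame(group, from, to, median_p, median_prob,
#'   significant, meaningful, n_individuals) with attribute
#'   `label_freq`: per-group median relative label frequencies
#' @export
group_transition_summary <- function(results, grouping,
                                     p_thresh = 0.01, prob_thresh = 0.075) {
  stopifnot(all(names(results) %in% names(grouping)))
  out <- NULL
  freq_attr <- list()
  for (g in sort(unique(grouping[names(results)]))) {
    ids <- names(results)[grouping[names(results)] == g]
    labs <- sort(unique(unlist(lapply(results[ids], function(r) {
      unique(c(r$from, r$to))
    }))))
    pairs <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    key <- paste(pairs$from, pairs$to, sep = "\r")
    pm <- matrix(1, nrow(pairs), length(ids))
    qm <- matrix(0, nrow(pairs), length(ids))
    for (j in seq_along(ids)) {
      r <- results[[ids[j]]]
      m <- match(paste(r$from, r$to, sep = "\r"), key)
      ok <- !is.na(m)
      pm[m[ok], j] <- r$p[ok]
      qm[m[ok], j] <- r$probability[ok]
    }
    med_p <- apply(pm, 1, stats::median)
    med_q <- apply(qm, 1, stats::median)
    out <- rbind(out, data.frame(
      group = g, from = pairs$from, to = pairs$to,
      median_p = med_p, median_prob = med_q,
      significant = med_p <= p_thresh,
      meaningful = med_q >= prob_thresh,
      n_individuals = length(ids), row.names = NULL))
    fm <- sapply(ids, function(id) {
      f <- attr(results[[id]], "label_freq")
      stats::setNames(as.numeric(f)[match(labs, names(f))], labs)
    })
    fm[is.na(fm)] <- 0
    freq_attr[[g]] <- apply(as.matrix(fm), 1, stats::median)
  }
  attr(out, "label_freq") <- freq_attr
  out
}

#' Export kinetograms (directed transition graphs) per group
#'
#' Nodes are behavior labels (size attribute = median relative
#' frequency); edges are the meaningful transitions (weight = median
#' transition probability) with a `significant` attribute for those
#' below the group p threshold. One GraphML and/or DOT file per group.
#'
#' @param gsum output of [group_transition_summary()]
#' @param dir output directory
#' @param formats subset of c("graphml", "dot")
#' @return invisible named list of igraph objects, one per group
#' @export
export_kinetogram <- function(gsum, dir, formats = c("graphml", "dot")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freq <- attr(gsum, "label_freq")
  graphs <- list()
  for (g in sort(unique(gsum$group))) {
    grows <- gsum[gsum$group == g, , drop = FALSE]
    sel <- grows[grows$meaningful, , drop = FALSE]
    verts <- if (!is.null(freq[[g]])) names(freq[[g]]) else
      sort(unique(c(grows$from, grows$to)))
    sizes <- if (!is.null(freq[[g]])) as.numeric(freq[[g]]) else
      rep(1, length(verts))
    gr <- igraph::graph_from_data_frame(
      d = data.frame(from = sel$from, to = sel$to,
                     weight = sel$median_prob,
                     significant = as.integer(sel$significant)),
      directed = TRUE,
      vertices = data.frame(name = verts, size = sizes))
    safe <- gsub("[^A-Za-z0-9_.-]", "_", g)
    if ("graphml" %in% formats) {
      igraph::write_graph(gr, file.path(dir, paste0(safe, ".graphml")),
                          format = "graphml")
    }
    if ("dot" %in% formats) {
      igraph::write_graph(gr, file.path(dir, paste0(safe, ".dot")),
                          format = "dot")
    }
    graphs[[g]] <- gr
  }
  invisible(graphs)
}
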