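test_that("transition counts tally bigrams with a structural-zero diagonal", {
  tm <- transition_counts(c("A", "B", "A", "B"))
  expect_equal(tm$observed["A", "B"], 2)
  expect_equal(tm$observed["B", "A"], 1)
  expect_equal(tm$total, 3)
  expect_true(all(diag(tm$observed) == 0))
  expect_error(transition_counts("A"), class = "dt_sequence_too_short")
  expect_error(transition_counts(c("A", "A", "B")),
               class = "dt_validation_error")

  set.seed(81)
  for (r in 1:20) {
    sq <- simulate_markov_sequence(uniform_kernel(LETTERS[1:4]), 60)
    tm <- transition_counts(sq)
    # naive bigram oracle
    for (i in seq_along(tm$labels)) for (j in seq_along(tm$labels)) {
      ref <- sum(sq[-length(sq)] == tm$labels[i] & sq[-1] == tm$labels[j])
      expect_identical(unname(tm$observed[i, j]), ref)
    }
  }
})

test_that("IPF reproduces margins and matches stats::loglin", {
  # 2x2 off-diagonal table is saturated: E = O exactly
  tm <- transition_counts(c("A", "B", "A", "B", "A"))
  tm <- quasi_independence_expected(tm)
  expect_equal(tm$expected, tm$observed, ignore_attr = TRUE)

  # symmetric 3x3 with all off-diagonal cells 4 is a fixed point
  O <- matrix(4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(O) <- 0
  tm <- structure(list(labels = LETTERS[1:3], observed = O, expected = NULL,
                       total = sum(O)), class = "transition_matrix")
  tm <- quasi_independence_expected(tm)
  expect_equal(tm$expected, O, ignore_attr = TRUE, tolerance = 1e-8)

  # asymmetric 3x3 against the independent loglin oracle
  O <- matrix(c(0, 5, 1, 4, 0, 2, 1, 2, 0), 3, 3, byrow = TRUE,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tm <- structure(list(labels = LETTERS[1:3], observed = O, expected = NULL,
                       total = sum(O)), class = "transition_matrix")
  tm <- quasi_independence_expected(tm)
  expect_equal(unclass(tm$expected), ipf_oracle(O), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(rowSums(tm$expected), rowSums(O), tolerance = 1e-8)
  expect_equal(colSums(tm$expected), colSums(O), tolerance = 1e-8)
})

test_that("G2 test: zero at the fixed point, adjusted df, oracle value", {
  O <- matrix(4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(O) <- 0
  tm <- structure(list(labels = LETTERS[1:3], observed = O, expected = NULL,
                       total = sum(O)), class = "transition_matrix")
  g <- g2_test(quasi_independence_expected(tm))
  expect_equal(g$g2, 0, tolerance = 1e-10)
  expect_equal(g$df, 1)  # (3-1)^2 - 3
  expect_true(g$defined)

  # k = 2 no-repeat table has df = -1: test not defined
  tm2 <- quasi_independence_expected(transition_counts(c("A", "B", "A", "B")))
  expect_false(g2_test(tm2)$defined)

  O <- matrix(c(0, 5, 1, 4, 0, 2, 1, 2, 0), 3, 3, byrow = TRUE,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tm3 <- structure(list(labels = LETTERS[1:3], observed = O, expected = NULL,
                        total = sum(O)), class = "transition_matrix")
  tm3 <- quasi_independence_expected(tm3)
  g3 <- g2_test(tm3)
  E <- ipf_oracle(O)
  ref <- 2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
  expect_equal(g3$g2, ref, tolerance = 1e-7)
  expect_equal(g3$p, pchisq(ref, 1, lower.tail = FALSE), tolerance = 1e-7)
})

test_that("no-repeat permutation preserves the multiset and the constraint", {
  expect_error(permute_no_repeats(c("A", "A", "A", "B")),
               class = "dt_infeasible")

  set.seed(83)
  seen <- character(0)
  for (r in 1:50) {
    x <- permute_no_repeats(c("A", "B", "A", "B", "A", "B"))
    seen <- c(seen, paste(x, collapse = ""))
  }
  expect_true(all(seen %in% c("ABABAB", "BABABA")))
  expect_length(unique(seen), 2)  # both arrangements occur in 50 draws

  base <- c(rep("A", 5), rep("B", 3), rep("C", 2))
  for (r in 1:2000) {
    x <- permute_no_repeats(base)
    expect_false(any(x[-1] == x[-length(x)]))
  }
  expect_identical(sort(permute_no_repeats(base)), sort(base))

  # constructive fallback path (rejection disabled)
  for (r in 1:200) {
    x <- permute_no_repeats(c(rep("A", 5), rep("B", 4), "C"),
                            max_attempts = 0)
    expect_false(any(x[-1] == x[-length(x)]))
    expect_identical(sort(x), sort(c(rep("A", 5), rep("B", 4), "C")))
  }
})

test_that("permutation p-values follow the strict-exceedance definition", {
  # ABABAB: valid arrangements are ABABAB (A->B count 3) and BABABA
  # (count 2); nothing exceeds the observed 3, so p(A->B) = 0
  r <- permutation_transition_test(c("A", "B", "A", "B", "A", "B"),
                                   n_perm = 400, seed = 5)
  expect_equal(r$p[r$from == "A" & r$to == "B"], 0)
  expect_equal(r$probability[r$from == "A" & r$to == "B"], 3 / 5)
  # B->A observed 2 is exceeded exactly when BABABA is drawn (~half)
  pba <- r$p[r$from == "B" & r$to == "A"]
  expect_gt(pba, 0.3); expect_lt(pba, 0.7)
  # probabilities over all ordered pairs sum to 1
  expect_equal(sum(r$probability), 1)

  # ge convention: (count >= obs) + 1 over n_perm + 1
  rge <- permutation_transition_test(c("A", "B", "A", "B", "A", "B"),
                                     n_perm = 400, seed = 5, ge = TRUE)
  expect_true(all(rge$p > 0))

  # a never-observed transition can still earn p > 0
  sq <- c("A", "B", "A", "B", "C")
  r2 <- permutation_transition_test(sq, n_perm = 300, seed = 7)
  expect_equal(r2$observed[r2$from == "C" & r2$to == "A"], 0)
  expect_gt(r2$p[r2$from == "C" & r2$to == "A"], 0)
})

test_that("group summaries take medians with absence conventions", {
  mk_res <- function(p_ab, q_ab) {
    structure(data.frame(from = c("A", "B"), to = c("B", "A"),
                         observed = c(5, 1), probability = c(q_ab, 0.05),
                         p = c(p_ab, 0.5)),
              label_freq = c(A = 0.5, B = 0.5))
  }
  results <- list(i1 = mk_res(0.001, 0.2), i2 = mk_res(0.002, 0.3),
                  i3 = mk_res(0.005, 0.25))
  grouping <- c(i1 = "dom_pre", i2 = "dom_pre", i3 = "dom_pre")
  gs <- group_transition_summary(results, grouping)
  ab <- gs[gs$from == "A" & gs$to == "B", ]
  expect_equal(ab$median_p, 0.002)
  expect_equal(ab$median_prob, 0.25)
  expect_true(ab$significant)
  expect_true(ab$meaningful)

  # median p above threshold: not significant
  results$i2$p[1] <- 0.05
  results$i3$p[1] <- 0.05
  gs2 <- group_transition_summary(results, grouping)
  expect_false(gs2[gs2$from == "A" & gs2$to == "B", ]$significant)

  # an individual lacking the transition contributes p = 1, prob = 0
  results2 <- list(
    i1 = mk_res(0.001, 0.2),
    i2 = structure(data.frame(from = "C", to = "A", observed = 2,
                              probability = 0.1, p = 0.2),
                   label_freq = c(A = 0.5, C = 0.5)),
    i3 = mk_res(0.001, 0.2))
  gs3 <- group_transition_summary(results2, c(i1 = "g", i2 = "g", i3 = "g"))
  ab3 <- gs3[gs3$from == "A" & gs3$to == "B", ]
  expect_equal(ab3$median_p, 0.001)  # median of (0.001, 1, 0.001)
  expect_equal(ab3$median_prob, 0.2)
})

test_that("kinetogram export round-trips through GraphML", {
  gsum <- data.frame(group = "dom_post",
                     from = c("tail_rattle", "lunge", "digging"),
                     to = c("lunge", "bite", "idle"),
                     median_p = c(0.001, 0.001, 0.5),
                     median_prob = c(0.2, 0.1, 0.01),
                     significant = c(TRUE, TRUE, FALSE),
                     meaningful = c(TRUE, TRUE, FALSE),
                     n_individuals = 5)
  dir <- withr::local_tempdir()
  graphs <- export_kinetogram(gsum, dir)
  expect_true(file.exists(file.path(dir, "dom_post.graphml")))
  expect_true(file.exists(file.path(dir, "dom_post.dot")))
  g <- igraph::read_graph(file.path(dir, "dom_post.graphml"),
                          format = "graphml")
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)  # only the meaningful transitions
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("tail_rattle lunge", "lunge bite"))
  expect_equal(sum(igraph::E(g)$significant), 2)

  # nothing meaningful -> nodes only
  gsum$meaningful <- FALSE
  g2 <- export_kinetogram(gsum, dir)$dom_post
  expect_equal(igraph::ecount(g2), 0)
})
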