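# Engineered 2x2 matrices with known phi behavior:
#   PASS (10,0,0,10): phi = 1, p << 0.1
#   FAIL (5,5,5,5):   phi = 0
#   EXCL (1,0,0,1):   N = 2 < 6
m_pass <- c(10, 0, 0, 10)
m_fail <- c(5, 5, 5, 5)
m_excl <- c(1, 0, 0, 1)
mk_mats <- function(...) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("a", "b", "c", "d")
  cbind(index = seq_len(nrow(df)), day = 1L, df,
        N = df$a + df$b + df$c + df$d)
}

test_that("phi coefficient matches its closed form and identities", {
  expect_equal(phi_coefficient(c(10, 0, 0, 10))$phi, 1)
  expect_equal(phi_coefficient(c(6, 4, 6, 4))$phi, 0)
  r <- phi_coefficient(c(8, 2, 3, 7))
  expect_equal(r$phi, 50 / sqrt(9900), tolerance = 1e-12)
  expect_equal(r$chi_sq, 20 * r$phi^2)
  expect_equal(r$p, 0.0246, tolerance = 1e-3)

  set.seed(61)
  for (r in 1:50) {
    m <- as.numeric(rmultinom(1, 40, rep(0.25, 4)))
    ph <- phi_coefficient(m)
    if (!is.na(ph$phi)) {
      expect_gte(ph$phi, -1); expect_lte(ph$phi, 1)
      expect_identical(ph$chi_sq, sum(m) * ph$phi^2)  # exact identity
    }
  }
})

test_that("phi exclusion: zero margins and N < 6", {
  r <- phi_coefficient(c(4, 2, 0, 0))  # subordinate row margin zero
  expect_true(is.na(r$phi))
  expect_true(r$excluded)
  expect_true(phi_coefficient(c(2, 1, 1, 1))$excluded)  # N = 5
  expect_false(phi_coefficient(c(2, 1, 2, 1))$excluded)
})

test_that("eventual dominant is the consistent winner of the last bursts", {
  mk <- function(agg1, sub1, agg2, sub2) {
    # all onsets inside one burst [0, 100] on day 1
    n <- agg1 + sub1 + agg2 + sub2
    event_log(data.frame(
      dyad_id = "d1", day = 1,
      subject_id = c(rep("X", agg1 + sub1), rep("Y", agg2 + sub2)),
      behavior = c(rep("lunge", agg1), rep("flee", sub1),
                   rep("lunge", agg2), rep("flee", sub2)),
      onset_s = seq(1, 99, length.out = n),
      offset_s = seq(1, 99, length.out = n) + 0.2))
  }
  bursts <- data.frame(dyad_id = "d1", day = 1, index = 1,
                       start = 0, end = 100, level = 2)
  expect_identical(assign_eventual_dominant(mk(9, 1, 1, 9), bursts)$dom, "X")
  expect_error(assign_eventual_dominant(mk(5, 5, 5, 5), bursts),
               class = "dt_role_ambiguity")
  # X higher on aggressive AND on subordinate: conditions conflict
  expect_error(assign_eventual_dominant(mk(9, 9, 1, 1), bursts),
               class = "dt_role_ambiguity")
  expect_identical(
    assign_eventual_dominant(mk(5, 5, 5, 5), bursts,
                             force = list(dom = "Y", sub = "X"))$dom, "Y")
})

test_that("phi resolution rule: direct applications", {
  r <- resolve_phi(mk_mats(m_fail, m_pass, m_pass))
  expect_true(r$resolved)
  expect_identical(r$resolution_burst_index, 2L)

  expect_false(resolve_phi(mk_mats(m_fail, m_fail))$resolved)
  # final evaluable burst fails -> unresolved
  expect_false(resolve_phi(mk_mats(m_pass, m_pass, m_fail))$resolved)
  # excluded bursts are skipped entirely, even at the end
  r2 <- resolve_phi(mk_mats(m_pass, m_excl, m_pass, m_excl))
  expect_identical(r2$resolution_burst_index, 1L)
  # nothing evaluable -> unresolved
  expect_false(resolve_phi(mk_mats(m_excl, m_excl))$resolved)
})

test_that("difference resolution rule: direct applications", {
  # (a-c, b-d): (-3, 2), (4, -1), (5, -4) -> resolved at burst 2
  m <- mk_mats(c(0, 2, 3, 0), c(4, 0, 0, 1), c(5, 0, 0, 4))
  r <- resolve_difference(m)
  expect_identical(r$resolution_burst_index, 2L)
  # all-zero matrices: 0 >= 0 everywhere -> resolved at burst 1
  z <- mk_mats(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_identical(resolve_difference(z)$resolution_burst_index, 1L)
  expect_false(resolve_difference(mk_mats(c(0, 5, 0, 0)))$resolved)
})

test_that("resolution rules agree with brute-force scans on random bursts", {
  set.seed(67)
  for (r in 1:200) {
    n <- sample(1:8, 1)
    mats <- mk_mats_random(n)
    rp <- resolve_phi(mats)
    expect_identical(rp$resolution_burst_index,
                     as.integer(resolve_phi_oracle(mats)))
    rd <- resolve_difference(mats)
    expect_identical(rd$resolution_burst_index,
                     as.integer(resolve_difference_oracle(mats)))
  }
})

test_that("cumulative interaction time counts completed days plus burst end", {
  bursts <- data.frame(dyad_id = "d1", day = c(1, 3), index = 1:2,
                       start = c(100, 400), end = c(120, 430), level = 2)
  mats <- mk_mats(m_fail, m_pass)
  r <- resolve_phi(mats, bursts)
  # mats day column is synthetic; cumulative time comes from the burst row
  expect_equal(r$cumulative_interaction_s, 2 * 1200 + 430)
})

test_that("segment_phases partitions each day with correct boundaries", {
  bursts <- data.frame(dyad_id = "d1", day = c(1, 1, 2, 2), index = 1:4,
                       start = c(100, 600, 200, 800),
                       end = c(130, 640, 260, 850), level = 2)
  rd <- list(resolved = TRUE, resolution_burst_index = 1L)
  rp <- list(resolved = TRUE, resolution_burst_index = 4L)
  ph <- segment_phases(bursts, rd, rp, days = 1:5, dyad_id = "d1")
  pre <- ph[ph$phase == "pre", ]
  expect_equal(pre$day, 1); expect_equal(pre$start, 0); expect_equal(pre$end, 100)
  post <- ph[ph$phase == "post", ]
  expect_equal(post$day[1], 2); expect_equal(post$start[1], 850)
  expect_true(all(3:5 %in% post$day))
  mid <- ph[ph$phase == "middle", ]
  expect_equal(sum(mid$end - mid$start), (1200 - 100) + 850)
  # exact partition of every day
  for (d in 1:5) {
    wd <- ph[ph$day == d, ]
    wd <- wd[order(wd$start), ]
    expect_equal(sum(wd$end - wd$start), 1200, tolerance = 1e-9)
    expect_equal(wd$start[1], 0)
    if (nrow(wd) > 1) expect_equal(wd$start[-1], wd$end[-nrow(wd)])
  }

  # unresolved phi: no post phase, middle to study end
  ph2 <- segment_phases(bursts, rd, list(resolved = FALSE), days = 1:5,
                        dyad_id = "d1")
  expect_equal(nrow(ph2[ph2$phase == "post", ]), 0)
  expect_equal(sum(ph2$end - ph2$start), 5 * 1200)

  # difference burst after phi burst: ordering violation
  expect_error(
    segment_phases(bursts, list(resolved = TRUE, resolution_burst_index = 4L),
                   list(resolved = TRUE, resolution_burst_index = 1L),
                   days = 1:2),
    class = "dt_phase_order_error")
})

test_that("phase proportions match a rasterization oracle", {
  log <- event_log(data.frame(
    dyad_id = "d1", day = 1, subject_id = c("s1", "s1", "s2"),
    behavior = c("idle", "digging", "flee"),
    onset_s = c(0, 40, 10), offset_s = c(40, 55, 90)),
    session_length = 100)
  phases <- data.frame(dyad_id = "d1", day = 1,
                       start = c(0, 40, 70), end = c(40, 70, 100),
                       phase = c("pre", "middle", "post"))
  tab <- phase_proportions(log, phases)
  g <- function(s, p, b) tab$proportion[tab$subject_id == s &
                                          tab$phase == p & tab$behavior == b]
  expect_equal(g("s1", "pre", "idle"), 1)       # idle covers the whole pre
  expect_equal(g("s1", "pre", "digging"), 0)    # absent in phase
  expect_equal(g("s1", "middle", "digging"), 0.5)
  expect_equal(g("s2", "post", "flee"), 2 / 3)
  for (s in c("s1", "s2")) for (p in c("pre", "middle", "post")) {
    for (b in c("idle", "digging", "flee")) {
      expect_equal(g(s, p, b),
                   phase_prop_raster(log, phases[phases$phase == p, ], s, b),
                   tolerance = 2e-3)
    }
  }
})

test_that("paired phase comparisons behave and reach the exact minimum p", {
  set.seed(71)
  n <- 21
  tab <- data.frame(
    dyad_id = rep(sprintf("d%02d", 1:n), each = 2),
    subject_id = paste0(rep(sprintf("d%02d", 1:n), each = 2), c("_1", "_2")),
    phase = "post", behavior = "digging",
    proportion = as.vector(rbind(runif(n, 0.5, 0.9), runif(n, 0.0, 0.4))))
  roles <- data.frame(dyad_id = rep(sprintf("d%02d", 1:n), each = 2),
                      subject_id = tab$subject_id,
                      role = rep(c("dom", "sub"), n))
  res <- compare_phase_behaviors(tab, roles)
  expect_equal(res$p, 2 * 0.5^21, tolerance = 1e-12)  # all dominants exceed
  expect_equal(res$V, n * (n + 1) / 2)

  # swapping roles flips the statistic, same p
  roles2 <- roles; roles2$role <- rep(c("sub", "dom"), n)
  res2 <- compare_phase_behaviors(tab, roles2)
  expect_equal(res2$p, res$p)
  expect_equal(res2$V, 0)

  # identical proportions: p = 1 with a note
  tab0 <- tab; tab0$proportion <- rep(0.3, nrow(tab0))
  res0 <- compare_phase_behaviors(tab0, roles)
  expect_equal(res0$p, 1)
  expect_identical(res0$note, "no informative pairs")
})
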