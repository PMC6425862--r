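test_that("time windows validate hours and canonicalize 24 to 0", {
  w <- time_window("dawn", c(22, 24, 2))
  expect_setequal(w$hours, c(22, 0, 2))
  expect_error(time_window("dawn", c(22, 24)), "3 distinct")
  expect_error(time_window("noon", c(10, 12, 14)))
})

test_that("window sums total the counts over exactly the window hours", {
  m <- make_matrix(rbind(rep(5, 12), c(rep(0, 6), 60, rep(0, 5))))
  pc <- normalize_diel(m, 1200)
  ws <- window_sums(pc, time_window("dusk", win12$dusk),
                    time_window("dawn", win12$dawn))
  # flat gene: counts all 100, three-hour windows -> 300 each
  expect_equal(ws$dusk_sum[1], 300L)
  expect_equal(ws$dawn_sum[1], 300L)
  # gene nonzero only at hour 12
  expect_equal(ws$dusk_sum[2], 1200L)
  expect_equal(ws$dawn_sum[2], 0L)
  expect_error(
    window_sums(pc, time_window("dusk", c(9, 12, 14)),
                time_window("dawn", win12$dawn)),
    "absent from the sampling grid")
  expect_error(
    window_sums(pc, time_window("dusk", c(10, 12, 2)),
                time_window("dawn", win12$dawn)),
    "overlap")
})

test_that("a 12-h rotation swaps the dusk and dawn window sums", {
  set.seed(21)
  m <- make_matrix(matrix(rexp(120, 0.1), 10))
  rot <- rotate_profiles(m, 12)
  dusk <- time_window("dusk", win12$dusk)
  dawn <- time_window("dawn", win12$dawn)
  ws <- window_sums(normalize_diel(m), dusk, dawn)
  wr <- window_sums(normalize_diel(rot), dusk, dawn)
  expect_equal(wr$dusk_sum, ws$dawn_sum)
  expect_equal(wr$dawn_sum, ws$dusk_sum)
})

test_that("fisher_right_tail matches the hand-derived worked tables", {
  expect_equal(fisher_right_tail(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_right_tail(0, 5, 5, 0), 1, tolerance = 1e-12)
  expect_equal(fisher_right_tail(5, 0, 0, 5), 1 / 252, tolerance = 1e-12)
  expect_error(fisher_right_tail(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_right_tail(0, 0, 0, 0), "at least 1")
})

test_that("fisher_right_tail is strictly decreasing in the first cell", {
  # fixed margins: row1 = 8, col1 = 10, N = 20
  for (a in 0:7) {
    b <- 8 - a; c <- 10 - a; d <- 2 + a
    expect_gt(fisher_right_tail(a, b, c, d),
              fisher_right_tail(a + 1, b - 1, c + 1, d - 1))
  }
})

test_that("fisher_right_tail agrees with stats::fisher.test right tail", {
  set.seed(31)
  for (i in 1:30) {
    t <- matrix(rpois(4, 40), 2)
    expect_equal(fisher_right_tail(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 stats::fisher.test(t, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("bh_fdr reproduces the step-up rejection set", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2), alpha = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  one <- bh_fdr(0.01)
  expect_true(one$reject)
  expect_equal(one$q, 0.01)
  none <- bh_fdr(rep(1, 10))
  expect_false(any(none$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr q-values match p.adjust and dominate Bonferroni", {
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    r <- bh_fdr(p, alpha = 0.05)
    expect_equal(r$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    bonf <- stats::p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(r$reject[bonf]))        # BH superset of Bonferroni
    expect_false(is.unsorted(r$q[order(r$p)]))  # monotone in sorted order
  }
})

test_that("flat transcriptome yields only 'neither' phases", {
  set.seed(51)
  m <- make_matrix(matrix(10 * exp(rnorm(100 * 12, 0, 0.05)), 100))
  ec <- call_phase(window_sums(normalize_diel(m),
                               time_window("dusk", win12$dusk),
                               time_window("dawn", win12$dawn)))
  expect_true(all(ec$phase == "neither"))
  expect_true(all(ec$p_dusk >= 0 & ec$p_dusk <= 1))
  expect_true(all(ec$p_dawn >= 0 & ec$p_dawn <= 1))
})

test_that("a planted dusk-loaded gene is called dusk against flat background", {
  set.seed(52)
  vals <- matrix(10 * exp(rnorm(50 * 12, 0, 0.05)), 50)
  planted <- rep(1, 12)
  planted[grid2h %in% win12$dusk] <- 100      # ~90% of mass in dusk window
  vals[1, ] <- planted
  ec <- call_phase(window_sums(normalize_diel(make_matrix(vals)),
                               time_window("dusk", win12$dusk),
                               time_window("dawn", win12$dawn)))
  expect_equal(ec$phase[1], "dusk")
  expect_lt(ec$q_dusk[1], 0.05)
  # the p-value matches a directly computed table
  ws <- window_sums(normalize_diel(make_matrix(vals)),
                    time_window("dusk", win12$dusk),
                    time_window("dawn", win12$dawn))
  p1 <- fisher_right_tail(ws$dusk_sum[1], ws$dawn_sum[1],
                          sum(ws$dusk_sum) - ws$dusk_sum[1],
                          sum(ws$dawn_sum) - ws$dawn_sum[1])
  expect_equal(ec$p_dusk[1], p1, tolerance = 1e-15)
})

test_that("phase calling commutes with a 12-h rotation (label swap)", {
  set.seed(53)
  sp <- synthetic_spec(n_ogs = 60, n_rescheduled = 15, noise_sigma = 0.15,
                       seed = 53)
  m <- generate_study(sp)$matrices$cam
  dusk <- time_window("dusk", win12$dusk)
  dawn <- time_window("dawn", win12$dawn)
  ec <- call_phase(window_sums(normalize_diel(m), dusk, dawn))
  er <- call_phase(window_sums(normalize_diel(rotate_profiles(m, 12)),
                               dusk, dawn))
  swap <- c(dawn = "dusk", dusk = "dawn", neither = "neither")
  expect_equal(er$phase, unname(swap[ec$phase]))
})
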