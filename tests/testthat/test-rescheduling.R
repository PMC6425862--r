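test_that("spearman_rho matches hand-derived values", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 4.5 / sqrt(22.5),
               tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("spearman_rho is symmetric, rank-invariant, and matches stats::cor", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(1:10, n, replace = TRUE) + runif(n, 0, 0.01)
    y <- sample(1:10, n, replace = TRUE) + runif(n, 0, 0.01)
    r <- spearman_rho(x, y)
    expect_equal(r, spearman_rho(y, x), tolerance = 1e-15)
    expect_equal(r, stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(r, spearman_rho(exp(x), y^3 + y), tolerance = 1e-12)
  }
})

test_that("spearman_rho matches all n = 4 rank permutations exactly", {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  for (i in seq_len(nrow(perms))) {
    y <- as.numeric(perms[i, ])
    expect_equal(spearman_rho(1:4, y),
                 stats::cor(1:4, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("anti-phase cosines on the 2-h grid have rho exactly -1", {
  # evaluated mirror-symmetrically so mathematically tied hours tie exactly
  x <- cosine_profile(0)
  y <- cosine_profile(12)
  expect_equal(spearman_rho(x, y), -1, tolerance = 1e-15)
  expect_equal(spearman_rho(x, x), 1, tolerance = 1e-15)
  expect_equal(max(abs(x - 10 * (1 + 3 * (1 + cos(2 * pi * grid2h / 24)) / 2))),
               0, tolerance = 1e-12)
})

# -- fixtures for call_rescheduled -------------------------------------------

fake_calls <- function(phases) {
  lapply(phases, function(ph) {
    df <- data.frame(gene_id = names(ph), dusk_sum = 0L, dawn_sum = 0L,
                     p_dusk = 0.5, p_dawn = 0.5, q_dusk = 1, q_dawn = 1,
                     phase = unname(ph), stringsAsFactors = FALSE)
    class(df) <- c("enrichment_calls", "data.frame")
    df
  })
}

trio_matrices <- function(cam_peak = 12, c3_peak = 0, genes = "g") {
  mk <- function(peak, sp)
    diel_matrix(rbind(cosine_profile(peak)),
                grid2h, paste0(genes, "_", sp), sp)
  list(cam = mk(cam_peak, "cam"), c3a = mk(c3_peak, "c3a"),
       c3b = mk(c3_peak, "c3b"))
}

trio_og <- ortholog_group("OG1", list(cam = "g_cam", c3a = "g_c3a",
                                      c3b = "g_c3b"))

test_that("a clean anti-phase trio with agreeing C3 phases is rescheduled", {
  calls <- fake_calls(list(cam = c(g_cam = "dusk"), c3a = c(g_c3a = "dawn"),
                           c3b = c(g_c3b = "dawn")))
  rc <- call_rescheduled(trio_og, calls, trio_matrices(), "cam",
                         c("c3a", "c3b"))
  expect_equal(nrow(rc), 1)
  expect_true(rc$criterion1)
  expect_true(rc$criterion2)
  expect_true(rc$rescheduled)
  expect_equal(rc$rho_cam_A, -1, tolerance = 1e-12)
  expect_equal(rc$rho_AB, 1, tolerance = 1e-12)
})

test_that("a CAM-C3 correlation at or above the threshold fails criterion 2", {
  calls <- fake_calls(list(cam = c(g_cam = "dusk"), c3a = c(g_c3a = "dawn"),
                           c3b = c(g_c3b = "dawn")))
  # shift one C3 gene only 6 h away: phases can agree but rho is ~0, not < -0.6
  mats <- trio_matrices()
  mats$c3a <- diel_matrix(rbind(cosine_profile(6)), grid2h, "g_c3a", "c3a")
  rc <- call_rescheduled(trio_og, calls, mats, "cam", c("c3a", "c3b"))
  expect_true(rc$criterion1)
  expect_false(rc$criterion2)
  expect_false(rc$rescheduled)
  expect_gt(rc$rho_cam_A, -0.6)
})

test_that("boundary correlations fail the strict thresholds", {
  calls <- fake_calls(list(cam = c(g_cam = "dusk"), c3a = c(g_c3a = "dawn"),
                           c3b = c(g_c3b = "dawn")))
  rc <- call_rescheduled(trio_og, calls, trio_matrices(), "cam",
                         c("c3a", "c3b"), rho_neg = -1, rho_pos = 1)
  expect_false(rc$criterion2)  # rho == -1 is not < -1; rho == 1 is not > 1
})

test_that("criterion 1 needs the CAM phase opposite to both agreeing C3 phases", {
  mats <- trio_matrices()
  for (ph in list(c(cam = "neither", c3a = "dawn", c3b = "dawn"),
                  c(cam = "dusk", c3a = "dawn", c3b = "dusk"),
                  c(cam = "dusk", c3a = "dusk", c3b = "dusk"))) {
    calls <- fake_calls(list(cam = stats::setNames(ph[["cam"]], "g_cam"),
                             c3a = stats::setNames(ph[["c3a"]], "g_c3a"),
                             c3b = stats::setNames(ph[["c3b"]], "g_c3b")))
    rc <- call_rescheduled(trio_og, calls, mats, "cam", c("c3a", "c3b"))
    expect_false(rc$criterion1)
    expect_false(rc$rescheduled)
  }
})

test_that("verdicts are invariant under swapping the two C3 species", {
  set.seed(71)
  st <- generate_study(synthetic_spec(n_ogs = 30, n_rescheduled = 8,
                                      seed = 71))
  mats <- st$matrices
  mats$c3b <- interpolate_timepoints(mats$c3b, grid2h)
  calls <- lapply(mats, function(m)
    call_phase(window_sums(normalize_diel(m),
                           time_window("dusk", win12$dusk),
                           time_window("dawn", win12$dawn))))
  r1 <- call_rescheduled(st$ortholog_groups, calls, mats, "cam",
                         c("c3a", "c3b"))
  r2 <- call_rescheduled(st$ortholog_groups, calls, mats, "cam",
                         c("c3b", "c3a"))
  g1 <- rescheduled_groups(r1)
  g2 <- rescheduled_groups(r2)
  expect_equal(g1$rescheduled, g2$rescheduled[match(g1$og_id, g2$og_id)])
  expect_false(any(r1$rescheduled & (r1$c3_phaseA != r1$c3_phaseB),
                   na.rm = TRUE))
})

test_that("groups missing a species are skipped with a reason, not an error", {
  calls <- fake_calls(list(cam = c(g_cam = "dusk"), c3a = c(g_c3a = "dawn"),
                           c3b = c(g_c3b = "dawn")))
  og_missing <- ortholog_group("OG2", list(cam = "g_cam", c3a = "g_c3a"))
  rc <- call_rescheduled(list(trio_og, og_missing), calls, trio_matrices(),
                         "cam", c("c3a", "c3b"))
  expect_equal(nrow(rc), 1)
  sk <- attr(rc, "skipped")
  expect_equal(sk$og_id, "OG2")
  expect_match(sk$reason, "c3b")
})

test_that("constant profiles give NA correlations and an NA criterion 2", {
  calls <- fake_calls(list(cam = c(g_cam = "dusk"), c3a = c(g_c3a = "dawn"),
                           c3b = c(g_c3b = "dawn")))
  mats <- trio_matrices()
  mats$cam <- diel_matrix(rbind(rep(5, 12)), grid2h, "g_cam", "cam")
  rc <- call_rescheduled(trio_og, calls, mats, "cam", c("c3a", "c3b"))
  expect_true(is.na(rc$rho_cam_A))
  expect_true(is.na(rc$criterion2))
  expect_false(isTRUE(rc$rescheduled))
  expect_false(rescheduled_groups(rc)$rescheduled)
})

test_that("multi-gene groups evaluate every combination with group-level OR", {
  calls <- fake_calls(list(
    cam = c(g1_cam = "dusk", g2_cam = "neither"),
    c3a = c(g_c3a = "dawn"), c3b = c(g_c3b = "dawn")))
  mats <- trio_matrices()
  mats$cam <- diel_matrix(rbind(cosine_profile(12), cosine_profile(13)),
                          grid2h, c("g1_cam", "g2_cam"), "cam")
  og <- ortholog_group("OG1", list(cam = c("g1_cam", "g2_cam"),
                                   c3a = "g_c3a", c3b = "g_c3b"))
  rc <- call_rescheduled(og, calls, mats, "cam", c("c3a", "c3b"))
  expect_equal(nrow(rc), 2)
  expect_equal(sum(rc$rescheduled), 1)
  expect_true(rescheduled_groups(rc)$rescheduled)
  expect_equal(rc$rescheduled, rc$criterion1 & rc$criterion2)
})
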