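# Flow scoring: scatter correction, quantile normalization, z-scores, hits.

sim_plate <- function(coupling = c(0.8, 0.3), noise = 0.05, n = 10000,
                      strains = "S1", effects = c(), seed = 1) {
  cfg <- flow_sim_config(n_events_per_well = n, scatter_coupling = coupling,
                         noise_sd = noise, strain_effect = effects,
                         null_effect_sd = 0, seed = seed)
  simulate_flow_plate(cfg, plate_layout(strains, n_wt = 4))
}

test_that("scatter correction removes the size dependence of fluorescence", {
  ev <- sim_plate(seed = 21)
  co <- correct_scatter(ev)
  expect_lt(abs(cor(co$corrected_log10_fl, log10(co$FSC))), 0.02)
  expect_lt(abs(cor(co$corrected_log10_fl, log10(co$SSC))), 0.02)
})

test_that("scatter correction reduces the wild-type coefficient of variation", {
  for (s in 1:3) {
    ev <- sim_plate(noise = 0.1, n = 5000, seed = s)
    co <- correct_scatter(ev)
    wt <- co$strain == "WT"
    expect_lte(cv(10^co$corrected_log10_fl[wt]), cv(ev$FL1[ev$strain == "WT"]))
  }
})

test_that("without coupling, correction is the identity up to a constant", {
  ev <- sim_plate(coupling = c(0, 0), noise = 0.1, n = 2000, seed = 4)
  co <- correct_scatter(ev)
  diffs <- co$corrected_log10_fl - log10(co$FL1 + 1)
  expect_lt(diff(range(diffs)), 0.02)
})

test_that("degenerate scatter falls back to no correction with a warning", {
  ev <- sim_plate(n = 200, seed = 5)
  ev$FSC <- 100
  expect_warning(co <- correct_scatter(ev), "degenerate")
  expect_equal(co$corrected_log10_fl, log10(co$FL1 + 1))
})

test_that("quantile normalization reproduces the hand-worked 3x2 example", {
  m <- cbind(P1 = c(1, 3, 5), P2 = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))
})

test_that("quantile normalization equalizes all column distributions", {
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- matrix(rnorm(60), ncol = 3)
      out <- quantile_normalize(m)
      sorted <- apply(out, 2, sort)
      expect_equal(sorted[, 1], sorted[, 2])
      expect_equal(sorted[, 1], sorted[, 3])
      # rank preservation within columns
      expect_equal(apply(out, 2, rank), apply(m, 2, rank))
      # agreement with the independent sort/average/unsort oracle
      expect_equal(unname(out), unname(hand_quantile_normalize(m)))
    }
  })
})

test_that("quantile normalization is idempotent and passes single plates", {
  m <- cbind(a = c(2, 1, 4), b = c(2, 1, 4))
  expect_equal(quantile_normalize(m), m)
  one <- matrix(1:5, ncol = 1)
  expect_identical(quantile_normalize(one), one)
})

test_that("z-scores follow the standard-score formula", {
  summaries <- tibble::tibble(
    strain = c("WT", "WT", "WT", "S1", "S2"),
    well_mean = c(1.9, 2.0, 2.1, 1.855, 2.0))
  # wt mean 2.0, wt sd 0.1; strain mean 1.855 -> z = -1.45
  sc <- zscore_strains(summaries, wt_label = "WT")
  expect_equal(sc$z[sc$strain == "S1"], -1.45)
  expect_equal(sc$z[sc$strain == "S2"], 0)
  expect_equal(sc$pct_of_wt[sc$strain == "S2"], 100)
  degen <- tibble::tibble(strain = c("WT", "WT", "S1"),
                          well_mean = c(2, 2, 1.5))
  expect_error(zscore_strains(degen), "degenerate reference")
})

test_that("z-scores are invariant under a common affine transform", {
  withr::with_seed(2, {
    summaries <- tibble::tibble(strain = c("WT", "WT", "WT", sprintf("S%d", 1:10)),
                                well_mean = rnorm(13, 2, 0.1))
    z1 <- zscore_strains(summaries)$z
    shifted <- summaries
    shifted$well_mean <- 3 * shifted$well_mean + 7
    z2 <- zscore_strains(shifted)$z
    expect_equal(z1, z2)
  })
})

test_that("a simulated -2 SD strain is recovered near z = -2", {
  zs <- sapply(1:20, function(s) {
    cfg <- flow_sim_config(n_events_per_well = 1000, null_effect_sd = 0.1,
                           strain_effect = c(HIT = -0.2), seed = s)
    ev <- simulate_flow_plate(cfg, plate_layout(c(sprintf("S%02d", 1:30), "HIT")))
    sc <- suppressMessages(flow_score_pipeline(ev, reference = "population"))
    sc$z[sc$strain == "HIT"]
  })
  expect_lt(abs(mean(zs) - (-2)), 0.3)
})

test_that("hit calling respects the inclusive threshold and sorting", {
  scores <- tibble::tibble(strain = c("A", "B", "C"), timepoint = 6,
                           mean_log10_fl = 0, pct_of_wt = 0,
                           z = c(-0.5, -1.45, -3.0))
  hits <- call_hits(scores, threshold_sd = 1.45)
  expect_equal(hits$strain, c("C", "B"))      # boundary inclusive, ascending z
  expect_equal(call_hits(scores, threshold_sd = 2.0)$strain, "C")
  # default thresholds by induction time
  expect_equal(nrow(call_hits(scores, timepoint = 6)), 2L)
  expect_equal(nrow(call_hits(scores, timepoint = 24)), 1L)
})

test_that("natural separation finds the largest sub-wild-type gap", {
  z <- c(-0.2, -1.1, -1.2, -1.7, -1.8)
  expect_equal(find_natural_separation(z), 1.45)
  # evenly spaced: tie broken toward the most negative gap
  even <- c(-0.5, -1.2, -1.4, -1.6, -1.8)
  expect_equal(find_natural_separation(even), 1.7)
  one <- c(0, -0.2, -0.5, -0.9, -1.3)
  expect_equal(find_natural_separation(one), 1.3)
  expect_warning(thr <- find_natural_separation(c(0, -0.1, -0.2, -0.3, -0.4)),
                 "default")
  expect_equal(thr, 1.45)
  expect_error(find_natural_separation(c(-2, -3)), "at least 5")
})
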