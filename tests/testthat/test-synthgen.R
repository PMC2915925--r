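# Generators: flow events, image stacks, catalogs — all with known truth.

test_that("noise-free uncoupled flow events have identical fluorescence", {
  cfg <- flow_sim_config(n_events_per_well = 50, noise_sd = 0,
                         null_effect_sd = 0, scatter_coupling = c(0, 0),
                         seed = 1)
  ev <- simulate_flow_plate(cfg, data.frame(well = c("A01", "A02"),
                                            strain = c("WT", "S1")))
  expect_equal(length(unique(round(log10(ev$FL1), 12))), 1L)
})

test_that("a half-fluorescence strain shifts mean log10 FL1 by -0.301", {
  n <- 10000
  cfg <- flow_sim_config(n_events_per_well = n,
                         strain_effect = c(S1 = -0.301), null_effect_sd = 0,
                         seed = 7)
  ev <- simulate_flow_plate(cfg, data.frame(well = c("A01", "A02"),
                                            strain = c("WT", "S1")))
  lfl <- log10(ev$FL1)
  d <- mean(lfl[ev$strain == "S1"]) - mean(lfl[ev$strain == "WT"])
  # closed-form oracle: SE of a difference of two independent means
  se <- sqrt(var(lfl[ev$strain == "S1"]) / n + var(lfl[ev$strain == "WT"]) / n)
  expect_lt(abs(d - (-0.301)), 3 * se)
})

test_that("flow simulation is bit-identical under a fixed seed", {
  cfg <- flow_sim_config(n_events_per_well = 200, seed = 11)
  lay <- plate_layout(c("S1", "S2"))
  expect_identical(simulate_flow_plate(cfg, lay), simulate_flow_plate(cfg, lay))
  expect_error(simulate_flow_plate(cfg, data.frame(well = character(0),
                                                   strain = character(0))),
               "no wells")
})

test_that("simulated fluorescence is coupled to scatter and plate effects", {
  cfg <- flow_sim_config(n_events_per_well = 5000, seed = 3,
                         plate_shift = c(P2 = 0.2))
  lay <- rbind(data.frame(plate = "P1", well = "A01", strain = "WT"),
               data.frame(plate = "P2", well = "A01", strain = "WT"))
  ev <- simulate_flow_plate(cfg, lay)
  expect_gt(cor(log10(ev$FL1), log10(ev$FSC)), 0.3)
  d <- mean(log10(ev$FL1[ev$plate == "P2"])) -
    mean(log10(ev$FL1[ev$plate == "P1"]))
  expect_lt(abs(d - 0.2), 0.02)
})

test_that("a rendered sphere matches the brute-force rasterization count", {
  cfg <- small_stack_config(noise_sd = 0, psf_sigma = c(0, 0, 0),
                            autofluorescence = 0, background_level = 0,
                            puncta_count_fixed = 1, puncta_radius_sd = 0,
                            puncta_radius_mean = 0.5, seed = 2)
  sim <- simulate_stack(cfg, keep_clean = TRUE)
  fg <- sum(sim$truth$clean > max(sim$truth$diffuse_by_cell) /
              sum(sim$truth$cell_labels > 0) + 1e-9)
  p <- sim$truth$puncta
  centre <- (c(p$z, p$y, p$x) + 0.5) * cfg$voxel_size
  oracle <- brute_force_sphere_count(centre, p$radius_um, cfg$voxel_size,
                                     cfg$shape)
  expect_equal(fg, oracle)
  expect_equal(p$volume_um3, 4 / 3 * pi * p$radius_um^3)
})

test_that("mislocalized preset routes at least 90% of reporter to cytosol", {
  for (s in 1:3) {
    sim <- simulate_stack(small_stack_config(phenotype_preset = "mislocalized",
                                             seed = s))
    expect_gte(sim$truth$diffuse_fraction, 0.9)
    expect_equal(nrow(sim$truth$puncta), 0L)
  }
})

test_that("inheritance preset places puncta in the bud or near the neck", {
  for (s in 1:3) {
    sim <- simulate_stack(stack_sim_config(phenotype_preset = "inheritance_defect",
                                           n_cells = 4, seed = s))
    p <- sim$truth$puncta
    expect_gte(mean(p$compartment == "bud" | p$near_neck), 0.8)
  }
})

test_that("size presets scale punctum radii by 0.5x and 2x", {
  base <- sapply(1:4, function(s) median(
    simulate_stack(small_stack_config(seed = s))$truth$puncta$radius_um))
  small <- sapply(1:4, function(s) median(
    simulate_stack(small_stack_config(phenotype_preset = "small",
                                      seed = s))$truth$puncta$radius_um))
  large <- sapply(1:4, function(s) median(
    simulate_stack(small_stack_config(phenotype_preset = "large",
                                      seed = s))$truth$puncta$radius_um))
  expect_lt(abs(median(small) / median(base) - 0.5), 0.15)
  expect_lt(abs(median(large) / median(base) - 2.0), 0.4)
})

test_that("stack ground truth conserves per-cell punctum counts and volume", {
  sim <- simulate_stack(stack_sim_config(n_cells = 4, seed = 9),
                        keep_clean = TRUE)
  tab <- table(factor(sim$truth$puncta$cell, levels = sim$truth$cells$id))
  expect_equal(as.integer(tab), sim$truth$cells$n_puncta)
  # pre-blur punctate intensity is proportional to rasterized volume
  expect_equal(sum(sim$truth$punctate_by_cell),
               sim$truth$reporter_punctate_sum)
  expect_identical(simulate_stack(stack_sim_config(n_cells = 2, seed = 5))$stack$voxels,
                   simulate_stack(stack_sim_config(n_cells = 2, seed = 5))$stack$voxels)
})

test_that("catalog simulation obeys inclusion probabilities and determinism", {
  all_in <- simulate_catalog(50, c(A = 1, B = 1), seed = 1)
  expect_true(all(all_in$membership))
  none <- simulate_catalog(50, c(A = 0, B = 0), seed = 1)
  expect_false(any(none$membership))
  expect_error(simulate_catalog(10, numeric(0)), "at least one")
  expect_error(simulate_catalog(10, rep(0.5, 6)), "at most five")

  cat1 <- simulate_catalog(1000, c(0.05, 0.05), seed = 42)
  # oracle: brute-force row-wise recount of the emitted matrix
  recount <- sum(apply(cat1$membership, 1, sum) >= 2)
  expect_equal(nrow(integrate_catalog(cat1, min_studies = 2)[
    !integrate_catalog(cat1, min_studies = 2)$validated_novel, ]), recount)
  expect_identical(simulate_catalog(100, c(0.3, 0.2), seed = 5)$membership,
                   simulate_catalog(100, c(0.3, 0.2), seed = 5)$membership)
})

test_that("annotation and interaction generators cover their universe", {
  genes <- sprintf("G%03d", 1:40)
  ann <- simulate_annotations(genes, n_terms = 5, seed = 2)
  expect_true(all(genes %in% ann$gene))
  edges <- simulate_interactions(genes, n_edges = 30, seed = 2)
  expect_equal(nrow(edges), 30L)
  expect_false(any(duplicated(paste(edges$gene_a, edges$gene_b))))
  expect_true(all(edges$gene_a < edges$gene_b))
})
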