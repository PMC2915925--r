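# Image pipeline: segmentation, filtering, thresholding, 3D reconstruction.

test_that("disjoint cells are segmented and overlap their truth masks", {
  cfg <- stack_sim_config(n_cells = 3, noise_sd = 0, psf_sigma = c(0, 0, 0),
                          budded_fraction = 0, seed = 12)
  sim <- simulate_stack(cfg)
  seg <- segment_cells(sim$stack, split_buds = FALSE)
  expect_equal(nrow(seg$cells), 3L)
  truth2d <- apply(sim$truth$cell_labels, c(2, 3), max)
  for (id in seg$cells$id) {
    sel <- seg$labels == id
    tid <- as.integer(names(which.max(table(truth2d[sel & truth2d > 0]))))
    tmask <- truth2d == tid
    expect_gte(sum(sel & tmask) / sum(tmask), 0.99)
  }
})

test_that("degenerate images give empty segmentations with a warning", {
  flat <- image_stack(array(5, c(4, 64, 64)), c(0.5, 0.1, 0.1))
  expect_warning(seg <- segment_cells(flat), "degenerate")
  expect_equal(nrow(seg$cells), 0L)
  withr::with_seed(1, {
    noise <- image_stack(array(abs(rnorm(4 * 64 * 64, 10, 2)), c(4, 64, 64)),
                         c(0.5, 0.1, 0.1))
  })
  seg2 <- suppressWarnings(segment_cells(noise))
  expect_equal(nrow(seg2$cells), 0L)
})

test_that("mother/bud sub-labelling recovers budded cells", {
  hit <- 0; tot <- 0
  for (s in 1:4) {
    sim <- simulate_stack(stack_sim_config(n_cells = 4, budded_fraction = 1,
                                           seed = 30 + s))
    seg <- segment_cells(sim$stack)
    tot <- tot + nrow(seg$cells)
    hit <- hit + sum(seg$cells$budded)
  }
  expect_gte(hit / tot, 0.75)
})

test_that("the low-pass filter preserves DC and never raises variance", {
  withr::with_seed(3, {
    arr <- array(abs(rnorm(8 * 48 * 48, 20, 3)), c(8, 48, 48))
  })
  stack <- image_stack(arr, c(0.5, 0.1, 0.1))
  f <- lowpass_filter(stack, 0.1)
  expect_lte(var(as.vector(f$voxels)), var(as.vector(arr)))
  const <- image_stack(array(7, c(4, 32, 32)), c(0.5, 0.1, 0.1))
  expect_equal(lowpass_filter(const, 0.1)$voxels, const$voxels)
})

test_that("a delta spike is attenuated by the discrete kernel centre weight", {
  arr <- array(0, c(1, 41, 41))
  arr[1, 21, 21] <- 100
  stack <- image_stack(arr, c(0.5, 0.1, 0.1))
  f <- lowpass_filter(stack, 0.1)
  k <- peroxiscreen:::gaussian_kernel_1d(1)      # sigma = 0.1 um / 0.1 um px
  expect_equal(f$voxels[1, 21, 21], 100 * max(k)^2)
  # a broad punctum (radius ~ 3 sigma) keeps most of its peak
  arr2 <- array(0, c(1, 41, 41))
  yy <- matrix(rep(1:41, 41), 41); xx <- t(yy)
  arr2[1, , ] <- ifelse((yy - 21)^2 + (xx - 21)^2 <= 9, 100, 0)
  f2 <- lowpass_filter(image_stack(arr2, c(0.5, 0.1, 0.1)), 0.1)
  expect_gte(f2$voxels[1, 21, 21], 80)
})

test_that("sub-voxel filter sigma returns the input with a warning", {
  stack <- image_stack(array(1:32, c(2, 4, 4)), c(0.5, 0.5, 0.5))
  expect_warning(f <- lowpass_filter(stack, 0.05), "returning input")
  expect_equal(f$voxels, stack$voxels)
})

test_that("cross-check: the separable Gaussian matches EBImage's filter", {
  withr::with_seed(5, m <- matrix(abs(rnorm(64 * 64, 10, 2)), 64))
  ours <- gaussian_smooth(m, c(2, 2))
  theirs <- EBImage::gblur(m, sigma = 2)
  inner <- 15:50   # away from borders, where padding conventions differ
  expect_lt(max(abs(ours[inner, inner] - theirs[inner, inner])), 1e-4)
})

test_that("thresholding a noise-free slice recovers the rendered discs", {
  arr <- array(10, c(3, 64, 64))
  yy <- matrix(rep(1:64, 64), 64); xx <- t(yy)
  disc <- (yy - 32)^2 + (xx - 32)^2 <= 16
  arr[2, , ][disc] <- 100
  stack <- image_stack(arr, c(0.5, 0.1, 0.1))
  bin <- threshold_slices(stack, method = "background_k_sd", k = 3)
  expect_equal(bin[2, , ], disc)
  expect_false(any(bin[1, , ]))
})

test_that("all-background slices yield no foreground", {
  withr::with_seed(6, arr <- array(abs(rnorm(4 * 48 * 48, 10, 1)), c(4, 48, 48)))
  stack <- image_stack(arr, c(0.5, 0.1, 0.1))
  bin <- threshold_slices(lowpass_filter(stack, 0.1), k = 5)
  expect_lt(mean(bin), 0.001)
})

test_that("otsu thresholding is invariant to positive rescaling", {
  withr::with_seed(7, {
    arr <- array(abs(rnorm(2 * 48 * 48, 10, 1)), c(2, 48, 48))
    arr[1, 10:20, 10:20] <- 60
  })
  s1 <- image_stack(arr, c(0.5, 0.1, 0.1))
  s2 <- image_stack(arr * 3.7, c(0.5, 0.1, 0.1))
  expect_equal(threshold_slices(s1, method = "otsu"),
               threshold_slices(s2, method = "otsu"))
  expect_error(threshold_slices(s1, method = "bogus"), "valid methods")
  expect_error(threshold_slices(s1, method = "fixed"), "requires value")
})

test_that("a rendered sphere is reconstructed with its rasterized volume", {
  vs <- c(0.2, 0.1, 0.1)
  shape <- c(20L, 64L, 64L)
  arr <- array(0, shape)
  centre <- c(2.05, 3.17, 3.33)
  r <- 0.5
  g <- expand.grid(z = 1:20, y = 1:64, x = 1:64)
  inside <- ((g$z - 0.5) * vs[1] - centre[1])^2 +
    ((g$y - 0.5) * vs[2] - centre[2])^2 +
    ((g$x - 0.5) * vs[3] - centre[3])^2 <= r^2
  arr[cbind(g$z, g$y, g$x)[inside, ]] <- 1
  obj <- reconstruct_volumes(arr > 0, voxel_size = vs, min_voxels = 2)
  expect_equal(nrow(obj), 1L)
  oracle <- brute_force_sphere_count(centre, r, vs, shape)
  expect_equal(obj$voxel_count, oracle)
  expect_equal(obj$volume_um3, oracle * prod(vs))
})

test_that("well-separated spheres stay distinct; empty stacks give no objects", {
  arr <- array(FALSE, c(10, 40, 40))
  arr[3:5, 5:8, 5:8] <- TRUE
  arr[8:9, 30:33, 30:33] <- TRUE
  obj <- reconstruct_volumes(arr, voxel_size = c(0.2, 0.1, 0.1))
  expect_equal(nrow(obj), 2L)
  none <- reconstruct_volumes(array(FALSE, c(4, 8, 8)),
                              voxel_size = c(0.2, 0.1, 0.1))
  expect_equal(nrow(none), 0L)
})

test_that("object volumes satisfy the voxel-count identity exactly", {
  withr::with_seed(9, arr <- array(runif(10 * 48 * 48) > 0.9, c(10, 48, 48)))
  vs <- c(0.5, 0.1, 0.1)
  obj <- reconstruct_volumes(arr, voxel_size = vs, min_voxels = 1)
  expect_equal(sum(obj$voxel_count), sum(arr))
  expect_equal(obj$volume_um3, obj$voxel_count * prod(vs))
})

test_that("whole-voxel translation leaves the voxel count unchanged", {
  arr <- array(FALSE, c(12, 40, 40))
  arr[4:6, 10:14, 10:13] <- TRUE
  shifted <- array(FALSE, c(12, 40, 40))
  shifted[6:8, 20:24, 22:25] <- TRUE
  v1 <- reconstruct_volumes(arr, voxel_size = c(0.2, 0.1, 0.1))
  v2 <- reconstruct_volumes(shifted, voxel_size = c(0.2, 0.1, 0.1))
  expect_equal(v1$voxel_count, v2$voxel_count)
})

test_that("raising the threshold never grows an object", {
  withr::with_seed(10, {
    arr <- array(abs(rnorm(6 * 48 * 48, 10, 2)), c(6, 48, 48))
    arr[3, 20:26, 20:26] <- arr[3, 20:26, 20:26] + 80
  })
  stack <- image_stack(arr, c(0.5, 0.1, 0.1))
  f <- lowpass_filter(stack, 0.1)
  lo <- threshold_slices(f, k = 3)
  hi <- threshold_slices(f, k = 6)
  expect_true(all(lo[hi]))      # hi-threshold foreground nests in lo's
  expect_lte(sum(hi), sum(lo))
})

test_that("shape mismatches between mask and segmentation are rejected", {
  sim <- simulate_stack(small_stack_config(seed = 3))
  seg <- segment_cells(sim$stack)
  bad <- array(FALSE, c(4, 8, 8))
  expect_error(reconstruct_volumes(bad, seg), "shape mismatch")
})

test_that("quantify_strain summarizes counts, intensity and compartments", {
  cfg <- stack_sim_config(n_cells = 4, puncta_count_fixed = 4, seed = 19)
  q <- suppressMessages(quantify_strain(list(simulate_stack(cfg)$stack)))
  expect_gte(nrow(q), 3)
  expect_true(all(abs(q$n_puncta - 4) <= 1))
  frac <- q$punctate_intensity / q$total_intensity
  expect_true(all(frac > 0.5))
  expect_error(quantify_strain(list()), "at least one")
})

test_that("mislocalized stacks lose nearly all punctate signal", {
  for (s in 1:3) {
    sim <- simulate_stack(stack_sim_config(phenotype_preset = "mislocalized",
                                           n_cells = 4, seed = 40 + s))
    q <- suppressMessages(quantify_strain(sim$stack))
    frac <- q$punctate_intensity / q$total_intensity
    expect_gte(mean(frac < 0.2), 0.9)
  }
})
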