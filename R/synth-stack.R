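# Synthetic 3D confocal stacks of oleate-induced budded yeast expressing a
# punctate peroxisomal reporter, with voxel-level ground truth. Phenotype
# presets mirror the screen's vocabulary: import failure (diffuse cytosolic
# reporter), partial import failure, loss of expression, inheritance defects
# (puncta clustered in the bud / at the bud neck), abnormally small or large
# peroxisomes, and clustering.

PHENOTYPE_PRESETS <- c("wildtype", "mislocalized", "partial_mislocalized",
                       "low_expression", "inheritance_defect", "small",
                       "large", "clustered")

#' Configuration for the stack simulator
#'
#' Defaults describe a 100x confocal acquisition of budded yeast: twenty
#' 0.5 um z-steps at 0.1 um pixel size, near-spherical peroxisomes of
#' ~0.3 um radius, Gaussian point-spread blur, and Gaussian read noise with
#' optional Poisson shot noise. Cells are two overlapping ellipsoids (mother
#' and bud) with a declared neck plane.
#'
#' @param shape stack dimensions `(n_z, n_y, n_x)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param n_cells number of cells rendered (placed on a jittered grid so
#'   cells never touch).
#' @param budded_fraction probability a cell carries a bud (the
#'   `inheritance_defect` preset forces budded cells).
#' @param phenotype_preset one of `"wildtype"`, `"mislocalized"`,
#'   `"partial_mislocalized"`, `"low_expression"`, `"inheritance_defect"`,
#'   `"small"`, `"large"`, `"clustered"`.
#' @param puncta_count_lambda per-cell punctum count is `1 + Poisson(lambda)`
#'   (0 for the fully penetrant `mislocalized` preset).
#' @param puncta_count_fixed if non-NULL, every cell gets exactly this many
#'   puncta instead of the Poisson draw.
#' @param puncta_radius_mean,puncta_radius_sd punctum radius distribution
#'   (um); the `small`/`large` presets scale the radius by 0.5x / 2x, with
#'   the punctum count doubled / halved (numerous smaller organelles versus
#'   fewer giant ones).
#' @param punctum_amplitude per-voxel reporter intensity inside a punctum.
#'   The matrix-protein concentration is constant, so a punctum's
#'   integrated intensity scales with its volume.
#' @param puncta_min_sep_um minimum distance between punctum centres within
#'   a cell (discrete organelles); the clustered preset ignores it.
#' @param autofluorescence uniform in-cell baseline (not counted as reporter).
#' @param background_level camera offset outside cells.
#' @param noise_sd Gaussian read-noise SD.
#' @param poisson_scale if non-NULL, Poisson shot noise: intensities are
#'   drawn as `rpois(x * scale) / scale` before read noise is added.
#' @param psf_sigma Gaussian point-spread SD per axis `(z, y, x)` in um.
#' @param mother_semi_um mother-cell ellipsoid semi-axes `(z, y, x)` in um.
#' @param bud_scale bud semi-axes as a fraction of the mother's.
#' @param seed integer; the generator is bit-reproducible under a fixed seed.
#' @return a validated config list of class `stack_sim_config`.
#' @export
stack_sim_config <- function(shape = c(20L, 176L, 176L),
                             voxel_size = c(0.5, 0.1, 0.1),
                             n_cells = 4L,
                             budded_fraction = 0.8,
                             phenotype_preset = "wildtype",
                             puncta_count_lambda = 3,
                             puncta_count_fixed = NULL,
                             puncta_radius_mean = 0.35,
                             puncta_radius_sd = 0.06,
                             punctum_amplitude = 1200,
                             puncta_min_sep_um = NULL,
                             autofluorescence = 3.5,
                             background_level = 10,
                             noise_sd = 2,
                             poisson_scale = NULL,
                             psf_sigma = c(0.25, 0.1, 0.1),
                             mother_semi_um = c(1.4, 1.9, 1.9),
                             bud_scale = 0.55,
                             seed = 1L) {
  phenotype_preset <- match.arg(phenotype_preset, PHENOTYPE_PRESETS)
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_cells >= 1, noise_sd >= 0, puncta_radius_mean > 0,
            punctum_amplitude > 0, background_level >= 0,
            budded_fraction >= 0, budded_fraction <= 1)
  structure(list(
    shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
    n_cells = as.integer(n_cells), budded_fraction = budded_fraction,
    phenotype_preset = phenotype_preset,
    puncta_count_lambda = puncta_count_lambda,
    puncta_count_fixed = puncta_count_fixed,
    puncta_radius_mean = puncta_radius_mean,
    puncta_radius_sd = puncta_radius_sd,
    punctum_amplitude = punctum_amplitude,
    puncta_min_sep_um = puncta_min_sep_um,
    autofluorescence = autofluorescence,
    background_level = background_level,
    noise_sd = noise_sd, poisson_scale = poisson_scale,
    psf_sigma = rep_len(as.numeric(psf_sigma), 3L),
    mother_semi_um = rep_len(as.numeric(mother_semi_um), 3L),
    bud_scale = bud_scale, seed = as.integer(seed)
  ), class = "stack_sim_config")
}

# preset knobs: radius scaling, reporter scaling, target diffuse fraction,
# punctum placement rule
preset_params <- function(preset) {
  switch(preset,
    wildtype             = list(rf = 1.0, scale = 1.00, df = 0.05, place = "uniform",  count = "normal"),
    mislocalized         = list(rf = 1.0, scale = 1.00, df = 1.00, place = "uniform",  count = "none"),
    partial_mislocalized = list(rf = 1.0, scale = 1.00, df = 0.65, place = "uniform",  count = "normal"),
    low_expression       = list(rf = 1.0, scale = 0.05, df = 0.05, place = "uniform",  count = "normal"),
    inheritance_defect   = list(rf = 1.0, scale = 1.00, df = 0.05, place = "bud_neck", count = "normal"),
    small                = list(rf = 0.5, scale = 1.00, df = 0.05, place = "uniform",  count = "many"),
    large                = list(rf = 2.0, scale = 1.00, df = 0.05, place = "uniform",  count = "few"),
    clustered            = list(rf = 1.0, scale = 1.00, df = 0.05, place = "cluster",  count = "normal")
  )
}

# voxel-centre coordinates (um) along one axis
axis_centres <- function(n, d) (seq_len(n) - 0.5) * d

# linear voxel indices inside an axis-aligned ellipsoid (evaluated over its
# bounding box only)
ellipsoid_indices <- function(centre, semi, voxel_size, shape) {
  lo <- pmax(1L, floor((centre - semi) / voxel_size + 0.5))
  hi <- pmin(shape, ceiling((centre + semi) / voxel_size + 0.5))
  if (any(lo > hi)) return(integer(0))
  zz <- axis_centres(shape[1], voxel_size[1])[lo[1]:hi[1]]
  yy <- axis_centres(shape[2], voxel_size[2])[lo[2]:hi[2]]
  xx <- axis_centres(shape[3], voxel_size[3])[lo[3]:hi[3]]
  g <- expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE)
  inside <- ((g$z - centre[1]) / semi[1])^2 +
            ((g$y - centre[2]) / semi[2])^2 +
            ((g$x - centre[3]) / semi[3])^2 <= 1
  gi <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3],
                    KEEP.OUT.ATTRS = FALSE)[inside, , drop = FALSE]
  (gi$z) + shape[1] * ((gi$y - 1L) + shape[2] * (gi$x - 1L))
}

in_ellipsoid <- function(p, centre, semi) {
  sum(((p - centre) / semi)^2) <= 1
}

# uniform sample inside an ellipsoid shrunk by `margin` (um) per axis
sample_in_ellipsoid <- function(centre, semi, margin = 0) {
  semi_eff <- pmax(semi - margin, 0.05)
  repeat {
    v <- runif(3, -1, 1)
    if (sum(v^2) <= 1) return(centre + v * semi_eff)
  }
}

make_cell_geometry <- function(config) {
  shape <- config$shape; vs <- config$voxel_size
  preset <- config$phenotype_preset
  field <- shape * vs                      # (z, y, x) extent in um
  nt <- ceiling(sqrt(config$n_cells))
  tile <- field[2:3] / nt
  a <- config$mother_semi_um
  # worst one-sided extent from the mother centre: bud offset + bud radius,
  # both at the upper end of the size jitter, plus the centre jitter
  amax <- 1.05 * a[2]
  bmax <- amax * config$bud_scale * 1.05
  extent <- amax + 0.6 * bmax + bmax + 0.3
  need <- 2 * extent + 0.2
  if (min(tile) < need) {
    stop(sprintf("field too small for %d cells: tile %.1f um < required %.1f um",
                 config$n_cells, min(tile), need))
  }
  cells <- vector("list", config$n_cells)
  slots <- expand.grid(ty = seq_len(nt), tx = seq_len(nt))[seq_len(config$n_cells), ]
  for (i in seq_len(config$n_cells)) {
    semi_m <- a * runif(1, 0.95, 1.05)
    semi_b <- semi_m * config$bud_scale * runif(1, 0.95, 1.05)
    budded <- if (preset == "inheritance_defect") TRUE else runif(1) < config$budded_fraction
    tile_centre <- c((slots$ty[i] - 0.5) * tile[1], (slots$tx[i] - 0.5) * tile[2])
    centre <- c(field[1] / 2 + runif(1, -0.5, 0.5),
                tile_centre + runif(2, -0.3, 0.3))
    bud_centre <- neck_point <- neck_normal <- NULL
    d_off <- x_star <- NA_real_
    if (budded) {
      theta <- runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))                 # (y, x) unit direction
      d_off <- semi_m[2] + 0.6 * semi_b[2]
      bud_centre <- c(centre[1], centre[2:3] + d_off * u)
      # plane through the intersection circle of the two (xy-circular) bodies
      x_star <- (d_off^2 + semi_m[2]^2 - semi_b[2]^2) / (2 * d_off)
      neck_point <- centre[2:3] + x_star * u
      neck_normal <- u
    }
    cells[[i]] <- list(id = i, centre = centre, semi_m = semi_m,
                       semi_b = semi_b, budded = budded,
                       bud_centre = bud_centre, neck_point = neck_point,
                       neck_normal = neck_normal, d_off = d_off,
                       x_star = x_star)
  }
  cells
}

# signed distance (um) of a (z,y,x) point to a cell's neck plane
neck_distance <- function(p, cell) {
  if (!cell$budded) return(NA_real_)
  abs(sum((p[2:3] - cell$neck_point) * cell$neck_normal))
}

place_punctum <- function(cell, r, place, cluster_centre) {
  if (place == "bud_neck" && cell$budded) {
    if (runif(1) < 0.7) {
      return(list(p = sample_in_ellipsoid(cell$bud_centre, cell$semi_b, r),
                  comp = "bud"))
    }
    for (try in 1:200) {
      p <- sample_in_ellipsoid(cell$centre, cell$semi_m, r)
      if (neck_distance(p, cell) <= 1) return(list(p = p, comp = "mother"))
    }
    return(list(p = p, comp = "mother"))     # rare fallback: last draw
  }
  if (place == "cluster") {
    for (try in 1:200) {
      p <- cluster_centre + rnorm(3, sd = 0.2)
      if (in_ellipsoid(p, cell$centre, pmax(cell$semi_m - r, 0.05))) {
        return(list(p = p, comp = "mother"))
      }
    }
    return(list(p = sample_in_ellipsoid(cell$centre, cell$semi_m, r),
                comp = "mother"))
  }
  # uniform: compartment chosen proportional to compartment volume
  vol_m <- prod(cell$semi_m)
  vol_b <- if (cell$budded) prod(cell$semi_b) else 0
  if (cell$budded && runif(1) < vol_b / (vol_m + vol_b)) {
    list(p = sample_in_ellipsoid(cell$bud_centre, cell$semi_b, r), comp = "bud")
  } else {
    list(p = sample_in_ellipsoid(cell$centre, cell$semi_m, r), comp = "mother")
  }
}

#' Simulate a 3D reporter stack with ground truth
#'
#' Renders budded-cell geometries and spherical puncta analytically, applies
#' the phenotype preset's reporter allocation (punctate vs diffuse), then the
#' Gaussian point-spread blur and the noise model. Ground truth (cell label
#' map with mother/bud compartments, the punctum catalogue, and the diffuse
#' reporter fraction) is recorded before blur and noise.
#'
#' @param config a [stack_sim_config()].
#' @param keep_clean also return the pre-blur, pre-noise intensity array and
#'   the pure punctate reporter array (used by rasterization oracles).
#' @return list with elements `stack` ([image_stack]) and `truth`
#'   (`stack_ground_truth`: `cell_labels`, `compartments` (1 mother, 2 bud),
#'   `cells`, `puncta`, `diffuse_fraction`, `warnings`).
#' @export
simulate_stack <- function(config, keep_clean = FALSE) {
  stopifnot(inherits(config, "stack_sim_config"))
  withr::with_seed(config$seed, simulate_stack_impl(config, keep_clean))
}

simulate_stack_impl <- function(config, keep_clean) {
  shape <- config$shape; vs <- config$voxel_size
  pp <- preset_params(config$phenotype_preset)
  cells <- make_cell_geometry(config)
  warnings <- character(0)

  cell_labels <- array(0L, shape)
  compartments <- array(0L, shape)
  for (cell in cells) {
    im <- ellipsoid_indices(cell$centre, cell$semi_m, vs, shape)
    cell_labels[im] <- cell$id
    compartments[im] <- 1L
    if (cell$budded) {
      ib <- ellipsoid_indices(cell$bud_centre, cell$semi_b, vs, shape)
      ib <- ib[compartments[ib] != 1L]       # mother wins ties
      cell_labels[ib] <- cell$id
      compartments[ib] <- 2L
    }
  }

  reporter <- array(0, shape)
  punctate_by_cell <- numeric(length(cells))
  diffuse_by_cell <- numeric(length(cells))
  vox_vol <- prod(vs)
  amp <- config$punctum_amplitude * pp$scale
  min_sep_gap <- config$puncta_min_sep_um %||% 0.8
  puncta <- list()

  for (cell in cells) {
    n_p <- if (pp$count == "none") 0L
      else if (!is.null(config$puncta_count_fixed)) as.integer(config$puncta_count_fixed)
      else if (pp$count == "few") 1L + rpois(1, config$puncta_count_lambda / 2)
      else if (pp$count == "many") 1L + rpois(1, config$puncta_count_lambda * 2)
      else 1L + rpois(1, config$puncta_count_lambda)
    cluster_centre <- if (pp$place == "cluster") {
      sample_in_ellipsoid(cell$centre, cell$semi_m * 0.5, 0)
    } else NULL
    placed <- list()
    for (j in seq_len(n_p)) {
      r <- max(rnorm(1, config$puncta_radius_mean * pp$rf,
                     config$puncta_radius_sd * pp$rf), 0.08)
      pl <- place_punctum(cell, r, pp$place, cluster_centre)
      if (pp$place != "cluster" && length(placed)) {
        # organelles are discrete: keep centres separated where possible
        ok <- function(p) all(vapply(placed, function(q) {
          sqrt(sum((p - q$p)^2)) >= r + q$r + min_sep_gap
        }, logical(1)))
        tries <- 0L
        while (!ok(pl$p) && tries < 150L) {
          pl <- place_punctum(cell, r, pp$place, cluster_centre)
          tries <- tries + 1L
        }
      }
      placed[[length(placed) + 1L]] <- list(p = pl$p, r = r)
      idx <- ellipsoid_indices(pl$p, rep(r, 3), vs, shape)
      if (length(idx) == 0L) {              # guarantee the nearest voxel
        ctr <- pmin(pmax(round(pl$p / vs + 0.5), 1L), shape)
        idx <- ctr[1] + shape[1] * ((ctr[2] - 1L) + shape[2] * (ctr[3] - 1L))
      }
      if (r < min(vs)) {
        warnings <- c(warnings, sprintf(
          "punctum of radius %.3f um smaller than one voxel in every axis (cell %d); may be undetectable",
          r, cell$id))
      }
      reporter[idx] <- reporter[idx] + amp
      punctate_by_cell[cell$id] <- punctate_by_cell[cell$id] + amp * length(idx)
      nd <- neck_distance(pl$p, cell)
      puncta[[length(puncta) + 1L]] <- tibble(
        cell = cell$id, compartment = pl$comp,
        z = pl$p[1] / vs[1] - 0.5, y = pl$p[2] / vs[2] - 0.5,
        x = pl$p[3] / vs[3] - 0.5,
        radius_um = r, volume_um3 = 4 / 3 * pi * r^3,
        neck_dist_um = nd, near_neck = !is.na(nd) & nd <= 1)
    }
  }
  puncta <- if (length(puncta)) dplyr::bind_rows(puncta) else tibble(
    cell = integer(0), compartment = character(0), z = numeric(0),
    y = numeric(0), x = numeric(0), radius_um = numeric(0),
    volume_um3 = numeric(0), neck_dist_um = numeric(0), near_neck = logical(0))

  # diffuse reporter: allocated per cell to reach the preset's diffuse
  # fraction; for the fully diffuse preset the budget equals the expected
  # wild-type punctate total (same expression, failed import)
  expected_count <- config$puncta_count_fixed %||% (1 + config$puncta_count_lambda)
  expected_punct <- amp * expected_count *
    (4 / 3) * pi * config$puncta_radius_mean^3 / vox_vol
  for (cell in cells) {
    cidx <- which(cell_labels == cell$id)
    if (length(cidx) == 0L) next
    punct <- punctate_by_cell[cell$id]
    dtot <- if (pp$df >= 1) expected_punct else pp$df / (1 - pp$df) * punct
    if (dtot > 0) {
      reporter[cidx] <- reporter[cidx] + dtot / length(cidx)
      diffuse_by_cell[cell$id] <- dtot
    }
  }
  total_rep <- sum(punctate_by_cell) + sum(diffuse_by_cell)
  diffuse_fraction <- if (total_rep > 0) sum(diffuse_by_cell) / total_rep else 0

  clean <- config$background_level + reporter
  clean[cell_labels > 0] <- clean[cell_labels > 0] + config$autofluorescence

  blurred <- clean
  sig_vox <- config$psf_sigma / vs
  if (any(sig_vox > 0)) blurred <- gaussian_smooth(blurred, sig_vox)
  noisy <- blurred
  if (!is.null(config$poisson_scale)) {
    noisy <- rpois(length(noisy), pmax(noisy, 0) * config$poisson_scale) /
      config$poisson_scale
    dim(noisy) <- shape
  }
  if (config$noise_sd > 0) noisy <- noisy + rnorm(length(noisy), sd = config$noise_sd)
  noisy <- pmax(noisy, 0)
  dim(noisy) <- shape

  cells_tbl <- dplyr::bind_rows(lapply(cells, function(cl) tibble(
    id = cl$id, budded = cl$budded,
    centre_z = cl$centre[1], centre_y = cl$centre[2], centre_x = cl$centre[3],
    semi_mz = cl$semi_m[1], semi_my = cl$semi_m[2], semi_mx = cl$semi_m[3],
    neck_y = if (cl$budded) cl$neck_point[1] else NA_real_,
    neck_x = if (cl$budded) cl$neck_point[2] else NA_real_,
    n_puncta = sum(puncta$cell == cl$id))))

  truth <- structure(list(
    cell_labels = cell_labels, compartments = compartments,
    cells = cells_tbl, puncta = puncta,
    diffuse_fraction = diffuse_fraction,
    punctate_by_cell = punctate_by_cell, diffuse_by_cell = diffuse_by_cell,
    preset = config$phenotype_preset,
    warnings = warnings), class = "stack_ground_truth")
  if (keep_clean) {
    truth$clean <- clean
    truth$reporter_punctate_sum <- sum(punctate_by_cell)
  }
  list(stack = image_stack(noisy, vs), truth = truth)
}

#' Simulate a field of isolated spheres
#'
#' A calibration phantom for the volumetry pipeline: bright spheres on a flat
#' background, placed on a jittered grid so they never touch, with analytic
#' ground-truth volumes.
#'
#' @param shape,voxel_size stack geometry (see [stack_sim_config()]).
#' @param n_spheres number of spheres.
#' @param radius_um length-2 range; radii drawn uniformly.
#' @param amplitude,background_level,noise_sd,psf_sigma rendering parameters
#'   as in [stack_sim_config()].
#' @param seed integer seed.
#' @return list with `stack` and `truth` (tibble: voxel-coordinate centroids,
#'   `radius_um`, analytic `volume_um3`, and the rasterized `voxel_count`).
#' @export
simulate_sphere_field <- function(shape = c(20L, 256L, 256L),
                                  voxel_size = c(0.2, 0.1, 0.1),
                                  n_spheres = 16L,
                                  radius_um = c(0.45, 0.7),
                                  amplitude = 120,
                                  background_level = 10,
                                  noise_sd = 2,
                                  psf_sigma = c(0.2, 0.1, 0.1),
                                  seed = 1L) {
  shape <- as.integer(shape)
  withr::with_seed(seed, {
    field <- shape * voxel_size
    nt <- ceiling(sqrt(n_spheres))
    tile <- field[2:3] / nt
    if (min(tile) < 2 * max(radius_um) + 1) stop("field too small for n_spheres")
    slots <- expand.grid(ty = seq_len(nt), tx = seq_len(nt))[seq_len(n_spheres), ]
    arr <- array(background_level, shape)
    rows <- vector("list", n_spheres)
    for (i in seq_len(n_spheres)) {
      r <- runif(1, radius_um[1], radius_um[2])
      ctr <- c(field[1] / 2 + runif(1, -1, 1),
               (slots$ty[i] - 0.5) * tile[1] + runif(1, -0.3, 0.3),
               (slots$tx[i] - 0.5) * tile[2] + runif(1, -0.3, 0.3))
      idx <- ellipsoid_indices(ctr, rep(r, 3), voxel_size, shape)
      arr[idx] <- arr[idx] + amplitude
      rows[[i]] <- tibble(
        z = ctr[1] / voxel_size[1] - 0.5, y = ctr[2] / voxel_size[2] - 0.5,
        x = ctr[3] / voxel_size[3] - 0.5, radius_um = r,
        volume_um3 = 4 / 3 * pi * r^3, voxel_count = length(idx))
    }
    sig_vox <- psf_sigma / voxel_size
    if (any(sig_vox > 0)) arr <- gaussian_smooth(arr, sig_vox)
    if (noise_sd > 0) arr <- arr + rnorm(length(arr), sd = noise_sd)
    arr <- pmax(arr, 0); dim(arr) <- shape
    list(stack = image_stack(arr, voxel_size), truth = dplyr::bind_rows(rows))
  })
}
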