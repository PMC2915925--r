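# 3D stack quantification, following the screen's image-analysis recipe:
# k-means cell segmentation on the smoothed z-projection, per-slice
# low-pass filtering and thresholding of the reporter channel, and
# recombination of the thresholded slices into 3D objects whose volumes are
# read off directly from voxel counts.

#' Segment cells by 2-class k-means on the z-mean projection
#'
#' The mean projection over the central z-window (cells grow as a monolayer,
#' so the informative slices are the central ones) is smoothed and — because puncta are orders of
#' magnitude brighter than the cell body and would otherwise dominate the
#' intensity scale — clipped just above the background level (median plus
#' ten scaled MADs) before 2-class k-means with deterministic initial
#' centres at the intensity extremes, so segmentation is reproducible
#' without a seed. Connected foreground components (8-connectivity) become
#' cells; components below `min_area_px` are discarded and unusually large
#' components are flagged ambiguous (possible merged neighbours). Optionally
#' each cell is sub-labelled into mother and bud by a two-lobe split with a
#' waist test.
#'
#' @param stack an [image_stack].
#' @param min_area_px minimum component area in pixels.
#' @param smooth_sigma_um smoothing SD before clustering, in um.
#' @param max_cell_area_um2 areas above this are flagged `ambiguous`
#'   (default: a 3 um-radius disc).
#' @param split_buds attempt mother/bud sub-labelling.
#' @param waist_ratio a component splits only if its waist width is below
#'   this fraction of the narrower lobe's width. Elongation (projected
#'   aspect ratio >= 1.25) is the primary budded criterion — an isolated
#'   cell projects nearly circular — so the default waist check is a weak
#'   consistency guard.
#' @param z_window fraction of the z range (lo, hi) averaged for the
#'   projection.
#' @return object of class `cell_segmentation`: `labels` (y by x integer
#'   matrix of cell ids), `sublabels` (1 mother, 2 bud, 0 unsplit),
#'   `cells` tibble, and the stack geometry.
#' @export
segment_cells <- function(stack, min_area_px = 200, smooth_sigma_um = 0.15,
                          max_cell_area_um2 = pi * 3^2, split_buds = TRUE,
                          waist_ratio = 1.1, z_window = c(0.25, 0.75)) {
  stopifnot(inherits(stack, "image_stack"))
  vs <- stack$voxel_size
  nz <- dim(stack)[1]
  zi <- max(1L, ceiling(z_window[1] * nz)):max(1L, ceiling(z_window[2] * nz))
  proj <- apply(stack$voxels[zi, , , drop = FALSE], c(2, 3), mean)
  sig <- smooth_sigma_um / vs[2:3]
  sm <- gaussian_smooth(proj, sig)

  empty <- function(msg) {
    warning(msg)
    structure(list(labels = matrix(0L, nrow(proj), ncol(proj)),
                   sublabels = matrix(0L, nrow(proj), ncol(proj)),
                   cells = tibble(id = integer(0), area_px = integer(0),
                                  ambiguous = logical(0), budded = logical(0)),
                   voxel_size = vs, n_z = dim(stack)[1]),
              class = "cell_segmentation")
  }
  rng <- range(sm)
  if (diff(rng) == 0) return(empty("uniform image: degenerate segmentation"))

  spread <- mad(sm)
  ceiling_lvl <- if (spread > 0) median(sm) + 8 * spread else {
    # noise-free image: any positive excess over the flat background is
    # signal, so clip just above the smallest excess
    excess <- sm - median(sm)
    median(sm) + 2 * min(excess[excess > 0])
  }
  smc <- pmin(sm, ceiling_lvl)
  rng <- range(smc)
  if (diff(rng) == 0) return(empty("uniform image: degenerate segmentation"))
  km <- kmeans(as.vector(smc), centers = matrix(rng, ncol = 1),
               algorithm = "Lloyd", iter.max = 100)
  fg_cluster <- which.max(km$centers)
  within_sd <- sqrt(max(km$tot.withinss / length(smc), 0))
  if (abs(diff(as.vector(km$centers))) < 2 * within_sd) {
    return(empty("no separable foreground: degenerate segmentation"))
  }
  mask <- matrix(km$cluster == fg_cluster, nrow(proj), ncol(proj))
  if (mean(mask) > 0.5) {
    # a unimodal (noise-only) field splits near its median and half the
    # pixels land in the upper class; cells never cover half the field
    return(empty("no separable foreground: degenerate segmentation"))
  }

  comp <- label_components(mask, connectivity = 26)   # 8-connectivity in 2D
  areas <- tabulate(comp[comp > 0])
  keep <- which(areas >= min_area_px)
  labels <- matrix(0L, nrow(proj), ncol(proj))
  sublabels <- matrix(0L, nrow(proj), ncol(proj))
  cells <- list()
  px_area <- vs[2] * vs[3]
  for (new_id in seq_along(keep)) {
    old <- keep[new_id]
    sel <- comp == old
    labels[sel] <- new_id
    info <- list(id = new_id, area_px = areas[old],
                 ambiguous = areas[old] * px_area > max_cell_area_um2,
                 budded = FALSE, mother_area_px = areas[old],
                 bud_area_px = 0L,
                 neck_y = NA_real_, neck_x = NA_real_,
                 neck_ny = NA_real_, neck_nx = NA_real_)
    if (split_buds) {
      sp <- split_mother_bud(which(sel, arr.ind = TRUE), waist_ratio)
      if (!is.null(sp)) {
        info$budded <- TRUE
        info$mother_area_px <- sp$mother_n
        info$bud_area_px <- sp$bud_n
        info$neck_y <- sp$neck_point[1] * vs[2]
        info$neck_x <- sp$neck_point[2] * vs[3]
        info$neck_ny <- sp$bud_dir[1]   # unit normal pointing into the bud
        info$neck_nx <- sp$bud_dir[2]
        sublabels[sel] <- sp$assign          # 1 mother, 2 bud, mask order
      }
    }
    if (!info$budded) sublabels[sel] <- 1L
    cells[[new_id]] <- as_tibble(info)
  }
  cells <- if (length(cells)) dplyr::bind_rows(cells) else
    tibble(id = integer(0), area_px = integer(0), ambiguous = logical(0),
           budded = logical(0))
  structure(list(labels = labels, sublabels = sublabels, cells = cells,
                 voxel_size = vs, n_z = dim(stack)[1]),
            class = "cell_segmentation")
}

# two-lobe split of a component's pixel coordinates; returns NULL when no
# convincing waist exists. An unbudded cell projects as a near-circular
# blob (aspect ~ 1), so an elongation guard rejects it before the waist
# search; a budded composite is elongated along the mother-bud axis and
# shows a width minimum at the neck.
split_mother_bud <- function(px, waist_ratio) {
  if (nrow(px) < 40) return(NULL)
  ctr <- colMeans(px)
  cc <- sweep(px, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  u <- ev$vectors[, 1]
  aspect <- sqrt(ev$values[1] / max(ev$values[2], 1e-9))
  if (aspect < 1.25) return(NULL)
  proj <- as.vector(cc %*% u)
  # width profile along the principal axis, lightly smoothed
  nb <- 24L
  br <- seq(min(proj), max(proj), length.out = nb + 1L)
  bin <- pmin(pmax(findInterval(proj, br, rightmost.closed = TRUE), 1L), nb)
  width <- tabulate(bin, nb)
  ws <- stats::filter(width, rep(1 / 3, 3))
  ws[is.na(ws)] <- width[is.na(ws)]
  # search the central extent of the axis (not the mass quantiles: the bud
  # holds little mass, so the waist sits far into the tail of the projection)
  span <- diff(range(proj))
  mid <- which(br[-1] > min(proj) + 0.15 * span &
               br[-(nb + 1)] < max(proj) - 0.15 * span)
  mid <- mid[mid > 1 & mid < nb]
  if (length(mid) < 2) return(NULL)
  waist_bin <- mid[which.min(ws[mid])]
  waist <- ws[waist_bin]
  peak_lo <- max(ws[seq_len(waist_bin - 1L)])
  peak_hi <- max(ws[seq(waist_bin + 1L, nb)])
  if (waist >= waist_ratio * min(peak_lo, peak_hi)) return(NULL)
  neck_t <- (br[waist_bin] + br[waist_bin + 1L]) / 2
  side <- proj > neck_t
  sizes <- c(sum(!side), sum(side))
  if (min(sizes) / sum(sizes) < 0.10) return(NULL)
  bud_is_pos <- sizes[2] < sizes[1]
  bud_sel <- if (bud_is_pos) side else !side
  # a real bud is a round lobe; a bright punctum bulging past the cell rim
  # projects as a shallow cap — reject lobes much wider than they are long
  e_bud <- max(abs(proj[bud_sel] - neck_t))
  perp <- sqrt(pmax(rowSums(cc^2) - proj^2, 0))
  w_bud <- 2 * quantile(perp[bud_sel], 0.95)
  if (e_bud < 0.6 * w_bud) return(NULL)
  # mother is the larger lobe; assignment is by side of the waist plane
  assign <- ifelse(bud_sel, 2L, 1L)
  bud_dir <- if (bud_is_pos) u else -u
  list(assign = assign, mother_n = max(sizes), bud_n = min(sizes),
       neck_point = ctr + neck_t * u,
       axis = u, bud_dir = bud_dir)
}

#' Low-pass filter a stack slice by slice
#'
#' 2D Gaussian smoothing applied to every z-slice, sized so single-voxel
#' noise spikes are suppressed while punctum-scale features persist.
#' Matching the per-slice thresholding step, filtering is also per slice.
#'
#' @param stack an [image_stack].
#' @param sigma_um smoothing SD in um (default half the expected punctum
#'   radius).
#' @return filtered [image_stack] of the same shape.
#' @export
lowpass_filter <- function(stack, sigma_um = 0.1) {
  stopifnot(inherits(stack, "image_stack"), sigma_um > 0)
  sig <- sigma_um / stack$voxel_size[2:3]
  if (max(sig) < 0.3) {
    warning("filter sigma below one voxel in every axis; returning input")
    return(stack)
  }
  out <- gaussian_smooth(stack$voxels, c(0, sig))
  image_stack(out, stack$voxel_size)
}

#' Threshold each slice to define peroxisome areas
#'
#' Thresholds are computed per slice within each cell's mask (or over the
#' whole slice when no segmentation is given). `background_k_sd` uses a
#' robust background estimate — median plus `k` times the scaled MAD of the
#' in-mask intensities — so sparse bright puncta do not inflate the
#' threshold. `otsu` is applied to min-max-normalized in-mask intensities
#' (hence invariant to positive rescaling) and floored at the robust
#' background bound so slices without objects stay empty; because Otsu
#' lands near half-maximum on bimodal slices, it recovers object volumes
#' with little point-spread inflation and is the method of choice for
#' volumetry calibration. `fixed` uses `value`.
#'
#' @param filtered a low-pass-filtered [image_stack].
#' @param method `"background_k_sd"` (default), `"otsu"` or `"fixed"`.
#' @param k multiplier for `background_k_sd`.
#' @param value threshold for `"fixed"`.
#' @param cell_mask y by x integer label matrix (e.g. `seg$labels`), or NULL
#'   for the whole field.
#' @return logical array of the stack's shape.
#' @export
threshold_slices <- function(filtered, method = "background_k_sd", k = 3,
                             value = NULL, cell_mask = NULL) {
  stopifnot(inherits(filtered, "image_stack"))
  valid <- c("background_k_sd", "otsu", "fixed")
  if (!method %in% valid) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(valid, collapse = ", "))
  }
  v <- filtered$voxels
  d <- dim(v)
  if (is.null(cell_mask)) {
    cell_mask <- matrix(1L, d[2], d[3])
  }
  if (!all(dim(cell_mask) == d[2:3])) stop("cell mask does not match stack shape")
  binary <- array(FALSE, d)
  for (id in setdiff(sort(unique(as.vector(cell_mask))), 0L)) {
    region <- cell_mask == id
    for (z in seq_len(d[1])) {
      slice <- v[z, , ]
      vals <- slice[region]
      if (length(vals) == 0L) next
      thr <- switch(method,
        background_k_sd = median(vals) + k * mad(vals),
        otsu = {
          rng <- range(vals)
          if (diff(rng) == 0) Inf else {
            nv <- (vals - rng[1]) / diff(rng)
            ot <- rng[1] + EBImage::otsu(matrix(nv, nrow = 1),
                                         range = c(0, 1)) * diff(rng)
            max(ot, median(vals) + k * mad(vals))
          }
        },
        fixed = {
          if (is.null(value)) stop("method 'fixed' requires value")
          value
        })
      sel <- region & slice > thr
      if (any(sel)) {
        bz <- binary[z, , ]
        bz[sel] <- TRUE
        binary[z, , ] <- bz
      }
    }
  }
  binary
}

#' Recombine thresholded slices into 3D objects and measure volumes
#'
#' Connected components with 26-connectivity across the thresholded stack;
#' each object's volume is its voxel count times the voxel volume. Objects
#' are assigned to the cell under their centroid; if the centroid falls on
#' background the majority cell label over the object's voxels is used.
#'
#' @param binary logical array `(z, y, x)`.
#' @param seg a `cell_segmentation` (or NULL: objects unassigned, cell 0).
#' @param voxel_size `(dz, dy, dx)` um; defaults to the segmentation's.
#' @param min_voxels objects below this voxel count are discarded.
#' @param connectivity 26 (default) or 6.
#' @return tibble, one row per object: `object`, `cell`, `compartment`,
#'   centroid `(z, y, x)` in 0-based voxel coordinates, `voxel_count`,
#'   `volume_um3`, `n_slices`, `neck_dist_um` and the per-slice area trace
#'   (`slice_areas` list column).
#' @export
reconstruct_volumes <- function(binary, seg = NULL, voxel_size = NULL,
                                min_voxels = 2, connectivity = 26) {
  d <- dim(binary)
  stopifnot(length(d) == 3L)
  if (!is.null(seg)) {
    if (!all(dim(seg$labels) == d[2:3])) stop("shape mismatch between binary stack and segmentation")
    voxel_size <- voxel_size %||% seg$voxel_size
  }
  if (is.null(voxel_size)) stop("voxel_size required when seg is NULL")
  empty <- tibble(object = integer(0), cell = integer(0),
                  compartment = character(0), z = numeric(0), y = numeric(0),
                  x = numeric(0), voxel_count = integer(0),
                  volume_um3 = numeric(0), n_slices = integer(0),
                  neck_dist_um = numeric(0), slice_areas = list())
  if (!any(binary)) return(empty)
  lab <- label_components(binary, connectivity)
  idx <- which(lab > 0)
  obj <- lab[idx]
  zi <- (idx - 1L) %% d[1]
  yi <- ((idx - 1L) %/% d[1]) %% d[2]
  xi <- (idx - 1L) %/% (d[1] * d[2])
  vox_vol <- prod(voxel_size)

  rows <- lapply(split(seq_along(idx), obj), function(ii) {
    n <- length(ii)
    cz <- mean(zi[ii]); cy <- mean(yi[ii]); cx <- mean(xi[ii])
    cell <- 0L; comp <- NA_character_; neck <- NA_real_
    if (!is.null(seg) && nrow(seg$cells)) {
      cell <- seg$labels[round(cy) + 1L, round(cx) + 1L]
      vox_cells <- seg$labels[cbind(yi[ii] + 1L, xi[ii] + 1L)]
      if (cell == 0L && any(vox_cells > 0)) {
        tab <- table(vox_cells[vox_cells > 0])
        cell <- as.integer(names(tab)[which.max(tab)])
      }
      if (cell > 0L) {
        comp <- "mother"
        ci <- seg$cells[seg$cells$id == cell, ]
        if (isTRUE(ci$budded)) {
          # compartment by the signed side of the neck plane (robust to
          # erosion of the dim bud rim in the projected mask)
          p <- c(cy * voxel_size[2], cx * voxel_size[3])
          s_neck <- sum((p - c(ci$neck_y, ci$neck_x)) *
                          c(ci$neck_ny, ci$neck_nx))
          comp <- if (s_neck > 0) "bud" else "mother"
          neck <- abs(s_neck)
        }
      }
    }
    tibble(object = NA_integer_, cell = as.integer(cell), compartment = comp,
           z = cz, y = cy, x = cx, voxel_count = n,
           volume_um3 = n * vox_vol,
           n_slices = length(unique(zi[ii])),
           neck_dist_um = neck,
           slice_areas = list(table(zi[ii])))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$voxel_count >= min_voxels, , drop = FALSE]
  if (nrow(out)) out$object <- seq_len(nrow(out))
  out
}

#' Quantify puncta per cell across one or more stacks
#'
#' Runs the full chain — cell segmentation, low-pass filtering, per-slice
#' thresholding, 3D reconstruction — and aggregates per cell: punctum counts
#' (split mother/bud where the cell has one), object volumes, punctate and
#' diffuse reporter intensity (background-subtracted raw intensity inside
#' versus outside the thresholded mask), the fraction of puncta within 1 um
#' of the neck plane, and a dispersion score: the RMS distance of the
#' cell's punctate foreground voxels to their centroid, normalized by the
#' cell's equivalent radius. Being voxel-based, the score stays informative
#' when tightly packed puncta fuse into one segmented object.
#'
#' @param stacks an [image_stack] or list of them (fields of the same strain).
#' @param filter_sigma_um,threshold_method,threshold_k,min_voxels tuning of
#'   the component steps. The aggregate pipeline defaults to `k = 4` and a
#'   10-voxel size floor: low-pass filtering correlates neighbouring
#'   voxels, so background exceedances arrive in small clumps that the
#'   per-operation defaults would keep.
#' @param min_area_px,split_buds passed to [segment_cells()].
#' @return tibble with one row per segmented cell (`stack` identifies the
#'   source field); object volumes carried in the `volumes` list column.
#' @export
quantify_strain <- function(stacks, filter_sigma_um = 0.1,
                            threshold_method = "background_k_sd",
                            threshold_k = 4, min_voxels = 10,
                            min_area_px = 200, split_buds = TRUE) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (length(stacks) == 0L) stop("at least one stack is required")
  rows <- list()
  for (si in seq_along(stacks)) {
    stack <- stacks[[si]]
    stopifnot(inherits(stack, "image_stack"))
    seg <- suppressWarnings(segment_cells(stack, min_area_px = min_area_px,
                                          split_buds = split_buds))
    if (nrow(seg$cells) == 0L) next
    vs <- stack$voxel_size
    bg_px <- seg$labels == 0L
    bg <- if (any(bg_px)) {
      median(apply(stack$voxels, 1, function(s) median(s[bg_px])))
    } else 0
    filtered <- lowpass_filter(stack, filter_sigma_um)
    binary <- threshold_slices(filtered, method = threshold_method,
                               k = threshold_k, cell_mask = seg$labels)
    objects <- reconstruct_volumes(binary, seg, min_voxels = min_voxels)
    d <- dim(stack$voxels)
    for (ci in seq_len(nrow(seg$cells))) {
      cinfo <- seg$cells[ci, ]
      cell_px <- seg$labels == cinfo$id
      cell_vox <- array(rep(cell_px, each = d[1]), d)
      net <- stack$voxels - bg
      total_int <- sum(net[cell_vox])
      punct_vox <- cell_vox & binary
      punct_int <- sum(net[punct_vox])
      obj <- objects[objects$cell == cinfo$id, , drop = FALSE]
      n_bud <- sum(obj$compartment == "bud", na.rm = TRUE)
      n_mother <- sum(obj$compartment == "mother", na.rm = TRUE)
      disp <- neck_frac <- bud_int <- mother_int <- NA_real_
      fg_idx <- which(punct_vox)
      if (length(fg_idx) >= 6) {
        fz <- ((fg_idx - 1L) %% d[1]) * vs[1]
        fy <- (((fg_idx - 1L) %/% d[1]) %% d[2]) * vs[2]
        fx <- ((fg_idx - 1L) %/% (d[1] * d[2])) * vs[3]
        pts <- cbind(fz, fy, fx)
        ctr <- colMeans(pts)
        r_eq <- sqrt(cinfo$area_px * vs[2] * vs[3] / pi)
        disp <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2))) / r_eq
        if (cinfo$budded) {
          # intensity-weighted, voxel-level mother/bud split: robust to
          # object merging and to centroid flips near the neck plane
          w <- pmax(net[fg_idx], 0)
          s_neck <- (fy - cinfo$neck_y) * cinfo$neck_ny +
            (fx - cinfo$neck_x) * cinfo$neck_nx
          tot_w <- sum(w)
          if (tot_w > 0) {
            bud_int <- sum(w[s_neck > 0])
            mother_int <- tot_w - bud_int
            neck_frac <- sum(w[abs(s_neck) <= 1]) / tot_w
          }
        }
      }
      rows[[length(rows) + 1L]] <- tibble(
        stack = si, cell = cinfo$id, budded = cinfo$budded,
        ambiguous = cinfo$ambiguous,
        area_px = cinfo$area_px,
        mother_area_um2 = cinfo$mother_area_px * vs[2] * vs[3],
        bud_area_um2 = if (cinfo$budded) cinfo$bud_area_px * vs[2] * vs[3] else NA_real_,
        n_puncta = nrow(obj), n_mother = n_mother, n_bud = n_bud,
        bud_intensity = bud_int, mother_intensity = mother_int,
        neck_fraction = neck_frac,
        total_intensity = total_int, punctate_intensity = punct_int,
        dispersion = disp,
        volumes = list(obj$volume_um3))
    }
  }
  if (length(rows) == 0L) {
    return(tibble(stack = integer(0), cell = integer(0), budded = logical(0),
                  ambiguous = logical(0), area_px = integer(0),
                  mother_area_um2 = numeric(0), bud_area_um2 = numeric(0),
                  n_puncta = integer(0), n_mother = integer(0),
                  n_bud = integer(0), bud_intensity = numeric(0),
                  mother_intensity = numeric(0), neck_fraction = numeric(0),
                  total_intensity = numeric(0),
                  punctate_intensity = numeric(0), dispersion = numeric(0),
                  volumes = list()))
  }
  dplyr::bind_rows(rows)
}
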