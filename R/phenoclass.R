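# Strain-level phenotype calls from per-cell quantification. The screen's
# categories were assigned by eye; these functions are an explicit numeric
# operationalization, with every cutoff exposed in the config.

#' Phenotype-classification configuration
#'
#' @param mislocalized_max strain is `mislocalized` when the median punctate
#'   fraction falls below this.
#' @param partial_max `partial_mislocalized` when the median punctate
#'   fraction lies in `[mislocalized_max, partial_max)`; `normal` at or above.
#' @param inherit_index,neck_fraction `inheritance_defect` when the median
#'   mother/bud density contrast exceeds `inherit_index` AND the median
#'   fraction of punctate intensity within 1 um of the neck exceeds
#'   `neck_fraction` — the phenotype couples neck clustering with a paucity
#'   of signal in mothers, and the conjunction keeps strains with a few
#'   giant puncta (which can leak intensity across the neck plane) from
#'   being miscalled.
#' @param size_ratio small/large calls need the median volume ratio to
#'   deviate from 1 by at least this factor.
#' @param size_alpha ... and the rank-sum test significant at this level.
#' @param cluster_dispersion `clustered` when the median dispersion score
#'   falls below this.
#' @param low_expr_z `low_expression` needs a flow z at or below this.
#' @param low_expr_signal_frac ... and a median punctate intensity below
#'   this fraction of the wild-type median (too little signal to segment).
#' @param min_cells minimum analyzable cells for image-based calls.
#' @param min_budded minimum budded cells to assess inheritance.
#' @param min_objects minimum objects per group for the size test.
#' @return config list.
#' @export
pheno_config <- function(mislocalized_max = 0.2, partial_max = 0.5,
                         inherit_index = 0.2, neck_fraction = 0.45,
                         size_ratio = 1.5, size_alpha = 0.01,
                         cluster_dispersion = 0.48, low_expr_z = -2,
                         low_expr_signal_frac = 0.15,
                         min_cells = 5, min_budded = 5, min_objects = 20) {
  as.list(environment())
}

#' Punctate fraction of the reporter signal
#'
#' Fraction of a cell's (background-subtracted) reporter intensity that lies
#' inside the thresholded punctum mask. Cells with non-positive total
#' intensity are undefined (NA) and excluded from strain calls.
#'
#' @param punctate,total per-cell punctate and total in-cell intensity.
#' @return numeric in `[0, 1]` (clamped), NA where total <= 0.
#' @export
punctate_fraction <- function(punctate, total) {
  out <- ifelse(total > 0, pmin(pmax(punctate / total, 0), 1), NA_real_)
  if (anyNA(out)) message(sum(is.na(out)), " cells with zero total intensity excluded")
  out
}

#' Mother/bud inheritance index
#'
#' Per budded cell with punctate signal, the density contrast
#' `(bud density - mother density) / (bud density + mother density)` with
#' density = punctate reporter intensity per projected compartment area:
#' +1 when all punctate signal sits in the bud, -1 when all sits in the
#' mother. Intensity on either side of the neck plane (rather than object
#' counts) keeps the index stable when clustered puncta fuse into one
#' segmented object; projected area is what the 2D mother/bud split
#' measures directly. The neck clustering score is the fraction of
#' punctate intensity within 1 um of the neck plane.
#'
#' @param cells per-cell table from [quantify_strain()].
#' @param config a [pheno_config()].
#' @return list: `call` ("defect", "normal" or "not_assessable"),
#'   `median_index`, `median_neck_fraction`, `n_budded`, per-cell `index`.
#' @export
inheritance_index <- function(cells, config = pheno_config()) {
  b <- cells[cells$budded & !is.na(cells$bud_intensity) &
               !is.na(cells$bud_area_um2), , drop = FALSE]
  if (nrow(b) < config$min_budded) {
    return(list(call = "not_assessable", median_index = NA_real_,
                median_neck_fraction = NA_real_, n_budded = nrow(b),
                index = numeric(0)))
  }
  db <- b$bud_intensity / b$bud_area_um2
  dm <- b$mother_intensity / b$mother_area_um2
  idx <- ifelse(db + dm > 0, (db - dm) / (db + dm), NA_real_)
  med_idx <- median(idx, na.rm = TRUE)
  med_neck <- median(b$neck_fraction, na.rm = TRUE)
  call <- if (!is.na(med_idx) && med_idx > config$inherit_index &&
              !is.na(med_neck) && med_neck > config$neck_fraction) {
    "defect"
  } else "normal"
  list(call = call, median_index = med_idx, median_neck_fraction = med_neck,
       n_budded = nrow(b), index = idx)
}

#' Size phenotype versus wild type
#'
#' Compares object volume distributions by Wilcoxon rank-sum; the call is
#' `small`/`large` only when the median ratio deviates from 1 by the config
#' factor and the test is significant. Effect size is the log2 median ratio.
#'
#' @param strain_volumes,wt_volumes object volumes (um^3).
#' @param config a [pheno_config()].
#' @param alpha significance level override (used for batch BH adjustment).
#' @return list: `call`, `log2_ratio`, `p_value`, `n_strain`, `n_wt`.
#' @export
size_phenotype <- function(strain_volumes, wt_volumes,
                           config = pheno_config(), alpha = NULL) {
  strain_volumes <- strain_volumes[is.finite(strain_volumes) & strain_volumes > 0]
  wt_volumes <- wt_volumes[is.finite(wt_volumes) & wt_volumes > 0]
  if (length(strain_volumes) < config$min_objects ||
      length(wt_volumes) < config$min_objects) {
    return(list(call = "not_assessable", log2_ratio = NA_real_,
                p_value = NA_real_, n_strain = length(strain_volumes),
                n_wt = length(wt_volumes)))
  }
  ratio <- median(strain_volumes) / median(wt_volumes)
  p <- suppressWarnings(wilcox.test(strain_volumes, wt_volumes)$p.value)
  alpha <- alpha %||% config$size_alpha
  call <- if (p < alpha && ratio <= 1 / config$size_ratio) "small"
    else if (p < alpha && ratio >= config$size_ratio) "large"
    else "normal"
  list(call = call, log2_ratio = log2(ratio), p_value = p,
       n_strain = length(strain_volumes), n_wt = length(wt_volumes))
}

#' Classify one strain
#'
#' Applies the screen's category precedence: expression loss detected by flow
#' (z at or below the cutoff with too little punctate signal to segment),
#' then mislocalization (full, then partial), inheritance defects, size
#' phenotypes, clustering, and finally normal. Confidence is the fraction of
#' cells supporting the winning call.
#'
#' @param cells per-cell table from [quantify_strain()].
#' @param wt_cells wild-type reference per-cell table (for size comparison).
#' @param flow_z optional flow-cytometry z-score of the strain.
#' @param config a [pheno_config()].
#' @param size_alpha optional per-strain significance level (BH-adjusted in
#'   batch classification).
#' @return one-row tibble: `category`, `score` (the category's statistic),
#'   `n_cells`, `confidence`, `flow_z`.
#' @export
classify_strain <- function(cells, wt_cells, flow_z = NULL,
                            config = pheno_config(), size_alpha = NULL) {
  cells <- cells[cells$total_intensity > 0, , drop = FALSE]
  n_cells <- nrow(cells)
  if (n_cells == 0L && is.null(flow_z)) stop("no data: no analyzable cells and no flow score")

  result <- function(category, score, confidence) {
    tibble(category = category, score = score, n_cells = n_cells,
           confidence = min(max(confidence, 0), 1),
           flow_z = flow_z %||% NA_real_)
  }

  wt_punct <- median(wt_cells$punctate_intensity)
  med_punct <- if (n_cells) median(cells$punctate_intensity) else 0
  if (!is.null(flow_z) && flow_z <= config$low_expr_z &&
      (n_cells < config$min_cells ||
         med_punct < config$low_expr_signal_frac * wt_punct)) {
    conf <- if (n_cells) {
      mean(cells$punctate_intensity < config$low_expr_signal_frac * wt_punct)
    } else 1
    return(result("low_expression", flow_z, conf))
  }
  if (n_cells < config$min_cells) {
    stop("no data: fewer than ", config$min_cells,
         " analyzable cells and no deficient flow score")
  }

  frac <- suppressMessages(
    punctate_fraction(cells$punctate_intensity, cells$total_intensity))
  med_frac <- median(frac, na.rm = TRUE)
  if (!is.na(med_frac) && med_frac < config$mislocalized_max) {
    return(result("mislocalized", med_frac, mean(frac < config$mislocalized_max,
                                                 na.rm = TRUE)))
  }
  if (!is.na(med_frac) && med_frac < config$partial_max) {
    return(result("partial_mislocalized", med_frac,
                  mean(frac < config$partial_max, na.rm = TRUE)))
  }

  inh <- inheritance_index(cells, config)
  if (inh$call == "defect") {
    return(result("inheritance_defect", inh$median_index,
                  mean(inh$index > config$inherit_index, na.rm = TRUE)))
  }

  disp <- cells$dispersion[!is.na(cells$dispersion)]
  clustered_signal <- length(disp) >= config$min_cells / 2 &&
    median(disp) < config$cluster_dispersion

  # apparent object volumes are meaningless when puncta are fused into
  # clusters, so the size comparison only runs on dispersed strains
  sz <- if (clustered_signal) {
    list(call = "not_assessable")
  } else {
    size_phenotype(unlist(cells$volumes), unlist(wt_cells$volumes),
                   config, alpha = size_alpha)
  }
  if (sz$call %in% c("small", "large")) {
    wt_med <- median(unlist(wt_cells$volumes))
    med_vol <- vapply(cells$volumes, function(v) {
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    support <- if (sz$call == "small") mean(med_vol < wt_med, na.rm = TRUE)
      else mean(med_vol > wt_med, na.rm = TRUE)
    return(result(sz$call, sz$log2_ratio, support))
  }

  if (clustered_signal) {
    return(result("clustered", median(disp),
                  mean(disp < config$cluster_dispersion)))
  }

  result("normal", med_frac, mean(frac >= config$partial_max, na.rm = TRUE))
}

#' Classify a batch of strains with BH-adjusted size tests
#'
#' When 20 or more strains are classified together, the size-phenotype
#' rank-sum p-values are Benjamini-Hochberg adjusted across strains (FDR
#' 0.05) before small/large calls are made — the genome-scale screening
#' correction.
#'
#' @param quants named list of per-cell tables (one per strain).
#' @param wt_cells wild-type reference per-cell table.
#' @param flow_z named numeric of flow z-scores (optional entries).
#' @param config a [pheno_config()].
#' @return tibble with one row per strain.
#' @export
classify_panel <- function(quants, wt_cells, flow_z = NULL,
                           config = pheno_config()) {
  strains <- names(quants) %||% as.character(seq_along(quants))
  wt_vols <- unlist(wt_cells$volumes)
  p_size <- vapply(quants, function(q) {
    size_phenotype(unlist(q$volumes), wt_vols, config)$p_value
  }, numeric(1))
  alpha <- rep(config$size_alpha, length(quants))
  if (length(quants) >= 20) {
    adj <- p.adjust(p_size, method = "BH")
    # encode the BH decision as a per-strain alpha: rejected strains get an
    # alpha just above their own p, others can never reach significance
    reject <- !is.na(adj) & adj <= 0.05
    alpha[!is.na(p_size)] <- 1e-300
    alpha[reject] <- p_size[reject] * (1 + 1e-9) + 1e-300
  }
  rows <- lapply(seq_along(quants), function(i) {
    fz <- if (!is.null(flow_z) && strains[i] %in% names(flow_z)) {
      flow_z[[strains[i]]]
    } else NULL
    out <- classify_strain(quants[[i]], wt_cells, flow_z = fz, config = config,
                           size_alpha = max(alpha[i], 1e-300))
    out$strain <- strains[i]
    out
  })
  dplyr::bind_rows(rows)[, c("strain", "category", "score", "n_cells",
                             "confidence", "flow_z")]
}
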