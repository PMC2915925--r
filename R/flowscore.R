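# Flow-cytometry scoring: regression correction for cell size/granularity,
# plate-to-plate quantile normalization, z-scores against a reference, and
# threshold hit calling.

#' Remove cell-size and granularity effects from fluorescence
#'
#' Fits `log10(FL1 + delta) ~ log10(FSC) + log10(SSC)` by least squares over
#' the wild-type reference events of each plate, then reports every event's
#' residual re-anchored at the fit's prediction for the reference-population
#' mean covariates. This removes the first-order dependence of fluorescence
#' on cell size (forward scatter) and granularity (side scatter) and reduces
#' the coefficient of variation of the wild-type population.
#'
#' Events with non-positive FSC or SSC are dropped (count reported). Plates
#' whose reference events have degenerate scatter (zero variance) fall back
#' to no correction for that plate, with a warning.
#'
#' @param events flow event table (`plate`, `well`, `strain`, `FSC`, `SSC`,
#'   `FL1`).
#' @param wt_label strain label(s) of the wild-type reference.
#' @param delta offset added to FL1 before log10 (admits zero-fluorescence
#'   events).
#' @param min_events_per_well wells below this event count trigger a warning.
#' @return the event table with an added `corrected_log10_fl` column.
#' @export
correct_scatter <- function(events, wt_label = "WT", delta = 1,
                            min_events_per_well = 30) {
  stopifnot(all(c("plate", "well", "strain", "FSC", "SSC", "FL1") %in%
                  names(events)))
  bad <- events$FSC <= 0 | events$SSC <= 0
  if (any(bad)) {
    message(sum(bad), " events with non-positive scatter dropped")
    events <- events[!bad, , drop = FALSE]
  }
  if (!any(events$FL1 > 0)) stop("all FL1 values are zero")
  counts <- table(paste(events$plate, events$well))
  if (any(counts < min_events_per_well)) {
    warning(sum(counts < min_events_per_well), " wells have fewer than ",
            min_events_per_well, " events")
  }
  events <- as_tibble(events)
  events$.lfl <- log10(events$FL1 + delta)
  events$.lfsc <- log10(events$FSC)
  events$.lssc <- log10(events$SSC)

  out <- lapply(split(events, events$plate), function(pl) {
    ref <- pl[pl$strain %in% wt_label, , drop = FALSE]
    if (nrow(ref) == 0L) {
      warning("plate ", pl$plate[1],
              ": no wild-type reference events; fitting on all events")
      ref <- pl
    }
    if (var(ref$.lfsc) == 0 || var(ref$.lssc) == 0) {
      warning("plate ", pl$plate[1],
              ": degenerate scatter covariates; mean-only correction")
      pl$corrected_log10_fl <- pl$.lfl
      return(pl)
    }
    fit <- lm(.lfl ~ .lfsc + .lssc, data = ref)
    b <- coef(fit)
    pl$corrected_log10_fl <- pl$.lfl -
      b[".lfsc"] * (pl$.lfsc - mean(ref$.lfsc)) -
      b[".lssc"] * (pl$.lssc - mean(ref$.lssc))
    pl
  })
  out <- dplyr::bind_rows(out)
  out$.lfl <- out$.lfsc <- out$.lssc <- NULL
  out
}

#' Summarize corrected events per well
#'
#' @param events output of [correct_scatter()].
#' @param stat `"mean"` (default, the screen's well statistic) or `"median"`.
#' @return tibble: `plate`, `well`, `strain`, `n_events`, `well_mean`.
#' @export
summarize_wells <- function(events, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot("corrected_log10_fl" %in% names(events))
  f <- if (stat == "mean") mean else median
  events |>
    dplyr::group_by(.data$plate, .data$well, .data$strain) |>
    dplyr::summarise(n_events = dplyr::n(),
                     well_mean = f(.data$corrected_log10_fl),
                     .groups = "drop")
}

#' Quantile-normalize per-well means across plates
#'
#' Forces every plate's (column's) empirical distribution onto the common
#' row-wise mean of the column-sorted matrix, preserving within-plate ranks;
#' tied ranks receive the mean of their target quantiles.
#'
#' @param mat numeric matrix, wells x plates. Missing cells are imputed with
#'   the plate median first (reported).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) <= 1L) return(mat)
  if (anyNA(mat)) {
    message(sum(is.na(mat)), " missing cells imputed with plate medians")
    for (j in seq_len(ncol(mat))) {
      mat[is.na(mat[, j]), j] <- median(mat[, j], na.rm = TRUE)
    }
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Score strains as standard scores against a reference
#'
#' `z = (strain mean - reference location) / reference scale`. With
#' `reference = "wt"` the location/scale are the mean and SD of the wild-type
#' well means (the spread of replicate reference wells). With
#' `reference = "population"` they are the robust location/scale (median and
#' scaled MAD) of all strain means — appropriate when strain-to-strain
#' biological variation, not well noise, defines the null.
#'
#' @param summaries tibble with `strain` and `well_mean` (one row per well;
#'   replicate wells of a strain are averaged).
#' @param wt_label wild-type strain label(s).
#' @param reference `"wt"` or `"population"`.
#' @param timepoint hours of oleate induction, carried into the output.
#' @param exclude strains excluded from scoring (e.g. the non-fluorescent
#'   control); they still appear in the input but get no score row.
#' @return tibble of per-strain scores: `strain`, `timepoint`,
#'   `mean_log10_fl`, `pct_of_wt`, `z`.
#' @export
zscore_strains <- function(summaries, wt_label = "WT",
                           reference = c("wt", "population"),
                           timepoint = NA_real_,
                           exclude = "BY4741") {
  reference <- match.arg(reference)
  stopifnot(all(c("strain", "well_mean") %in% names(summaries)))
  summaries <- summaries[!summaries$strain %in% exclude, , drop = FALSE]
  per_strain <- summaries |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(mean_log10_fl = mean(.data$well_mean), .groups = "drop")

  wt_wells <- summaries$well_mean[summaries$strain %in% wt_label]
  if (reference == "wt") {
    if (length(wt_wells) < 2) stop("need at least two wild-type reference wells")
    loc <- mean(wt_wells)
    scl <- sd(wt_wells)
  } else {
    # robust location/scale of the strain population, with one trimming
    # pass so a handful of strong hits does not inflate the null scale
    x <- per_strain$mean_log10_fl
    loc <- median(x)
    scl <- mad(x)
    if (scl > 0) {
      keep <- abs(x - loc) / scl <= 3
      if (sum(keep) >= 5) {
        loc <- median(x[keep])
        scl <- mad(x[keep])
      }
    }
  }
  if (scl == 0) stop("degenerate reference")
  wt_mean <- if (length(wt_wells)) mean(wt_wells) else loc
  per_strain |>
    dplyr::mutate(timepoint = timepoint,
                  pct_of_wt = 100 * 10^(.data$mean_log10_fl - wt_mean),
                  z = (.data$mean_log10_fl - loc) / scl) |>
    dplyr::select("strain", "timepoint", "mean_log10_fl", "pct_of_wt", "z")
}

#' Call low-fluorescence hits at an SD threshold
#'
#' Returns strains whose z-score is at or below `-threshold_sd` (the boundary
#' is inclusive), sorted most-deficient first. The screen's defaults are
#' 1.45 SD at 6 h of induction and 2 SD at 24 h.
#'
#' @param scores output of [zscore_strains()].
#' @param timepoint used to pick the default threshold when `threshold_sd`
#'   is NULL (6 -> 1.45, 24 -> 2).
#' @param threshold_sd positive threshold in SD units, or `"auto"` to derive
#'   it from the natural separation of the sub-wild-type tail
#'   (see [find_natural_separation()]).
#' @param exclude strain labels never reported as hits (reference strains).
#' @return tibble of hit strains, ascending in z.
#' @export
call_hits <- function(scores, timepoint = NULL, threshold_sd = NULL,
                      exclude = c("WT", "BY4741")) {
  if (is.null(threshold_sd)) {
    tp <- timepoint %||% scores$timepoint[1]
    threshold_sd <- if (!is.null(tp) && !is.na(tp) && tp >= 24) 2.0 else 1.45
  } else if (identical(threshold_sd, "auto")) {
    threshold_sd <- find_natural_separation(scores$z)
  }
  stopifnot(is.numeric(threshold_sd), threshold_sd > 0)
  hits <- scores[scores$z <= -threshold_sd & !scores$strain %in% exclude, ,
                 drop = FALSE]
  hits <- hits[order(hits$z), , drop = FALSE]
  attr(hits, "threshold_sd") <- threshold_sd
  hits
}

#' Find the natural separation in the sub-wild-type tail
#'
#' Scans the order statistics of z-scores below -1 for the largest gap
#' between consecutive values and returns the (positive) midpoint of that
#' gap as the SD threshold. Ties are broken toward the more negative gap.
#'
#' @param z numeric z-scores (at least 5).
#' @param default threshold returned (with a warning) when no value lies
#'   below -1.
#' @return positive threshold in SD units.
#' @export
find_natural_separation <- function(z, default = 1.45) {
  if (length(z) < 5) stop("need at least 5 z values")
  tail_z <- sort(z[z < -1], decreasing = TRUE)   # boundary-nearest first
  if (length(tail_z) == 0L) {
    warning("no z value below -1; returning default threshold ", default)
    return(default)
  }
  if (length(tail_z) == 1L) return(abs(tail_z))
  gaps <- tail_z[-length(tail_z)] - tail_z[-1]
  # ties (to floating-point tolerance) break toward the most negative gap
  i <- max(which(gaps >= max(gaps) - 1e-9))
  -(tail_z[i] + tail_z[i + 1]) / 2
}

#' Score a flow-event table end to end
#'
#' Runs scatter correction, per-well summaries, cross-plate quantile
#' normalization (when more than one plate is present) and z-scoring.
#'
#' @param events raw flow event table.
#' @param wt_label,reference,timepoint,exclude passed to the component steps.
#' @param stat per-well statistic (see [summarize_wells()]).
#' @return tibble of per-strain scores (see [zscore_strains()]).
#' @export
flow_score_pipeline <- function(events, wt_label = "WT",
                                reference = c("wt", "population"),
                                timepoint = NA_real_, stat = "mean",
                                exclude = "BY4741") {
  corrected <- correct_scatter(events, wt_label = wt_label)
  wells <- summarize_wells(corrected, stat = stat)
  plates <- unique(wells$plate)
  if (length(plates) > 1L) {
    wide <- lapply(plates, function(p) {
      w <- wells[wells$plate == p, ]
      setNames(w$well_mean, w$well)
    })
    common <- Reduce(intersect, lapply(wide, names))
    mat <- sapply(wide, function(v) v[common])
    colnames(mat) <- plates
    norm <- quantile_normalize(mat)
    for (p in plates) {
      sel <- wells$plate == p & wells$well %in% common
      wells$well_mean[sel] <- norm[match(wells$well[sel], common), p]
    }
  }
  zscore_strains(wells, wt_label = wt_label, reference = reference,
                 timepoint = timepoint, exclude = exclude)
}
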