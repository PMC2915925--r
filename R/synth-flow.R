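# Synthetic flow-cytometry event tables. The generative model is the inverse
# of the scoring model: log10 fluorescence is a linear function of log10
# forward/side scatter (cell size and granularity) plus a strain effect, a
# plate effect, and Gaussian residual noise; scatter itself is log-normal.

#' Configuration for the flow-event simulator
#'
#' Each event's fluorescence follows
#' `log10(FL1) = wt_log10_fl + strain_effect + plate_shift +
#'  b_fsc * (log10 FSC - mu_FSC) + b_ssc * (log10 SSC - mu_SSC) + eps`,
#' with `eps ~ N(0, noise_sd)` and FSC/SSC log-normal. Scatter covariates are
#' centred at their population means so `wt_log10_fl` is the wild-type mean
#' log10 fluorescence. Strains without a listed effect receive a small
#' biological effect drawn once per strain from `N(0, null_effect_sd)` —
#' gene deletions perturb reporter expression slightly even when they are not
#' hits, and this strain-to-strain spread is the natural null scale of the
#' screen.
#'
#' @param n_events_per_well events recorded per well (>= 1).
#' @param wt_log10_fl wild-type mean log10 fluorescence (arbitrary units).
#' @param strain_effect named numeric: additive log10 shift per strain
#'   (0 for wild type; unlisted strains draw from the null distribution).
#' @param null_effect_sd SD of the per-strain biological effect for unlisted
#'   strains (0 disables it).
#' @param scatter_coupling length-2 `(b_fsc, b_ssc)` coefficients.
#' @param plate_shift named numeric: additive per-plate log10 offset.
#' @param noise_sd residual event-level SD in log10 units (>= 0).
#' @param fsc_log10_mean,fsc_log10_sd,ssc_log10_mean,ssc_log10_sd log10
#'   scatter distribution parameters.
#' @param wt_label strain label treated as the wild-type reporter reference.
#' @param control_label label of the non-fluorescent control strain.
#' @param control_log10_fl mean log10 autofluorescence of the non-fluorescent
#'   control.
#' @param seed integer; output is bit-identical under a fixed seed.
#' @return config list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events_per_well = 5000L,
                            wt_log10_fl = 2.0,
                            strain_effect = c(),
                            null_effect_sd = 0.1,
                            scatter_coupling = c(b_fsc = 0.8, b_ssc = 0.3),
                            plate_shift = c(),
                            noise_sd = 0.15,
                            fsc_log10_mean = 2.3, fsc_log10_sd = 0.12,
                            ssc_log10_mean = 1.9, ssc_log10_sd = 0.15,
                            wt_label = "WT",
                            control_label = "BY4741",
                            control_log10_fl = 0.5,
                            seed = 1L) {
  stopifnot(n_events_per_well >= 1, noise_sd >= 0, null_effect_sd >= 0,
            fsc_log10_sd >= 0, ssc_log10_sd >= 0,
            length(scatter_coupling) == 2L)
  structure(list(
    n_events_per_well = as.integer(n_events_per_well),
    wt_log10_fl = wt_log10_fl, strain_effect = strain_effect,
    null_effect_sd = null_effect_sd,
    scatter_coupling = as.numeric(scatter_coupling),
    plate_shift = plate_shift, noise_sd = noise_sd,
    fsc_log10_mean = fsc_log10_mean, fsc_log10_sd = fsc_log10_sd,
    ssc_log10_mean = ssc_log10_mean, ssc_log10_sd = ssc_log10_sd,
    wt_label = wt_label, control_label = control_label,
    control_log10_fl = control_log10_fl,
    seed = as.integer(seed)
  ), class = "flow_sim_config")
}

#' Simulate a plate (or several) of flow-cytometry events
#'
#' @param config a [flow_sim_config()].
#' @param layout data frame with columns `well`, `strain` and optionally
#'   `plate` (default a single plate `"P1"`); wells must be unique within a
#'   plate.
#' @return tibble with one row per event: `plate`, `well`, `strain`, `FSC`,
#'   `SSC`, `FL1` (all linear scale).
#' @export
simulate_flow_plate <- function(config, layout) {
  stopifnot(inherits(config, "flow_sim_config"))
  layout <- as.data.frame(layout)
  if (nrow(layout) == 0L) stop("no wells")
  if (is.null(layout$plate)) layout$plate <- "P1"
  stopifnot(all(c("well", "strain") %in% names(layout)))
  if (anyDuplicated(paste(layout$plate, layout$well))) {
    stop("layout wells must be unique within a plate")
  }

  withr::with_seed(config$seed, {
    strains <- sort(unique(as.character(layout$strain)))
    eff <- setNames(numeric(length(strains)), strains)
    drawn <- rnorm(length(strains), 0, config$null_effect_sd)
    listed <- names(config$strain_effect)
    for (i in seq_along(strains)) {
      s <- strains[i]
      eff[s] <- if (s %in% listed) config$strain_effect[[s]]
        else if (s %in% c(config$wt_label, config$control_label)) 0
        else drawn[i]
    }

    n <- config$n_events_per_well
    res <- lapply(seq_len(nrow(layout)), function(i) {
      strain <- as.character(layout$strain[i])
      plate <- as.character(layout$plate[i])
      lfsc <- rnorm(n, config$fsc_log10_mean, config$fsc_log10_sd)
      lssc <- rnorm(n, config$ssc_log10_mean, config$ssc_log10_sd)
      base <- if (strain == config$control_label) config$control_log10_fl
        else config$wt_log10_fl
      pshift <- if (plate %in% names(config$plate_shift)) {
        config$plate_shift[[plate]]
      } else 0
      lfl <- base + eff[strain] + pshift +
        config$scatter_coupling[1] * (lfsc - config$fsc_log10_mean) +
        config$scatter_coupling[2] * (lssc - config$ssc_log10_mean)
      if (config$noise_sd > 0) lfl <- lfl + rnorm(n, 0, config$noise_sd)
      tibble(plate = plate, well = as.character(layout$well[i]),
             strain = strain, FSC = 10^lfsc, SSC = 10^lssc, FL1 = 10^lfl)
    })
    dplyr::bind_rows(res)
  })
}

#' Build a standard 96-well screening layout
#'
#' Strains are laid out row-major across wells A01..H12; the wild-type
#' reference and the non-fluorescent control occupy the requested number of
#' wells at the start of each plate.
#'
#' @param strains character vector of deletion-strain labels.
#' @param n_wt wild-type reference wells per plate.
#' @param n_control non-fluorescent control wells per plate.
#' @param wt_label,control_label labels used for the reference wells.
#' @param plate plate identifier.
#' @return tibble with `plate`, `well`, `strain`.
#' @export
plate_layout <- function(strains, n_wt = 4, n_control = 1,
                         wt_label = "WT", control_label = "BY4741",
                         plate = "P1") {
  labels <- c(rep(wt_label, n_wt), rep(control_label, n_control),
              as.character(strains))
  if (length(labels) > 96) stop("more than 96 wells requested")
  wells <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", 1:12))
  tibble(plate = plate, well = wells[seq_along(labels)], strain = labels)
}
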