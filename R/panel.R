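# End-to-end phenotype panel: simulate strains of every phenotype preset
# (imaging stacks plus a flow plate), quantify, and classify, returning the
# confusion between preset and call. This is the screen's synthetic
# ground-truth benchmark.

#' Simulate and classify a multi-preset strain panel
#'
#' For each preset, `n_per_preset` strains are simulated as
#' `stacks_per_strain` confocal fields. Flow z-scores come from a simulated
#' screen plate scored with the full flow pipeline (population reference):
#' `low_expression` strains carry a strong negative expression effect, all
#' others draw from the null strain-effect distribution. Wild-type reference
#' cells for the size comparison come from dedicated wild-type replicates.
#'
#' @param n_per_preset strains per preset.
#' @param presets phenotype presets to include (default: all eight).
#' @param stacks_per_strain confocal fields per strain.
#' @param n_wt_ref wild-type reference strains imaged for the size baseline.
#' @param seed master seed; every simulated object derives its own seed
#'   from it.
#' @param stack_args named list of overrides passed to [stack_sim_config()].
#' @param config a [pheno_config()].
#' @return list: `calls` (tibble strain/preset/category/...), `accuracy`,
#'   `recall` (named per preset), `confusion` (table).
#' @export
run_phenotype_panel <- function(n_per_preset = 20,
                                presets = PHENOTYPE_PRESETS,
                                stacks_per_strain = 4,
                                n_wt_ref = 4,
                                seed = 1L,
                                stack_args = list(),
                                config = pheno_config()) {
  presets <- match.arg(presets, PHENOTYPE_PRESETS, several.ok = TRUE)
  grid <- expand.grid(rep = seq_len(n_per_preset), preset = presets,
                      stringsAsFactors = FALSE)
  grid$strain <- sprintf("%s_%02d", grid$preset, grid$rep)

  quantify_preset <- function(preset, strain_seed) {
    stacks <- lapply(seq_len(stacks_per_strain), function(k) {
      cfg <- do.call(stack_sim_config, c(
        list(phenotype_preset = preset,
             seed = child_seed(strain_seed, k)),
        stack_args))
      simulate_stack(cfg)$stack
    })
    suppressMessages(quantify_strain(stacks))
  }

  # flow plate: low-expression strains are true expression hits
  eff <- setNames(rep(-0.45, sum(grid$preset == "low_expression")),
                  grid$strain[grid$preset == "low_expression"])
  fcfg <- flow_sim_config(n_events_per_well = 1000,
                          strain_effect = eff,
                          seed = child_seed(seed, 991))
  layouts <- split(grid$strain, ceiling(seq_len(nrow(grid)) / 90))
  flow_scores <- dplyr::bind_rows(lapply(seq_along(layouts), function(i) {
    lay <- plate_layout(layouts[[i]], n_wt = 4, n_control = 1,
                        plate = sprintf("P%02d", i))
    ev <- simulate_flow_plate(fcfg, lay)
    suppressMessages(flow_score_pipeline(ev, reference = "population"))
  }))
  flow_z <- setNames(flow_scores$z, flow_scores$strain)

  wt_cells <- dplyr::bind_rows(lapply(seq_len(n_wt_ref), function(i) {
    quantify_preset("wildtype", child_seed(seed, 7000 + i))
  }))

  quants <- lapply(seq_len(nrow(grid)), function(i) {
    quantify_preset(grid$preset[i], child_seed(seed, i))
  })
  names(quants) <- grid$strain

  calls <- classify_panel(quants, wt_cells, flow_z = flow_z, config = config)
  calls$preset <- grid$preset[match(calls$strain, grid$strain)]
  calls$expected <- ifelse(calls$preset == "wildtype", "normal", calls$preset)
  calls$correct <- calls$category == calls$expected

  recall <- tapply(calls$correct, calls$preset, mean)
  list(calls = as_tibble(calls),
       accuracy = mean(calls$correct),
       recall = recall,
       confusion = table(preset = calls$preset, call = calls$category))
}
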