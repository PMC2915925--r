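#!/usr/bin/env Rscript

# Score the simulated flow plates: scatter regression correction, per-well
# summaries, cross-plate quantile normalization, z-scores against the strain
# population, and hit calling at the screen's thresholds (1.45 SD at 6 h,
# 2 SD at 24 h, plus the data-driven natural-separation threshold).

library(peroxiscreen)

dir.create("results/flow", showWarnings = FALSE, recursive = TRUE)

for (tp in c(6, 24)) {
  files <- list.files("results/sim", sprintf("flow_%02dh_", tp),
                      full.names = TRUE)
  stopifnot(length(files) > 0)
  events <- dplyr::bind_rows(lapply(files, read_flow_events))
  scores <- flow_score_pipeline(events, reference = "population",
                                timepoint = tp)
  write_tsv_table(scores, sprintf("results/flow/scores_%02dh.tsv", tp))

  hits <- call_hits(scores, timepoint = tp)
  write_tsv_table(hits, sprintf("results/flow/hits_%02dh.tsv", tp))
  auto <- find_natural_separation(scores$z)
  message(sprintf(
    "%2d h: %d strains scored, %d hits at %.2f SD (natural separation %.2f SD)",
    tp, nrow(scores), nrow(hits), attr(hits, "threshold_sd"), auto))
  message("  strongest deficits: ",
          paste(sprintf("%s (z=%.1f, %.0f%% of WT)", head(hits$strain, 3),
                        head(hits$z, 3), head(hits$pct_of_wt, 3)),
                collapse = ", "))
}
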