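#!/usr/bin/env Rscript

# Simulate the raw materials of the screen: flow-cytometry plates at 6 h and
# 24 h of oleate induction (with planted expression hits), confocal stacks
# for a strain panel, and a toy multi-study hit catalog with annotations and
# interactions. Everything is written under results/sim/.

library(peroxiscreen)

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
set.seed(1)

strains <- sprintf("YDL%03dW", 1:170)
hits6 <- setNames(rep(-0.25, 6), sample(strains, 6))    # ~ -2.5 SD at 6 h
hits24 <- setNames(rep(-0.32, 5), sample(setdiff(strains, names(hits6)), 5))

for (tp in c(6, 24)) {
  eff <- if (tp == 6) hits6 else c(hits6 * 0.6, hits24)
  plates <- split(strains, ceiling(seq_along(strains) / 85))
  for (p in seq_along(plates)) {
    cfg <- flow_sim_config(n_events_per_well = 2000, strain_effect = eff,
                           plate_shift = setNames(0.05 * (p - 1),
                                                  sprintf("P%d", p)),
                           seed = 100 * tp + p)
    lay <- plate_layout(plates[[p]], plate = sprintf("P%d", p))
    ev <- simulate_flow_plate(cfg, lay)
    write_flow_events(ev, sprintf("results/sim/flow_%02dh_P%d.csv", tp, p))
  }
}
message("flow plates written: ", length(list.files("results/sim", "flow_")))

# one example stack per phenotype preset, as TIFF + sidecar + truth summary
for (preset in c("wildtype", "mislocalized", "inheritance_defect", "large")) {
  sim <- simulate_stack(stack_sim_config(phenotype_preset = preset,
                                         seed = 500 + nchar(preset)))
  write_image_stack(sim$stack, sprintf("results/sim/stack_%s.tif", preset))
  message(sprintf("%-20s diffuse fraction %.2f, %d puncta in %d cells",
                  preset, sim$truth$diffuse_fraction,
                  nrow(sim$truth$puncta), nrow(sim$truth$cells)))
}

# toy multi-study catalog (studies I-V), annotations, interactions
cat5 <- simulate_catalog(600, c(I = 0.12, II = 0.10, III = 0.08, IV = 0.10,
                                V = 0.06), n_validated_novel = 12, seed = 7)
write_catalog_tsv(cat5, "results/sim/catalog.tsv")
ann <- simulate_annotations(cat5$genes, n_terms = 15, seed = 7)
write_tsv_table(ann, "results/sim/annotations.tsv")
edges <- simulate_interactions(cat5$genes, n_edges = 400, seed = 7)
write_tsv_table(edges, "results/sim/interactions.tsv")
message("catalog: ", length(cat5$genes), " genes, ",
        length(cat5$validated_novel), " validated novel")
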