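#!/usr/bin/env Rscript

# Multi-study integration: apply the validated-regulator rule (hit in >= 2
# studies, or independently validated) to the simulated catalog, recompute
# the screen's printed overlap arithmetic from its count tables, run
# hypergeometric enrichment on the toy annotations, and export the
# compartment-annotated regulator network.

library(peroxiscreen)

dir.create("results/meta", showWarnings = FALSE, recursive = TRUE)

cat5 <- read_catalog_tsv("results/sim/catalog.tsv")
regs <- integrate_catalog(cat5, min_studies = 2)
write_tsv_table(regs, "results/meta/regulators.tsv")
message(nrow(regs), " validated regulators of ", length(cat5$genes),
        " genes (", sum(regs$validated_novel), " rescued as validated novel)")

# the screen's printed accounting, recomputed from raw counts
lib <- library_summary()
meta <- meta_summary()
message(sprintf("library: %d unique strains, %d analyzed (%d%%)",
                lib$n_unique, lib$n_analyzed, lib$pct_analyzed))
message(sprintf("prior regulators recovered: %d of %d (%d%%)",
                meta$prior_overlap$n_intersect, meta$prior_overlap$n_b,
                meta$pct_prior_recovered))
message(sprintf("fatty-acid-only regulators: %d of %d (%d%%)",
                meta$fa_overlap$n_intersect, meta$fa_overlap$n_b,
                meta$pct_fatty_acid_only))

ann <- read.delim("results/sim/annotations.tsv")
enr <- enrich(regs$gene, ann, cat5$genes)
write_tsv_table(enr, "results/meta/enrichment.tsv")
message("top enriched terms:")
for (i in seq_len(min(3, nrow(enr)))) {
  message(sprintf("  %s: k=%d/%d, p=%.3g (BH %.3g)", enr$term[i], enr$k[i],
                  enr$K[i], enr$p[i], enr$p_adj[i]))
}

edges <- read.delim("results/sim/interactions.tsv")
names(edges) <- c("gene_a", "gene_b")
net <- export_network(regs, edges, known_genes = cat5$genes)
write_tsv_table(net$nodes, "results/meta/network_nodes.tsv")
write_tsv_table(net$edges, "results/meta/network_edges.tsv")
write_sif(net, "results/meta/network.sif")
message(nrow(net$nodes), " nodes, ", nrow(net$edges),
        " regulator-regulator edges (", net$n_dropped_edges, " dropped)")
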