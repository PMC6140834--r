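#!/usr/bin/env Rscript
# Step 5: stage-wise miRNA-mRNA interaction networks.
#
# Pearson-correlates each predicted miRNA-target pair over the four
# per-time-point mean expression profiles, keeps pairs whose miRNA and
# target are both DE in a stage, attaches up/down direction attributes and
# the correlation sign, filters to immune targets, and exports
# Cytoscape-compatible SIF/GraphML plus the stage-wise immune pair table.

suppressPackageStartupMessages(library(gutliveR))

run_dir <- "results/run"
inputs <- file.path(run_dir, "inputs")
lib <- load_immune_library(file.path(inputs, "immune_library.tsv"))
targets <- read_target_map(file.path(inputs, "target_map.tsv"))
mir_cm <- read_count_matrix(file.path(inputs, "gut_mirna_counts.tsv"),
                            file.path(inputs, "gut_mirna_samples.tsv"))
mrna_cm <- read_count_matrix(file.path(inputs, "gut_mrna_counts.tsv"),
                             file.path(inputs, "gut_mrna_samples.tsv"))

corr <- pair_correlations(mir_cm, mrna_cm, targets)
cat("correlations computed for", nrow(corr), "target pairs\n")

de_set <- function(prefix, stage) {
  tab <- read.delim(file.path(run_dir, "de",
                              paste0(prefix, "_", stage, ".tsv")))
  list(up_set = tab$feature_id[tab$call == "up"],
       down_set = tab$feature_id[tab$call == "down"])
}

summaries <- list()
for (stage in names(stage_definitions())) {
  net <- stage_network(corr, de_set("gut_mirna", stage),
                       de_set("gut", stage), stage)
  imm <- immune_subnetwork(net, lib)
  export_network(net, file.path(run_dir, "network", paste0(stage, "_all")))
  export_network(imm$edges,
                 file.path(run_dir, "network", paste0(stage, "_immune")))
  summaries[[stage]] <- imm$summary
  cat(sprintf("%-6s %3d edges (%d immune), %d negative\n", stage,
              nrow(net), nrow(imm$edges), sum(net$sign == "negative")))
}
summary <- do.call(rbind, summaries)
write.table(summary, file.path(run_dir, "network", "immune_pairs_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("networks exported under", file.path(run_dir, "network"), "\n")
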