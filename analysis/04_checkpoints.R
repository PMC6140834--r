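#!/usr/bin/env Rscript
# Step 4: immune checkpoint selection.
#
# Aggregates expression to (process, category) level, runs Welch t-tests
# between the time points each tissue rule needs (BH across categories per
# comparison), and applies the homeostasis rules: gut = perturbed late in
# the trial but back to baseline at 7w; liver = departed from the 0d
# baseline at any point.

suppressPackageStartupMessages(library(gutliveR))

run_dir <- "results/run"
inputs <- file.path(run_dir, "inputs")
lib <- load_immune_library(file.path(inputs, "immune_library.tsv"))

for (tissue in c("gut", "liver")) {
  cm <- read_count_matrix(
    file.path(inputs, paste0(tissue, "_mrna_counts.tsv")),
    file.path(inputs, paste0(tissue, "_mrna_samples.tsv")))
  prof <- suppressMessages(category_profile(cm, lib))
  tests <- category_tests(prof, checkpoint_comparisons(tissue), alpha = 0.05)
  chk <- select_checkpoints(tests, tissue)
  dir.create(file.path(run_dir, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  write.table(chk, file.path(run_dir, "checkpoints",
                             paste0(tissue, "_checkpoints.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- chk[chk$selected, ]
  cat(tissue, "checkpoint categories selected:", nrow(sel), "of",
      nrow(chk), "\n")
  if (nrow(sel)) {
    print(sel[, c("process", "category")], row.names = FALSE)
  }
}
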