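#!/usr/bin/env Rscript
# Step 1: simulate the study dataset.
#
# Generates one synthetic Cq dataset with the study's factorial design
# (9 brain regions x 2 genotypes x 3 biological replicates -- 6 for the WT
# hypothalamus -- x 3 technical replicates): 11 reference-gene candidates
# (3 of them designed unstable) plus the target-gene assays. Writes the raw
# long-format table and the generator's ground truth for later steps.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(refstab)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- study_config(seed)
sim <- simulate_cq(cfg)
write_cq_table(sim$table, "results/simulated_cq.tsv")

truth <- data.frame(
  gene = names(sim$truth$instability),
  instability = unname(sim$truth$instability),
  tier = ifelse(names(sim$truth$instability) %in% attr(cfg, "designed_panel"),
                "panel",
         ifelse(names(sim$truth$instability) %in% attr(cfg, "designed_unstable"),
                "unstable",
         ifelse(names(sim$truth$instability) %in% attr(cfg, "candidates"),
                "candidate", "target")))
)
write.table(truth[order(truth$instability), ], "results/simulation_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d genes x %d wells (seed %d)",
                length(sim$table$genes), ncol(sim$table$cq), seed))
message("designed panel: ", paste(attr(cfg, "designed_panel"), collapse = ", "))
message("designed unstable: ", paste(attr(cfg, "designed_unstable"), collapse = ", "))
message("wrote results/simulated_cq.tsv and results/simulation_truth.tsv")
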