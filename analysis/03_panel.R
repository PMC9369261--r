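#!/usr/bin/env Rscript
# Step 3: two-axis stability ranking and panel compilation.
#
# Sweeps the comprehensive ranking of the 8 screened candidates along both
# design axes -- stability across the nine regions within each genotype
# (per-region rankings averaged), and stability across the two genotypes
# within each region (pooled, NormFinder grouped by genotype) -- then
# combines the two axis scores 50%/50% and selects the top-3 panel.
# Writes one ranking report per condition plus the combination table.
#
# Run analysis/02_screen.R first.

library(refstab)

tab <- read_cq_table("results/simulated_cq.tsv")
col <- suppressWarnings(collapse_technical_replicates(tab))
screened <- readLines("results/screened_candidates.txt")

pw <- run_panel_workflow(col, "results", genes = screened,
                         weights = c(0.5, 0.5), k = 3)

message(sprintf("wrote %d ranking reports and the panel table:", length(pw$files)))
for (f in pw$files) message("  ", f)
message("combined ranking (50% regions / 50% genotypes):")
print(round(sort(pw$panel$combined_rank), 3))
message("reference-gene panel: ", paste(pw$panel$panel, collapse = "-"))
writeLines(pw$panel$panel, "results/panel_genes.txt")
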