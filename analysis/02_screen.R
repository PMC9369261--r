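#!/usr/bin/env Rscript
# Step 2: initial candidate screen.
#
# Collapses technical replicates and ranks all 11 reference-gene candidates
# across the nine brain regions of the wild-type animals with the four
# stability methods combined by geometric-mean rank; the top 8 survive.
# Mirrors the screen that removed the three classic but unstable
# housekeeping genes before the main ranking.
#
# Run analysis/01_simulate.R first.

library(refstab)

tab <- read_cq_table("results/simulated_cq.tsv")
col <- suppressWarnings(collapse_technical_replicates(tab))
cand <- attr(study_config(), "candidates")

wt <- subset_condition(col, genotype = "WT", genes = cand)
ranking <- comprehensive_rank(stability_suite(wt))
screened <- screen_candidates(ranking, 8)

d <- data.frame(gene = ranking$final_order,
                geomean_rank = unname(ranking$geomean_rank[ranking$final_order]),
                kept = ranking$final_order %in% screened)
write.table(d, "results/screening.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(screened, "results/screened_candidates.txt")

message("comprehensive ranking (WT, across regions):")
print(d, row.names = FALSE)
message("removed: ", paste(setdiff(cand, screened), collapse = ", "))
message("wrote results/screening.tsv and results/screened_candidates.txt")
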