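#!/usr/bin/env Rscript
# Stage 1: segmentation accuracy — how many of the true edible components the
# tool found, missed, or invented, overall and by record type.

library(dieteval)

reference <- read_records("results/data/reference.jsonl")
app <- read_records("results/data/app.jsonl")
links <- read_links("results/data/links.csv")

mt <- links_to_match_table(links, reference, app)
acc <- segmentation_accuracy(segmentation_coding(mt, reference))

utils::write.csv(acc, "results/segmentation_accuracy.csv", row.names = FALSE)

tot <- acc[acc$stratum == "total", ]
message(sprintf(
  "Of %d true segments the tool found %.1f%% +/- %.1f, omitted %.1f%%, intruded %.1f%%.",
  tot$n_true, tot$pct_found, tot$hw_found, tot$pct_omitted, tot$pct_intruded))
message("Full table in results/segmentation_accuracy.csv")
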