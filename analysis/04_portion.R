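#!/usr/bin/env Rscript
# Stage 3: portion-size estimation — weight error of exactly classified
# segments, summarised per food type, group and category, with paired t-tests
# and boxplot-ready quantiles.

library(dieteval)

reference <- read_records("results/data/reference.jsonl")
app <- read_records("results/data/app.jsonl")
links <- read_links("results/data/links.csv")
tax <- read_taxonomy("results/data/taxonomy.csv")

mt <- links_to_match_table(links, reference, app)
grades <- tibble::tibble(record_id = links$record_id,
                         ref_segment_id = links$ref_segment_id,
                         grade = grade_match(
                           reference$food_type[match(
                             paste(links$record_id, links$ref_segment_id),
                             paste(reference$record_id, reference$segment_id))],
                           app$food_type[match(
                             paste(links$record_id, links$app_segment_id),
                             paste(app$record_id, app$segment_id))],
                           tax,
                           too_generic = links$too_generic,
                           slight_variant = links$slight_variant,
                           overlooked_ingredient = links$overlooked_ingredient,
                           synonym = links$synonym))

errors <- weight_errors(mt, grades, reference, app)
for (lv in c("type", "group", "category")) {
  smry <- group_error_summary(errors, level = lv, tax = tax)
  utils::write.csv(smry, sprintf("results/portion_%s.csv", lv),
                   row.names = FALSE)
}

message(sprintf(
  "%d exact segments: mean true %.1f g, mean estimated %.1f g, mean error %.1f g.",
  nrow(errors), mean(errors$true_weight), mean(errors$est_weight),
  mean(errors$error_g)))
message(sprintf(
  "Mean absolute error %.1f%%; individual errors range %.1f%% to %.1f%%.",
  mean(errors$abs_pct_error), min(errors$pct_error), max(errors$pct_error)))
grp <- utils::read.csv("results/portion_group.csv")
sig <- grp$label[!is.na(grp$p) & grp$p <= 0.05]
message("Groups with significant weight bias: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none")
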