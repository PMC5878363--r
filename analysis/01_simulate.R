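#!/usr/bin/env Rscript
# Stage 1 — simulate the ground-truth population and emit the three
# registry extracts (clinical cohort, HIV surveillance, STD surveillance)
# with identity corruption and differential lab capture, plus the truth
# set used later to score the linkage.

library(hivcarelink)

seed <- 20260925L
n <- 6054L

cfg <- sim_config(n, seed = seed)
pop <- generate_population(cfg)
reg <- emit_registries(pop)

dir.create("results/registries", recursive = TRUE, showWarnings = FALSE)
write_cohort_extract(reg$cohort, "results/registries/cohort")
write_surveillance_extract(reg$surveillance, "results/registries/surveillance")
write_std_extract(reg$std, "results/registries/std")
readr::write_csv(reg$truth$pairs, "results/registries/truth_pairs.csv")
readr::write_csv(reg$truth$std_pairs, "results/registries/truth_std_pairs.csv")

cat(sprintf(
  "simulated %d persons: %d cohort rows (%d co-enrolled twice), %d in HIV surveillance, %d in STD registry\n",
  n, nrow(reg$cohort$persons),
  sum(grepl("B$", reg$cohort$persons$study_id)),
  nrow(reg$surveillance$persons), nrow(reg$std$persons)))
cat(sprintf(
  "lab capture asymmetry: cohort %d VL / %d CD4, surveillance %d VL / %d CD4\n",
  sum(reg$cohort$labs$test_type == "VL"),
  sum(reg$cohort$labs$test_type == "CD4"),
  sum(reg$surveillance$labs$test_type == "VL"),
  sum(reg$surveillance$labs$test_type == "CD4")))
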