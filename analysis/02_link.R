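#!/usr/bin/env Rscript
# Stage 2 — collapse co-enrollment, run the 11-key cohort-to-surveillance
# linkage and the 10-key STD linkage, and score both against the truth set.

library(hivcarelink)

cohort_raw <- read_cohort_extract("results/registries/cohort")
surv <- read_surveillance_extract("results/registries/surveillance")
std <- read_std_extract("results/registries/std")
truth_pairs <- readr::read_csv("results/registries/truth_pairs.csv",
                               show_col_types = FALSE)

cohort <- dedup_coenrollment(cohort_raw)
link <- link_records(cohort, surv)
truth <- collapse_truth_pairs(truth_pairs,
                              attr(cohort, "coenrollment_map"))
ev <- evaluate_linkage(link, truth)
std_events <- link_std(cohort, std)

dir.create("results/linkage", recursive = TRUE, showWarnings = FALSE)
pairs <- dplyr::mutate(link$pairs,
                       matched_key_ids = purrr::map_chr(
                         matched_key_ids, paste, collapse = ";"))
readr::write_csv(pairs, "results/linkage/pairs.csv")
readr::write_csv(std_events, "results/linkage/std_events.csv")
jsonlite::write_json(
  list(precision = ev$precision, recall = ev$recall, f1 = ev$f1,
       accepted = sum(!link$pairs$review_flag),
       review = sum(link$pairs$review_flag),
       unmatched_cohort = length(link$unmatched_cohort)),
  "results/linkage/evaluation.json", auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "linked %d of %d cohort persons (%.2f%%); precision %.4f recall %.4f; %d pairs flagged for review\n",
  sum(!link$pairs$review_flag), nrow(cohort$persons),
  100 * sum(!link$pairs$review_flag) / nrow(cohort$persons),
  ev$precision, ev$recall, sum(link$pairs$review_flag)))
cat(sprintf("STD linkage: %d deduplicated events, %d new from surveillance\n",
            nrow(std_events), sum(std_events$origin == "surveillance")))
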