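#!/usr/bin/env Rscript
# Stage 4 — apply the eligibility filter and compute per-person continuum
# outcomes (retention, ART, viral suppression, ever-suppression, LTFU,
# care-site category) on the pre- and post-linkage datasets over the same
# matched-and-eligible universe.

library(hivcarelink)

cohort <- dedup_coenrollment(read_cohort_extract("results/registries/cohort"))
surv <- read_surveillance_extract("results/registries/surveillance")
std_events <- readr::read_csv("results/linkage/std_events.csv",
                              show_col_types = FALSE)
pairs <- readr::read_csv("results/linkage/pairs.csv",
                         show_col_types = FALSE)
link <- structure(list(pairs = dplyr::mutate(
  pairs, matched_key_ids = strsplit(matched_key_ids, ";"))),
  class = "link_result")

post <- merge_linked(cohort, surv, link, std_events = std_events)
pre <- cohort_as_merged(cohort)
w <- analysis_window()

status_post_all <- compute_continuum(post, w)
universe <- status_post_all$study_id[status_post_all$matched]
status_post <- status_post_all[status_post_all$matched, ]
status_pre <- compute_continuum(pre, w, universe = universe)
status_pre$matched <- TRUE

dir.create("results/continuum", recursive = TRUE, showWarnings = FALSE)
readr::write_csv(status_pre, "results/continuum/status_pre.csv")
readr::write_csv(status_post, "results/continuum/status_post.csv")

excl <- attr(status_post_all, "exclusions")
cat(sprintf("eligible universe: %d matched persons (excluded: %s)\n",
            length(universe),
            paste(names(excl), excl, sep = "=", collapse = ", ")))
cat(sprintf("pre-linkage:  RIC %.2f%%, VS %.2f%%\n",
            100 * mean(status_pre$ric),
            100 * mean(status_pre$vs, na.rm = TRUE)))
cat(sprintf("post-linkage: RIC %.2f%%, VS %.2f%%  (sites: %s)\n",
            100 * mean(status_post$ric),
            100 * mean(status_post$vs, na.rm = TRUE),
            paste(names(table(status_post$site_category)),
                  table(status_post$site_category),
                  sep = "=", collapse = ", ")))
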