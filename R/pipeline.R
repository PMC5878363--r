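#' Run the full synthetic linkage-and-continuum pipeline
#'
#' Convenience driver: generates the ground-truth population, emits the
#' corrupted registry extracts, collapses co-enrollment, links cohort to
#' HIV surveillance (11-key) and to STD surveillance (10-key), builds the
#' pre- and post-linkage analysis datasets, computes continuum outcomes on
#' the matched-and-eligible universe (identical pre and post, so the two
#' are comparable person by person) and assembles the comparison report.
#'
#' @param config a [sim_config()].
#' @param min_keys linkage acceptance threshold.
#' @return list with every intermediate product: `population`,
#'   `registries`, `cohort` (co-enrollment collapsed), `link`,
#'   `evaluation`, `std_events`, `pre`, `post`, `status_pre`,
#'   `status_post`, `comparison`, `truth_pairs` (co-enrollment-collapsed
#'   truth).
#' @export
run_pipeline <- function(config, min_keys = 2L) {
  population <- generate_population(config)
  registries <- emit_registries(population)
  cohort <- dedup_coenrollment(registries$cohort)
  link <- link_records(cohort, registries$surveillance,
                       min_keys = min_keys)
  truth_pairs <- collapse_truth_pairs(registries$truth$pairs,
                                      attr(cohort, "coenrollment_map"))
  evaluation <- evaluate_linkage(link, truth_pairs)
  std_events <- link_std(cohort, registries$std, min_keys = min_keys)
  post <- merge_linked(cohort, registries$surveillance, link,
                       std_events = std_events)
  pre <- cohort_as_merged(cohort)

  status_post_all <- compute_continuum(post, config$window)
  universe <- status_post_all$study_id[status_post_all$matched]
  status_post <- status_post_all[status_post_all$matched, ]
  status_pre <- compute_continuum(pre, config$window, universe = universe)
  # carry the match flag into the pre view (matching is a property of the
  # person, not of the dataset the outcomes are read from)
  status_pre$matched <- TRUE

  list(
    population = population, registries = registries, cohort = cohort,
    link = link, evaluation = evaluation, std_events = std_events,
    pre = pre, post = post,
    status_pre = status_pre, status_post = status_post,
    status_post_all = status_post_all,
    comparison = compare_pre_post(status_pre, status_post),
    truth_pairs = truth_pairs
  )
}

#' Collapse a truth pair set through a co-enrollment map
#'
#' Re-expresses true (study ID, surveillance ID) pairs in terms of the
#' study IDs kept after [dedup_coenrollment()], deduplicating pairs that
#' referred to the same person through different enrollments.
#'
#' @param pairs tibble `study_id`, `ehars_id`.
#' @param map co-enrollment map (`study_id`, `kept_study_id`), or `NULL`.
#' @return collapsed pair tibble.
#' @export
collapse_truth_pairs <- function(pairs, map = NULL) {
  if (is.null(map)) return(dplyr::distinct(pairs))
  hit <- match(pairs$study_id, map$study_id)
  pairs$study_id <- ifelse(is.na(hit), pairs$study_id,
                           map$kept_study_id[hit])
  dplyr::distinct(pairs)
}
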