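#' Match one identity key across two registries
#'
#' Exact equality join on `key_string` for a single key id, excluding empty
#' keys. One registry key colliding with several records on the other side
#' yields several candidate pairs; conflict resolution happens later in
#' [merge_and_dedup()].
#'
#' @param cohort_keys,surveillance_keys long key tables from [build_keys()]
#'   (columns `native_id`, `key_id`, `key_string`).
#' @param key_id which key to match.
#' @return tibble `(study_id, ehars_id, key_id)` of candidate pairs.
#' @export
match_single_key <- function(cohort_keys, surveillance_keys, key_id) {
  kid <- key_id
  ck <- dplyr::filter(cohort_keys, .data$key_id == kid, .data$key_string != "")
  sk <- dplyr::filter(surveillance_keys, .data$key_id == kid, .data$key_string != "")
  dplyr::inner_join(
    dplyr::select(ck, study_id = "native_id", "key_string"),
    dplyr::select(sk, ehars_id = "native_id", "key_string"),
    by = "key_string", relationship = "many-to-many"
  ) |>
    dplyr::transmute(.data$study_id, .data$ehars_id, key_id = kid)
}

#' Merge the per-key candidate sets into a person-level match map
#'
#' The per-key candidate datasets are unioned and deduplicated by the
#' (study ID, surveillance ID) pair, accumulating the set of keys on which
#' each pair agreed. A pair is accepted when it agrees on at least
#' `min_keys` distinct keys, or on the SSN-exact key (key 1) alone. Pairs
#' left in a one-to-many conflict after acceptance are resolved in favour
#' of the pair with the most agreeing keys; ties are flagged for manual
#' review (`review_flag`) and excluded from the automated one-to-one map.
#'
#' @param candidates row-bound candidate pairs from [match_single_key()]
#'   (columns `study_id`, `ehars_id`, `key_id`).
#' @param min_keys minimum number of distinct agreeing keys (default 2).
#' @param cohort_ids,surveillance_ids optional full native-ID universes, used
#'   to report the unmatched sets.
#' @return object of class `link_result`: list with `pairs` (tibble
#'   `study_id`, `ehars_id`, `n_keys`, `matched_key_ids` list-column,
#'   `review_flag`), `unmatched_cohort`, `unmatched_surveillance`.
#' @export
merge_and_dedup <- function(candidates, min_keys = 2L,
                            cohort_ids = NULL, surveillance_ids = NULL) {
  pairs <- candidates |>
    dplyr::distinct(.data$study_id, .data$ehars_id, .data$key_id) |>
    dplyr::group_by(.data$study_id, .data$ehars_id) |>
    dplyr::summarise(
      n_keys = dplyr::n(),
      matched_key_ids = list(sort(.data$key_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      accepted = .data$n_keys >= min_keys |
        purrr::map_lgl(.data$matched_key_ids, ~ 1L %in% .x)
    ) |>
    dplyr::filter(.data$accepted) |>
    dplyr::select(-"accepted")

  if (nrow(pairs) == 0L) {
    return(structure(
      list(pairs = tibble::tibble(study_id = character(0),
                                  ehars_id = character(0),
                                  n_keys = integer(0),
                                  matched_key_ids = list(),
                                  review_flag = logical(0)),
           unmatched_cohort = cohort_ids %||% character(0),
           unmatched_surveillance = surveillance_ids %||% character(0)),
      class = "link_result"))
  }

  # one-to-many conflict resolution: an SSN-exact (key 1) agreement outranks
  # any key count, then most agreeing keys wins; exact ties are reviewed
  pairs <- pairs |>
    dplyr::mutate(
      strength = .data$n_keys +
        100L * purrr::map_int(.data$matched_key_ids, ~ as.integer(1L %in% .x))
    ) |>
    dplyr::arrange(.data$study_id, .data$ehars_id) |>
    dplyr::group_by(.data$study_id) |>
    dplyr::mutate(
      best_c = .data$strength == max(.data$strength),
      amb_c = dplyr::n() > 1L & sum(.data$strength == max(.data$strength)) > 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$ehars_id) |>
    dplyr::mutate(
      best_s = .data$strength == max(.data$strength),
      amb_s = dplyr::n() > 1L & sum(.data$strength == max(.data$strength)) > 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$best_c & .data$best_s) |>
    dplyr::mutate(review_flag = .data$amb_c | .data$amb_s) |>
    dplyr::select("study_id", "ehars_id", "n_keys", "matched_key_ids",
                  "review_flag")

  accepted <- dplyr::filter(pairs, !.data$review_flag)
  structure(
    list(
      pairs = pairs,
      unmatched_cohort = setdiff(
        cohort_ids %||% character(0), accepted$study_id),
      unmatched_surveillance = setdiff(
        surveillance_ids %||% character(0), accepted$ehars_id)
    ),
    class = "link_result"
  )
}

#' @export
print.link_result <- function(x, ...) {
  acc <- sum(!x$pairs$review_flag)
  cat("<link_result> ", acc, " accepted pair(s), ",
      sum(x$pairs$review_flag), " flagged for review, ",
      length(x$unmatched_cohort), " unmatched cohort ID(s)\n", sep = "")
  invisible(x)
}

#' Link a cohort extract to an HIV surveillance extract (11-key algorithm)
#'
#' Builds the 11 identity keys in both registries, matches each key
#' separately (producing 11 per-key candidate datasets), then merges and
#' deduplicates them by the (study ID, surveillance ID) pair.
#'
#' @param cohort a `cohort_extract`.
#' @param surveillance a `surveillance_extract`.
#' @param min_keys acceptance threshold, see [merge_and_dedup()].
#' @return a `link_result`.
#' @export
link_records <- function(cohort, surveillance, min_keys = 2L) {
  ck <- build_keys(
    dplyr::rename(cohort$persons, native_id = "study_id"), "hiv11")
  sk <- build_keys(
    dplyr::rename(surveillance$persons, native_id = "ehars_id"), "hiv11")
  candidates <- purrr::map_dfr(1:11, ~ match_single_key(ck, sk, .x))
  merge_and_dedup(candidates, min_keys = min_keys,
                  cohort_ids = cohort$persons$study_id,
                  surveillance_ids = surveillance$persons$ehars_id)
}

#' Link STD surveillance events to cohort participants (10-key algorithm)
#'
#' Matches the cohort against the STD registry on the 10-key variant (the
#' 11-key set minus the SSN-exact key), unions matched persons' STD
#' surveillance events with the cohort's own STD events, and deduplicates
#' by (study ID, disease, disease date). Same-disease events whose dates
#' differ by at most `dedup_window_days` collapse to the earlier date.
#'
#' @param cohort a `cohort_extract`.
#' @param std a `std_extract` (persons + events tables).
#' @param min_keys acceptance threshold for the identity match.
#' @param dedup_window_days near-duplicate window (default 14 days).
#' @return tibble `(study_id, disease, disease_date, origin)` of
#'   deduplicated per-person STD events; `origin` is `cohort`,
#'   `surveillance`, or `both` for a collapsed near-duplicate.
#' @export
link_std <- function(cohort, std, min_keys = 2L, dedup_window_days = 14L) {
  ck <- build_keys(
    dplyr::rename(cohort$persons, native_id = "study_id"), "std10")
  sk <- build_keys(
    dplyr::rename(std$persons, native_id = "std_id"), "std10")
  candidates <- purrr::map_dfr(2:11, ~ match_single_key(ck, sk, .x))
  link <- merge_and_dedup(candidates, min_keys = min_keys,
                          cohort_ids = cohort$persons$study_id,
                          surveillance_ids = std$persons$std_id)
  map <- dplyr::filter(link$pairs, !.data$review_flag) |>
    dplyr::select("study_id", std_id = "ehars_id")

  surv_events <- dplyr::inner_join(std$events, map, by = "std_id") |>
    dplyr::transmute(.data$study_id, .data$disease, .data$disease_date,
                     origin = "surveillance")
  cohort_events <- dplyr::transmute(cohort$std, .data$study_id, .data$disease,
                                    .data$disease_date, origin = "cohort")
  dedup_std_events(dplyr::bind_rows(cohort_events, surv_events),
                   dedup_window_days)
}

# Deduplicate STD events on (study_id, disease, disease_date); same-disease
# events within the window collapse to the earlier date (greedy, in date
# order, cohort-first on ties so output is deterministic).
dedup_std_events <- function(events, dedup_window_days = 14L) {
  events |>
    dplyr::arrange(.data$study_id, .data$disease, .data$disease_date,
                   .data$origin) |>
    dplyr::group_by(.data$study_id, .data$disease) |>
    dplyr::group_modify(function(df, key) {
      kept_date <- as.Date(character(0))
      kept_origin <- character(0)
      for (i in seq_len(nrow(df))) {
        d <- df$disease_date[i]
        j <- which(abs(as.numeric(d - kept_date)) <= dedup_window_days)
        if (length(j) == 0L) {
          kept_date <- c(kept_date, d)
          kept_origin <- c(kept_origin, df$origin[i])
        } else if (kept_origin[j[1L]] != df$origin[i]) {
          kept_origin[j[1L]] <- "both"
        }
      }
      tibble::tibble(disease_date = kept_date, origin = kept_origin)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$study_id, .data$disease, .data$disease_date)
}

#' Evaluate a linkage result against a known truth set
#'
#' @param result a `link_result`.
#' @param truth data frame with columns `study_id`, `ehars_id` listing every
#'   true same-person pair.
#' @return list with `precision`, `recall`, `f1`, `false_pairs`,
#'   `missed_pairs`, and `zero_denominator` (TRUE when no pair was accepted,
#'   in which case precision is reported as 1 by convention).
#' @export
evaluate_linkage <- function(result, truth) {
  truth <- dplyr::distinct(truth, .data$study_id, .data$ehars_id)
  if (nrow(truth) == 0L) stop("empty truth set")
  accepted <- dplyr::filter(result$pairs, !.data$review_flag) |>
    dplyr::select("study_id", "ehars_id")
  tp <- dplyr::inner_join(accepted, truth, by = c("study_id", "ehars_id"))
  zero_denom <- nrow(accepted) == 0L
  precision <- if (zero_denom) 1 else nrow(tp) / nrow(accepted)
  recall <- nrow(tp) / nrow(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(
    precision = precision,
    recall = recall,
    f1 = f1,
    false_pairs = dplyr::anti_join(accepted, truth,
                                   by = c("study_id", "ehars_id")),
    missed_pairs = dplyr::anti_join(truth, accepted,
                                    by = c("study_id", "ehars_id")),
    zero_denominator = zero_denom
  )
}
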