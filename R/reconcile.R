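#' Fuzzy laboratory deduplication rule
#'
#' Tolerances under which two laboratory results from different sources are
#' considered the same draw. Defaults are conservative and fully
#' configurable: same test type, dates within 7 days, viral loads within
#' 0.1 log10 (or both below 200 copies/mL), CD4 exactly equal.
#'
#' @param date_window_days maximum date difference in days.
#' @param vl_log10_tolerance maximum |log10 ratio| for two VL values.
#' @param cd4_abs_tolerance maximum absolute CD4 difference (cells/mm3).
#' @return list of class `fuzzy_lab_rule`.
#' @export
fuzzy_lab_rule <- function(date_window_days = 7L, vl_log10_tolerance = 0.1,
                           cd4_abs_tolerance = 0L) {
  stopifnot(date_window_days >= 0, vl_log10_tolerance >= 0,
            cd4_abs_tolerance >= 0)
  structure(list(date_window_days = date_window_days,
                 vl_log10_tolerance = vl_log10_tolerance,
                 cd4_abs_tolerance = cd4_abs_tolerance),
            class = "fuzzy_lab_rule")
}

.lab_values_match <- function(type, v1, v2, bd1, bd2, rule) {
  if (type == "CD4") return(abs(v1 - v2) <= rule$cd4_abs_tolerance)
  lo1 <- bd1 || v1 < 200; lo2 <- bd2 || v2 < 200
  if (lo1 && lo2) return(TRUE)
  if (v1 <= 0 || v2 <= 0) return(FALSE)
  abs(log10(v1) - log10(v2)) <= rule$vl_log10_tolerance
}

# Greedy chronological fuzzy dedup of one person's labs of all types.
# Input must carry collection_date, test_type, value, below_detection,
# origin; sorted deterministically (date, cohort-first, value) before the
# pass. A collapsed pair keeps the earlier date and the cohort value.
.dedup_person_labs <- function(df, rule) {
  ord <- order(df$collection_date, df$origin != "cohort", df$value,
               df$lab_id)
  df <- df[ord, ]
  n <- nrow(df)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    merged <- FALSE
    for (j in kept_idx) {
      # fuzzy matching reconciles differences *by data source*: only a
      # cross-source pair can be the same draw reported twice; repeat
      # tests within one source are real repeats and never collapse
      if (df$origin[j] == df$origin[i]) next
      if (df$test_type[j] != df$test_type[i]) next
      if (abs(as.numeric(df$collection_date[i] - df$collection_date[j])) >
            rule$date_window_days) next
      if (!.lab_values_match(df$test_type[i], df$value[j], df$value[i],
                             df$below_detection[j], df$below_detection[i],
                             rule)) next
      # collapse i into j: j already has the earlier date; prefer the
      # cohort-origin value when the origins differ
      if (df$origin[j] != "cohort" && df$origin[i] == "cohort") {
        df$value[j] <- df$value[i]
        df$below_detection[j] <- df$below_detection[i]
        df$origin[j] <- "cohort"
      }
      merged <- TRUE
      break
    }
    if (!merged) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  df[keep, ]
}

#' Deduplicate a person's laboratory results across sources
#'
#' Greedy chronological pass: a lab collapses into an earlier kept lab of
#' the same test type from the *other* source when their dates differ by
#' at most the rule's window and their values agree within tolerance
#' (VL: both < 200 copies/mL — below-detection results count as < 200 —
#' or |log10 ratio| within tolerance; CD4: absolute difference within
#' tolerance). Only cross-source pairs can be one draw reported twice;
#' near-in-time repeats within one source are genuine repeat tests and
#' are never collapsed. The surviving record keeps the earlier date and
#' the cohort-origin value. Deterministic for any input order.
#'
#' @param labs tibble of one or more persons' labs with columns `study_id`,
#'   `lab_id`, `test_type`, `value`, `below_detection`, `collection_date`,
#'   `source_facility`, `origin`.
#' @param rule a [fuzzy_lab_rule()].
#' @return tibble of surviving labs.
#' @export
dedup_labs <- function(labs, rule = fuzzy_lab_rule()) {
  if (nrow(labs) == 0L) return(labs)
  parts <- split(as.data.frame(labs), labs$study_id)
  out <- lapply(parts, .dedup_person_labs, rule = rule)
  res <- tibble::as_tibble(dplyr::bind_rows(out))
  dplyr::arrange(res, .data$study_id, .data$collection_date, .data$lab_id)
}

#' Default CDC-style transmission-risk hierarchy
#'
#' Highest priority first; reconciliation returns the highest-priority
#' category documented by any source and never synthesizes a combined
#' category that no source recorded.
#' @return character vector of risk categories in priority order.
#' @export
default_risk_hierarchy <- function() {
  c("msm_idu", "idu", "msm", "heterosexual", "perinatal", "other_unknown")
}

#' Reconcile documented transmission-risk categories
#'
#' @param risks character vector of documented categories (NAs dropped).
#' @param hierarchy priority order, see [default_risk_hierarchy()].
#' @return the highest-priority documented category; order-independent and
#'   idempotent.
#' @export
reconcile_risk <- function(risks, hierarchy = default_risk_hierarchy()) {
  risks <- risks[!is.na(risks)]
  if (length(risks) == 0L) stop("no documented risk category supplied")
  bad <- setdiff(risks, hierarchy)
  if (length(bad) > 0L) stop("unknown risk category: ",
                             paste(bad, collapse = ", "))
  hierarchy[min(match(risks, hierarchy))]
}

# vectorized two-source reconciliation used by merge_linked
.reconcile_risk_vec <- function(a, b, hierarchy) {
  ra <- match(a, hierarchy); rb <- match(b, hierarchy)
  r <- pmin(ra, rb, na.rm = TRUE)
  out <- hierarchy[r]
  out[is.na(ra) & is.na(rb)] <- NA_character_
  out
}

#' Collapse co-enrolled participants to one analytic record
#'
#' Participants consenting at more than one cohort site appear twice in the
#' cohort extract under different study IDs. Duplicate enrollments are
#' detected by exact agreement on the SSN key or on the full
#' name + DOB + sex key, collapsed onto the earliest-enrollment study ID
#' (lexicographically smallest on a tie); the duplicate's labs, visits,
#' prescriptions and STD events are reassigned to the kept record.
#'
#' @param cohort a `cohort_extract`.
#' @return the collapsed `cohort_extract`, with a `coenrollment_map`
#'   attribute (tibble `study_id`, `kept_study_id`).
#' @export
dedup_coenrollment <- function(cohort) {
  keys <- build_keys(dplyr::rename(cohort$persons, native_id = "study_id"),
                     "hiv11")
  keys <- dplyr::filter(keys, .data$key_id %in% c(1L, 2L),
                        .data$key_string != "")
  edges <- dplyr::inner_join(keys, keys,
                             by = c("key_id", "key_string"),
                             relationship = "many-to-many") |>
    dplyr::filter(.data$native_id.x < .data$native_id.y) |>
    dplyr::distinct(a = .data$native_id.x, b = .data$native_id.y)

  ids <- cohort$persons$study_id
  root <- setNames(ids, ids)
  find <- function(x) {
    while (root[[x]] != x) x <- root[[x]]
    x
  }
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$a[e]); rb <- find(edges$b[e])
    if (ra != rb) root[[max(ra, rb)]] <- min(ra, rb)
  }
  comp <- vapply(ids, find, "")
  # keep the earliest enrollment within each component
  pers <- dplyr::mutate(cohort$persons, .comp = comp)
  kept <- pers |>
    dplyr::group_by(.data$.comp) |>
    dplyr::arrange(.data$enrollment_date, .data$study_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  map <- dplyr::left_join(
    tibble::tibble(study_id = ids, .comp = comp),
    dplyr::select(kept, kept_study_id = "study_id", ".comp"),
    by = ".comp") |>
    dplyr::select("study_id", "kept_study_id")
  relabel <- function(df) {
    df$study_id <- map$kept_study_id[match(df$study_id, map$study_id)]
    df
  }
  out <- cohort_extract(
    persons = dplyr::select(kept, -".comp"),
    labs = relabel(cohort$labs), art = relabel(cohort$art),
    std = dplyr::distinct(relabel(cohort$std)),
    visits = dplyr::distinct(relabel(cohort$visits))
  )
  attr(out, "coenrollment_map") <- map
  out
}

#' Build the post-linkage merged dataset
#'
#' Applies the field-reconciliation rules to every accepted (study ID,
#' surveillance ID) pair and passes unmatched cohort persons through
#' untouched:
#'
#' * HIV diagnosis date: the earlier date, regardless of source; likewise
#'   the AIDS diagnosis date.
#' * Vital status: deceased if either source says deceased.
#' * Transmission risk: hierarchical reconciliation
#'   ([default_risk_hierarchy()]).
#' * OI at AIDS: TRUE if either source documents one, FALSE if documented
#'   absent, NA if neither source knows.
#' * Race/ethnicity and state of residence: the cohort value wins; a
#'   disagreement is tagged `both-conflict` in the provenance column.
#' * Sex at birth is a matching variable: a conflict sets
#'   `review_sex_conflict` rather than silently overriding.
#' * Labs: union of both sources, fuzzy-deduplicated ([dedup_labs()]).
#' * ART prescriptions and visits: cohort only (not collected by
#'   surveillance).
#'
#' @param cohort a `cohort_extract` (after [dedup_coenrollment()] if
#'   co-enrollment is possible).
#' @param surveillance a `surveillance_extract`, or `NULL` for a
#'   cohort-only (pre-linkage) dataset.
#' @param link a `link_result` from [link_records()], or `NULL`.
#' @param std_events optional deduplicated STD event table from
#'   [link_std()]; defaults to the cohort's own STD events.
#' @param rule a [fuzzy_lab_rule()].
#' @param hierarchy risk priority order.
#' @return object of class `merged_cohort`: tibbles `persons` (with
#'   per-field provenance columns), `labs`, `art`, `std`, `visits`.
#' @export
merge_linked <- function(cohort, surveillance = NULL, link = NULL,
                         std_events = NULL, rule = fuzzy_lab_rule(),
                         hierarchy = default_risk_hierarchy()) {
  map <- if (!is.null(link)) {
    dplyr::filter(link$pairs, !.data$review_flag) |>
      dplyr::select("study_id", "ehars_id")
  } else tibble::tibble(study_id = character(0), ehars_id = character(0))

  p <- dplyr::left_join(cohort$persons, map, by = "study_id")
  if (!is.null(surveillance)) {
    sp <- dplyr::rename_with(surveillance$persons, ~ paste0(.x, "_s"))
    p <- dplyr::left_join(p, sp, by = c(ehars_id = "ehars_id_s"))
  } else {
    p <- dplyr::mutate(p, first_name_s = NA_character_,
                       last_name_s = NA_character_, dob_s = as.Date(NA),
                       sex_at_birth_s = NA_character_, ssn_s = NA_character_,
                       hiv_dx_date_s = as.Date(NA),
                       aids_dx_date_s = as.Date(NA), oi_at_aids_s = NA,
                       transmission_risk_s = NA_character_,
                       state_of_residence_s = NA_character_,
                       vital_status_s = NA_character_)
  }
  matched <- !is.na(p$ehars_id)

  dx_c <- p$hiv_dx_date; dx_s <- p$hiv_dx_date_s
  dx <- dplyr::coalesce(pmin(dx_c, dx_s, na.rm = FALSE),
                        dx_c, dx_s)
  prov_dx <- dplyr::case_when(
    !is.na(dx_c) & !is.na(dx_s) & dx_c == dx_s ~ "both",
    !is.na(dx_c) & !is.na(dx_s) & dx_s < dx_c ~ "surveillance",
    !is.na(dx_c) & !is.na(dx_s) ~ "cohort",
    !is.na(dx_s) ~ "surveillance",
    !is.na(dx_c) ~ "cohort",
    TRUE ~ NA_character_
  )
  risk <- .reconcile_risk_vec(p$transmission_risk, p$transmission_risk_s,
                              hierarchy)
  prov_risk <- dplyr::case_when(
    !matched | is.na(p$transmission_risk_s) ~ "cohort",
    p$transmission_risk == p$transmission_risk_s ~ "both",
    risk == p$transmission_risk ~ "cohort",
    TRUE ~ "surveillance"
  )
  vital <- ifelse(p$vital_status == "deceased" |
                    (!is.na(p$vital_status_s) &
                       p$vital_status_s == "deceased"),
                  "deceased", "alive")
  prov_vital <- dplyr::case_when(
    !matched | is.na(p$vital_status_s) ~ "cohort",
    p$vital_status == p$vital_status_s ~ "both",
    TRUE ~ ifelse(vital == p$vital_status, "cohort", "surveillance")
  )
  # residence: the cohort value wins, disagreement tagged for audit
  prov_residence <- dplyr::case_when(
    !matched | is.na(p$state_of_residence_s) ~ "cohort",
    p$state_of_residence == p$state_of_residence_s ~ "both",
    TRUE ~ "both-conflict"
  )
  oi <- dplyr::case_when(
    !is.na(p$oi_at_aids) & p$oi_at_aids ~ TRUE,
    !is.na(p$oi_at_aids_s) & p$oi_at_aids_s ~ TRUE,
    !is.na(p$oi_at_aids) | !is.na(p$oi_at_aids_s) ~ FALSE,
    TRUE ~ NA
  )
  aids <- p$aids_ever | !is.na(p$aids_dx_date_s)
  sex_conflict <- matched & !is.na(p$sex_at_birth_s) &
    p$sex_at_birth != "unknown" & p$sex_at_birth_s != "unknown" &
    p$sex_at_birth != p$sex_at_birth_s

  persons <- tibble::tibble(
    study_id = p$study_id, ehars_id = p$ehars_id,
    first_name = p$first_name, last_name = p$last_name, dob = p$dob,
    sex_at_birth = p$sex_at_birth, ssn = p$ssn,
    enrollment_site = p$enrollment_site,
    enrollment_date = p$enrollment_date,
    race_ethnicity = p$race_ethnicity,
    state_of_residence = p$state_of_residence,
    transmission_risk = risk,
    hiv_dx_date = dx,
    aids_ever = aids, aids_dx_date = p$aids_dx_date_s,
    oi_at_aids = oi,
    housing = p$housing, employment = p$employment,
    insurance = p$insurance, comorbidities = p$comorbidities,
    vital_status = vital,
    withdrawal_date = p$withdrawal_date, transfer_date = p$transfer_date,
    prov_hiv_dx_date = prov_dx, prov_transmission_risk = prov_risk,
    prov_state_of_residence = prov_residence, prov_vital_status = prov_vital,
    review_sex_conflict = sex_conflict
  )

  labs_c <- dplyr::mutate(cohort$labs, origin = "cohort")
  labs <- labs_c
  if (!is.null(surveillance) && nrow(map) > 0L) {
    labs_s <- dplyr::inner_join(surveillance$labs, map, by = "ehars_id") |>
      dplyr::mutate(origin = "surveillance") |>
      dplyr::select(dplyr::all_of(names(labs_c)))
    labs <- dplyr::bind_rows(labs_c, labs_s)
    # only persons with any surveillance lab can hold cross-source
    # duplicates; everyone else passes through
    with_surv <- unique(labs_s$study_id)
    labs <- dplyr::bind_rows(
      dplyr::filter(labs, !(.data$study_id %in% with_surv)),
      dedup_labs(dplyr::filter(labs, .data$study_id %in% with_surv), rule)
    )
  }
  labs <- dplyr::arrange(labs, .data$study_id, .data$collection_date,
                         .data$lab_id)

  std <- if (!is.null(std_events)) std_events else
    dplyr::mutate(cohort$std, origin = "cohort")

  structure(list(persons = dplyr::arrange(persons, .data$study_id),
                 labs = labs, art = cohort$art, std = std,
                 visits = cohort$visits),
            class = "merged_cohort")
}

#' Pre-linkage (cohort-only) analysis dataset
#'
#' The cohort extract recast in the merged-dataset shape with every
#' provenance tag `cohort`; computing outcomes on this object gives the
#' pre-linkage result.
#'
#' @param cohort a `cohort_extract`.
#' @return a `merged_cohort`.
#' @export
cohort_as_merged <- function(cohort) {
  merge_linked(cohort, surveillance = NULL, link = NULL)
}

#' @export
print.merged_cohort <- function(x, ...) {
  cat("<merged_cohort> ", nrow(x$persons), " person(s) (",
      sum(!is.na(x$persons$ehars_id)), " matched), ", nrow(x$labs),
      " lab(s)\n", sep = "")
  invisible(x)
}
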