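#' Analysis window for care-continuum outcomes
#'
#' The 12-month outcome window plus the loss-to-follow-up rule. Defaults
#' follow the standard retention definition: two HIV-related encounters at
#' least 90 days apart between 2014-06-15 and 2015-06-15, loss to
#' follow-up after 18 months without any dated evidence of care as of
#' 2015-06-15. Endpoints are inclusive and "at least 90 days" is >= 90
#' exact calendar days.
#'
#' @param start,end window bounds (coerced with [as.Date()]).
#' @param min_gap_days minimum encounter gap for retention.
#' @param ltfu_months calendar months without care that define LTFU.
#' @param as_of reference date for LTFU and ever-suppression.
#' @return list of class `analysis_window`.
#' @export
analysis_window <- function(start = "2014-06-15", end = "2015-06-15",
                            min_gap_days = 90L, ltfu_months = 18L,
                            as_of = end) {
  w <- list(start = as.Date(start), end = as.Date(end),
            min_gap_days = as.integer(min_gap_days),
            ltfu_months = as.integer(ltfu_months), as_of = as.Date(as_of))
  stopifnot(w$start < w$end,
            w$min_gap_days <= as.numeric(w$end - w$start))
  structure(w, class = "analysis_window")
}

#' Eligibility filter for the continuum analysis
#'
#' Keeps persons who were actively enrolled before the window end with at
#' least one year of follow-up (enrollment at least one year before
#' `window$end`), had not withdrawn or transferred care before the window
#' start, and were alive at the window start. Exclusion reasons are
#' tallied in the `exclusions` attribute (a person is counted under the
#' first reason that applies).
#'
#' @param merged a `merged_cohort`.
#' @param window an [analysis_window()].
#' @return the filtered `merged_cohort` persons tibble with an
#'   `exclusions` attribute (named integer vector).
#' @export
filter_eligible <- function(merged, window = analysis_window()) {
  p <- merged$persons
  followup_short <- as.numeric(window$end - p$enrollment_date) < 365
  withdrawn <- !is.na(p$withdrawal_date) & p$withdrawal_date < window$start
  transferred <- !is.na(p$transfer_date) & p$transfer_date < window$start
  # deceased persons without a death date are excluded conservatively
  dead_by_start <- p$vital_status == "deceased"
  reason <- dplyr::case_when(
    followup_short ~ "followup_lt_1yr",
    withdrawn ~ "withdrawn",
    transferred ~ "transferred",
    dead_by_start ~ "deceased",
    TRUE ~ NA_character_
  )
  out <- p[is.na(reason), ]
  attr(out, "exclusions") <- table(factor(
    reason, levels = c("followup_lt_1yr", "withdrawn", "transferred",
                       "deceased")))
  out
}

#' Loss to follow-up
#'
#' TRUE when the latest dated evidence of care (any lab or visit) precedes
#' `as_of` by `ltfu_months` calendar months or more (inclusive at exactly
#' the boundary, same day-of-month anchor). A person with no dated events
#' at all is LTFU and flagged degenerate via the `"degenerate"` attribute.
#'
#' @param event_dates vector of lab/visit dates for one person.
#' @param as_of reference date.
#' @param ltfu_months threshold in calendar months.
#' @return logical flag.
#' @export
is_ltfu <- function(event_dates, as_of, ltfu_months = 18L) {
  event_dates <- event_dates[!is.na(event_dates)]
  cutoff <- as.Date(as_of) %m-% months(ltfu_months)
  if (length(event_dates) == 0L) {
    return(structure(TRUE, degenerate = TRUE))
  }
  max(event_dates) <= cutoff
}

#' @importFrom lubridate %m-%
#' @export
lubridate::`%m-%`

#' Retention in care
#'
#' TRUE when two HIV-related encounter dates inside the window (endpoints
#' inclusive) lie at least `window$min_gap_days` exact calendar days apart;
#' encounters on the same date count once, and encounters may come from
#' different care sites.
#'
#' @param encounter_dates vector of visit/lab dates for one person.
#' @param window an [analysis_window()].
#' @return logical flag.
#' @export
retained_in_care <- function(encounter_dates, window = analysis_window()) {
  d <- unique(encounter_dates[!is.na(encounter_dates)])
  d <- d[d >= window$start & d <= window$end]
  length(d) >= 2L &&
    as.numeric(max(d) - min(d)) >= window$min_gap_days
}

#' On antiretroviral therapy during the window
#'
#' TRUE when any prescription interval overlaps the window (inclusive):
#' `start_date <= window$end` and (`end_date` missing — an open, ongoing
#' prescription — or `end_date >= window$start`). Prescriptions come from
#' the cohort source only; surveillance does not collect ART.
#'
#' @param starts,ends prescription start/end dates (same length; `ends`
#'   may be NA for ongoing prescriptions).
#' @param window an [analysis_window()].
#' @return logical flag.
#' @export
on_art <- function(starts, ends, window = analysis_window()) {
  if (length(starts) == 0L) return(FALSE)
  any(starts <= window$end & (is.na(ends) | ends >= window$start))
}

#' Viral suppression (last VL on file below 200 copies/mL)
#'
#' Defined only among persons retained in care and on ART with at least
#' one VL dated on or before the window end; otherwise `NA` (not in the
#' denominator). The last-dated VL decides; below-detection results count
#' as suppressed. Ties on the last date keep the cohort-origin value, then
#' the lower value.
#'
#' @param labs one person's lab tibble (columns `test_type`, `value`,
#'   `below_detection`, `collection_date`, `origin`).
#' @param ric,art the person's retention and ART flags.
#' @param window an [analysis_window()].
#' @return TRUE/FALSE, or NA when undefined.
#' @export
virally_suppressed <- function(labs, ric, art, window = analysis_window()) {
  vl <- labs[labs$test_type == "VL" & !is.na(labs$collection_date) &
               labs$collection_date <= window$end, ]
  if (!isTRUE(ric) || !isTRUE(art) || nrow(vl) == 0L) return(NA)
  ord <- order(vl$collection_date, vl$origin != "cohort", vl$value,
               decreasing = c(TRUE, FALSE, FALSE), method = "radix")
  last <- vl[ord[1L], ]
  isTRUE(last$below_detection) || last$value < 200
}

#' Ever virally suppressed since enrollment
#'
#' TRUE when any VL below 200 copies/mL (below-detection included) is
#' dated between enrollment and `as_of`.
#'
#' @param labs one person's lab tibble.
#' @param enrollment_date enrollment date.
#' @param as_of reference date.
#' @return logical flag.
#' @export
ever_suppressed <- function(labs, enrollment_date, as_of) {
  vl <- labs[labs$test_type == "VL", ]
  any(vl$collection_date >= enrollment_date & vl$collection_date <= as_of &
        (vl$below_detection | vl$value < 200), na.rm = TRUE)
}

#' Classify receipt of care by number of clinical sites
#'
#' For a singly-enrolled person: `one` when every lab (or no lab at all)
#' comes from the enrollment site; `three_plus` when at least 2 labs come
#' from at least 2 distinct non-enrollment facilities; `two` otherwise
#' (labs from exactly one other facility, or fewer than 2 labs spread over
#' other facilities).
#'
#' @param lab_facilities vector of source facilities of the person's labs.
#' @param enrollment_site the person's cohort enrollment site.
#' @return `"one"`, `"two"` or `"three_plus"`.
#' @export
classify_care_sites <- function(lab_facilities, enrollment_site) {
  other <- lab_facilities[!is.na(lab_facilities) &
                            lab_facilities != enrollment_site]
  if (length(other) == 0L) return("one")
  if (length(other) >= 2L && length(unique(other)) >= 2L) {
    return("three_plus")
  }
  "two"
}

#' Compute per-person continuum status on an analysis dataset
#'
#' Applies [filter_eligible()], then computes retention, ART, viral
#' suppression (defined only in the retained-and-on-ART, VL-on-file
#' subset), ever-suppression, loss to follow-up and the care-site category
#' for every eligible person of a pre- or post-linkage `merged_cohort`.
#'
#' @param merged a `merged_cohort`.
#' @param window an [analysis_window()].
#' @param universe optional character vector of study IDs fixing the
#'   analysis universe (e.g. the post-linkage eligible set, so that pre-
#'   and post-linkage outcomes are compared over identical persons). When
#'   given, the eligibility filter is skipped.
#' @return tibble with one row per eligible person: `study_id`, `matched`,
#'   `ric`, `on_art`, `vs` (NA outside its denominator), `ever_vs`,
#'   `ltfu`, `site_category`; the eligibility exclusion tally is attached
#'   as the `exclusions` attribute.
#' @export
compute_continuum <- function(merged, window = analysis_window(),
                              universe = NULL) {
  eligible <- if (is.null(universe)) {
    filter_eligible(merged, window)
  } else {
    merged$persons[merged$persons$study_id %in% universe, ]
  }
  ids <- eligible$study_id

  labs <- as.data.frame(merged$labs[merged$labs$study_id %in% ids, ])
  labs_by <- split(labs, factor(labs$study_id, levels = ids))
  visits_by <- split(merged$visits$visit_date,
                     factor(merged$visits$study_id, levels = ids))
  art_by <- split(merged$art[c("start_date", "end_date")],
                  factor(merged$art$study_id, levels = ids))

  # the LTFU cutoff is one fixed calendar date per run
  ltfu_cutoff <- window$as_of %m-% months(window$ltfu_months)

  out <- purrr::pmap(
    list(ids, eligible$enrollment_site, eligible$enrollment_date,
         seq_along(ids)),
    function(id, site, enr, k) {
      pl <- labs_by[[k]]
      pv <- visits_by[[k]]
      pa <- art_by[[k]]
      enc <- c(pl$collection_date, pv)
      enc <- enc[!is.na(enc)]
      ric <- retained_in_care(enc, window)
      art <- on_art(pa$start_date, pa$end_date, window)
      vs <- virally_suppressed(pl, ric, art, window)
      list(
        ric = ric, on_art = art, vs = vs,
        ever_vs = ever_suppressed(pl, enr, window$as_of),
        ltfu = length(enc) == 0L || max(enc) <= ltfu_cutoff,
        site_category = classify_care_sites(pl$source_facility, site)
      )
    })
  res <- tibble::tibble(
    study_id = ids,
    matched = !is.na(eligible$ehars_id),
    ric = purrr::map_lgl(out, "ric"),
    on_art = purrr::map_lgl(out, "on_art"),
    vs = purrr::map_lgl(out, "vs"),
    ever_vs = purrr::map_lgl(out, "ever_vs"),
    ltfu = purrr::map_lgl(out, "ltfu"),
    site_category = purrr::map_chr(out, "site_category")
  )
  attr(res, "exclusions") <- attr(eligible, "exclusions")
  res
}
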