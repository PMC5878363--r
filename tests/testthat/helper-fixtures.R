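# Small in-code fixture builders shared across the suite.

make_identity <- function(first = "John", last = "Smith",
                          dob = as.Date("1970-03-07"), sex = "male",
                          ssn = "123456789") {
  tibble::tibble(first_name = first, last_name = last, dob = as.Date(dob),
                 sex_at_birth = sex, ssn = ssn)
}

# persons table in the key-builder layout
make_key_input <- function(n_or_df) {
  if (is.data.frame(n_or_df)) {
    df <- n_or_df
  } else {
    df <- purrr::map_dfr(seq_len(n_or_df), ~ make_identity())
  }
  dplyr::mutate(df, native_id = sprintf("P%03d", dplyr::row_number()),
                .before = 1)
}

make_labs <- function(study_id, dates, types = "VL", values = 50,
                      origin = "cohort", facility = "CS01",
                      below = FALSE) {
  n <- max(lengths(list(dates, types, values, origin, facility, below)))
  tibble::tibble(
    study_id = rep_len(study_id, n),
    lab_id = sprintf("LAB%03d", seq_len(n)),
    test_type = rep_len(types, n),
    value = rep_len(values, n),
    below_detection = rep_len(below, n),
    collection_date = as.Date(rep_len(dates, n)),
    source_facility = rep_len(facility, n),
    origin = rep_len(origin, n)
  )
}

# a minimal merged_cohort with one configurable person
make_merged_person <- function(study_id = "C1", ehars_id = "E1",
                               enrollment_site = "CS01",
                               enrollment_date = as.Date("2012-01-01"),
                               vital_status = "alive",
                               withdrawal_date = as.Date(NA),
                               transfer_date = as.Date(NA),
                               labs = NULL, visits = as.Date(character(0)),
                               art = NULL) {
  persons <- tibble::tibble(
    study_id = study_id, ehars_id = ehars_id,
    first_name = "A", last_name = "B", dob = as.Date("1970-01-01"),
    sex_at_birth = "male", ssn = "123456789",
    enrollment_site = enrollment_site, enrollment_date = enrollment_date,
    race_ethnicity = "nh_black", state_of_residence = "DC",
    transmission_risk = "msm", hiv_dx_date = as.Date("2005-01-01"),
    aids_ever = FALSE, aids_dx_date = as.Date(NA), oi_at_aids = NA,
    housing = "permanent", employment = "fulltime", insurance = "private",
    comorbidities = NA_character_, vital_status = vital_status,
    withdrawal_date = withdrawal_date, transfer_date = transfer_date,
    prov_hiv_dx_date = "cohort", prov_transmission_risk = "cohort",
    prov_state_of_residence = "cohort", prov_vital_status = "cohort",
    review_sex_conflict = FALSE
  )
  structure(list(
    persons = persons,
    labs = labs %||% make_labs(study_id, as.Date(character(0)))[0, ],
    art = art %||% tibble::tibble(study_id = character(0),
                                  start_date = as.Date(character(0)),
                                  end_date = as.Date(character(0))),
    std = tibble::tibble(study_id = character(0), disease = character(0),
                         disease_date = as.Date(character(0)),
                         origin = character(0)),
    visits = tibble::tibble(study_id = rep(study_id, length(visits)),
                            visit_date = as.Date(visits))
  ), class = "merged_cohort")
}

`%||%` <- rlang::`%||%`

# one small default-config pipeline, memoized across test files
.fixture_env <- new.env(parent = emptyenv())
run_pipeline_fixture <- function() {
  if (is.null(.fixture_env$res)) {
    .fixture_env$res <- run_pipeline(sim_config(60, seed = 2))
  }
  .fixture_env$res
}

# brute-force all-pairs key-equality oracle for linkage
brute_force_candidates <- function(cohort_keys, surv_keys) {
  out <- list()
  for (kid in sort(unique(cohort_keys$key_id))) {
    ck <- cohort_keys[cohort_keys$key_id == kid, ]
    sk <- surv_keys[surv_keys$key_id == kid, ]
    for (a in seq_len(nrow(ck))) {
      for (b in seq_len(nrow(sk))) {
        if (ck$key_string[a] != "" &&
              ck$key_string[a] == sk$key_string[b]) {
          out[[length(out) + 1L]] <- tibble::tibble(
            study_id = ck$native_id[a], ehars_id = sk$native_id[b],
            key_id = kid)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
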