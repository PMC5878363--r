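#' Emit the three registry extracts and the truth set from a population
#'
#' Derives, from one ground-truth population, the clinical-cohort extract,
#' the HIV surveillance extract and the STD surveillance extract, applying
#' per-registry identity corruption (each registry transcribes the person
#' independently) and differential capture per the [capture_model()]:
#'
#' * surveillance holds resident persons (scaled by `overlap_fraction`)
#'   plus non-residents at `p_nonresident_lab_reported`;
#' * a lab reaches the cohort database with certainty at the enrollment
#'   site, else at `p_cohort_captures_external_lab`; it reaches
#'   surveillance at the type- and value-dependent capture rates;
#' * the cohort record of the HIV diagnosis date may lag the true date
#'   (later chart-recorded diagnosis), surveillance carries the true
#'   (earliest) date — the raw material for the earliest-date
#'   reconciliation rule;
#' * reporting noise on transmission risk, OI history and vital status
#'   emulates the imperfect inter-registry agreement of real data;
#' * a small fraction of persons is co-enrolled at a second cohort site
#'   and appears twice in the cohort extract under a second study ID.
#'
#' Deterministic given the population's `sim_config`; per-person RNG
#' substreams are derived from its seed.
#'
#' @param population a [generate_population()] result.
#' @param config its [sim_config()] (defaults to the one stored in the
#'   population).
#' @return list with `cohort`, `surveillance`, `std` extracts and `truth`
#'   (list: `pairs` (study_id, ehars_id), `std_pairs` (study_id, std_id),
#'   `persons` per-person ID map, `labs` per-lab capture flags).
#' @export
emit_registries <- function(population, config = population$config) {
  cm <- config$capture_model
  em <- config$error_model
  r <- config$rates
  pp <- population$persons
  if (is.null(pp) || nrow(pp) == 0L) {
    stop("empty population; generate with n_persons > 0")
  }
  P <- as.list(pp)
  L <- if (!is.null(population$labs)) as.list(population$labs) else NULL
  S <- if (!is.null(population$std)) as.list(population$std) else NULL
  A <- if (!is.null(population$art)) as.list(population$art) else NULL
  V <- if (!is.null(population$visits)) as.list(population$visits) else NULL
  idx_of <- function(tab) {
    if (is.null(tab)) return(list())
    split(seq_along(tab$person_uid), tab$person_uid)
  }
  lab_by <- idx_of(population$labs)
  std_by <- idx_of(population$std)
  art_by <- idx_of(population$art)
  vis_by <- idx_of(population$visits)

  n <- nrow(pp)
  co_p <- vector("list", 2L * n); co_l <- vector("list", n)
  co_a <- vector("list", n); co_s <- vector("list", n)
  co_v <- vector("list", n)
  su_p <- vector("list", n); su_l <- vector("list", n)
  st_p <- vector("list", n); st_e <- vector("list", n)
  tr_pairs <- vector("list", 2L * n); tr_std <- vector("list", n)
  tr_persons <- vector("list", n); tr_labs <- vector("list", n)

  for (k in seq_len(n)) {
    i <- P$person_uid[k]
    with_substream(config$seed, i, 2L, {
      study_id <- sprintf("C%06d", i)
      ehars_id <- sprintf("E%06d", i)
      std_id <- sprintf("S%06d", i)
      resident <- P$resident[k]
      enroll_num <- as.numeric(P$enrollment_date[k])

      in_surv <- runif(1) < (if (resident) cm$overlap_fraction else
                               cm$p_nonresident_lab_reported)

      # the cohort holds the identity as enrolled (the reference copy);
      # the surveillance and STD registries hold independently corrupted
      # transcriptions, so the error-model rates read as per-pair rates
      id_cohort <- list(first_name = P$first_name[k],
                        last_name = P$last_name[k], dob = P$dob[k],
                        ssn = P$ssn[k])
      id_surv <- .corrupt_fast(P$first_name[k], P$last_name[k],
                               P$dob[k], P$ssn[k], em)
      id_std <- .corrupt_fast(P$first_name[k], P$last_name[k],
                              P$dob[k], P$ssn[k], em)

      # cohort-recorded HIV diagnosis may lag the true (surveillance) date
      dx_true <- as.numeric(P$hiv_dx_date[k])
      dx_cohort <- if (runif(1) < r$p_cohort_dx_lag) {
        min(dx_true + round(runif(1, 0.5, 4) * 365.25), enroll_num)
      } else dx_true
      dx_surv <- if (runif(1) < 0.05) NA_real_ else dx_true

      true_risk <- P$transmission_risk[k]
      risk_cohort <- if (runif(1) < 0.85) true_risk else "other_unknown"
      risk_surv <- if (runif(1) < 0.80) true_risk else
        sample(c("other_unknown", setdiff(.risk_levels, true_risk)), 1L,
               prob = c(0.7, rep(0.3 / 5, 5)))
      dead <- P$vital_status[k] == "deceased"
      vital_cohort <- if (dead && runif(1) < 0.6) "deceased" else "alive"
      vital_surv <- if (dead && runif(1) < 0.97) "deceased" else "alive"
      aids <- P$aids_ever[k]
      aids_cohort <- aids && runif(1) < 0.9
      oi_cohort <- if (aids && runif(1) < 0.55) P$oi_at_aids[k] else NA
      oi_surv <- if (aids && runif(1) < 0.85) P$oi_at_aids[k] else NA
      aids_dx_surv <- if (aids) {
        min(dx_true + round(runif(1, 0, 5) * 365.25),
            as.numeric(config$window$as_of))
      } else NA_real_

      co_p[[2L * k - 1L]] <- list(
        study_id = study_id, enrollment_site = P$enrollment_site[k],
        enrollment_date = enroll_num,
        first_name = id_cohort$first_name, last_name = id_cohort$last_name,
        dob = as.numeric(id_cohort$dob),
        sex_at_birth = P$sex_at_birth[k], ssn = id_cohort$ssn,
        race_ethnicity = P$race_ethnicity[k],
        state_of_residence = P$state_of_residence[k],
        transmission_risk = risk_cohort,
        hiv_dx_date = dx_cohort,
        aids_ever = aids_cohort, oi_at_aids = oi_cohort,
        housing = P$housing[k], employment = P$employment[k],
        insurance = P$insurance[k], comorbidities = P$comorbidities[k],
        vital_status = vital_cohort,
        withdrawal_date = as.numeric(P$withdrawal_date[k]),
        transfer_date = as.numeric(P$transfer_date[k])
      )

      # lab capture
      li <- lab_by[[as.character(i)]]
      lab_cap_c <- logical(0); lab_cap_s <- logical(0)
      if (length(li) > 0L) {
        fac <- L$source_facility[li]
        typ <- L$test_type[li]
        val <- L$value[li]
        bdl <- L$below_detection[li]
        cdt <- as.numeric(L$collection_date[li])
        uid <- L$lab_uid[li]
        at_site <- fac == P$enrollment_site[k]
        lab_cap_c <- at_site |
          runif(length(li)) < cm$p_cohort_captures_external_lab
        suppressed_vl <- typ == "VL" & (bdl | val < 200)
        p_surv <- ifelse(typ == "CD4", cm$p_surv_cd4_capture,
                         ifelse(suppressed_vl,
                                cm$p_surv_vl_capture_suppressed,
                                cm$p_surv_vl_capture_unsuppressed))
        lab_cap_s <- in_surv & (runif(length(li)) < p_surv)
        if (any(lab_cap_c)) {
          w <- which(lab_cap_c)
          co_l[[k]] <- list(
            study_id = rep(study_id, length(w)), lab_id = uid[w],
            test_type = typ[w], value = val[w], below_detection = bdl[w],
            collection_date = cdt[w], source_facility = fac[w]
          )
        }
        if (any(lab_cap_s)) {
          w <- which(lab_cap_s)
          jit <- ifelse(runif(length(w)) < r$p_surv_lab_date_jitter,
                        sample(c(-3:-1, 1:3), length(w), replace = TRUE), 0)
          su_l[[k]] <- list(
            ehars_id = rep(ehars_id, length(w)), lab_id = uid[w],
            test_type = typ[w], value = val[w], below_detection = bdl[w],
            collection_date = cdt[w] + jit, source_facility = fac[w]
          )
        }
        tr_labs[[k]] <- list(
          lab_uid = uid, person_uid = rep(i, length(li)),
          in_cohort = lab_cap_c, in_surveillance = lab_cap_s
        )
      }

      # ART and visits are cohort-only and fully captured
      ai <- art_by[[as.character(i)]]
      if (length(ai) > 0L) {
        co_a[[k]] <- list(study_id = rep(study_id, length(ai)),
                          start_date = as.numeric(A$start_date[ai]),
                          end_date = as.numeric(A$end_date[ai]))
      }
      vi <- vis_by[[as.character(i)]]
      if (length(vi) > 0L) {
        co_v[[k]] <- list(study_id = rep(study_id, length(vi)),
                          visit_date = as.numeric(V$visit_date[vi]))
      }

      # STD events: cohort chart capture and registry reporting
      si <- std_by[[as.character(i)]]
      any_std_reported <- FALSE
      if (length(si) > 0L) {
        cap_c <- runif(length(si)) < r$p_cohort_captures_std
        p_rep <- if (resident) r$p_std_reported_resident else
          r$p_std_reported_nonresident
        cap_s <- runif(length(si)) < p_rep
        if (any(cap_c)) {
          w <- si[cap_c]
          co_s[[k]] <- list(study_id = rep(study_id, length(w)),
                            disease = S$disease[w],
                            disease_date = as.numeric(S$disease_date[w]))
        }
        if (any(cap_s)) {
          w <- si[cap_s]
          st_e[[k]] <- list(std_id = rep(std_id, length(w)),
                            disease = S$disease[w],
                            disease_date = as.numeric(S$disease_date[w]))
          any_std_reported <- TRUE
        }
      }
      if (any_std_reported) {
        st_p[[k]] <- list(std_id = std_id,
                          first_name = id_std$first_name,
                          last_name = id_std$last_name,
                          dob = as.numeric(id_std$dob),
                          sex_at_birth = P$sex_at_birth[k],
                          ssn = id_std$ssn)
        tr_std[[k]] <- list(study_id = study_id, std_id = std_id)
      }

      if (in_surv) {
        su_p[[k]] <- list(
          ehars_id = ehars_id, first_name = id_surv$first_name,
          last_name = id_surv$last_name, dob = as.numeric(id_surv$dob),
          sex_at_birth = P$sex_at_birth[k], ssn = id_surv$ssn,
          hiv_dx_date = dx_surv, aids_dx_date = aids_dx_surv,
          oi_at_aids = oi_surv, transmission_risk = risk_surv,
          state_of_residence = if (runif(1) < 0.95)
            P$state_of_residence[k] else "other",
          vital_status = vital_surv
        )
        tr_pairs[[2L * k - 1L]] <- list(study_id = study_id,
                                        ehars_id = ehars_id)
      }

      # co-enrollment at a second cohort site under a second study ID
      co_site <- P$coenroll_site[k]
      if (!is.na(co_site)) {
        study_id2 <- sprintf("C%06dB", i)
        id2 <- .corrupt_fast(P$first_name[k], P$last_name[k], P$dob[k],
                             P$ssn[k], em)
        co_p[[2L * k]] <- list(
          study_id = study_id2, enrollment_site = co_site,
          enrollment_date = enroll_num + 180,
          first_name = id2$first_name, last_name = id2$last_name,
          dob = as.numeric(id2$dob), sex_at_birth = P$sex_at_birth[k],
          ssn = id2$ssn, race_ethnicity = P$race_ethnicity[k],
          state_of_residence = P$state_of_residence[k],
          transmission_risk = risk_cohort,
          hiv_dx_date = dx_cohort,
          aids_ever = aids_cohort, oi_at_aids = oi_cohort,
          housing = P$housing[k], employment = P$employment[k],
          insurance = P$insurance[k], comorbidities = P$comorbidities[k],
          vital_status = vital_cohort,
          withdrawal_date = NA_real_, transfer_date = NA_real_
        )
        if (length(li) > 0L) {
          w <- li[L$source_facility[li] == co_site]
          if (length(w) > 0L) {
            co_l[[k]]$study_id <- c(co_l[[k]]$study_id,
                                    rep(study_id2, length(w)))
            co_l[[k]]$lab_id <- c(co_l[[k]]$lab_id,
                                  paste0(L$lab_uid[w], "B"))
            co_l[[k]]$test_type <- c(co_l[[k]]$test_type, L$test_type[w])
            co_l[[k]]$value <- c(co_l[[k]]$value, L$value[w])
            co_l[[k]]$below_detection <- c(co_l[[k]]$below_detection,
                                           L$below_detection[w])
            co_l[[k]]$collection_date <- c(co_l[[k]]$collection_date,
                                           as.numeric(L$collection_date[w]))
            co_l[[k]]$source_facility <- c(co_l[[k]]$source_facility,
                                           L$source_facility[w])
          }
        }
        if (in_surv) {
          tr_pairs[[2L * k]] <- list(study_id = study_id2,
                                     ehars_id = ehars_id)
        }
      }

      tr_persons[[k]] <- list(
        person_uid = i, study_id = study_id,
        study_id_coenrolled = if (!is.na(co_site)) sprintf("C%06dB", i)
          else NA_character_,
        ehars_id = if (in_surv) ehars_id else NA_character_,
        std_id = if (any_std_reported) std_id else NA_character_
      )
    })
  }

  cohort <- cohort_extract(
    persons = .bind_fast(co_p, c("enrollment_date", "dob", "hiv_dx_date",
                                 "withdrawal_date", "transfer_date")),
    labs = .bind_fast(co_l, "collection_date") %||%
      .empty_lab_table("study_id"),
    art = .bind_fast(co_a, c("start_date", "end_date")) %||%
      tibble::tibble(study_id = character(0),
                     start_date = as.Date(character(0)),
                     end_date = as.Date(character(0))),
    std = .bind_fast(co_s, "disease_date") %||%
      tibble::tibble(study_id = character(0), disease = character(0),
                     disease_date = as.Date(character(0))),
    visits = .bind_fast(co_v, "visit_date") %||%
      tibble::tibble(study_id = character(0),
                     visit_date = as.Date(character(0)))
  )
  surveillance <- surveillance_extract(
    persons = .bind_fast(su_p, c("dob", "hiv_dx_date", "aids_dx_date")),
    labs = .bind_fast(su_l, "collection_date") %||%
      .empty_lab_table("ehars_id")
  )
  std <- std_extract(
    persons = .bind_fast(st_p, "dob") %||%
      tibble::tibble(std_id = character(0), first_name = character(0),
                     last_name = character(0), dob = as.Date(character(0)),
                     sex_at_birth = character(0), ssn = character(0)),
    events = .bind_fast(st_e, "disease_date") %||%
      tibble::tibble(std_id = character(0), disease = character(0),
                     disease_date = as.Date(character(0)))
  )
  truth <- list(
    pairs = .bind_fast(tr_pairs) %||%
      tibble::tibble(study_id = character(0), ehars_id = character(0)),
    std_pairs = .bind_fast(tr_std) %||%
      tibble::tibble(study_id = character(0), std_id = character(0)),
    persons = .bind_fast(tr_persons),
    labs = .bind_fast(tr_labs) %||%
      tibble::tibble(lab_uid = character(0), person_uid = integer(0),
                     in_cohort = logical(0), in_surveillance = logical(0))
  )
  list(cohort = cohort, surveillance = surveillance, std = std,
       truth = truth)
}

# fast scalar identity corruption used inside the emission loop;
# corrupt_identity() is the documented wrapper over the same draws
.corrupt_fast <- function(first, last, dob, ssn, model) {
  # first name: nickname substitution, else typo
  nick <- .nickname_map[names(.nickname_map) == first]
  canon <- names(.nickname_map)[.nickname_map == first]
  alt <- c(unname(nick), canon)[1]
  if (!is.na(alt) && runif(1) < model$p_nickname_substitution) {
    first <- alt
  } else if (runif(1) < model$p_typo_per_name) {
    first <- .apply_typo(first)
  }
  if (runif(1) < model$p_last_name_change) {
    last <- sample(setdiff(.last_names, last), 1L)
  } else if (runif(1) < model$p_typo_per_name) {
    last <- .apply_typo(last)
  }
  d <- lubridate::day(dob); mo <- lubridate::month(dob)
  if (d <= 12L && d != mo && runif(1) < model$p_dob_day_month_swap) {
    dob <- as.Date(sprintf("%04d-%02d-%02d", lubridate::year(dob), d, mo))
  }
  if (!is.na(ssn) && runif(1) < model$p_ssn_missing) ssn <- NA_character_
  list(first_name = first, last_name = last, dob = dob, ssn = ssn)
}

.empty_lab_table <- function(id) {
  tibble::as_tibble(setNames(
    list(character(0), character(0), character(0), numeric(0), logical(0),
         as.Date(character(0)), character(0)),
    c(id, "lab_id", "test_type", "value", "below_detection",
      "collection_date", "source_facility")))
}

#' Ground-truth merged dataset for a synthetic population
#'
#' Builds the complete, uncorrupted analysis dataset directly from the
#' truth (every lab, visit, prescription and STD event; true diagnosis
#' dates and vital status), bypassing linkage. This is the oracle against
#' which the linked-and-reconciled pipeline is compared in parameter
#' recovery checks.
#'
#' @param population a [generate_population()] result.
#' @return a `merged_cohort` (same shape as [merge_linked()] output).
#' @export
population_as_merged <- function(population) {
  pp <- population$persons
  study_id <- sprintf("C%06d", pp$person_uid)
  persons <- tibble::tibble(
    study_id = study_id,
    ehars_id = NA_character_,
    first_name = pp$first_name, last_name = pp$last_name, dob = pp$dob,
    sex_at_birth = pp$sex_at_birth, ssn = pp$ssn,
    enrollment_site = pp$enrollment_site,
    enrollment_date = pp$enrollment_date,
    race_ethnicity = pp$race_ethnicity,
    state_of_residence = pp$state_of_residence,
    transmission_risk = pp$transmission_risk,
    hiv_dx_date = pp$hiv_dx_date,
    aids_ever = pp$aids_ever, aids_dx_date = as.Date(NA),
    oi_at_aids = pp$oi_at_aids,
    housing = pp$housing, employment = pp$employment,
    insurance = pp$insurance, comorbidities = pp$comorbidities,
    vital_status = pp$vital_status,
    withdrawal_date = pp$withdrawal_date,
    transfer_date = pp$transfer_date,
    prov_hiv_dx_date = "cohort", prov_transmission_risk = "cohort",
    prov_state_of_residence = "cohort", prov_vital_status = "cohort",
    review_sex_conflict = FALSE
  )
  uid_to_id <- setNames(study_id, pp$person_uid)
  relabel <- function(df) {
    if (is.null(df)) return(NULL)
    df$study_id <- unname(uid_to_id[as.character(df$person_uid)])
    df$person_uid <- NULL
    df
  }
  labs <- relabel(population$labs)
  if (!is.null(labs)) {
    labs <- dplyr::transmute(labs, .data$study_id, lab_id = .data$lab_uid,
                             .data$test_type, .data$value,
                             .data$below_detection, .data$collection_date,
                             .data$source_facility, origin = "cohort")
  }
  structure(list(
    persons = dplyr::arrange(persons, .data$study_id),
    labs = labs %||% .merged_empty_labs(),
    art = relabel(population$art) %||%
      tibble::tibble(study_id = character(0),
                     start_date = as.Date(character(0)),
                     end_date = as.Date(character(0))),
    std = {
      s <- relabel(population$std)
      if (!is.null(s)) dplyr::mutate(s, origin = "cohort") else
        tibble::tibble(study_id = character(0), disease = character(0),
                       disease_date = as.Date(character(0)),
                       origin = character(0))
    },
    visits = relabel(population$visits) %||%
      tibble::tibble(study_id = character(0),
                     visit_date = as.Date(character(0)))
  ), class = "merged_cohort")
}

.merged_empty_labs <- function() {
  tibble::tibble(study_id = character(0), lab_id = character(0),
                 test_type = character(0), value = numeric(0),
                 below_detection = logical(0),
                 collection_date = as.Date(character(0)),
                 source_facility = character(0), origin = character(0))
}
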