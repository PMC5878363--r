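#' Identity-corruption error model
#'
#' Per-field perturbation probabilities applied independently to each
#' registry's copy of a person's identity (a registry sees its own
#' transcription of the person, so both copies can be corrupted). At most
#' one perturbation is applied per field per call.
#'
#' @param p_typo_per_name probability of a single-character typographic
#'   error (substitution, insertion or deletion — always edit distance 1)
#'   in each of first and last name.
#' @param p_dob_day_month_swap probability that day and month of the DOB
#'   are transposed (applied only when the day is a plausible month,
#'   i.e. <= 12, as happens in real data entry).
#' @param p_ssn_missing probability the SSN is absent from the record.
#' @param p_nickname_substitution probability a first name is replaced by
#'   its nickname (or vice versa) per the packaged nickname map.
#' @param p_last_name_change probability the surname is replaced outright
#'   (marriage/divorce-style change).
#' @return list of class `error_model`.
#' @export
error_model <- function(p_typo_per_name = 0.02,
                        p_dob_day_month_swap = 0.02,
                        p_ssn_missing = 0.15,
                        p_nickname_substitution = 0.03,
                        p_last_name_change = 0.015) {
  m <- list(p_typo_per_name = p_typo_per_name,
            p_dob_day_month_swap = p_dob_day_month_swap,
            p_ssn_missing = p_ssn_missing,
            p_nickname_substitution = p_nickname_substitution,
            p_last_name_change = p_last_name_change)
  stopifnot(all(unlist(m) >= 0), all(unlist(m) <= 1))
  structure(m, class = "error_model")
}

#' Differential-capture model for the two lab-reporting streams
#'
#' Controls which true laboratory results reach which registry, emulating
#' the asymmetry between clinic abstraction (complete at the enrollment
#' site, patchy elsewhere) and surveillance reporting (CD4 reported
#' regardless of value; suppressed viral loads under-reported; labs of
#' non-residents reported to other jurisdictions).
#'
#' @param p_surv_vl_capture_suppressed probability a VL < 200 copies/mL
#'   reaches the surveillance registry.
#' @param p_surv_vl_capture_unsuppressed probability a VL >= 200 does.
#' @param p_surv_cd4_capture probability a CD4 result does.
#' @param p_nonresident_lab_reported probability a non-resident appears in
#'   the surveillance registry at all.
#' @param p_cohort_captures_external_lab probability the cohort database
#'   captures a lab drawn outside the participant's enrollment site.
#' @param overlap_fraction fraction of resident cohort persons present in
#'   the surveillance registry.
#' @return list of class `capture_model`.
#' @export
capture_model <- function(p_surv_vl_capture_suppressed = 0.30,
                          p_surv_vl_capture_unsuppressed = 0.85,
                          p_surv_cd4_capture = 0.98,
                          p_nonresident_lab_reported = 0.79,
                          p_cohort_captures_external_lab = 0.30,
                          overlap_fraction = 0.985) {
  m <- list(p_surv_vl_capture_suppressed = p_surv_vl_capture_suppressed,
            p_surv_vl_capture_unsuppressed = p_surv_vl_capture_unsuppressed,
            p_surv_cd4_capture = p_surv_cd4_capture,
            p_nonresident_lab_reported = p_nonresident_lab_reported,
            p_cohort_captures_external_lab = p_cohort_captures_external_lab,
            overlap_fraction = overlap_fraction)
  stopifnot(all(unlist(m) >= 0), all(unlist(m) <= 1))
  structure(m, class = "capture_model")
}

#' Default category marginals for the synthetic population
#'
#' Demographic and care-pattern marginal frequencies of the emulated
#' population (sex, race/ethnicity, state of residence, transmission risk,
#' the 1 / 2 / >=3 care-site mixture, and per-stratum viral-suppression
#' rates). Probability vectors are normalized to sum to exactly 1.
#'
#' @return named list of named probability vectors.
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(male = 0.7401, female = 0.2599)),
    race = norm(c(nh_black = 0.7370, nh_white = 0.1567,
                  other_unknown = 0.1063)),
    residence = norm(c(DC = 0.7414, MD = 0.1884, VA = 0.0569,
                       other = 0.0143)),
    risk = norm(c(msm_idu = 0.0168, idu = 0.04, msm = 0.4959,
                  heterosexual = 0.3393, perinatal = 0.0498,
                  other_unknown = 0.0583)),
    site_mix = norm(c(one = 0.7683, two = 0.1549, three_plus = 0.0768)),
    suppression = c(one = 0.8951, two = 0.785, three_plus = 0.723)
  )
}

# Secondary behavioural rates of the generator (engagement, mortality,
# event intensities); documented in the methods vignette.
default_rates <- function() {
  list(
    engaged = c(one = 0.66, two = 0.75, three_plus = 0.93),
    p_coenroll = 0.02, p_dead = 0.03,
    p_withdrawn = 0.08, p_transfer = 0.04,
    labs_per_year_engaged = 3.5, labs_per_year_sporadic = 0.8,
    visits_per_year_engaged = 1.5, visits_per_year_sporadic = 0.3,
    std_per_year = 0.26,
    p_on_art_engaged = 0.98, p_on_art_sporadic = 0.7,
    p_cohort_dx_lag = 0.3, p_below_detection = 0.7,
    p_cohort_captures_std = 0.75, p_std_reported_resident = 0.8,
    p_std_reported_nonresident = 0.25,
    p_surv_lab_date_jitter = 0.25,
    p_aids = c(one = 0.612, two = 0.668, three_plus = 0.778),
    p_hypertension = c(one = 0.2298, two = 0.305, three_plus = 0.377),
    p_mental_health = c(one = 0.389, two = 0.509, three_plus = 0.613),
    p_diabetes = c(one = 0.0886, two = 0.135, three_plus = 0.149),
    p_cardiovascular = c(one = 0.156, two = 0.196, three_plus = 0.257)
  )
}

#' Simulation configuration for the synthetic dual-registry generator
#'
#' @param n_persons number of ground-truth cohort participants.
#' @param seed master RNG seed; every person derives an independent
#'   substream from it, so increasing `n_persons` leaves earlier persons
#'   bit-identical.
#' @param error_model an [error_model()].
#' @param capture_model a [capture_model()].
#' @param marginals category frequencies, see [default_marginals()].
#' @param window an [analysis_window()].
#' @param rates secondary behavioural rates (internal defaults).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_persons, seed = 1L,
                       error_model = hivcarelink::error_model(),
                       capture_model = hivcarelink::capture_model(),
                       marginals = default_marginals(),
                       window = analysis_window(),
                       rates = default_rates()) {
  stopifnot(n_persons >= 0, is.numeric(seed))
  for (nm in c("sex", "race", "residence", "risk", "site_mix")) {
    if (abs(sum(marginals[[nm]]) - 1) > 1e-9) {
      stop("marginal '", nm, "' does not sum to 1")
    }
  }
  structure(
    list(n_persons = as.integer(n_persons), seed = as.integer(seed),
         error_model = error_model, capture_model = capture_model,
         marginals = marginals, window = window, rates = rates),
    class = "sim_config"
  )
}

# rbind a list of per-person named lists of equal-length column vectors,
# restoring Date columns (stored as numeric day offsets) at the end.
.bind_fast <- function(rows, date_cols = character(0)) {
  rows <- rows[lengths(rows) > 0L]
  if (length(rows) == 0L) return(NULL)
  cols <- names(rows[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  for (cn in intersect(date_cols, cols)) {
    out[[cn]] <- as.Date(out[[cn]], origin = "1970-01-01")
  }
  tibble::as_tibble(out)
}

.sample1 <- function(p) sample(names(p), 1L, prob = p)

#' Generate the ground-truth population
#'
#' Draws `n_persons` complete person histories (clean identity,
#' demographics, care sites, labs, visits, ART prescriptions, STD events,
#' vital status) from the configured marginals. Everything downstream —
#' the registry extracts, their corruption and their differential capture —
#' is derived from this single truth in [emit_registries()].
#'
#' Per-stratum construction guarantees that the true care-site category
#' equals the drawn stratum: 1-site persons draw all labs at their
#' enrollment site; 2-site persons get at least one lab at exactly one
#' other facility; >=3-site persons at least two labs at two distinct
#' other facilities.
#'
#' @param config a [sim_config()].
#' @return list of class `true_population` with tibbles `persons`, `labs`,
#'   `visits`, `art`, `std`; deterministic given `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_persons == 0L) {
    return(structure(list(persons = NULL, labs = NULL, visits = NULL,
                          art = NULL, std = NULL, config = config),
                     class = "true_population"))
  }
  m <- config$marginals
  r <- config$rates
  as_of <- config$window$as_of
  enroll_lo <- as.Date("2011-01-01")
  enroll_hi <- as.Date("2014-09-01")

  persons <- vector("list", config$n_persons)
  labs <- vector("list", config$n_persons)
  visits <- vector("list", config$n_persons)
  art <- vector("list", config$n_persons)
  std <- vector("list", config$n_persons)

  for (i in seq_len(config$n_persons)) {
    with_substream(config$seed, i, 1L, {
      sex <- .sample1(m$sex)
      first <- sample(if (sex == "male") .first_names_male else
                        .first_names_female, 1L)
      last <- sample(.last_names, 1L)
      dob <- as.Date("1945-01-01") + floor(runif(1) * 16436)
      ssn <- sprintf("%09d", (i * 811 + 123457) %% 1e9)
      race <- .sample1(m$race)
      residence <- .sample1(m$residence)
      resident <- residence == "DC"
      risk <- .sample1(m$risk)
      stratum <- .sample1(m$site_mix)
      suppressed <- runif(1) < m$suppression[[stratum]]
      site <- sample(.cohort_sites, 1L)
      n_extra <- switch(stratum, one = 0L, two = 1L,
                        three_plus = sample(2:3, 1L))
      extra_pool <- setdiff(c(.external_sites, .cohort_sites), site)
      extra_w <- ifelse(startsWith(extra_pool, "EX"), 0.7 / 20, 0.3 / 12)
      extras <- if (n_extra > 0L)
        sample(extra_pool, n_extra, prob = extra_w) else character(0)

      enroll <- enroll_lo +
        floor(runif(1) * as.numeric(enroll_hi - enroll_lo))
      dx <- enroll - round(runif(1, 0.5, 28) * 365.25)
      engaged <- runif(1) < r$engaged[[stratum]]
      dead <- runif(1) < r$p_dead
      death <- if (dead)
        enroll + 30 + floor(runif(1) * max(as.numeric(as_of - enroll) - 30,
                                           1)) else as.Date(NA)
      withdrawal <- if (!dead && runif(1) < r$p_withdrawn)
        enroll + floor(runif(1) * as.numeric(as_of - enroll)) else
          as.Date(NA)
      transfer <- if (!dead && is.na(withdrawal) && runif(1) < r$p_transfer)
        enroll + floor(runif(1) * as.numeric(as_of - enroll)) else
          as.Date(NA)
      end_fu <- min(as_of, death, na.rm = TRUE)
      years <- max(as.numeric(end_fu - enroll) / 365.25, 0.1)

      # laboratory history
      lab_rate <- if (engaged) r$labs_per_year_engaged else
        r$labs_per_year_sporadic
      n_lab <- rpois(1L, lab_rate * years)
      forced_fac <- switch(stratum, one = character(0), two = extras,
                           three_plus = rep(extras[1:2], 1L))
      n_lab <- max(n_lab, length(forced_fac))
      if (n_lab > 0L) {
        if (engaged) {
          d_lab <- enroll + floor(runif(n_lab) * as.numeric(end_fu - enroll))
        } else {
          center <- enroll + floor(runif(1) * as.numeric(end_fu - enroll))
          d_lab <- pmin(pmax(center + round(runif(n_lab, -45, 45)), enroll),
                        end_fu)
        }
        # multi-site care is fragmented: most labs drawn away from the
        # enrollment site, so the cohort chart alone under-sees these
        # persons (the silent-transfer phenomenon)
        fac <- switch(stratum,
          one = rep(site, n_lab),
          two = sample(c(site, extras), n_lab, replace = TRUE,
                       prob = c(0.65, 0.35)),
          three_plus = sample(c(site, extras), n_lab, replace = TRUE,
                              prob = c(0.35, rep(0.65 / length(extras),
                                                 length(extras))))
        )
        fac[seq_along(forced_fac)] <- forced_fac
        type <- sample(c("CD4", "VL"), n_lab, replace = TRUE)
        bd <- rep(FALSE, n_lab)
        val <- numeric(n_lab)
        is_cd4 <- type == "CD4"
        val[is_cd4] <- round(exp(rnorm(sum(is_cd4), log(480), 0.5)))
        for (j in which(!is_cd4)) {
          if (suppressed) {
            if (runif(1) < r$p_below_detection) {
              val[j] <- 0; bd[j] <- TRUE
            } else val[j] <- round(runif(1, 20, 199))
          } else {
            val[j] <- if (runif(1) < 0.15) round(runif(1, 20, 199)) else
              round(10^runif(1, 2.6, 5.3))
          }
        }
        labs[[i]] <- list(
          person_uid = rep(i, n_lab),
          lab_uid = sprintf("L%06d_%02d", i, seq_len(n_lab)),
          test_type = type, value = val, below_detection = bd,
          collection_date = as.numeric(d_lab), source_facility = fac
        )
      }

      # HIV care visits (always at the enrollment site, cohort-only);
      # multi-site persons keep fewer visits at their home clinic
      v_rate <- if (engaged) r$visits_per_year_engaged else
        r$visits_per_year_sporadic
      if (stratum != "one") v_rate <- v_rate * 0.5
      n_vis <- rpois(1L, v_rate * years)
      if (n_vis > 0L) {
        visits[[i]] <- list(
          person_uid = rep(i, n_vis),
          visit_date = as.numeric(
            enroll + floor(runif(n_vis) * as.numeric(end_fu - enroll)))
        )
      }

      # ART prescription
      on_art <- runif(1) < (if (engaged) r$p_on_art_engaged else
                              r$p_on_art_sporadic)
      if (on_art) {
        a_start <- enroll + floor(runif(1, 0, 120))
        a_end <- if (runif(1) < 0.95) as.Date(NA) else
          a_start + floor(runif(1, 180, 900))
        art[[i]] <- list(person_uid = i, start_date = as.numeric(a_start),
                         end_date = as.numeric(a_end))
      }

      # STD events
      n_std <- rpois(1L, r$std_per_year * years)
      if (n_std > 0L) {
        std[[i]] <- list(
          person_uid = rep(i, n_std),
          disease = sample(c("syphilis", "gonorrhea", "chlamydia"), n_std,
                           replace = TRUE, prob = c(0.25, 0.4, 0.35)),
          disease_date = as.numeric(
            enroll + floor(runif(n_std) * as.numeric(end_fu - enroll)))
        )
      }

      aids <- runif(1) < r$p_aids[[stratum]]
      oi <- if (aids) runif(1) < 0.28 else NA
      comorb <- c(
        if (runif(1) < r$p_hypertension[[stratum]]) "hypertension",
        if (runif(1) < r$p_mental_health[[stratum]]) "mental_health",
        if (runif(1) < r$p_diabetes[[stratum]]) "diabetes",
        if (runif(1) < r$p_cardiovascular[[stratum]]) "cardiovascular")
      housing <- .sample1(switch(stratum,
        one = c(permanent = 0.8121, temporary = 0.0785, homeless = 0.0111,
                other_unknown = 0.0983),
        two = c(permanent = 0.775, temporary = 0.112, homeless = 0.012,
                other_unknown = 0.101),
        three_plus = c(permanent = 0.738, temporary = 0.130,
                       homeless = 0.021, other_unknown = 0.111)))
      employment <- .sample1(switch(stratum,
        one = c(fulltime = 0.3112, parttime = 0.0342, unemployed = 0.2216,
                other = 0.433),
        two = c(fulltime = 0.175, parttime = 0.033, unemployed = 0.316,
                other = 0.476),
        three_plus = c(fulltime = 0.066, parttime = 0.028,
                       unemployed = 0.384, other = 0.522)))
      insurance <- .sample1(switch(stratum,
        one = c(private = 0.3505, public = 0.5757, other = 0.0738),
        two = c(private = 0.208, public = 0.719, other = 0.073),
        three_plus = c(private = 0.075, public = 0.861, other = 0.064)))
      coenroll_site <- if (runif(1) < r$p_coenroll)
        sample(setdiff(.cohort_sites, site), 1L) else NA_character_

      persons[[i]] <- list(
        person_uid = i, first_name = first, last_name = last,
        dob = as.numeric(dob), sex_at_birth = sex, ssn = ssn,
        race_ethnicity = race, state_of_residence = residence,
        resident = resident, transmission_risk = risk,
        hiv_dx_date = as.numeric(dx), enrollment_site = site,
        enrollment_date = as.numeric(enroll),
        coenroll_site = coenroll_site, stratum = stratum,
        suppressed = suppressed, engaged = engaged,
        aids_ever = aids, oi_at_aids = oi,
        housing = housing, employment = employment, insurance = insurance,
        comorbidities = if (length(comorb)) paste(comorb, collapse = ";")
          else NA_character_,
        vital_status = if (dead) "deceased" else "alive",
        death_date = as.numeric(death),
        withdrawal_date = as.numeric(withdrawal),
        transfer_date = as.numeric(transfer)
      )
    })
  }

  structure(
    list(
      persons = .bind_fast(persons, c("dob", "hiv_dx_date",
                                      "enrollment_date", "death_date",
                                      "withdrawal_date", "transfer_date")),
      labs = .bind_fast(labs, "collection_date"),
      visits = .bind_fast(visits, "visit_date"),
      art = .bind_fast(art, c("start_date", "end_date")),
      std = .bind_fast(std, "disease_date"),
      config = config
    ),
    class = "true_population"
  )
}

#' @export
print.true_population <- function(x, ...) {
  cat("<true_population> ", nrow(x$persons %||% tibble::tibble()),
      " person(s), ", nrow(x$labs %||% tibble::tibble()), " true lab(s)\n",
      sep = "")
  invisible(x)
}

# one edit-distance-1 typo: substitution, insertion or deletion
.apply_typo <- function(name) {
  letters_up <- strsplit(name, "")[[1]]
  n <- length(letters_up)
  op <- sample(c("sub", "ins", if (n > 2L) "del"), 1L)
  pos <- sample.int(n, 1L)
  new_char <- sample(setdiff(letters, tolower(letters_up[pos])), 1L)
  if (op == "sub") {
    letters_up[pos] <- if (pos == 1L) toupper(new_char) else new_char
  } else if (op == "ins") {
    letters_up <- append(letters_up, new_char, after = pos)
  } else {
    letters_up <- letters_up[-pos]
  }
  paste(letters_up, collapse = "")
}

#' Corrupt one identity per the error model
#'
#' Applies at most one perturbation per field, drawing from the current RNG
#' state; the input is untouched and a perturbation log is returned.
#'
#' @param identity one-row data frame (or named list) with `first_name`,
#'   `last_name`, `dob` (Date), `sex_at_birth`, `ssn`.
#' @param model an [error_model()].
#' @return list with `identity` (one-row tibble) and `log` (tibble
#'   `field`, `action`).
#' @export
corrupt_identity <- function(identity, model) {
  id <- tibble::as_tibble(identity[c("first_name", "last_name", "dob",
                                     "sex_at_birth", "ssn")])
  log <- list()
  # first name: nickname substitution, else typo
  fn <- id$first_name
  nick <- .nickname_map[names(.nickname_map) == fn]
  canon <- names(.nickname_map)[.nickname_map == fn]
  alt <- c(unname(nick), canon)[1]
  if (!is.na(alt) && runif(1) < model$p_nickname_substitution) {
    id$first_name <- alt
    log <- c(log, list(c("first_name", "nickname")))
  } else if (runif(1) < model$p_typo_per_name) {
    id$first_name <- .apply_typo(fn)
    log <- c(log, list(c("first_name", "typo")))
  }
  # last name: change outright, else typo
  if (runif(1) < model$p_last_name_change) {
    id$last_name <- sample(setdiff(.last_names, id$last_name), 1L)
    log <- c(log, list(c("last_name", "change")))
  } else if (runif(1) < model$p_typo_per_name) {
    id$last_name <- .apply_typo(id$last_name)
    log <- c(log, list(c("last_name", "typo")))
  }
  # DOB: day/month transposition when the day could be a month
  d <- lubridate::day(id$dob); mo <- lubridate::month(id$dob)
  if (d <= 12L && d != mo && runif(1) < model$p_dob_day_month_swap) {
    id$dob <- as.Date(sprintf("%04d-%02d-%02d", lubridate::year(id$dob),
                              d, mo))
    log <- c(log, list(c("dob", "day_month_swap")))
  }
  if (!is.na(id$ssn) && runif(1) < model$p_ssn_missing) {
    id$ssn <- NA_character_
    log <- c(log, list(c("ssn", "missing")))
  }
  log_df <- if (length(log)) {
    tibble::tibble(field = vapply(log, `[`, "", 1L),
                   action = vapply(log, `[`, "", 2L))
  } else tibble::tibble(field = character(0), action = character(0))
  list(identity = id, log = log_df)
}
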