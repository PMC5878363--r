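test_that("single-key matching is an exact join excluding empty keys", {
  a <- build_keys(make_key_input(make_identity()), "hiv11")
  b <- build_keys(make_key_input(make_identity(first = "Peter",
                                               last = "Jones",
                                               ssn = "987654321")), "hiv11")
  expect_equal(nrow(match_single_key(a, b, 2L)), 0L)

  # one cohort key colliding with two surveillance records -> two pairs
  surv2 <- make_key_input(dplyr::bind_rows(make_identity(),
                                           make_identity()))
  ks <- build_keys(surv2, "hiv11")
  expect_equal(nrow(match_single_key(a, ks, 2L)), 2L)
})

test_that("keyed matching equals the brute-force all-pairs oracle", {
  for (sd in 1:20) {
    cfg <- sim_config(15, seed = sd)
    reg <- emit_registries(generate_population(cfg))
    ck <- build_keys(dplyr::rename(reg$cohort$persons,
                                   native_id = "study_id"), "hiv11")
    sk <- build_keys(dplyr::rename(reg$surveillance$persons,
                                   native_id = "ehars_id"), "hiv11")
    fast <- purrr::map_dfr(1:11, ~ match_single_key(ck, sk, .x)) |>
      dplyr::arrange(.data$study_id, .data$ehars_id, .data$key_id)
    slow <- brute_force_candidates(ck, sk) |>
      dplyr::arrange(.data$study_id, .data$ehars_id, .data$key_id)
    expect_equal(as.data.frame(fast), as.data.frame(slow))
  }
})

test_that("the acceptance rule keeps >=2 keys or the SSN key alone", {
  cand <- tibble::tibble(
    study_id = c("C1", "C1", "C1", "C2", "C3"),
    ehars_id = c("E1", "E1", "E1", "E2", "E3"),
    key_id = c(2L, 3L, 5L, 10L, 1L))
  res <- merge_and_dedup(cand, min_keys = 2,
                         cohort_ids = c("C1", "C2", "C3"),
                         surveillance_ids = c("E1", "E2", "E3"))
  acc <- dplyr::filter(res$pairs, !.data$review_flag)
  expect_setequal(acc$study_id, c("C1", "C3"))   # C2: one weak key only
  expect_equal(acc$matched_key_ids[acc$study_id == "C1"][[1]], c(2, 3, 5))
  expect_true("C2" %in% res$unmatched_cohort)
  expect_true("E2" %in% res$unmatched_surveillance)
})

test_that("one-to-many conflicts resolve to the strongest pair, ties review", {
  cand <- tibble::tibble(
    study_id = c("C1", "C1", "C1"),
    ehars_id = c("E1", "E1", "E2"),
    key_id = c(2L, 3L, 9L))
  # E1 agrees on 2 keys, E2 on 1: E2 not accepted anyway under min_keys=2
  res <- merge_and_dedup(cand, min_keys = 2)
  expect_equal(res$pairs$ehars_id, "E1")
  expect_false(res$pairs$review_flag)

  tie <- tibble::tibble(
    study_id = "C1", ehars_id = c("E1", "E1", "E2", "E2"),
    key_id = c(2L, 3L, 2L, 3L))
  res2 <- merge_and_dedup(tie, min_keys = 2)
  expect_true(all(res2$pairs$review_flag))
})

test_that("linkage is invariant to input row order and min_keys is monotone", {
  res <- run_pipeline_fixture()
  cohort <- res$cohort
  surv <- res$registries$surveillance
  base <- link_records(cohort, surv)

  set.seed(31)
  shuf <- cohort
  perm <- sample(nrow(shuf$persons))
  shuf$persons <- shuf$persons[perm, ]
  shuffled <- link_records(shuf, surv)
  norm <- function(l) dplyr::arrange(l$pairs, .data$study_id)
  expect_equal(as.data.frame(norm(shuffled)), as.data.frame(norm(base)))

  loose <- link_records(cohort, surv, min_keys = 1)
  acc_base <- dplyr::filter(base$pairs, !.data$review_flag)
  acc_loose <- dplyr::filter(loose$pairs, !.data$review_flag)
  expect_true(all(paste(acc_base$study_id, acc_base$ehars_id) %in%
                    paste(acc_loose$study_id, acc_loose$ehars_id)))
})

test_that("zero corruption with complete identifiers links perfectly", {
  cfg <- sim_config(150, seed = 12,
                    error_model = error_model(0, 0, 0, 0, 0))
  res <- run_pipeline(cfg)
  expect_equal(res$evaluation$recall, 1.0)
  expect_equal(res$evaluation$precision, 1.0)
})

test_that("linkage evaluation implements the stated conventions", {
  truth <- tibble::tibble(study_id = sprintf("C%d", 1:10),
                          ehars_id = sprintf("E%d", 1:10))
  perfect <- structure(list(pairs = tibble::tibble(
    study_id = truth$study_id, ehars_id = truth$ehars_id,
    n_keys = 11L, matched_key_ids = list(1:11), review_flag = FALSE)),
    class = "link_result")
  ev <- evaluate_linkage(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  empty <- structure(list(pairs = perfect$pairs[0, ]),
                     class = "link_result")
  ev0 <- evaluate_linkage(empty, truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)     # zero-denominator convention
  expect_true(ev0$zero_denominator)
  expect_error(evaluate_linkage(perfect, truth[0, ]), "empty truth")

  # 10 accepted pairs, one wrong and one true pair missed
  mixed <- perfect
  mixed$pairs$ehars_id[10] <- "E99"
  evm <- evaluate_linkage(mixed, truth)
  expect_equal(evm$precision, 9 / 10)
  expect_equal(evm$recall, 9 / 10)
  expect_equal(nrow(evm$false_pairs), 1L)
  expect_equal(nrow(evm$missed_pairs), 1L)
})

test_that("STD events deduplicate by person, disease and date window", {
  events <- tibble::tibble(
    study_id = c("C1", "C1", "C1", "C1", "C2"),
    disease = c("gonorrhea", "gonorrhea", "syphilis", "chlamydia",
                "gonorrhea"),
    disease_date = as.Date(c("2014-02-01", "2014-02-01", "2014-02-01",
                             "2014-02-01", "2014-02-01")),
    origin = c("cohort", "surveillance", "cohort", "surveillance",
               "cohort"))
  out <- hivcarelink:::dedup_std_events(events)
  expect_equal(nrow(out), 4L)  # exact duplicate collapsed, diseases kept
  expect_equal(out$origin[out$study_id == "C1" &
                            out$disease == "gonorrhea"], "both")

  near <- tibble::tibble(
    study_id = "C1", disease = "gonorrhea",
    disease_date = as.Date(c("2014-02-01", "2014-02-10")),
    origin = c("cohort", "surveillance"))
  out2 <- hivcarelink:::dedup_std_events(near, dedup_window_days = 14)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$disease_date, as.Date("2014-02-01"))  # earlier kept
  out3 <- hivcarelink:::dedup_std_events(near, dedup_window_days = 5)
  expect_equal(nrow(out3), 2L)
})

test_that("surveillance-only STD diagnoses add to the cohort count", {
  res <- run_pipeline_fixture()
  linked <- res$std_events
  cohort_n <- nrow(hivcarelink:::dedup_std_events(
    dplyr::mutate(res$cohort$std, origin = "cohort")))
  surv_only <- sum(linked$origin == "surveillance")
  expect_equal(nrow(linked), cohort_n + surv_only)
  expect_gt(surv_only, 0L)
})
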