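test_that("cross-source lab duplicates collapse to the earlier date and cohort value", {
  labs <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "VL", 150, "cohort"),
    make_labs("C1", as.Date("2014-05-03"), "VL", 150, "surveillance"))
  out <- dedup_labs(labs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$collection_date, as.Date("2014-05-01"))
  expect_equal(out$origin, "cohort")

  # surveillance-first chronological order still keeps the cohort value
  labs2 <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "VL", 180, "surveillance"),
    make_labs("C1", as.Date("2014-05-03"), "VL", 170, "cohort"))
  out2 <- dedup_labs(labs2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$collection_date, as.Date("2014-05-01"))
  expect_equal(out2$value, 170)
  expect_equal(out2$origin, "cohort")
})

test_that("CD4 values outside tolerance never collapse", {
  labs <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "CD4", 410, "cohort"),
    make_labs("C1", as.Date("2014-05-01"), "CD4", 300, "surveillance"))
  expect_equal(nrow(dedup_labs(labs)), 2L)
  expect_equal(nrow(dedup_labs(
    labs, fuzzy_lab_rule(cd4_abs_tolerance = 150))), 1L)
  # different test types are never compared
  mixed <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "CD4", 150, "cohort"),
    make_labs("C1", as.Date("2014-05-01"), "VL", 150, "surveillance"))
  expect_equal(nrow(dedup_labs(mixed)), 2L)
})

test_that("VL matching uses the below-200 rule and the log10 band", {
  both_low <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "VL", 0, "cohort",
              below = TRUE),
    make_labs("C1", as.Date("2014-05-02"), "VL", 150, "surveillance"))
  expect_equal(nrow(dedup_labs(both_low)), 1L)
  straddle <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "VL", 190, "cohort"),
    make_labs("C1", as.Date("2014-05-02"), "VL", 210, "surveillance"))
  expect_equal(nrow(dedup_labs(straddle)), 1L)   # |log10 ratio| = .043
  apart <- dplyr::bind_rows(
    make_labs("C1", as.Date("2014-05-01"), "VL", 300, "cohort"),
    make_labs("C1", as.Date("2014-05-02"), "VL", 5000, "surveillance"))
  expect_equal(nrow(dedup_labs(apart)), 2L)
})

test_that("dedup recovers the true lab count for doubly-captured persons", {
  # true labs emitted to both registries uncorrupted: the merged union
  # must dedup back to exactly the true count
  res <- run_pipeline_fixture()
  truth <- res$registries$truth
  pop <- res$population
  both <- truth$labs |>
    dplyr::group_by(.data$person_uid) |>
    dplyr::summarise(all_both = all(.data$in_cohort & .data$in_surveillance),
                     n_true = dplyr::n()) |>
    dplyr::filter(.data$all_both)
  skip_if(nrow(both) == 0, "no doubly-captured person in fixture")
  tp <- truth$persons
  for (k in seq_len(nrow(both))) {
    uid <- both$person_uid[k]
    sid <- tp$study_id[tp$person_uid == uid]
    if (!is.na(tp$study_id_coenrolled[tp$person_uid == uid])) next
    merged_labs <- res$post$labs[res$post$labs$study_id == sid, ]
    # date jitter can land within the window of a distinct true lab, so
    # require the clean case: no surveillance jitter collisions
    pl <- pop$labs[pop$labs$person_uid == uid, ]
    gaps <- diff(sort(pl$collection_date))
    if (length(gaps) && min(as.numeric(gaps)) <= 10) next
    expect_equal(nrow(merged_labs), both$n_true[k])
  }
})

test_that("risk reconciliation follows the hierarchy without synthesis", {
  expect_equal(reconcile_risk(c("msm", "idu")), "idu")
  expect_equal(reconcile_risk(c("heterosexual", "msm")), "msm")
  expect_equal(reconcile_risk("other_unknown"), "other_unknown")
  expect_equal(reconcile_risk(c("msm_idu", "msm")), "msm_idu")
  expect_error(reconcile_risk(character(0)), "no documented")
  # order independence and idempotence under augmentation
  set.seed(3)
  for (i in 1:20) {
    s <- sample(default_risk_hierarchy(), sample(1:4, 1))
    r <- reconcile_risk(s)
    expect_equal(reconcile_risk(sample(s)), r)
    expect_equal(reconcile_risk(c(r, s)), r)
  }
})

test_that("person reconciliation applies the earliest-date and OR rules", {
  res <- run_pipeline_fixture()
  cohort <- res$cohort
  surv <- res$registries$surveillance
  link <- res$link
  merged <- res$post$persons
  pairs <- dplyr::filter(link$pairs, !.data$review_flag)
  j <- merged |>
    dplyr::inner_join(pairs, by = c("study_id", "ehars_id")) |>
    dplyr::left_join(cohort$persons, by = "study_id",
                     suffix = c("", "_c")) |>
    dplyr::left_join(surv$persons, by = "ehars_id", suffix = c("", "_s"))
  # earliest diagnosis date regardless of source
  expect_equal(j$hiv_dx_date,
               pmin(j$hiv_dx_date_c, j$hiv_dx_date_s, na.rm = TRUE))
  # deceased if either source says so
  expect_equal(j$vital_status == "deceased",
               j$vital_status_c == "deceased" |
                 j$vital_status_s == "deceased")
  # unmatched persons pass through with cohort provenance
  um <- merged[is.na(merged$ehars_id), ]
  expect_true(all(um$prov_hiv_dx_date %in% c("cohort", NA)))
})

test_that("a sex conflict is flagged for review, not overridden", {
  res <- run_pipeline_fixture()
  cohort <- res$cohort
  surv <- res$registries$surveillance
  pair1 <- dplyr::filter(res$link$pairs, !.data$review_flag)[1, ]
  i <- which(surv$persons$ehars_id == pair1$ehars_id)
  surv$persons$sex_at_birth[i] <-
    setdiff(c("male", "female"),
            surv$persons$sex_at_birth[i])[1]
  merged <- merge_linked(cohort, surv, res$link)
  row <- merged$persons[merged$persons$study_id == pair1$study_id, ]
  expect_true(row$review_sex_conflict)
  orig <- cohort$persons$sex_at_birth[
    cohort$persons$study_id == pair1$study_id]
  expect_equal(row$sex_at_birth, orig)
})

test_that("per-person lab counts are bounded by the source counts", {
  res <- run_pipeline_fixture()
  count_by <- function(df) {
    stats::setNames(as.integer(table(df$study_id)),
                    names(table(df$study_id)))
  }
  pre_n <- count_by(res$pre$labs)
  post_n <- count_by(res$post$labs)
  for (sid in names(pre_n)) {
    expect_gte(post_n[[sid]] %||% 0L, pre_n[[sid]])
  }
})

test_that("co-enrolled duplicates collapse onto the earliest enrollment", {
  reg <- run_pipeline_fixture()$registries
  raw <- reg$cohort
  dup_ids <- grep("B$", raw$persons$study_id, value = TRUE)
  skip_if(length(dup_ids) == 0, "no co-enrolled person in fixture")
  collapsed <- dedup_coenrollment(raw)
  expect_false(any(dup_ids %in% collapsed$persons$study_id))
  map <- attr(collapsed, "coenrollment_map")
  primary <- sub("B$", "", dup_ids[1])
  expect_equal(map$kept_study_id[map$study_id == dup_ids[1]], primary)
  # the duplicate's labs now ride on the kept record
  moved <- raw$labs$lab_id[raw$labs$study_id == dup_ids[1]]
  expect_true(all(moved %in%
                    collapsed$labs$lab_id[collapsed$labs$study_id ==
                                            primary]))
})
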