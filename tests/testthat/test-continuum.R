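w <- analysis_window()

test_that("eligibility keeps active persons and tallies exclusions", {
  m <- make_merged_person("C1")
  m2 <- make_merged_person("C2", withdrawal_date = as.Date("2013-05-01"))
  m3 <- make_merged_person("C3",
                           enrollment_date = w$end - 364)
  m4 <- make_merged_person("C4", vital_status = "deceased")
  m5 <- make_merged_person("C5", transfer_date = as.Date("2014-01-01"))
  all <- m
  all$persons <- dplyr::bind_rows(m$persons, m2$persons, m3$persons,
                                  m4$persons, m5$persons)
  out <- filter_eligible(all, w)
  expect_equal(out$study_id, "C1")
  excl <- attr(out, "exclusions")
  expect_equal(as.integer(excl[c("withdrawn", "followup_lt_1yr",
                                 "deceased", "transferred")]),
               c(1L, 1L, 1L, 1L))
  # exactly one year of follow-up qualifies
  m6 <- make_merged_person("C6", enrollment_date = w$end - 365)
  expect_equal(filter_eligible(m6, w)$study_id, "C6")
})

test_that("eligibility tally matches the generator's bookkeeping", {
  res <- run_pipeline_fixture()
  pop <- res$population$persons
  st <- compute_continuum(res$post, w)
  manual <- sum(
    as.numeric(w$end - res$post$persons$enrollment_date) >= 365 &
      !(!is.na(res$post$persons$withdrawal_date) &
          res$post$persons$withdrawal_date < w$start) &
      !(!is.na(res$post$persons$transfer_date) &
          res$post$persons$transfer_date < w$start) &
      res$post$persons$vital_status == "alive")
  expect_equal(nrow(st), manual)
})

test_that("loss to follow-up uses inclusive calendar-month arithmetic", {
  as_of <- as.Date("2015-06-15")
  expect_true(is_ltfu(as.Date("2013-12-15"), as_of, 18))   # exactly 18 mo
  expect_false(is_ltfu(as.Date("2014-01-15"), as_of, 18))  # 17 months
  deg <- is_ltfu(as.Date(character(0)), as_of, 18)
  expect_true(deg)
  expect_true(attr(deg, "degenerate"))
})

test_that("LTFU agrees with a brute-force scan over event dates", {
  set.seed(14)
  as_of <- as.Date("2015-06-15")
  cutoff <- as_of %m-% months(18)
  for (i in 1:500) {
    n <- sample(0:6, 1)
    dates <- as_of - sample(0:1200, n, replace = TRUE)
    got <- as.logical(is_ltfu(dates, as_of, 18))
    want <- if (n == 0) TRUE else all(dates <= cutoff)
    expect_identical(got, want)
  }
})

test_that("retention requires two encounters at least 90 days apart", {
  expect_true(retained_in_care(as.Date(c("2014-07-01", "2014-10-15")), w))
  expect_false(retained_in_care(as.Date(c("2014-07-01", "2014-09-01")), w))
  expect_true(retained_in_care(as.Date(c("2014-07-01", "2014-09-29")), w))
  expect_false(retained_in_care(as.Date(c("2014-07-01", "2014-09-28")), w))
  # same-day encounters count once; events outside the window are ignored
  expect_false(retained_in_care(rep(as.Date("2014-07-01"), 5), w))
  expect_false(retained_in_care(as.Date(c("2013-01-01", "2014-07-01")), w))
  # window endpoints are inclusive
  expect_true(retained_in_care(as.Date(c("2014-06-15", "2015-06-15")), w))
})

test_that("ART requires a prescription interval overlapping the window", {
  expect_true(on_art(as.Date("2013-01-01"), as.Date(NA), w))
  expect_false(on_art(as.Date("2013-01-01"), as.Date("2014-06-14"), w))
  expect_true(on_art(as.Date("2015-06-15"), as.Date(NA), w))
  expect_true(on_art(as.Date("2013-01-01"), as.Date("2014-06-15"), w))
  expect_false(on_art(as.Date("2015-06-16"), as.Date(NA), w))
  expect_false(on_art(as.Date(character(0)), as.Date(character(0)), w))
})

test_that("suppression follows the strict last-VL-below-200 rule", {
  vl <- function(...) make_labs("C1", ...)
  expect_true(virally_suppressed(
    vl(as.Date("2015-05-01"), "VL", 50), TRUE, TRUE, w))
  expect_false(virally_suppressed(
    vl(as.Date("2015-05-01"), "VL", 201), TRUE, TRUE, w))
  expect_true(virally_suppressed(
    vl(as.Date("2015-05-01"), "VL", 199), TRUE, TRUE, w))
  expect_false(virally_suppressed(
    vl(as.Date("2015-05-01"), "VL", 200), TRUE, TRUE, w))
  # only the last VL counts
  two <- vl(as.Date(c("2014-01-01", "2015-02-01")), "VL", c(50000, 40))
  expect_true(virally_suppressed(two, TRUE, TRUE, w))
  # undefined outside the RIC & ART & VL-on-file denominator
  expect_true(is.na(virally_suppressed(two, FALSE, TRUE, w)))
  expect_true(is.na(virally_suppressed(two, TRUE, FALSE, w)))
  expect_true(is.na(virally_suppressed(two[0, ], TRUE, TRUE, w)))
  # same-date tie: cohort value first, then the lower value
  tie <- dplyr::bind_rows(
    make_labs("C1", as.Date("2015-05-01"), "VL", 5000, "surveillance"),
    make_labs("C1", as.Date("2015-05-01"), "VL", 150, "cohort"))
  expect_true(virally_suppressed(tie, TRUE, TRUE, w))
  # a below-detection result counts as suppressed
  bd <- vl(as.Date("2015-05-01"), "VL", 0, below = TRUE)
  expect_true(virally_suppressed(bd, TRUE, TRUE, w))
})

test_that("ever-suppression scans enrollment through the reference date", {
  enr <- as.Date("2012-01-01"); as_of <- w$as_of
  expect_true(ever_suppressed(
    make_labs("C1", as.Date("2013-01-01"), "VL", 150), enr, as_of))
  expect_false(ever_suppressed(
    make_labs("C1", as.Date("2013-01-01"), "VL", 300), enr, as_of))
  expect_false(ever_suppressed(
    make_labs("C1", as.Date("2011-06-01"), "VL", 150), enr, as_of))
})

test_that("care-site classification follows the three-category rule", {
  expect_equal(classify_care_sites(c("A", "A", "A"), "A"), "one")
  expect_equal(classify_care_sites(character(0), "A"), "one")
  expect_equal(classify_care_sites(c("A", "B"), "A"), "two")
  expect_equal(classify_care_sites(c("B", "C"), "A"), "three_plus")
  expect_equal(classify_care_sites(c("A", "B", "B"), "A"), "two")
  expect_equal(classify_care_sites(c("B", "B"), "A"), "two")
  expect_equal(classify_care_sites("B", "A"), "two")
  expect_equal(classify_care_sites(c("A", "B", "C"), "A"), "three_plus")
})

test_that("adding data never downgrades ric, ever-vs or site category", {
  set.seed(22)
  site_rank <- c(one = 1, two = 2, three_plus = 3)
  for (i in 1:60) {
    n <- sample(0:6, 1)
    dates <- w$start + sample(0:365, n, replace = TRUE)
    facs <- sample(c("CS01", "CS02", "EX01"), n, replace = TRUE)
    labs <- make_labs("C1", dates, "VL",
                      sample(c(50, 5000), n, replace = TRUE),
                      facility = facs)
    extra_date <- w$start + sample(0:365, 1)
    labs2 <- dplyr::bind_rows(labs, make_labs(
      "C1", extra_date, "VL", sample(c(50, 5000), 1),
      facility = sample(c("CS01", "CS02", "EX02"), 1)))
    labs2$lab_id <- sprintf("LAB%03d", seq_len(nrow(labs2)))
    expect_gte(retained_in_care(labs2$collection_date, w),
               retained_in_care(labs$collection_date, w))
    expect_gte(ever_suppressed(labs2, w$start, w$as_of),
               ever_suppressed(labs, w$start, w$as_of))
    expect_gte(
      site_rank[[classify_care_sites(labs2$source_facility, "CS01")]],
      site_rank[[classify_care_sites(labs$source_facility, "CS01")]])
  }
})

test_that("suppression is defined exactly on the RIC & ART & VL subset", {
  res <- run_pipeline_fixture()
  st <- compute_continuum(res$post, w)
  has_vl <- res$post$labs |>
    dplyr::filter(.data$test_type == "VL", .data$collection_date <= w$end) |>
    dplyr::distinct(.data$study_id)
  should_have <- st$ric & st$on_art & st$study_id %in% has_vl$study_id
  expect_identical(!is.na(st$vs), should_have)
})

test_that("an empty surveillance contribution reproduces the pre-linkage result", {
  res <- run_pipeline_fixture()
  cohort <- res$cohort
  empty_surv <- surveillance_extract(
    persons = res$registries$surveillance$persons[0, ],
    labs = res$registries$surveillance$labs[0, ])
  empty_link <- link_records(cohort, empty_surv)
  post_empty <- merge_linked(cohort, empty_surv, empty_link)
  pre <- cohort_as_merged(cohort)
  ids <- pre$persons$study_id
  expect_identical(compute_continuum(post_empty, w, universe = ids),
                   compute_continuum(pre, w, universe = ids))
})
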