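test_that("percentages reproduce printed two- and one-decimal values", {
  expect_equal(proportion(2907, 4476), 64.95)
  expect_equal(proportion(0, 100), 0)
  expect_equal(proportion(2592, 2678), 96.79)
  expect_equal(proportion(234, 290, digits = 1), 80.7)
  expect_true(is.na(proportion(0, 0)))
  expect_equal(proportion_label(2907, 4476), "64.95")
  expect_equal(proportion_label(0, 100), "0.00")
  expect_error(proportion(5, 4))
})

test_that("kappa matches hand computation and the independent oracle", {
  expect_equal(cohen_kappa(matrix(c(45, 5, 5, 45), 2)), 0.8)
  expect_equal(cohen_kappa(diag(c(10, 20, 30))), 1)
  # independent margins: p_o == p_e -> 0
  expect_equal(cohen_kappa(matrix(c(9, 3, 3, 1), 2)), 0)
  expect_equal(cohen_kappa(matrix(c(7, 0, 0, 0), 2)), 1)  # degenerate
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
  # kappa stays in [-1, 1] and equals 1 iff off-diagonal mass is zero
  set.seed(8)
  for (i in 1:50) {
    m <- matrix(rpois(4, 5), 2)
    if (sum(m) == 0) next
    k <- cohen_kappa(m)
    expect_gte(k, -1); expect_lte(k, 1)
    if (sum(m) - sum(diag(m)) == 0) expect_equal(k, 1) else
      expect_lt(k, 1)
  }
  # cross-check against e1071's implementation on random tables
  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rpois(9, 8) + 1, 3)
    expect_equal(cohen_kappa(m), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("chi-square matches hand computation and is permutation-valid", {
  flat <- chi_square_test(matrix(c(10, 10, 20, 20), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  hand <- chi_square_test(matrix(c(10, 20, 20, 10), 2))
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-9)  # sum (O-E)^2/E
  expect_equal(hand$df, 1L)
  expect_equal(hand$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "cell")
  expect_equal(chi_square_test(matrix(c(3, 4), 2))$df, 0L)

  # permutation oracle: shuffle group labels of a 2x2 layout large enough
  # for the asymptotic distribution to apply
  tab <- matrix(c(520, 480, 480, 520), 2)   # rows = groups
  obs <- chi_square_test(tab)
  outcome <- rep(c(1, 0, 1, 0), c(520, 480, 480, 520))
  group <- rep(c(1, 2, 1, 2), c(520, 480, 480, 520))
  set.seed(100)
  n_perm <- 100000
  stat_perm <- numeric(n_perm)
  n1 <- sum(group == 1)
  succ_tot <- sum(outcome)
  tot <- length(outcome)
  for (b in seq_len(n_perm)) {
    s1 <- sum(sample.int(tot, n1) <= succ_tot)  # successes drawn by group 1
    m <- matrix(c(s1, succ_tot - s1, n1 - s1,
                  (tot - succ_tot) - (n1 - s1)), 2)
    e <- outer(rowSums(m), colSums(m)) / tot
    stat_perm[b] <- sum((m - e)^2 / e)
  }
  p_perm <- mean(stat_perm >= obs$statistic - 1e-9)
  expect_lt(abs(p_perm - obs$p_value), 0.01)
  # statistic invariant to row/column permutation
  expect_equal(chi_square_test(tab[2:1, 2:1])$statistic, obs$statistic)
})

test_that("rank-sum test matches exact enumeration and the normal limit", {
  same <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)

  # enumeration oracle over all C(6,3) = 20 assignments
  ranksum <- function(x, pool) sum(match(x, sort(pool)))
  pool <- 1:6
  combos <- utils::combn(6, 3)
  sums <- apply(combos, 2, function(ix) sum(ix))
  obs_sum <- ranksum(1:3, pool)
  p_one <- mean(sums <= obs_sum)
  expect_equal(p_one, 1 / 20)
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(res$p_value, 2 * p_one)
  expect_equal(res$statistic, 0)  # U of x: no y value below any x

  # normal approximation close to exact enumeration at n1 = n2 = 6
  x <- c(8, 21, 30, 31, 35, 39)
  y <- c(3, 5, 10, 13, 17, 23)
  exact_p <- wilcoxon_rank_sum(x, y)$p_value   # n1+n2 <= 12, tie-free
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(exact_p - approx_p), 0.01)
})

test_that("the cascade nests its denominators and hand-counts correctly", {
  all_in <- tibble::tibble(
    study_id = sprintf("C%d", 1:10), matched = TRUE, ric = TRUE,
    on_art = TRUE, vs = TRUE, ever_vs = TRUE, ltfu = FALSE,
    site_category = "one")
  c1 <- build_cascade(all_in)
  expect_equal(c1$pct, c(100, 100, 100, 100))

  mixed <- tibble::tibble(
    study_id = sprintf("C%d", 1:10), matched = TRUE,
    ric = c(rep(TRUE, 6), rep(FALSE, 4)),
    on_art = c(rep(TRUE, 5), FALSE, rep(TRUE, 4)),
    vs = c(TRUE, TRUE, FALSE, TRUE, NA, rep(NA, 5)),
    ever_vs = TRUE, ltfu = FALSE,
    site_category = rep(c("one", "two"), 5))
  cm <- build_cascade(mixed)
  expect_equal(cm$numerator, c(10, 6, 5, 3))
  expect_equal(cm$denominator, c(10, 10, 6, 4))
  # counts never increase along the cascade
  expect_true(all(diff(cm$numerator) <= 0))
  strat <- build_cascade(mixed, stratify_by_sites = TRUE)
  expect_equal(sum(strat$stratum == "overall"), 4L)
  expect_equal(strat$numerator[strat$stratum == "one" &
                                 strat$stage == "persons"], 5)
})

test_that("pre/post comparison flags identity and constructed shifts", {
  st <- tibble::tibble(
    study_id = sprintf("C%02d", 1:100), matched = TRUE,
    ric = rep(c(TRUE, FALSE), 50), on_art = TRUE,
    vs = NA, ever_vs = FALSE, ltfu = FALSE,
    site_category = rep(c("one", "two"), 50))
  idn <- compare_pre_post(st, st, variables = c("ric", "site_category"))
  expect_true(all(idn$summary$kappa == 1))
  expect_true(all(idn$summary$p_value == 1))

  post <- st
  flip <- which(!st$ric)[1:10]           # 10% flip false -> true
  post$ric[flip] <- TRUE
  cmp <- compare_pre_post(st, post, variables = "ric")
  pre_pct <- cmp$contingency$pre_pct[cmp$contingency$category == "TRUE"]
  post_pct <- cmp$contingency$post_pct[cmp$contingency$category == "TRUE"]
  expect_equal(post_pct - pre_pct, 10)
  expect_lt(cmp$summary$kappa, 1)

  bad <- st[-1, ]
  expect_error(compare_pre_post(st, bad, "ric"), "C01")
})

test_that("report percentages recompute from stored numerators exactly", {
  res <- run_pipeline_fixture()
  casc <- res$comparison$cascade_post
  expect_equal(casc$pct,
               proportion(casc$numerator, casc$denominator))
  cont <- res$comparison$contingency
  expect_equal(cont$pre_pct, proportion(cont$pre_n, cont$pre_total))
})
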