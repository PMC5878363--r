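#' Percentage with explicit numerator and denominator
#'
#' @param numerator,denominator non-negative counts (vectorized);
#'   `numerator <= denominator` required.
#' @param digits decimals the percentage is reported to (2 by default; 1
#'   where a table prints 1).
#' @return numeric percentage `100 * numerator / denominator` rounded to
#'   `digits`; `NA_real_` is the explicit undefined marker for a zero
#'   denominator.
#' @export
#' @examples
#' proportion(2907, 4476) # 64.95
proportion <- function(numerator, denominator, digits = 2L) {
  stopifnot(all(numerator >= 0), all(denominator >= 0),
            all(numerator <= denominator | denominator == 0))
  out <- round(100 * numerator / denominator, digits)
  out[denominator == 0] <- NA_real_
  out
}

#' Render a percentage cell as fixed-decimal text
#' @inheritParams proportion
#' @return character, e.g. `"64.95"`; `""` when undefined.
#' @export
proportion_label <- function(numerator, denominator, digits = 2L) {
  p <- proportion(numerator, denominator, digits)
  ifelse(is.na(p), "", sprintf(paste0("%.", digits, "f"), p))
}

#' Cohen's kappa for a square agreement table
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/total` and expected agreement
#' `p_e = sum(row_i * col_i) / total^2`. A fully degenerate table (all
#' mass in one cell, `p_e = 1`) returns 1 by convention.
#'
#' @param table square numeric matrix (or table) of cross-classified
#'   counts.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("kappa requires a square table")
  total <- sum(m)
  if (total <= 0) stop("kappa requires a non-empty table")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (1 - p_e == 0) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Agreement band label for a kappa value
#'
#' Reporting labels only: strong (>= .60), moderate (.40–.59), poor to
#' fair (< .40).
#' @param kappa numeric vector.
#' @return character vector of labels.
#' @export
kappa_band <- function(kappa) {
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    kappa >= 0.60 ~ "strong",
    kappa >= 0.40 ~ "moderate",
    TRUE ~ "poor to fair"
  )
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = (r-1)(c-1)` and the
#' upper-tail chi-square p value; no continuity correction. A table with a
#' single row or column (no contrast) returns statistic 0, df 0, p 1. Any
#' expected cell of exactly zero is an error naming the cell.
#'
#' @param table matrix of non-negative counts.
#' @return list `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (sum(m) <= 0) stop("chi-square requires a non-empty table")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1L, ]
    stop("expected count of zero in cell (", bad[1L], ",", bad[2L], ")")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact enumeration when `n1 + n2 <= 12` and the data
#' are tie-free, otherwise the normal approximation with tie correction
#' (no continuity correction). Two identical constant samples have no
#' rank information and return p = 1 by convention.
#'
#' @param x,y non-empty numeric samples.
#' @return list `statistic` (Mann-Whitney U of `x`), `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Paper-style p-value label
#' @param p numeric vector of p values.
#' @return character: `"<.001"` below 0.001, `">.99"` above 0.99, else
#'   three decimals without the leading zero (e.g. `".016"`).
#' @export
format_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "<.001",
    p > 0.99 ~ ">.99",
    TRUE ~ sub("^0", "", sprintf("%.3f", p))
  )
}

.cascade_one <- function(status, label) {
  n <- nrow(status)
  ric_n <- sum(status$ric)
  ric_art_n <- sum(status$ric & status$on_art)
  vs_den <- sum(!is.na(status$vs))
  vs_n <- sum(status$vs, na.rm = TRUE)
  tibble::tibble(
    stratum = label,
    stage = c("persons", "ric", "on_art", "vs"),
    numerator = c(n, ric_n, ric_art_n, vs_n),
    denominator = c(n, n, ric_n, vs_den),
    pct = proportion(c(n, ric_n, ric_art_n, vs_n),
                     c(n, n, ric_n, vs_den))
  )
}

#' Nested care-continuum cascade counts
#'
#' Stages persons -> retained in care -> retained and on ART -> virally
#' suppressed; each stage's denominator is the prior stage's numerator
#' (the suppression denominator additionally requires a VL on file, the
#' subset where suppression is defined). Every percentage carries its
#' numerator and denominator.
#'
#' @param status a [compute_continuum()] tibble.
#' @param stratify_by_sites also break the cascade down by care-site
#'   category.
#' @return tibble `stratum`, `stage`, `numerator`, `denominator`, `pct`.
#' @export
build_cascade <- function(status, stratify_by_sites = FALSE) {
  out <- .cascade_one(status, "overall")
  if (stratify_by_sites) {
    for (s in c("one", "two", "three_plus")) {
      out <- dplyr::bind_rows(
        out, .cascade_one(status[status$site_category == s, ], s))
    }
  }
  out
}

#' Compare pre- and post-linkage continuum outcomes
#'
#' For each outcome variable, cross-classifies the same persons pre versus
#' post (paired agreement, Cohen's kappa) and tests the pre/post outcome
#' distributions with an independent chi-square (the suppression variable
#' is compared over its defined subsets, which may differ pre/post).
#' Significance is flagged at p < .05.
#'
#' @param pre,post [compute_continuum()] tibbles over the same person
#'   universe.
#' @param variables outcome columns to compare.
#' @return list of class `comparison_report`: `summary` (one row per
#'   variable: kappa, band, chi-square, p), `contingency` (tidy per
#'   category counts), `cascade_pre`, `cascade_post`.
#' @export
compare_pre_post <- function(pre, post,
                             variables = c("ric", "on_art", "vs",
                                           "ever_vs", "ltfu",
                                           "site_category")) {
  if (!setequal(pre$study_id, post$study_id)) {
    diff_ids <- c(setdiff(pre$study_id, post$study_id),
                  setdiff(post$study_id, pre$study_id))
    stop("pre/post universes differ; offending IDs: ",
         paste(head(diff_ids, 10L), collapse = ", "))
  }
  pre <- dplyr::arrange(pre, .data$study_id)
  post <- dplyr::arrange(post, .data$study_id)

  rows <- list(); cont <- list()
  for (v in variables) {
    a <- pre[[v]]; b <- post[[v]]
    ok <- !is.na(a) & !is.na(b)
    lev <- sort(unique(c(a[ok], b[ok])))
    kap <- if (any(ok)) {
      cohen_kappa(table(factor(a[ok], lev), factor(b[ok], lev)))
    } else NA_real_
    # marginal pre/post distribution test over the defined values
    pre_counts <- table(factor(a[!is.na(a)], lev))
    post_counts <- table(factor(b[!is.na(b)], lev))
    chi <- chi_square_test(rbind(pre = pre_counts, post = post_counts))
    rows[[v]] <- tibble::tibble(
      variable = v, kappa = kap, kappa_band = kappa_band(kap),
      chi_square = chi$statistic, df = chi$df, p_value = chi$p_value,
      p_label = format_p(chi$p_value),
      significant = !is.na(chi$p_value) & chi$p_value < 0.05
    )
    cont[[v]] <- tibble::tibble(
      variable = v, category = as.character(lev),
      pre_n = as.integer(pre_counts), pre_total = sum(pre_counts),
      post_n = as.integer(post_counts), post_total = sum(post_counts),
      pre_pct = proportion(as.integer(pre_counts), sum(pre_counts)),
      post_pct = proportion(as.integer(post_counts), sum(post_counts))
    )
  }
  structure(list(
    summary = dplyr::bind_rows(rows),
    contingency = dplyr::bind_rows(cont),
    cascade_pre = build_cascade(pre),
    cascade_post = build_cascade(post)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$summary)
  invisible(x)
}
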