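#' Nonparametric toolbox for cohort comparisons
#'
#' The three tests used for the study's cohort statistics: a two-sided
#' Mann-Whitney rank-sum test for age-group comparisons, Spearman rank
#' correlation for between-medium associations, and a Kolmogorov-Smirnov
#' normality screen.  All return a common `cohort_test` record with the
#' statistic, two-sided p value, a method label recording the exact
#' computational path taken, and the sample sizes.
#'
#' @name cohort_stats
NULL

new_cohort_test <- function(statistic, p_value, method, n) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("<%s>\n  statistic = %.6g, p = %.4g, n = %s\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Compares two independent samples by ranks.  With both sample sizes at
#' most 20 and no ties, the exact null distribution of U is used; larger
#' samples (or ties, which are always mid-ranked) use the normal
#' approximation with tie correction and continuity correction.  The
#' `method` field records which path was taken.
#'
#' @param a,b Numeric samples, both nonempty.
#' @param method `"auto"` (default), or force `"exact"` / `"approx"`.
#' @return A `cohort_test` with the U statistic for the first sample.
#' @export
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
rank_sum_compare <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be nonempty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(method,
    auto = max(length(a), length(b)) <= 20 && !has_ties,
    exact = TRUE,
    approx = FALSE)
  if (use_exact && has_ties)
    stop("exact Mann-Whitney p values are unavailable with ties; ",
         "use method = \"approx\"")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact))
  label <- if (use_exact) "Mann-Whitney U (exact)"
           else "Mann-Whitney U (normal approximation, mid-ranked ties)"
  new_cohort_test(wt$statistic, wt$p.value, label,
                  c(length(a), length(b)))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the
#' t approximation (exact p values are not defined under ties).  A
#' constant input has no rank ordering, so the coefficient is undefined
#' and the call errors rather than silently returning 0.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A `cohort_test` with `statistic` = rho in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3))$statistic   # 0.6
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length (got ", length(x), " and ",
         length(y), ")")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("Spearman correlation is undefined for a constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  new_cohort_test(ct$estimate, ct$p.value,
                  "Spearman rank correlation (average ranks, t approximation)",
                  length(x))
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the data against a normal distribution with the
#' sample mean and standard deviation.  Estimating the parameters from the
#' same sample makes the nominal p value conservative (the Lilliefors
#' caveat); the method label records this.  Used as the study used it: a
#' screen deciding whether to fall back to rank-based tests.
#'
#' @param values Numeric vector, `n >= 5`, non-constant.
#' @return A `cohort_test` with the KS D statistic.
#' @export
ks_normality <- function(values) {
  if (length(values) < 5)
    stop("need at least 5 observations (got ", length(values), ")")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("values are constant; normality testing is meaningless")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s))
  new_cohort_test(kt$statistic, kt$p.value,
                  "One-sample Kolmogorov-Smirnov vs fitted normal (Lilliefors caveat: nominal p is conservative)",
                  length(values))
}

#' Cohort statistics report
#'
#' Runs the study's comparison battery on a cohort: for every
#' concentration variable, a KS normality screen (pooled) and a two-sided
#' rank-sum comparison between the two age groups.
#'
#' @param cohort A `metal_cohort`.
#' @return A tibble with columns `variable`, `grouping`, `method`,
#'   `statistic`, `p_value`.
#' @export
cohort_stats_report <- function(cohort) {
  stopifnot(is.list(cohort), !is.null(cohort$concentrations))
  conc <- dplyr::mutate(
    cohort$concentrations,
    variable = paste(.data$metal, .data$medium, sep = "_"))
  rows <- lapply(unique(conc$variable), function(v) {
    sub <- conc[conc$variable == v, ]
    yng <- sub$value[sub$age_group == "y3_6"]
    old <- sub$value[sub$age_group == "y7_12"]
    out <- list()
    if (stats::sd(sub$value) > 0) {
      ks <- ks_normality(sub$value)
      out$ks <- tibble::tibble(variable = v, grouping = "pooled",
                               method = ks$method, statistic = ks$statistic,
                               p_value = ks$p_value)
    }
    if (length(unique(c(yng, old))) > 1) {
      rs <- rank_sum_compare(yng, old, method = "approx")
      out$rs <- tibble::tibble(variable = v, grouping = "y3_6 vs y7_12",
                               method = rs$method, statistic = rs$statistic,
                               p_value = rs$p_value)
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}
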