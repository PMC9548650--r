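#' Assign a subject to an age group
#'
#' Young: 18 <= age < 40; Middle: 40 <= age < 60; Old: 60 <= age <= 88.
#' The cohort design covers ages 18-88; ages outside that range are rejected.
#'
#' @param age age in years (numeric scalar).
#' @return `"Young"`, `"Middle"` or `"Old"`.
#' @export
assign_group <- function(age) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age))
    stop("age must be a numeric scalar")
  if (age < 18 || age > 88)
    stop("age ", age, " outside the supported range [18, 88]")
  if (age < 40) "Young" else if (age < 60) "Middle" else "Old"
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant.
#' @return list with `r`, `p` (two-sided, from t = r*sqrt((n-2)/(1-r^2)) on
#'   n-2 degrees of freedom) and `n`.
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3, got ", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation between age and HSFC at one level
#'
#' The aging analysis: Pearson correlation (with two-sided p) between
#' subjects' ages and their HSFC values at the hemisphere level or within
#' one sub-module.
#'
#' @param records HSFC records (`subject_id`, `level`, `hsfc`), e.g. from
#'   [hsfc_cohort].
#' @param meta metadata data.frame with `subject_id` and `age`.
#' @param level one of the HSFC levels present in `records`.
#' @return list with `r`, `p`, `n`.
#' @export
age_hsfc_correlation <- function(records, meta, level = "hemisphere") {
  level <- match.arg(level, .HSFC_LEVELS)
  recs <- records[records$level == level, ]
  m <- match(recs$subject_id, meta$subject_id)
  ok <- !is.na(m) & !is.na(recs$hsfc)
  if (sum(ok) < 3L)
    stop("need >= 3 subjects with both HSFC at level '", level,
         "' and age; got ", sum(ok))
  pearson_r_p(meta$age[m[ok]], recs$hsfc[ok])
}

#' Chi-square test of independence on a 2 x K contingency table
#'
#' Classic Pearson chi-square without continuity correction, as used for the
#' sex-by-age-group demographic comparison.
#'
#' @param table a 2 x K matrix of counts with positive row and column sums.
#' @return list with `chi2`, `df` (= K - 1), `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("need a 2 x K table with K >= 2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total")
  ct <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Computes the F-test for equality of K group means from (mean, SD, n)
#' summaries alone: the between-group sum of squares from the group means
#' against the grand mean, and the within-group sum of squares as
#' sum((n_i - 1) * s_i^2). Used for the age-by-group comparison, where only
#' the published summary statistics are available.
#'
#' @param means,sds,ns numeric vectors of length K >= 2 (all `ns >= 2`,
#'   all `sds >= 0`).
#' @return list with `F`, `df1` (= K - 1), `df2` (= sum(ns) - K), `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k)
    stop("means, sds, ns must have equal length >= 2")
  if (any(sds < 0)) stop("negative SD")
  if (any(ns < 2)) stop("every group needs n >= 2")
  grand <- sum(ns * means) / sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- sum(ns) - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Demographic comparison table across age groups
#'
#' Convenience wrapper reproducing the standard cohort table: a chi-square
#' test of sex by age group and an F-test of age by group (from per-group
#' summaries of the raw ages).
#'
#' @param meta metadata data.frame with `subject_id`, `age`, `sex`.
#' @return list with per-group `n`, `age_mean`, `age_sd`, `sex_counts`
#'   (male/female by group), and the `sex_test` / `age_test` results.
#' @export
demographics <- function(meta) {
  stopifnot(all(c("age", "sex") %in% names(meta)))
  group <- factor(vapply(meta$age, assign_group, character(1L)),
                  levels = c("Young", "Middle", "Old"))
  sex_counts <- table(factor(meta$sex, levels = c("male", "female")), group)
  ns <- as.vector(table(group))
  means <- tapply(meta$age, group, mean)
  sds <- tapply(meta$age, group, stats::sd)
  list(n = ns,
       age_mean = as.vector(means), age_sd = as.vector(sds),
       sex_counts = unclass(sex_counts),
       sex_test = chi_square_independence(as.matrix(sex_counts)),
       age_test = anova_from_summary(as.vector(means), as.vector(sds), ns))
}

#' Cross-parcellation HSFC robustness
#'
#' Pearson correlation, over subjects, between HSFC values computed from two
#' different parcellation schemes of the same signals (e.g. a fine scheme and
#' its coarsened counterpart). High correlation indicates HSFC is not
#' specific to one parcellation.
#'
#' @param hsfc_a,hsfc_b HSFC record data.frames (`subject_id`, `level`,
#'   `hsfc`).
#' @param level HSFC level to compare (default `"hemisphere"`).
#' @return list with `r`, `p`, `n` (number of shared subjects).
#' @export
cross_template_correlation <- function(hsfc_a, hsfc_b, level = "hemisphere") {
  level <- match.arg(level, .HSFC_LEVELS)
  a <- hsfc_a[hsfc_a$level == level, ]
  b <- hsfc_b[hsfc_b$level == level, ]
  shared <- intersect(a$subject_id, b$subject_id)
  if (length(shared) < 3L)
    stop("record sets share only ", length(shared),
         " subject(s) at level '", level, "'; need >= 3")
  pearson_r_p(a$hsfc[match(shared, a$subject_id)],
              b$hsfc[match(shared, b$subject_id)])
}
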