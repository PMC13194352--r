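# Group-comparison statistics: Student's t (raw and summary form), Pearson
# chi-square / Fisher, Shapiro-Wilk, Levene, Pearson correlation, and
# age-stratified subgroup analysis with a group x stratum interaction.

#' Two-sample pooled-variance Student's t-test
#'
#' Accepts either raw vectors (`group1`, `group2`) or summary statistics
#' (mean, SD, n per group); both forms use the identical pooled formula, so
#' summaries computed from the same vectors reproduce the raw-data statistic
#' exactly. The sign convention is group2 minus group1 (control first, ASD
#' second reproduces the published table).
#'
#' @param group1,group2 raw numeric vectors (optional).
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics (used when raw vectors
#'   are absent).
#' @param variable label carried into the result.
#' @return a one-row data.frame of class `group_comparison`: per-group mean,
#'   sd, n, the t statistic, df, and two-sided p. A zero-variance pair with
#'   unequal means yields an infinite statistic flagged via `degenerate`.
#' @export
#' @examples
#' two_sample_t(mean1 = 28.20, sd1 = 8.91, n1 = 50,
#'              mean2 = 39.65, sd2 = 8.37, n2 = 50)  # t = 6.623
two_sample_t <- function(group1 = NULL, group2 = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         variable = NA_character_) {
  if (!is.null(group1) && !is.null(group2)) {
    n1 <- length(group1); n2 <- length(group2)
    mean1 <- mean(group1); mean2 <- mean(group2)
    sd1 <- stats::sd(group1); sd2 <- stats::sd(group2)
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, logical(1))))
    stop("supply either raw vectors or the full set of summary statistics")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- FALSE
  if (se == 0) {
    tstat <- if (mean2 == mean1) 0 else sign(mean2 - mean1) * Inf
    degenerate <- !is.finite(tstat)
  } else tstat <- (mean2 - mean1) / se
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
  structure(data.frame(variable = variable, mean1 = mean1, sd1 = sd1, n1 = n1,
                       mean2 = mean2, sd2 = sd2, n2 = n2, statistic = tstat,
                       df = df, p = p, test = "t", degenerate = degenerate),
            class = c("group_comparison", "data.frame"))
}

#' Pearson chi-square (or Fisher's exact) test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1; Fisher's exact
#' test is substituted automatically when any expected count is below 5.
#'
#' @param a,b first row counts (e.g. control male/female).
#' @param c,d second row counts.
#' @return one-row data.frame: `statistic` (chi-square; NA for Fisher), `df`,
#'   `p`, `test`.
#' @export
#' @examples
#' chi_square_2x2(28, 22, 27, 23)  # chi-square = 0.04
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("table has a zero margin")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    return(data.frame(statistic = NA_real_, df = NA_integer_, p = p,
                      test = "fisher"))
  }
  n <- sum(m)
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  data.frame(statistic = stat, df = 1L,
             p = stats::pchisq(stat, 1, lower.tail = FALSE),
             test = "chi-square")
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant sample")
  r <- stats::shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Levene's test for homogeneity of variance (two groups)
#'
#' One-way ANOVA on absolute deviations from the group center (mean by
#' default, median for the Brown-Forsythe variant), referenced to an F
#' distribution.
#'
#' @param x,y numeric samples.
#' @param center "mean" (classic Levene) or "median".
#' @return list with `statistic`, `df`, `p`.
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("constant inputs")
  cf <- if (center == "mean") mean else stats::median
  d <- c(abs(x - cf(x)), abs(y - cf(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  a <- stats::anova(stats::lm(d ~ g))
  list(statistic = a[["F value"]][1], df = c(a$Df[1], a$Df[2]),
       p = a[["Pr(>F)"]][1])
}

#' Pearson correlation with t-based two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(r$estimate), p = r$p.value, n = length(x))
}

#' Age-stratified subgroup analysis with interaction test
#'
#' Splits the cohort at `age_cut` (below vs at-or-above), runs the
#' group-comparison t-test within each stratum, and tests the group x stratum
#' interaction in the linear model `value ~ group * stratum`.
#'
#' @param cohort data.frame with the group, age and index columns.
#' @param variable index column name to analyse.
#' @param age_cut stratum boundary in years (default 8: 4--7 vs 8--12).
#' @param group_col,age_col column names (defaults `group`, `age_yr`).
#' @return list with `strata` (named list of `group_comparison` rows) and
#'   `interaction_p`.
#' @export
subgroup_analysis <- function(cohort, variable, age_cut = 8,
                              group_col = "group", age_col = "age_yr") {
  stratum <- ifelse(cohort[[age_col]] < age_cut, "younger", "older")
  g <- factor(cohort[[group_col]])
  if (nlevels(g) != 2) stop("exactly two groups required")
  tab <- table(stratum, g)
  if (nrow(tab) < 2 || any(tab == 0))
    stop("both strata must contain both groups")
  lv <- levels(g)
  strata <- lapply(split(seq_len(nrow(cohort)), stratum), function(i) {
    two_sample_t(cohort[[variable]][i][g[i] == lv[1]],
                 cohort[[variable]][i][g[i] == lv[2]], variable = variable)
  })
  fit <- stats::lm(cohort[[variable]] ~ g * factor(stratum))
  cf <- summary(fit)$coefficients
  inter <- grep(":", rownames(cf))
  list(strata = strata, interaction_p = unname(cf[inter, "Pr(>|t|)"]))
}

#' Group comparison table for a subject-level cohort
#'
#' Runs the published analysis layout over a cohort table: Student's t for
#' every continuous variable (control as group 1, ASD as group 2) and the
#' chi-square test for sex.
#'
#' @param cohort data.frame with `group`, demographic and index columns.
#' @param variables continuous columns to compare; defaults to all numeric
#'   columns except identifiers.
#' @return data.frame, one row per variable (sex row uses the chi-square).
#' @export
compare_groups <- function(cohort, variables = NULL) {
  ctrl <- cohort[cohort$group == "control", ]
  asd <- cohort[cohort$group == "ASD", ]
  if (!nrow(ctrl) || !nrow(asd))
    stop("both groups must be present; single-group input: tests skipped")
  if (is.null(variables)) {
    num <- vapply(cohort, is.numeric, logical(1))
    variables <- setdiff(names(cohort)[num], c("n_beats"))
    variables <- variables[vapply(variables, function(v)
      !all(is.na(ctrl[[v]])) && !all(is.na(asd[[v]])), logical(1))]
  }
  rows <- lapply(variables, function(v)
    two_sample_t(ctrl[[v]], asd[[v]], variable = v))
  out <- do.call(rbind, rows)
  if ("sex" %in% names(cohort)) {
    cs <- chi_square_2x2(sum(ctrl$sex == "M"), sum(ctrl$sex == "F"),
                         sum(asd$sex == "M"), sum(asd$sex == "F"))
    sex_row <- out[1, ]
    sex_row[] <- NA
    sex_row$variable <- "sex_male"
    sex_row$mean1 <- mean(ctrl$sex == "M"); sex_row$mean2 <- mean(asd$sex == "M")
    sex_row$n1 <- nrow(ctrl); sex_row$n2 <- nrow(asd)
    sex_row$statistic <- cs$statistic; sex_row$df <- cs$df
    sex_row$p <- cs$p; sex_row$test <- cs$test
    sex_row$degenerate <- FALSE
    out <- rbind(out, sex_row)
  }
  rownames(out) <- NULL
  out
}
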