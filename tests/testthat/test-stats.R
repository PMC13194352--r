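# Group-comparison statistics.

test_that("summary-statistic t reproduces the published table rows", {
  t1 <- two_sample_t(mean1 = 28.20, sd1 = 8.91, n1 = 50,
                     mean2 = 39.65, sd2 = 8.37, n2 = 50)
  expect_equal(round(t1$statistic, 3), 6.623)
  expect_equal(t1$df, 98)
  expect_lt(t1$p, 0.001)
  t2 <- two_sample_t(mean1 = 34.47, sd1 = 2.99, n1 = 50,
                     mean2 = 37.53, sd2 = 2.39, n2 = 50)
  expect_equal(round(t2$statistic, 3), 5.653)
  t3 <- two_sample_t(mean1 = 243.54, sd1 = 26.25, n1 = 50,
                     mean2 = 238.50, sd2 = 29.72, n2 = 50)
  expect_equal(round(t3$statistic, 3), -0.899)
})

test_that("raw-vector and summary forms agree to 1e-9", {
  set.seed(42)
  for (i in 1:10) {
    x <- stats::rnorm(30 + i, 10, 3)
    y <- stats::rnorm(45 - i, 12, 2.5)
    raw <- two_sample_t(x, y)
    summ <- two_sample_t(mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
                         mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y))
    expect_lt(abs(raw$statistic - summ$statistic), 1e-9)
    expect_lt(abs(raw$p - summ$p), 1e-9)
  }
})

test_that("degenerate variance cases are handled explicitly", {
  expect_equal(two_sample_t(rep(5, 10), rep(5, 12))$statistic, 0)
  res <- two_sample_t(rep(5, 10), rep(7, 12))
  expect_true(is.infinite(res$statistic) && res$degenerate)
  expect_error(two_sample_t(1:5, 3), "n >= 2")
})

test_that("chi-square without continuity correction matches the sex table", {
  cs <- chi_square_2x2(28, 22, 27, 23)
  expect_equal(round(cs$statistic, 2), 0.04)
  expect_equal(cs$statistic, 100 * (28 * 23 - 22 * 27)^2 / (55 * 45 * 50 * 50),
               tolerance = 1e-12)
  expect_equal(round(cs$p, 3), 0.841)
  # agreement with the base implementation
  ref <- stats::chisq.test(matrix(c(28, 22, 27, 23), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(cs$statistic, unname(ref$statistic))
  # transposition invariance
  expect_equal(chi_square_2x2(28, 27, 22, 23)$statistic, cs$statistic)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
})

test_that("Fisher's exact test is substituted for small expected counts", {
  res <- chi_square_2x2(2, 8, 9, 1)
  expect_equal(res$test, "fisher")
  expect_equal(res$p, stats::fisher.test(matrix(c(2, 8, 9, 1), 2,
                                                byrow = TRUE))$p.value)
  expect_error(chi_square_2x2(0, 0, 5, 5), "zero margin")
})

test_that("Shapiro-Wilk is calibrated under normality and powered against skew", {
  set.seed(7)
  p_norm <- replicate(100, shapiro_wilk(stats::rnorm(5000))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, shapiro_wilk(stats::rexp(100))$p)
  expect_gte(mean(p_exp < 0.05), 0.90)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(1:2), "3 <= n")
})

test_that("Levene's test calibration, power, and degenerate case", {
  set.seed(8)
  p_null <- replicate(100, {
    levene_test(stats::rnorm(50), stats::rnorm(50))$p
  })
  expect_gte(mean(p_null > 0.05), 0.88)
  p_alt <- replicate(100, {
    levene_test(stats::rnorm(50, sd = 3), stats::rnorm(50, sd = 1))$p
  })
  expect_gte(mean(p_alt < 0.05), 0.90)
  x <- stats::rnorm(20)
  expect_equal(levene_test(x, x)$statistic, 0)
  expect_error(levene_test(rep(1, 5), rep(2, 5)), "constant")
})

test_that("Pearson correlation: exact, recovered, and null behaviour", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_error(pearson_r(x, rep(3, 20)), "constant")

  # generator correlation 0.72 recovered inside Fisher-z bounds at n = 50
  hits <- vapply(1:100, function(s) {
    tab <- generate_cohort_indices(asd_cohort_spec(n_per_group = 50), seed = s)
    asd <- tab[tab$group == "ASD", ]
    r <- pearson_r(asd$s2_split_ms, asd$asd_size_mm)$r
    r >= 0.52 && r <= 0.85
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  set.seed(9)
  null_ok <- replicate(100, abs(pearson_r(stats::rnorm(50),
                                          stats::rnorm(50))$r) < 0.28)
  expect_gte(mean(null_ok), 0.90)
})

test_that("subgroup analysis tests strata and the age interaction", {
  make_cohort <- function(delta_young, delta_old, seed) {
    set.seed(seed)
    n <- 50
    data.frame(
      group = rep(c("control", "ASD"), each = 2 * n),
      age_yr = rep(rep(c(5, 10), each = n), 2),
      s2_split_ms = c(stats::rnorm(n, 28, 9), stats::rnorm(n, 28, 9),
                      stats::rnorm(n, 28 + delta_young, 9),
                      stats::rnorm(n, 28 + delta_old, 9)))
  }
  # equal group effect in both strata: interaction null holds
  p_null <- vapply(1:50, function(s)
    subgroup_analysis(make_cohort(10, 10, s), "s2_split_ms")$interaction_p,
    numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)
  # effect confined to one stratum: interaction detected
  p_alt <- vapply(1:50, function(s)
    subgroup_analysis(make_cohort(10, 0, s), "s2_split_ms")$interaction_p,
    numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.80)
  # each stratum's own comparison is returned
  res <- subgroup_analysis(make_cohort(12, 12, 1), "s2_split_ms")
  expect_named(res$strata, c("older", "younger"))
  expect_lt(res$strata$younger$p, 0.05)

  bad <- make_cohort(10, 10, 2)
  bad <- bad[!(bad$group == "ASD" & bad$age_yr == 5), ]
  expect_error(subgroup_analysis(bad, "s2_split_ms"), "both strata")
})

test_that("compare_groups reproduces the table layout on a drawn cohort", {
  tab <- generate_cohort_indices(asd_cohort_spec(), seed = 2)
  cmp <- compare_groups(tab)
  expect_true(all(c("s2_split_ms", "s1s2_rr_pct", "sex_male") %in%
                  cmp$variable))
  split_row <- cmp[cmp$variable == "s2_split_ms", ]
  expect_lt(split_row$p, 0.001)
  expect_gt(split_row$statistic, 0)     # ASD minus control is positive
  expect_equal(cmp$test[cmp$variable == "sex_male"], "chi-square")
  expect_error(compare_groups(tab[tab$group == "ASD", ]), "single-group")
})
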