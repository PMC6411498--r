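# Demographic matching statistics: reconstruction from printed summaries,
# raw-data equivalence, and the chi-squared independence test.

test_that("one-way ANOVA reconstructs matched-cohort rows from printed summaries", {
  ns <- c(44, 36, 37)
  age <- anova_from_summary(c(58.6, 57.2, 58.4), c(7.2, 3.8, 6.8), ns)
  expect_equal(round(age$F, 1), 0.6)
  expect_equal(round(age$p, 2), 0.57, tolerance = 0.02)
  edu <- anova_from_summary(c(15.8, 15.8, 16.1), c(2.3, 2.4, 2.1), ns)
  expect_equal(round(edu$F, 1), 0.2)
  avlt <- anova_from_summary(c(8.75, 9.86, 10.03), c(2.95, 2.86, 3.07), ns)
  expect_equal(round(avlt$F, 1), 2.3)
  expect_identical(age$df, c(2L, 114L))
})

test_that("ANOVA edge cases: equal means, degenerate zero variance, bad input", {
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 3), c(10, 10, 10))$F, 0)
  deg <- anova_from_raw(list(c(0, 0), c(1, 1)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(anova_from_raw(list(1, c(1, 2))), "2 values")
  expect_error(anova_from_summary(5, 1, 10), ">= 2 groups")
  expect_error(anova_from_summary(c(5, 6), c(1, NA), c(5, 5)), "missing SD")
})

test_that("summary and raw entry points agree, and match the reference fit", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(sample(5:30, 1), mean = i / 2))
    a_raw <- anova_from_raw(vals)
    a_sum <- anova_from_summary(vapply(vals, mean, 1),
                                vapply(vals, sd, 1), lengths(vals))
    expect_equal(a_raw$F, a_sum$F, tolerance = 1e-10)
    # independent reference: stats::aov on the same data
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(seq_len(k), lengths(vals))))
    ref <- anova(aov(y ~ g, df))
    expect_equal(a_raw$F, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(a_raw$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("chi-squared independence matches the printed sex row and closed forms", {
  sex <- chi_square_independence(rbind(c(15, 29), c(11, 25), c(9, 28)))
  expect_equal(round(sex$chisq, 1), 0.9)
  expect_equal(round(sex$p, 2), 0.63)
  expect_identical(sex$df, 2L)
  # proportional rows: exact independence
  expect_equal(chi_square_independence(rbind(c(10, 20), c(5, 10)))$chisq, 0)
  # 2x2 diagonal table: chi-squared = n by hand
  expect_equal(chi_square_independence(rbind(c(10, 0), c(0, 10)))$chisq, 20)
  # agreement with the base implementation, no continuity correction
  tab <- rbind(c(13, 7, 4), c(8, 12, 9))
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  ours <- chi_square_independence(tab)
  expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("demographics_table summarizes a generated covariate table", {
  demo <- make_demographics(c(NC = 20L, HT = 20L, HM = 20L), seed = 3)
  tab <- demographics_table(demo)
  expect_identical(tab$variable, c("age", "education", "mmse", "avlt_ltm", "sex"))
  expect_true(all(tab$p > 0 & tab$p <= 1))
})
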