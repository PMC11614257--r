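test_that("the normality gate passes near-normal data, flags skew, refuses constants", {
  expect_error(shapiro_wilk_gate(rep(5, 10)), "constant")
  g <- shapiro_wilk_gate(qnorm(ppoints(20)))
  expect_gt(g$W, 0.95)
  expect_true(g$pass)
  set.seed(3)
  x <- rexp(50)
  expect_warning(g2 <- shapiro_wilk_gate(x), "normality gate failed")
  expect_lt(g2$p_value, 0.05)
  expect_false(g2$pass)
})

test_that("the pooled t-test is symmetric and null on identical groups", {
  r <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(21)
  a <- rnorm(15, 50, 8); b <- rnorm(20, 55, 8)
  r1 <- two_group_test(a, b)
  r2 <- two_group_test(b, a)
  expect_equal(abs(r1$statistic), abs(r2$statistic))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$absolute_difference_pct, abs(mean(a) - mean(b)))
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches a from-scratch sums-of-squares oracle", {
  set.seed(42)
  groups <- list(a = rnorm(10, 50, 5), b = rnorm(10, 53, 5),
                 c = rnorm(10, 49, 5))
  an <- one_way_anova(groups)
  # independent SS decomposition
  values <- unlist(groups)
  gm <- mean(values)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  F_oracle <- (ss_between / 2) / (ss_within / 27)
  expect_equal(an$F, F_oracle, tolerance = 1e-10)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 27)
  expect_equal(an$p_value, pf(F_oracle, 2, 27, lower.tail = FALSE),
               tolerance = 1e-10)
  # fully tied data return F = 0, p = 1 rather than erroring
  tied <- one_way_anova(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(tied$F, 0)
  expect_equal(tied$p_value, 1)
})

test_that("with two groups ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(sample(5:30, 1), 50, 6)
    b <- rnorm(sample(5:30, 1), 52, 6)
    an <- one_way_anova(list(a = a, b = b))
    tt <- two_group_test(a, b)
    expect_equal(an$F, tt$statistic^2, tolerance = 1e-9)
    expect_equal(an$p_value, tt$p_value, tolerance = 1e-9)
  }
})

test_that("Bonferroni contrasts multiply by the family size, cap at 1, and guard on the omnibus", {
  set.seed(5)
  groups <- list(a = rnorm(12, 50, 3), b = rnorm(12, 55, 3),
                 c = rnorm(12, 60, 3), d = rnorm(12, 50, 3))
  res <- bonferroni_pairwise(groups)
  expect_equal(attr(res, "family_size"), 6)
  for (r in res) {
    if (r$adjusted_p_value < 1) {
      expect_equal(r$adjusted_p_value, r$p_value * 6)
    }
    expect_gte(r$adjusted_p_value, r$p_value)
    expect_lte(r$adjusted_p_value, 1)
  }
  # two groups: the adjustment is the identity
  two <- bonferroni_pairwise(list(a = rnorm(10, 0, 1), b = rnorm(10, 3, 1)),
                             force = TRUE)
  expect_equal(two[[1]]$adjusted_p_value, two[[1]]$p_value)
  # a flat omnibus refuses pairwise testing unless forced
  set.seed(6)
  null_groups <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_gt(one_way_anova(null_groups)$p_value, 0.05)
  expect_error(bonferroni_pairwise(null_groups), "not significant")
  expect_silent(bonferroni_pairwise(null_groups, force = TRUE))
})

test_that("summary-statistic comparison reproduces the published urban/rural contrast", {
  r <- compare_from_summaries(55.3, 1.26, 162, 49.3, 1.17, 238,
                              label = "urban vs rural")
  expect_equal(r$absolute_difference_pct, 6.0)
  # published p = 0.0007; the normal approximation lands in the same order
  expect_gt(r$p_value, 1e-4)
  expect_lt(r$p_value, 1e-3)
  expect_true(r$significant)
  eq <- compare_from_summaries(50, 1, 10, 50, 1, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  half <- compare_from_summaries(55.3, 2.52, 162, 49.3, 2.34, 238)
  expect_equal(abs(half$statistic), abs(r$statistic) / 2)
  expect_error(compare_from_summaries(1, 0, 10, 2, 0, 10), "zero")
})

test_that("compare_groups picks the t-test for two levels and ANOVA beyond", {
  set.seed(31)
  df <- make_facility_table(60, fill = function(n) rbinom(n, 1, 0.5),
                            region = rep(c("Oromia", "Amhara", "Tigray"), 20))
  df$location <- rep(c("rural", "urban"), 30)
  res <- facility_readiness(df)
  cg2 <- compare_groups(res, "location")
  expect_true(!is.null(cg2$omnibus$statistic))  # t-test shape
  cg3 <- compare_groups(res, "region")
  expect_true(!is.null(cg3$omnibus$F))          # ANOVA shape
  expect_true(all(c("group", "n", "mean_pct") %in% names(cg3$summaries)))
})
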