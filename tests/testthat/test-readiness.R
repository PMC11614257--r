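test_that("dimension scores are the percentage of yes answers", {
  specs <- dimension_specs()
  r <- setNames(c(1, 1, 1, 1, 0, 0, 0), specs$structure$item_ids)
  s <- score_dimension(r, specs$structure)
  expect_equal(s$raw_total, 4)
  expect_equal(s$score_pct, 100 * 4 / 7)
  expect_equal(s$weighted_pct, 0.25 * 100 * 4 / 7)

  all_yes <- setNames(rep(1, 26), specs$attributes$item_ids)
  expect_equal(score_dimension(all_yes, specs$attributes)$score_pct, 100)
  none <- setNames(rep(0, 11), specs$core$item_ids)
  s0 <- score_dimension(none, specs$core)
  expect_equal(s0$score_pct, 0)
  expect_equal(s0$weighted_pct, 0)

  # a missing item is an error naming the item, never imputed
  expect_error(score_dimension(r[-1], specs$structure), "structure_1")
})

test_that("the dimension instrument has the canonical item counts and weights", {
  specs <- dimension_specs()
  expect_equal(lengths(lapply(specs, `[[`, "item_ids")),
               c(structure = 7L, core = 11L, supportive = 10L,
                 attributes = 26L))
  expect_equal(lengths(specs$attributes$subcategories),
               c(simplicity = 7L, flexibility = 2L, acceptability = 5L,
                 usefulness = 8L, stability = 4L))
  expect_equal(sum(vapply(specs, `[[`, numeric(1), "weight")), 1)
  expect_error(dimension_specs(c(structure = 0.5, core = 0.5,
                                 supportive = 0.5, attributes = 0.5)),
               "sum to 1")
})

test_that("the equal-weight composite of the published national dimension means is 44.9", {
  o <- overall_readiness(c(51.7, 20.0, 38.4, 69.6))
  expect_equal(o, 44.925)
  expect_equal(mdsrpi:::round_half_up(o, 1), 44.9)
  expect_equal(overall_readiness(rep(100, 4)), 100)
  expect_equal(overall_readiness(c(80, 0, 0, 0), c(1, 0, 0, 0)), 80)
  expect_error(overall_readiness(c(1, 2, 3, 4), c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
})

test_that("EPHI ratings form a total monotone step map with the published footnote labels", {
  expect_equal(as.character(classify_ephi(20.0)), "not functioning")
  expect_equal(as.character(classify_ephi(38.4)), "less functioning")
  expect_equal(as.character(classify_ephi(44.9)), "less functioning")
  expect_equal(as.character(classify_ephi(51.7)), "fairly functioning")
  expect_equal(as.character(classify_ephi(69.6)), "fairly functioning")
  expect_equal(as.character(classify_ephi(90.0)), "effectively functioning")
  expect_equal(as.character(classify_ephi(100)), "very effectively functioning")
  # total on [0,100], exactly five levels, monotone non-decreasing
  grid <- seq(0, 100, by = 0.1)
  r <- classify_ephi(grid)
  expect_false(anyNA(r))
  expect_equal(nlevels(r), 5)
  expect_true(all(diff(as.integer(r)) >= 0))
  expect_error(classify_ephi(101), "\\[0, 100\\]")
})

test_that("facility scoring is item-order invariant and monotone in yes answers", {
  set.seed(11)
  df <- make_facility_table(20, fill = function(n) rbinom(n, 1, 0.5))
  res <- facility_readiness(df)
  expect_true(all(res$overall_pct >= 0 & res$overall_pct <= 100))
  # shuffling item columns changes nothing
  items <- item_columns()
  perm <- c(setdiff(names(df), items), sample(items))
  res2 <- facility_readiness(df[, perm])
  expect_equal(res2$overall_pct, res$overall_pct)
  # flipping one "no" to "yes" never decreases any score
  i <- which(df$core_5 == 0)[1]
  df2 <- df
  df2$core_5[i] <- 1L
  res3 <- facility_readiness(df2)
  expect_gt(res3$core_pct[i], res$core_pct[i])
  expect_gt(res3$overall_pct[i], res$overall_pct[i])
  expect_true(all(res3$overall_pct >= res$overall_pct))
})

test_that("group summaries reproduce the published national interval and degenerate cases", {
  # published national overall row: mean 44.9, SE 0.52 -> CI 43.9 to 45.9
  m <- 44.9; se <- 0.52
  expect_equal(mdsrpi:::round_half_up(m - 1.96 * se, 1), 43.9)
  expect_equal(mdsrpi:::round_half_up(m + 1.96 * se, 1), 45.9)
  s <- summarize_group(c(50), "solo")
  expect_equal(s$mean_pct, 50)
  expect_true(is.na(s$se_pct) && is.na(s$ci_low_pct))
  expect_error(summarize_group(numeric(0)), "non-empty")
  # Monte-Carlo: mean of a known distribution lands within 3 SE
  set.seed(99)
  x <- rnorm(10000, mean = 45, sd = 10)
  g <- summarize_group(x, "mc")
  expect_lt(abs(g$mean_pct - 45), 3 * g$se_pct)
  expect_equal(g$ci_high_pct - g$mean_pct, g$mean_pct - g$ci_low_pct,
               tolerance = 1e-12)
})

test_that("readiness summaries by stratifier include a rated national row", {
  set.seed(7)
  df <- make_facility_table(40, fill = function(n) rbinom(n, 1, 0.45),
                            region = rep(c("Oromia", "Amhara"), 20))
  res <- facility_readiness(df)
  tab <- readiness_summary(res, "region")
  expect_true("national" %in% tab$group)
  nat <- tab[tab$group == "national", ]
  expect_equal(nat$n, 40)
  expect_equal(nat$rating,
               as.character(classify_ephi(mean(res$overall_pct))))
  expect_error(readiness_summary(res, "altitude"), "unknown stratifier")
})
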