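test_that("the five indicators follow their count-ratio definitions", {
  tigray <- list(expected = 2715, identified = 598, notified = 265,
                 reviewed = 566, reviewed_community = 444)
  ind <- compute_indicators(tigray)
  r1 <- function(x) mdsrpi:::round_half_up(x, 1)
  expect_equal(r1(ind[["Rn"]]), 44.3)
  expect_equal(r1(ind[["CRn"]]), 9.8)
  expect_equal(r1(ind[["Rr"]]), 213.6)   # uncapped, above 100
  expect_equal(r1(ind[["CRr"]]), 20.8)
  expect_equal(r1(ind[["CRDp"]]), 78.4)

  # all counts equal: every ratio is 100
  k <- list(expected = 7, identified = 7, notified = 7, reviewed = 7,
            reviewed_community = 7)
  expect_equal(unname(compute_indicators(k)), rep(100, 5))

  # zero denominators flag the indicator undefined, not 0 or Inf
  z <- list(expected = 100, identified = 10, notified = 0, reviewed = 0,
            reviewed_community = 0)
  ind0 <- compute_indicators(z)
  expect_true(is.na(ind0[["Rr"]]))
  expect_true(is.na(ind0[["CRDp"]]))
  expect_equal(ind0[["CRn"]], 0)
})

test_that("indicators are invariant to proportional scaling of all counts", {
  base <- list(expected = 500, identified = 120, notified = 90,
               reviewed = 100, reviewed_community = 40)
  for (k in c(2, 5, 13)) {
    scaled <- lapply(base, function(v) v * k)
    expect_equal(compute_indicators(scaled), compute_indicators(base))
  }
})

test_that("coverage, review and notification rates obey the cascade identity", {
  # d_r/E = (d_r/d_n) * (d_n/E) exactly, unrounded
  panel <- ethiopia_mdsr_counts()
  for (i in seq_len(nrow(panel))) {
    ind <- compute_indicators(panel[i, ])
    expect_equal(ind[["CRr"]], ind[["Rr"]] * ind[["CRn"]] / 100,
                 tolerance = 1e-12)
  }
})

test_that("national aggregation sums counts componentwise", {
  panel <- ethiopia_mdsr_counts()
  nat <- aggregate_national(panel)
  expect_equal(nat$notified, 5696)
  expect_equal(nat$reviewed, 4530)
  expect_equal(nat$expected, 60639)  # regional sum unless overridden
  expect_equal(aggregate_national(panel, 60686)$expected, 60686)
  one <- panel[3, ]
  expect_equal(aggregate_national(one)[, -1],
               one[, -1], ignore_attr = TRUE)
  two <- rbind(one, one)
  expect_equal(unlist(aggregate_national(two)[, -1]),
               2 * unlist(one[, -1]), ignore_attr = TRUE)
  # permuting regions changes nothing
  perm <- panel[sample(nrow(panel)), ]
  expect_equal(aggregate_national(perm), aggregate_national(panel))
})

test_that("the weighted composite reproduces the published worked example and is linear", {
  snnpr <- c(Rn = 64.7, CRn = 3.5, CRr = 4.4, Rr = 126.9, CRDp = 30.8)
  expect_equal(mdsrpi:::round_half_up(compute_mdsrpi(snnpr)$mdsrpi_pct, 1),
               37.3)
  zero <- setNames(rep(0, 5), names(snnpr))
  expect_equal(compute_mdsrpi(zero)$mdsrpi_pct, 0)
  expect_equal(compute_mdsrpi(zero)$performance_class, "low")
  hundred <- setNames(rep(100, 5), names(snnpr))
  expect_equal(compute_mdsrpi(hundred)$mdsrpi_pct, 100)
  expect_equal(compute_mdsrpi(hundred)$performance_class, "good")
  # linearity in each indicator
  for (nm in names(snnpr)) {
    bumped <- snnpr
    bumped[nm] <- bumped[nm] + 10
    w <- c(Rn = 0.1, CRn = 0.3, CRr = 0.3, Rr = 0.2, CRDp = 0.1)
    expect_equal(compute_mdsrpi(bumped)$mdsrpi_pct,
                 compute_mdsrpi(snnpr)$mdsrpi_pct + 10 * w[[nm]])
  }
  # undefined indicators are refused by name
  snnpr["Rr"] <- NA
  expect_error(compute_mdsrpi(snnpr), "undefined indicator.*Rr")
})

test_that("performance classes use the 0.4/0.6 cuts with a closed moderate interval", {
  expect_equal(classify_mdsrpi(33.9), "low")
  expect_equal(classify_mdsrpi(40.0), "moderate")
  expect_equal(classify_mdsrpi(60.0), "moderate")
  expect_equal(classify_mdsrpi(64.2), "good")
  expect_error(classify_mdsrpi(-1), "non-negative")
})

test_that("the full panel analysis reproduces the published indicator grid", {
  perf <- as.data.frame(mdsr_performance(ethiopia_mdsr_counts()))
  regional <- perf[perf$region != "Total", ]
  printed <- printed_indicator_grid()
  expect_equal(regional$region, printed$region)
  for (i in seq_len(nrow(printed))) {
    for (cl in c("Rn", "CRn", "CRr", "Rr", "CRDp")) {
      loose <- any(loose_cells$region == printed$region[i] &
                     loose_cells$indicator == cl)
      tol <- if (loose) 0.25 else 0.05
      expect_lt(abs(regional[[cl]][i] - printed[[cl]][i]), tol,
                label = sprintf("%s %s = %.3f vs published %.1f",
                                printed$region[i], cl, regional[[cl]][i],
                                printed[[cl]][i]))
    }
    expect_lt(abs(regional$mdsrpi_pct[i] - printed$mdsrpi[i]), 0.1)
  }
  # class labels: Tigray good; Amhara, Harari, Dire Dawa moderate; rest low
  cls <- setNames(regional$performance_class, regional$region)
  expect_equal(unname(cls["Tigray"]), "good")
  expect_equal(unname(cls[c("Amhara", "Harari", "Dire Dawa")]),
               rep("moderate", 3))
  expect_equal(sum(cls == "low"), 7)
})
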