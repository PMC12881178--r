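test_that("a constant day at its own baseline has AUC 120 and net iAUC 0", {
  s <- make_glucose(seq(0, 24, by = 0.25), rep(5, 97))
  out <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 5)
  expect_equal(out$total_auc, 120)
  expect_equal(out$net_iauc, 0)
  expect_equal(out$tir, 100)
  expect_equal(out$mean_glucose, 5)
  expect_equal(out$cv, 0)
})

test_that("two-sample trapezoid matches the hand computation", {
  s <- make_glucose(c(8, 8.25), c(5, 7))
  out <- summarise_interval(s, DAY0 + 8 * 3600, DAY0 + 8.25 * 3600 + 1,
                            baseline = 5)
  expect_equal(out$total_auc, 1.5)
  expect_equal(out$net_iauc, 0.25)
})

test_that("range percentages count epochs, one high epoch of 96 is 1.04%", {
  vals <- rep(6, 96)
  vals[40] <- 11
  s <- make_glucose(seq(0, 23.75, by = 0.25), vals)
  out <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 6)
  expect_equal(out$tar, 100 / 96, tolerance = 1e-9)
  expect_equal(out$tir, 100 * 95 / 96, tolerance = 1e-9)
  expect_equal(out$tbr, 0)
})

test_that("TIR + below-range band + TAR + TBR partition the epochs", {
  withr::local_seed(61)
  for (i in 1:10) {
    vals <- runif(96, 2, 13)
    s <- make_glucose(seq(0, 23.75, by = 0.25), vals)
    out <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 6)
    mid <- 100 * mean(vals >= 3.0 & vals < 3.9)
    expect_equal(out$tir + out$tar + out$tbr + mid, 100, tolerance = 1e-9)
  }
})

test_that("trapezoid equals the closed-form integral on piecewise-linear
           profiles and is additive under interval splitting", {
  withr::local_seed(71)
  for (i in 1:25) {
    n_knots <- sample(3:7, 1)
    knot_h <- sort(c(0, 24, runif(n_knots, 0.5, 23.5)))
    knot_v <- runif(length(knot_h), 3, 12)
    hours <- seq(0, 24, by = 0.25)
    vals <- approx(knot_h, knot_v, xout = hours)$y
    s <- make_glucose(hours, vals)
    out <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 5)
    # closed form: sum of trapezoids between consecutive knots, each linear
    # piece integrating to mean height x width -- but knots need not lie on
    # the epoch grid, so integrate the sampled polyline exactly instead
    exact <- sum(diff(hours) * (head(vals, -1) + tail(vals, -1)) / 2)
    expect_equal(out$total_auc, exact, tolerance = 1e-12)

    cut <- DAY0 + sample(seq(1, 23), 1) * 3600
    left <- summarise_interval(s, DAY0, cut, baseline = 5)
    right <- summarise_interval(s, cut, DAY0 + 86400, baseline = 5)
    expect_equal(left$total_auc + right$total_auc, out$total_auc,
                 tolerance = 1e-12)
    expect_equal(left$net_iauc + right$net_iauc, out$net_iauc,
                 tolerance = 1e-12)
  }
})

test_that("gaps beyond the bridging limit contribute no area or duration", {
  hours <- c(0, 0.25, 0.5, 3, 3.25)  # 2.5-h hole after 0.5
  s <- make_glucose(hours, c(5, 5, 5, 7, 7))
  out <- summarise_interval(s, DAY0, DAY0 + 4 * 3600, baseline = 5,
                            max_gap_min = 60)
  expect_equal(out$covered_h, 0.75)
  expect_equal(out$total_auc, 5 * 0.5 + 7 * 0.25)
  expect_equal(out$net_iauc, 7 * 0.25 - 5 * 0.25)
})

test_that("a shift of glucose and baseline leaves net iAUC unchanged", {
  withr::local_seed(81)
  vals <- runif(97, 4, 10)
  s <- make_glucose(seq(0, 24, by = 0.25), vals)
  s2 <- make_glucose(seq(0, 24, by = 0.25), vals + 2)
  a <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 5)
  b <- summarise_interval(s2, DAY0, DAY0 + 86400, baseline = 7)
  expect_equal(b$net_iauc, a$net_iauc, tolerance = 1e-9)
  expect_equal(b$mean_glucose, a$mean_glucose + 2)
})

test_that("fewer than two epochs flags the summary invalid", {
  s <- make_glucose(8, 6)
  out <- summarise_interval(s, DAY0, DAY0 + 86400, baseline = 6)
  expect_false(out$valid)
  expect_true(is.na(out$net_iauc))
})

test_that("postprandial iAUC subtracts the last pre-meal concentration", {
  meal <- DAY0 + 12 * 3600
  # flat at baseline -> 0
  flat <- make_glucose(seq(11, 14.5, by = 0.25), rep(5.5, 15))
  expect_equal(postprandial_iauc(flat, meal)$iauc, 0)

  # linear rise 5 -> 7 across the 2-h window: AUC 12, iAUC 2
  hours <- seq(12, 14, by = 0.25)
  rise <- make_glucose(c(11.75, hours), c(5, 5 + (hours - 12)))
  out <- postprandial_iauc(rise, meal)
  expect_equal(out$baseline, 5)
  expect_equal(out$iauc, 12 - 10)
})

test_that("postprandial iAUC can be negative and respects the lookback", {
  meal <- DAY0 + 12 * 3600
  hours <- seq(12, 14, by = 0.25)
  dip <- make_glucose(c(11.75, hours), c(6, rep(5, length(hours))))
  expect_equal(postprandial_iauc(dip, meal)$iauc, (5 - 6) * 2)

  # baseline sample older than the lookback -> flagged missing
  stale <- make_glucose(c(10.5, hours), c(6, rep(5, length(hours))))
  out <- postprandial_iauc(stale, meal, baseline_lookback_min = 60)
  expect_false(out$valid)
  expect_true(is.na(out$iauc))
})

test_that("regimen-level metrics are unweighted means of valid days", {
  expect_equal(daily_then_regimen_mean(c(10, 14)), 12)
  expect_equal(daily_then_regimen_mean(9.2), 9.2)
  expect_equal(daily_then_regimen_mean(c(3, NA, 5)), 4)
  expect_true(is.na(daily_then_regimen_mean(c(NA_real_, NA_real_))))
  withr::local_seed(91)
  x <- runif(6)
  expect_equal(daily_then_regimen_mean(x),
               daily_then_regimen_mean(rev(x)))
})
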