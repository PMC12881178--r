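day1 <- as.Date("2021-03-01")

# glucose stream with a given number of present epochs on day1
coverage_glucose <- function(n_epochs) {
  make_glucose(seq(0, by = 0.25, length.out = n_epochs), rep(6, n_epochs))
}

# event day with given wear composition (remainder of 24 h is nonwear)
wear_day <- function(sed_h, stand_h, step_h, steps) {
  dur <- c(sed_h, stand_h, step_h)
  act <- c("sedentary", "standing", "stepping")
  keep <- dur > 0
  ev <- make_events(cumsum(c(0, dur[keep][-sum(keep)])), dur[keep], act[keep],
                    steps = ifelse(act[keep] == "stepping", steps, 0))
  ev
}

test_that("the FGM rule is strictly greater than the coverage threshold", {
  ev <- wear_day(5, 4, 2, 600)
  expect_true(classify_day(coverage_glucose(68), ev, day1)$fgm_valid)  # 70.8%
  expect_false(classify_day(coverage_glucose(67), ev, day1)$fgm_valid) # 69.8%
  # coverage exactly at the threshold is invalid (strict >)
  at_thr <- classify_day(coverage_glucose(68), ev, day1,
                         fgm_coverage_min = 68 / 96)
  expect_false(at_thr$fgm_valid)
})

test_that("wear-day thresholds sit exactly on the quoted boundaries", {
  glu <- coverage_glucose(96)
  # >= 10 h wear (inclusive)
  expect_true(classify_day(glu, wear_day(5, 3, 2, 600), day1)$pal_valid)
  expect_false(classify_day(glu, wear_day(4.99, 3, 2, 600), day1)$pal_valid)
  expect_true(classify_day(glu, wear_day(5.00, 3.00, 2.00, 600),
                           day1)$wear_h >= 10)
  # >= 500 steps (inclusive)
  expect_true(classify_day(glu, wear_day(5, 3, 2, 500), day1)$pal_valid)
  expect_false(classify_day(glu, wear_day(5, 3, 2, 499), day1)$pal_valid)
  # < 95% of wear in one activity (strict)
  at_95 <- wear_day(19, 0.6, 0.4, 600)   # 19/20 = 0.95 exactly
  expect_false(classify_day(glu, at_95, day1)$pal_valid)
  under_95 <- wear_day(18.9, 0.7, 0.4, 600)
  expect_true(classify_day(glu, under_95, day1)$pal_valid)
})

test_that("the boundary example day is valid on both streams", {
  glu <- coverage_glucose(69)           # 69/96 = 0.719 > 0.70
  ev <- wear_day(9.4, 0.2, 0.4, 500)    # wear 10 h, 94% sitting
  d <- classify_day(glu, ev, day1)
  expect_true(d$fgm_valid)
  expect_true(d$pal_valid)
  expect_true(d$both_valid)
})

test_that("absent data yields an invalid day with zeroed quantities", {
  d <- classify_day(make_glucose(numeric(0), numeric(0)),
                    make_events(8, 1, "standing"), day1 + 30)
  expect_false(d$both_valid)
  expect_equal(d$fgm_coverage, 0)
  expect_equal(d$wear_h, 0)
})

test_that("validity is monotone in added epochs and wear", {
  glu_lo <- coverage_glucose(70)
  glu_hi <- coverage_glucose(90)
  ev_lo <- wear_day(6, 3, 2, 800)
  ev_hi <- wear_day(8, 4, 3, 1200)
  lo <- classify_day(glu_lo, ev_lo, day1)
  hi <- classify_day(glu_hi, ev_hi, day1)
  expect_true(hi$fgm_valid >= lo$fgm_valid)
  expect_true(hi$pal_valid >= lo$pal_valid)
})

test_that("eligible days are the intersection of validity and the regimen", {
  v <- dplyr::bind_rows(lapply(0:3, function(k) {
    tibble::tibble(date = day1 + k,
                   both_valid = k %in% c(1, 2))
  }))
  expect_equal(eligible_days(v, day1, day1 + 3), day1 + c(1, 2))
  expect_equal(eligible_days(v, day1 + 2, day1 + 3), day1 + 2)
  none <- v
  none$both_valid <- FALSE
  expect_length(eligible_days(none, day1, day1 + 3), 0)
  # idempotent and within the regimen interval
  el <- eligible_days(v, day1, day1 + 3)
  expect_true(all(el >= day1 & el <= day1 + 3))
})
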