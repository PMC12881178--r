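ww_full <- function(wake = 7, sleep = 23) {
  waking_window(as.Date("2021-03-01"), DAY0 + wake * 3600, DAY0 + sleep * 3600)
}

# waking tiling from bout minutes: stand 5 min between sitting bouts
bout_day <- function(bout_min, wake = 7) {
  n <- length(bout_min)
  dur <- c(rbind(rep(5 / 60, n), bout_min / 60), 5 / 60)
  act <- c(rbind(rep("standing", n), rep("sedentary", n)), "standing")
  make_events(wake + cumsum(c(0, dur[-length(dur)])), dur, act,
              steps = rep(0, length(dur)))
}

test_that("a single 45-min bout lands in the 30-60 class only", {
  ev <- bout_day(45)
  b <- sedentary_bouts(ev, ww_full())
  expect_equal(b$n_30_60, 1)
  expect_equal(b$n_ge30, 1)
  expect_equal(b$n_ge60, 0)
  expect_equal(b$h_30_60, 0.75)
  expect_equal(b$sitting_h, 0.75)
})

test_that("bouts {20, 40, 70} min enumerate into the printed classes", {
  ev <- bout_day(c(20, 40, 70))
  b <- sedentary_bouts(ev, ww_full())
  expect_equal(b$n_0_30, 1)
  expect_equal(b$n_30_60, 1)
  expect_equal(b$n_ge60, 1)
  expect_equal(b$n_ge30, 2)
  expect_equal(b$n_bouts, 3)
  expect_equal(b$h_0_30 + b$h_30_60 + b$h_ge60, 130 / 60, tolerance = 1e-9)
  expect_equal(b$sitting_h, 130 / 60, tolerance = 1e-9)
  expect_equal(b$sit_upright_transitions, 3)
})

test_that("alternating 5-min sits give one short bout and transition each", {
  ev <- bout_day(rep(5, 10))
  b <- sedentary_bouts(ev, ww_full())
  expect_equal(b$n_0_30, 10)
  expect_equal(b$n_bouts, 10)
  expect_equal(b$sit_upright_transitions, 10)
})

test_that("boundary durations go to the upper class", {
  b30 <- sedentary_bouts(bout_day(30), ww_full())
  expect_equal(b30$n_30_60, 1)
  expect_equal(b30$n_0_30, 0)
  b60 <- sedentary_bouts(bout_day(60), ww_full())
  expect_equal(b60$n_ge60, 1)
  expect_equal(b60$n_30_60, 0)
})

test_that("a bout ending the window is not a sit-upright transition", {
  # day ends while sitting: last bout has no upright follower
  ev <- make_events(c(7, 7.5, 8), c(0.5, 0.5, 15),
                    c("standing", "sedentary", "sedentary"))
  b <- sedentary_bouts(ev, ww_full())
  expect_equal(b$n_bouts, 1)
  expect_equal(b$sit_upright_transitions, 0)
})

test_that("nonwear terminates a bout without counting as a transition", {
  ev <- make_events(c(7, 8, 10, 11), c(1, 2, 1, 12),
                    c("sedentary", "nonwear", "sedentary", "standing"))
  b <- sedentary_bouts(ev, ww_full())
  expect_equal(b$n_bouts, 2)
  expect_equal(b$sit_upright_transitions, 1)
})

test_that("bout metrics agree with brute-force enumeration on random days", {
  withr::local_seed(101)
  ww <- ww_full()
  for (i in 1:50) {
    ev <- random_tiling(sample(5:80, 1), t0_h = 6, span_h = 18)
    b <- sedentary_bouts(ev, ww)
    o <- brute_force_bouts(ev, ww$wake_time, ww$sleep_time)
    expect_equal(b$n_bouts, o$n_bouts)
    expect_equal(b$sitting_h, o$sitting_h, tolerance = 1e-9)
    expect_equal(b$sit_upright_transitions, o$transitions)
    expect_equal(b$h_0_30, o$h_0_30, tolerance = 1e-9)
    expect_equal(b$h_30_60, o$h_30_60, tolerance = 1e-9)
    expect_equal(b$h_ge60, o$h_ge60, tolerance = 1e-9)
    # partition identity
    expect_equal(b$h_0_30 + b$h_30_60 + b$h_ge60, b$sitting_h,
                 tolerance = 1e-12)
    expect_equal(b$n_ge30, b$n_30_60 + b$n_ge60)
  }
})

test_that("stepping splits at 100 steps/min into light and MVPA", {
  # 60 min at exactly 100 steps/min -> 1 h MVPA, 6000 MVPA steps
  ev <- make_events(8, 1, "stepping", steps = 6000)
  s <- classify_stepping(ev)
  expect_equal(s$mvpa_h, 1)
  expect_equal(s$mvpa_steps, 6000)
  expect_equal(s$light_h, 0)

  # 10 min at 60 steps/min -> light
  ev2 <- make_events(8, 10 / 60, "stepping", steps = 600)
  s2 <- classify_stepping(ev2)
  expect_equal(s2$light_h, 10 / 60)
  expect_equal(s2$light_steps, 600)

  # cadence 99.9 stays light
  ev3 <- make_events(8, 10 / 60, "stepping", steps = 999)
  expect_equal(classify_stepping(ev3)$light_steps, 999)
})

test_that("subdividing a stepping event at constant cadence changes nothing", {
  one <- make_events(8, 0.5, "stepping", steps = 3300)
  two <- make_events(c(8, 8.25), c(0.25, 0.25), c("stepping", "stepping"),
                     steps = c(1650, 1650))
  expect_equal(classify_stepping(one), classify_stepping(two))
})

test_that("compliance criteria sit exactly on the quoted boundaries", {
  expect_true(check_compliance(0.9, 0.8, "SIT")$fully_compliant)
  expect_true(check_compliance(1.0, 1.0, "SIT")$fully_compliant)   # <= 1 h
  expect_false(check_compliance(1.01, 0.8, "SIT")$criterion_1)
  expect_false(check_compliance(0.9, 1.01, "SIT")$criterion_2)

  expect_true(check_compliance(3.0, 2.0, "SITLESS")$fully_compliant)  # >= 3, >= 2
  expect_false(check_compliance(2.99, 2.0, "SITLESS")$criterion_1)
  f <- check_compliance(3.2, 1.9, "SITLESS")
  expect_true(f$criterion_1)
  expect_false(f$criterion_2)
  expect_false(f$fully_compliant)
})
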