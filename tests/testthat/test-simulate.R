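test_that("a fixed seed reproduces the trial exactly", {
  cfg <- small_sim_config()
  t1 <- simulate_trial(cfg, seed = 99)
  t2 <- simulate_trial(cfg, seed = 99)
  expect_identical(t1$glucose, t2$glucose)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$meals, t2$meals)
  t3 <- simulate_trial(cfg, seed = 100)
  expect_false(identical(t1$glucose$glucose, t3$glucose$glucose))
})

test_that("generated events tile the monitoring span without gaps", {
  trial <- simulate_trial(small_sim_config(), seed = 5)
  for (pid in unique(trial$events$participant_id)) {
    ev <- trial$events[trial$events$participant_id == pid, ]
    s <- as.numeric(ev$start)
    e <- s + ev$duration_s
    expect_true(all(abs(s[-1] - e[-length(e)]) < 1e-6))
    expect_equal(nrow(nonwear_intervals(ev)), 0)
    # full-day conservation on an interior day
    tot <- daily_totals(ev, trial$regimen_days$date[2])
    expect_equal(tot$wear_h, 24, tolerance = 1e-9)
  }
})

test_that("generated glucose stays within the sensor range on the 15-min grid", {
  trial <- simulate_trial(small_sim_config(), seed = 6)
  expect_true(all(trial$glucose$glucose >= 1.1 & trial$glucose$glucose <= 27.8))
  secs <- as.numeric(trial$glucose$timestamp)
  expect_true(all(secs %% (15 * 60) == 0))
})

test_that("the trial layout has two regimens separated by washout days", {
  cfg <- sim_config()
  trial <- simulate_trial(cfg, seed = 3)
  rd <- trial$regimen_days[trial$regimen_days$participant_id == "P01", ]
  expect_equal(nrow(rd), 11)
  expect_equal(sum(rd$regimen == "WASHOUT"), 3)
  expect_equal(sum(rd$regimen == "SIT"), 4)
  expect_equal(sum(rd$regimen == "SITLESS"), 4)
  # counterbalanced order across participants
  firsts <- vapply(split(trial$regimen_days, trial$regimen_days$participant_id),
                   function(x) x$regimen[1], "")
  expect_equal(sum(firsts == "SIT"), 7)
  expect_equal(sum(firsts == "SITLESS"), 7)
})

test_that("a noise-free, meal-free, flat configuration gives constant glucose", {
  cfg <- small_sim_config(glucose = list(
    noise_sd = 0, missingness = 0, diurnal_amp = 0,
    meal_iauc_2h = list(SIT = c(breakfast = 0, lunch = 0, dinner = 0),
                        SITLESS = c(breakfast = 0, lunch = 0, dinner = 0),
                        WASHOUT = c(breakfast = 0, lunch = 0, dinner = 0)),
    daytime_drop = c(SIT = 0, SITLESS = 0, WASHOUT = 0),
    amplitude_cv = list(participant = 0, regimen = 0, day = 0)
  ))
  trial <- simulate_trial(cfg, seed = 8)
  g1 <- trial$glucose[trial$glucose$participant_id == "P01", ]
  expect_lt(diff(range(g1$glucose)), 1e-12)

  ev <- trial$events[trial$events$participant_id == "P01", ]
  ww <- detect_waking_window(ev, trial$regimen_days$date[1])
  base <- waking_glucose(g1, ww)
  out <- summarise_interval(g1, ww$wake_time, ww$sleep_time, base)
  expect_equal(out$net_iauc, 0, tolerance = 1e-9)
})

test_that("behavioural targets are recovered by the pipeline's daily totals", {
  # generator-vs-pipeline round trip at the daily level: means over many
  # simulated days approach the configured regimen targets
  cfg <- sim_config()
  trial <- simulate_trial(cfg, seed = 77)
  res <- run_pipeline(trial, outcomes = c("sitting_h", "standing_h",
                                          "stepping_h"))
  sm <- res$regimen_summaries
  sit_mean <- tapply(sm$sitting_h, sm$regimen, mean)
  expect_equal(unname(sit_mean["SIT"]), sum(cfg$behaviour$SIT$sed_h),
               tolerance = 0.15)
  expect_equal(unname(sit_mean["SITLESS"]), sum(cfg$behaviour$SITLESS$sed_h),
               tolerance = 0.25)
})

test_that("trial CSV round trip preserves all streams", {
  trial <- simulate_trial(small_sim_config(), seed = 12)
  dir <- withr::local_tempdir()
  write_trial_csv(trial, dir)
  back <- read_trial_csv(dir)
  expect_equal(nrow(back$glucose), nrow(trial$glucose))
  expect_equal(sort(unique(back$events$participant_id)),
               sort(unique(trial$events$participant_id)))
  p1 <- trial$glucose[trial$glucose$participant_id == "P01", ]
  b1 <- back$glucose[back$glucose$participant_id == "P01", ]
  expect_equal(as.numeric(b1$timestamp), as.numeric(p1$timestamp))
  expect_equal(b1$glucose, p1$glucose, tolerance = 1e-9)
  expect_equal(back$meals$meal, trial$meals$meal)
})

test_that("infeasible behaviour budgets are rejected", {
  expect_error(sim_config(behaviour = list(SIT = list(
    sed_h = c(short = 10, mid = 8, long = 8)
  ))), "24 h")
  expect_error(sim_config(glucose = list(missingness = 1)), "missingness")
})

test_that("the calibrated configuration stores its solved glucose terms", {
  cfg <- study_calibration(n_draws = 100)
  expect_gt(cfg$glucose$unit_iauc, 0.5)
  expect_lt(cfg$glucose$unit_iauc, 2)
  expect_gt(cfg$glucose$daytime_drop[["SITLESS"]], 0)
  expect_lt(cfg$glucose$daytime_drop[["SITLESS"]], 2)
  # amplitudes follow the configured 2-h iAUC targets
  expect_equal(cfg$glucose$kernel_amplitude$SIT$lunch /
                 cfg$glucose$kernel_amplitude$SITLESS$lunch,
               2.5 / 1.5, tolerance = 1e-9)
})
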