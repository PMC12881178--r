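# Shared fixture builders: everything is generated in code at test time.

DAY0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# glucose series from clock hours (relative to DAY0) and values
make_glucose <- function(hours, values, id = "T1") {
  glucose_series(id, DAY0 + hours * 3600, values)
}

# event series from clock hours, durations in hours
make_events <- function(start_h, dur_h, activity, steps = NULL, id = "T1",
                        nonwear_gap_s = 0) {
  if (is.null(steps)) steps <- ifelse(activity == "stepping", 100, 0)
  pal_events(id, DAY0 + start_h * 3600, dur_h * 3600, activity, steps,
             nonwear_gap_s = nonwear_gap_s)
}

# a full sandwiched day: sleep until `wake`, one waking tiling, sleep after
# `sleep`; waking segments given as (dur_h, activity, steps) rows
make_sandwich_day <- function(segments_dur, segments_act, segments_steps,
                              wake = 7, sleep = 23, id = "T1") {
  dur <- c(wake, segments_dur, 24 + 8 - sleep)
  act <- c("sedentary", segments_act, "sedentary")
  stp <- c(0, segments_steps, 0)
  start <- cumsum(c(0, dur[-length(dur)]))
  stopifnot(abs(wake + sum(segments_dur) - sleep) < 1e-9)
  make_events(start, dur, act, stp, id = id)
}

# independent brute-force sedentary-bout enumerator: walks the event list
# one event at a time (no vectorised tricks), clipping to the window first
brute_force_bouts <- function(events, wake_time, sleep_time) {
  s <- as.numeric(events$start)
  e <- s + events$duration_s
  a <- as.numeric(wake_time)
  b <- as.numeric(sleep_time)
  keep <- which(pmin(e, b) - pmax(s, a) > 1e-9)
  durations <- numeric(0)
  acts <- character(0)
  for (i in keep) {
    durations <- c(durations, (min(e[i], b) - max(s[i], a)) / 60)
    acts <- c(acts, events$activity[i])
  }
  bouts <- numeric(0)
  trans <- 0L
  cur <- 0
  open <- FALSE
  for (i in seq_along(durations)) {
    if (acts[i] == "sedentary") {
      cur <- cur + durations[i]
      open <- TRUE
    } else {
      if (open) {
        bouts <- c(bouts, cur)
        if (acts[i] %in% c("standing", "stepping")) trans <- trans + 1L
        cur <- 0
        open <- FALSE
      }
    }
  }
  if (open) bouts <- c(bouts, cur)
  list(
    bouts_min = bouts,
    n_bouts = length(bouts),
    sitting_h = sum(bouts) / 60,
    transitions = trans,
    h_0_30 = sum(bouts[bouts < 30]) / 60,
    h_30_60 = sum(bouts[bouts >= 30 & bouts < 60]) / 60,
    h_ge60 = sum(bouts[bouts >= 60]) / 60,
    n_0_30 = sum(bouts < 30),
    n_30_60 = sum(bouts >= 30 & bouts < 60),
    n_ge60 = sum(bouts >= 60)
  )
}

# random contiguous event tiling of a window, for conservation properties
random_tiling <- function(n_events, t0_h = 7, span_h = 16, id = "T1",
                          classes = c("sedentary", "standing", "stepping")) {
  w <- rexp(n_events) + 0.05
  dur_h <- span_h * w / sum(w)
  act <- sample(classes, n_events, replace = TRUE)
  steps <- ifelse(act == "stepping",
                  pmax(1, round(runif(n_events, 20, 120) * dur_h * 60)), 0)
  make_events(t0_h + cumsum(c(0, dur_h[-n_events])), dur_h, act, steps,
              id = id)
}

# small, fast trial configuration for pipeline-level tests
small_sim_config <- function(...) {
  sim_config(n_participants = 4, days_per_regimen = 2, washout_days = 1, ...)
}
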