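#' Sedentary bout decomposition within a waking window
#'
#' A sedentary bout is a maximal run of sitting/lying events inside the
#' waking window; any standing, stepping or nonwear event terminates it.
#' Bouts are clipped to the window before classification. The duration
#' classes `0-30`, `30-60` and `>=60` minutes partition total sitting time
#' (boundary durations go to the upper class); the reported `>=30` and `>60`
#' rows are derived overlapping views of that partition. A sit-upright
#' transition is counted at every boundary where a sedentary bout is
#' immediately followed by standing or stepping.
#'
#' @param events a [pal_events()] series.
#' @param waking a [waking_window()] (or any list with `wake_time` and
#'   `sleep_time`).
#' @return one-row tibble with counts (`n_*`) and hours (`h_*`) for classes
#'   `0_30`, `30_60`, `ge60`, plus derived `ge30`/`gt60` views, `n_bouts`,
#'   `sitting_h` and `sit_upright_transitions`.
#' @export
sedentary_bouts <- function(events, waking) {
  cl <- clip_events_num(as.numeric(events$start), events$duration_s,
                        events$activity, events$steps,
                        as.numeric(waking$wake_time),
                        as.numeric(waking$sleep_time))
  tibble::new_tibble(bouts_from_clip(cl), nrow = 1L)
}

bouts_from_clip <- function(cl) {
  n_ev <- length(cl$duration_s)
  if (!n_ev) {
    return(list(
      n_0_30 = 0L, n_30_60 = 0L, n_ge60 = 0L, n_ge30 = 0L, n_gt60 = 0L,
      h_0_30 = 0, h_30_60 = 0, h_ge60 = 0, h_ge30 = 0, h_gt60 = 0,
      n_bouts = 0L, sitting_h = 0, sit_upright_transitions = 0L
    ))
  }
  sed <- cl$activity == "sedentary"
  r <- rle(sed)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  bout_start <- idx_start[r$values]
  bout_end <- idx_end[r$values]
  cum_min <- cumsum(cl$duration_s) / 60
  bout_min <- cum_min[bout_end] -
    c(0, cum_min)[bout_start]  # run sums via cumulative differences

  # a transition requires an upright (standing/stepping) event right after
  # the bout, still inside the window
  trans <- bout_end < n_ev &
    cl$activity[pmin(bout_end + 1L, n_ev)] %in% c("standing", "stepping")

  cls_short <- bout_min < 30
  cls_mid <- bout_min >= 30 & bout_min < 60
  cls_long <- bout_min >= 60
  list(
    n_0_30 = sum(cls_short), n_30_60 = sum(cls_mid), n_ge60 = sum(cls_long),
    n_ge30 = sum(cls_mid) + sum(cls_long), n_gt60 = sum(cls_long),
    h_0_30 = sum(bout_min[cls_short]) / 60,
    h_30_60 = sum(bout_min[cls_mid]) / 60,
    h_ge60 = sum(bout_min[cls_long]) / 60,
    h_ge30 = sum(bout_min[cls_mid | cls_long]) / 60,
    h_gt60 = sum(bout_min[cls_long]) / 60,
    n_bouts = length(bout_min),
    sitting_h = sum(bout_min) / 60,
    sit_upright_transitions = sum(trans)
  )
}

#' Split stepping into light and moderate-to-vigorous by cadence
#'
#' A stepping event counts as MVPA when its cadence is at least
#' `cadence_threshold` steps/min (default 100, consistent with 6000 steps
#' being roughly one hour of moderate-intensity walking); otherwise light.
#' The split is invariant to subdividing an event at constant cadence.
#'
#' @param events a [pal_events()] series (already clipped as desired).
#' @param cadence_threshold steps/min.
#' @return one-row tibble: `light_h`, `mvpa_h`, `light_steps`, `mvpa_steps`.
#' @export
classify_stepping <- function(events, cadence_threshold = 100) {
  cl <- list(duration_s = events$duration_s, activity = events$activity,
             steps = events$steps)
  tibble::new_tibble(stepping_from_clip(cl, cadence_threshold), nrow = 1L)
}

stepping_from_clip <- function(cl, cadence_threshold) {
  is_st <- cl$activity == "stepping"
  dur <- cl$duration_s[is_st]
  steps <- cl$steps[is_st]
  mvpa <- steps / (dur / 60) >= cadence_threshold
  list(
    light_h = sum(dur[!mvpa]) / 3600,
    mvpa_h = sum(dur[mvpa]) / 3600,
    light_steps = sum(steps[!mvpa]),
    mvpa_steps = sum(steps[mvpa])
  )
}

#' Daily activity summary for one participant-day
#'
#' Combines waking-window posture totals, the sedentary bout decomposition
#' and the cadence-classified stepping split into the Table-4-style daily
#' outcome row.
#'
#' @param events a [pal_events()] series.
#' @param day calendar date.
#' @param waking a [waking_window()].
#' @param cadence_threshold steps/min separating light from MVPA stepping.
#' @return one-row tibble.
#' @export
daily_activity <- function(events, day, waking, cadence_threshold = 100) {
  cl <- clip_events_num(as.numeric(events$start), events$duration_s,
                        events$activity, events$steps,
                        as.numeric(waking$wake_time),
                        as.numeric(waking$sleep_time))
  row <- c(list(date = lubridate::as_date(day)),
           totals_from_clip(cl),
           stepping_from_clip(cl, cadence_threshold),
           bouts_from_clip(cl))
  tibble::new_tibble(row, nrow = 1L)
}

#' Check a day's compliance with its regimen protocol
#'
#' SIT: (1) standing time <= 1 h/day and (2) stepping time <= 1 h/day.
#' SITless: (1) standing time >= 3 h/day and (2) stepping time >= 2 h/day.
#' Boundaries are inclusive, as stated.
#'
#' @param standing_h,stepping_h daily waking totals, hours.
#' @param regimen `"SIT"` or `"SITLESS"`.
#' @return one-row tibble: `criterion_1`, `criterion_2`, `fully_compliant`.
#' @export
check_compliance <- function(standing_h, stepping_h,
                             regimen = c("SIT", "SITLESS")) {
  regimen <- match.arg(regimen)
  if (regimen == "SIT") {
    c1 <- standing_h <= 1
    c2 <- stepping_h <= 1
  } else {
    c1 <- standing_h >= 3
    c2 <- stepping_h >= 2
  }
  tibble::tibble(regimen = regimen, criterion_1 = c1, criterion_2 = c2,
                 fully_compliant = c1 & c2)
}
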