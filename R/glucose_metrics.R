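#' Summarise interstitial glucose over an interval
#'
#' Computes the daily glycaemic metric set over `[t0, t1]`: mean glucose,
#' glycaemic variability (%CV as a fraction, SD/mean), percent of present
#' epochs in range 3.9-10.0 mmol/L (TIR), above 10.0 (TAR) and below 3.0
#' (TBR), total trapezoidal AUC, and net incremental AUC obtained by
#' subtracting `baseline` (the day's waking glucose concentration) times the
#' covered duration from the total AUC.
#'
#' Epoch-count metrics (mean, CV, TIR/TAR/TBR) use epochs in `[t0, t1)`;
#' the trapezoid additionally uses a sample falling exactly at `t1` as the
#' right edge so that a full calendar day integrates over 24 h. Gaps longer
#' than `max_gap_min` are not bridged: they contribute no area and shrink the
#' covered duration used in the baseline product.
#'
#' @param series a [glucose_series()].
#' @param t0,t1 interval bounds (POSIXct).
#' @param baseline baseline glucose, mmol/L, subtracted per covered hour for
#'   the net iAUC.
#' @param max_gap_min maximum gap bridged linearly, minutes.
#' @param tir_range,tar_above,tbr_below range thresholds, mmol/L.
#' @return one-row tibble: `mean_glucose`, `cv`, `tir`, `tar`, `tbr` (%),
#'   `total_auc`, `net_iauc` (mmol/L x h), `covered_h`, `n_epochs`, `valid`.
#'   Fewer than 2 present epochs gives an all-`NA` row with `valid = FALSE`.
#' @export
summarise_interval <- function(series, t0, t1, baseline,
                               max_gap_min = 60,
                               tir_range = c(3.9, 10.0),
                               tar_above = 10.0,
                               tbr_below = 3.0) {
  in_stat <- series$timestamp >= t0 & series$timestamp < t1
  in_int <- series$timestamp >= t0 & series$timestamp <= t1
  g <- series$glucose[in_stat]
  n <- length(g)
  if (n < 2 || is.na(baseline)) {
    return(tibble::new_tibble(list(
      mean_glucose = NA_real_, cv = NA_real_, tir = NA_real_, tar = NA_real_,
      tbr = NA_real_, total_auc = NA_real_, net_iauc = NA_real_,
      covered_h = NA_real_, n_epochs = n, valid = FALSE
    ), nrow = 1L))
  }
  tr <- trapezoid_auc(series$timestamp[in_int], series$glucose[in_int],
                      max_gap_min = max_gap_min)
  tibble::new_tibble(list(
    mean_glucose = mean(g),
    cv = sd(g) / mean(g),
    tir = 100 * mean(g >= tir_range[1] & g <= tir_range[2]),
    tar = 100 * mean(g > tar_above),
    tbr = 100 * mean(g < tbr_below),
    total_auc = tr$auc,
    net_iauc = tr$auc - baseline * tr$covered_h,
    covered_h = tr$covered_h,
    n_epochs = n,
    valid = TRUE
  ), nrow = 1L)
}

#' Waking glucose concentration for a day
#'
#' The baseline used for the daily net iAUC: by default the first present
#' epoch at or after the detected wake time (`rule = "first_waking"`), or the
#' mean of epochs in the first `fasting_minutes` after waking
#' (`rule = "fasting_mean"`).
#'
#' @param series a [glucose_series()].
#' @param waking a [waking_window()].
#' @param rule baseline rule.
#' @param fasting_minutes averaging window for `"fasting_mean"`.
#' @return mmol/L, or `NA` when no sample is available.
#' @export
waking_glucose <- function(series, waking,
                           rule = c("first_waking", "fasting_mean"),
                           fasting_minutes = 60) {
  rule <- match.arg(rule)
  after <- series$timestamp >= waking$wake_time &
    series$timestamp < waking$sleep_time
  if (!any(after)) return(NA_real_)
  if (rule == "first_waking") {
    return(series$glucose[which(after)[1]])
  }
  win <- after & series$timestamp < waking$wake_time + fasting_minutes * 60
  if (!any(win)) return(NA_real_)
  mean(series$glucose[win])
}

#' Postprandial 2-h incremental AUC for one meal
#'
#' Trapezoidal AUC of glucose over the two hours following `meal_time`, minus
#' the last glucose concentration prior to the meal multiplied by the covered
#' duration. The value can be negative. The baseline sample must fall within
#' `baseline_lookback_min` minutes before the meal; otherwise, or when fewer
#' than 2 epochs are present in the window, the result is `NA` and the meal
#' is excluded from that day's mean.
#'
#' @param series a [glucose_series()].
#' @param meal_time POSIXct meal start.
#' @param window_h postprandial window length, hours.
#' @param baseline_lookback_min how far back the baseline sample may be.
#' @param max_gap_min gap-bridging limit for the trapezoid.
#' @return one-row tibble: `iauc` (mmol/L x h over the window), `baseline`,
#'   `covered_h`, `valid`.
#' @export
postprandial_iauc <- function(series, meal_time, window_h = 2,
                              baseline_lookback_min = 60,
                              max_gap_min = 60) {
  before <- series$timestamp < meal_time &
    series$timestamp >= meal_time - baseline_lookback_min * 60
  baseline <- if (any(before)) series$glucose[max(which(before))] else NA_real_
  in_win <- series$timestamp >= meal_time &
    series$timestamp <= meal_time + window_h * 3600
  tr <- trapezoid_auc(series$timestamp[in_win], series$glucose[in_win],
                      max_gap_min = max_gap_min)
  if (is.na(baseline) || tr$n < 2) {
    return(tibble::new_tibble(list(iauc = NA_real_, baseline = baseline,
                                   covered_h = NA_real_, valid = FALSE),
                              nrow = 1L))
  }
  tibble::new_tibble(list(
    iauc = tr$auc - baseline * tr$covered_h,
    baseline = baseline,
    covered_h = tr$covered_h,
    valid = TRUE
  ), nrow = 1L)
}

#' Mean of per-day metric values within a regimen
#'
#' Regimen-level metrics are the unweighted mean of the eligible (valid)
#' days' values; `NA` days are dropped. Zero usable days gives `NA`, which
#' excludes the participant-regimen from analysis.
#'
#' @param values per-day metric values for one participant-regimen.
#' @return scalar mean, or `NA_real_`.
#' @export
daily_then_regimen_mean <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  mean(values)
}
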