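#' Classify a participant-day's validity on both streams
#'
#' Applies the trial's valid-day rules: the FGM day is valid when strictly
#' more than 70% of the 24-h period's epochs were recorded; the activPAL wear
#' day is valid when wear time is at least 10 h, at least 500 steps were
#' recorded, and strictly less than 95% of (wear) time was spent in a single
#' activity. Absent data yields an invalid day with zeroed quantities.
#'
#' @param glucose a [glucose_series()] (may be empty).
#' @param events a [pal_events()] series (may be empty).
#' @param date calendar date.
#' @param fgm_coverage_min FGM coverage threshold (exclusive).
#' @param wear_min_h minimum wear time, hours (inclusive).
#' @param steps_min minimum steps (inclusive).
#' @param max_single_activity maximum fraction of wear time in one activity
#'   (exclusive).
#' @return one-row tibble: `date`, `fgm_coverage`, `fgm_valid`, `wear_h`,
#'   `steps`, `max_single_activity_fraction`, `pal_valid`, `both_valid`.
#' @export
classify_day <- function(glucose, events, date,
                         fgm_coverage_min = 0.70,
                         wear_min_h = 10,
                         steps_min = 500,
                         max_single_activity = 0.95) {
  date <- lubridate::as_date(date)
  cov <- if (nrow(glucose)) epoch_coverage(glucose, date) else 0
  tot <- daily_totals(events, date)
  frac <- if (tot$wear_h > 0) {
    max(tot$sedentary_h, tot$standing_h, tot$stepping_h) / tot$wear_h
  } else {
    1
  }
  fgm_valid <- cov > fgm_coverage_min
  pal_valid <- tot$wear_h >= wear_min_h && tot$steps >= steps_min &&
    frac < max_single_activity
  tibble::new_tibble(list(
    date = date,
    fgm_coverage = cov,
    fgm_valid = fgm_valid,
    wear_h = tot$wear_h,
    steps = tot$steps,
    max_single_activity_fraction = frac,
    pal_valid = pal_valid,
    both_valid = fgm_valid && pal_valid
  ), nrow = 1L)
}

#' Days of a regimen eligible for analysis
#'
#' A date is eligible when it falls inside the regimen interval and both the
#' FGM and activPAL streams are valid on it. An empty result means the
#' participant is excluded from that regimen's analysis (at least one doubly
#' valid day is required).
#'
#' @param validities tibble of [classify_day()] rows.
#' @param regimen_start,regimen_end first and last calendar date of the
#'   regimen (inclusive).
#' @return vector of eligible dates (possibly empty).
#' @export
eligible_days <- function(validities, regimen_start, regimen_end) {
  regimen_start <- lubridate::as_date(regimen_start)
  regimen_end <- lubridate::as_date(regimen_end)
  keep <- validities$both_valid &
    validities$date >= regimen_start & validities$date <= regimen_end
  sort(validities$date[keep])
}
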