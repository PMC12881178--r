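# Internal time helpers. All timestamps are timezone-naive local clock times
# represented as POSIXct in UTC; epochs are left-labelled and half-open,
# [t, t + epoch_minutes).

.tz <- "UTC"

as_clock_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::force_tz(x, .tz))
  }
  out <- suppressWarnings(lubridate::ymd_hms(x, tz = .tz, truncated = 3))
  if (anyNA(out) && !anyNA(x)) {
    stop("ambiguous or unparseable timestamp format", call. = FALSE)
  }
  out
}

day_start <- function(date) {
  lubridate::as_datetime(lubridate::as_date(date), tz = .tz)
}

day_end <- function(date) {
  day_start(date) + 86400
}

floor_epoch <- function(t, epoch_minutes = 15L) {
  lubridate::floor_date(t, unit = lubridate::minutes(epoch_minutes))
}

hours_between <- function(t0, t1) {
  as.numeric(difftime(t1, t0, units = "hours"))
}

#' Trapezoidal area under a sampled curve with gap handling
#'
#' Integrates a sparsely sampled, epoch-averaged signal by the trapezoid rule.
#' Consecutive samples separated by more than `max_gap_min` minutes are not
#' bridged: the curve is integrated segment-wise and the gap contributes
#' neither area nor covered duration.
#'
#' @param times POSIXct sample times (sorted, unique).
#' @param values numeric sample values.
#' @param max_gap_min maximum gap, in minutes, across which two samples are
#'   joined linearly.
#' @return list with `auc` (value-units x hours), `covered_h` (hours of the
#'   interval actually integrated) and `n` (number of samples used).
#' @keywords internal
trapezoid_auc <- function(times, values, max_gap_min = 60) {
  keep <- !is.na(values)
  times <- times[keep]
  values <- values[keep]
  n <- length(values)
  if (n < 2) {
    return(list(auc = NA_real_, covered_h = if (n == 1) 0 else NA_real_, n = n))
  }
  dt <- as.numeric(diff(times), units = "hours")
  ok <- dt <= max_gap_min / 60 + 1e-9
  mid <- (values[-n] + values[-1]) / 2
  list(
    auc = sum(mid[ok] * dt[ok]),
    covered_h = sum(dt[ok]),
    n = n
  )
}
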