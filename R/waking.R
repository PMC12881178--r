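#' Construct a waking window
#'
#' @param date calendar date the window belongs to.
#' @param wake_time,sleep_time POSIXct bounds; sleep may fall after midnight.
#' @param fallback logical; TRUE when the window is a configured default
#'   rather than one detected from the posture stream.
#' @return list of class `waking_window` with `date`, `wake_time`,
#'   `sleep_time`, `duration_h`, `fallback`.
#' @export
waking_window <- function(date, wake_time, sleep_time, fallback = FALSE) {
  duration_h <- hours_between(wake_time, sleep_time)
  if (is.na(duration_h) || duration_h <= 0 || duration_h > 24) {
    stop("waking window must have 0 < duration <= 24 h", call. = FALSE)
  }
  structure(
    list(date = lubridate::as_date(date), wake_time = wake_time,
         sleep_time = sleep_time, duration_h = duration_h,
         fallback = isTRUE(fallback)),
    class = "waking_window"
  )
}

#' Detect a participant-day's waking window from the posture stream
#'
#' The waking window is the complement of the night's sleep, inferred with a
#' transparent heuristic: a candidate sleep block is a maximal run of
#' sedentary and/or nonwear events with zero steps lasting at least
#' `min_sleep_h` hours. The block ending the night before `date` and the
#' block starting the night of `date` are chosen as the candidates with the
#' greatest overlap with the night anchor window (default 22:00-10:00);
#' the waking window runs from the end of the first to the start of the
#' second. If either block is missing the configured fallback window
#' (default 07:00-23:00) is returned with a warning.
#'
#' @param events a [pal_events()] series covering the night before and after
#'   `date`.
#' @param date calendar date.
#' @param min_sleep_h minimum length of a candidate sleep block, hours.
#' @param night_anchor numeric `c(start_h, end_h)` clock hours of the night
#'   anchor window; the end is on the following day.
#' @param fallback_window numeric `c(wake_h, sleep_h)` clock hours used when
#'   no candidate block is found.
#' @return a [waking_window()].
#' @export
detect_waking_window <- function(events, date,
                                 min_sleep_h = 3,
                                 night_anchor = c(22, 10),
                                 fallback_window = c(7, 23)) {
  date <- lubridate::as_date(date)
  sleepish <- events$activity %in% c("sedentary", "nonwear") & events$steps == 0
  r <- rle(sleepish)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  blocks <- tibble::tibble(
    start = events$start[idx_start[r$values]],
    end = events$start[idx_end[r$values]] +
      events$duration_s[idx_end[r$values]]
  )
  blocks <- blocks[hours_between(blocks$start, blocks$end) >= min_sleep_h, ,
                   drop = FALSE]

  pick <- function(anchor_lo, anchor_hi) {
    ov <- pmin(as.numeric(blocks$end), as.numeric(anchor_hi)) -
      pmax(as.numeric(blocks$start), as.numeric(anchor_lo))
    if (!nrow(blocks) || all(ov <= 0)) return(NULL)
    blocks[which.max(ov), ]
  }

  night_before <- pick(day_start(date - 1) + night_anchor[1] * 3600,
                       day_start(date) + night_anchor[2] * 3600)
  night_after <- pick(day_start(date) + night_anchor[1] * 3600,
                      day_start(date + 1) + night_anchor[2] * 3600)

  if (is.null(night_before) || is.null(night_after) ||
      night_before$end >= night_after$start) {
    warning("no usable sleep block around ", format(date),
            "; using fallback waking window", call. = FALSE)
    return(waking_window(date,
                         day_start(date) + fallback_window[1] * 3600,
                         day_start(date) + fallback_window[2] * 3600,
                         fallback = TRUE))
  }
  waking_window(date, night_before$end, night_after$start)
}

#' Rescale an extensive waking-hours metric to a nominal 16-h day
#'
#' Extensive metrics (time-integrals such as net iAUC, or time-in-range
#' minutes) accumulated over a waking window of `duration_h` hours are
#' rescaled by `16 / duration_h`. Intensive metrics (means, %CV, percent of
#' epochs in range) are reported unchanged and must not be passed here.
#'
#' @param value extensive metric aggregated over the waking window.
#' @param duration_h waking window duration, hours (> 0).
#' @param target_h nominal day length, default 16 h.
#' @return rescaled metric.
#' @export
normalise_to_16h <- function(value, duration_h, target_h = 16) {
  if (any(duration_h <= 0)) stop("duration must be > 0", call. = FALSE)
  value * target_h / duration_h
}

#' @export
print.waking_window <- function(x, ...) {
  cat(sprintf("<waking_window> %s: %s -> %s (%.2f h)%s\n",
              format(x$date), format(x$wake_time, "%H:%M"),
              format(x$sleep_time, "%H:%M"), x$duration_h,
              if (x$fallback) " [fallback]" else ""))
  invisible(x)
}
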