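.pal_activities <- c("sedentary", "standing", "stepping", "nonwear")

#' Construct a canonical activPAL posture-event series
#'
#' An event series is a tibble with columns `participant_id`, `start`
#' (POSIXct), `duration_s`, `activity` (one of `"sedentary"`, `"standing"`,
#' `"stepping"`, `"nonwear"`), `steps` and derived `cadence` (steps per
#' minute; 0 for non-stepping events). Events must be non-overlapping; gaps
#' longer than `nonwear_gap_s` are filled with explicit nonwear events so the
#' series tiles its monitoring span.
#'
#' @param participant_id single string.
#' @param start event start times.
#' @param duration_s event durations, seconds (> 0).
#' @param activity activity class per event.
#' @param steps step count per event; positive exactly when `activity` is
#'   `"stepping"`.
#' @param nonwear_gap_s gaps larger than this are recorded as nonwear; the
#'   default 0 expects contiguous files and records any gap as nonwear.
#' @return tibble of class `pal_events`, ordered by start time.
#' @export
pal_events <- function(participant_id, start, duration_s, activity, steps,
                       nonwear_gap_s = 0) {
  stopifnot(length(participant_id) == 1L)
  start <- as_clock_time(start)
  duration_s <- as.numeric(duration_s)
  steps <- as.numeric(steps)
  activity <- as.character(activity)
  if (any(is.na(match(activity, .pal_activities)))) {
    stop("unknown activity class; expected one of ",
         paste(.pal_activities, collapse = ", "), call. = FALSE)
  }
  if (any(duration_s <= 0)) stop("event durations must be > 0", call. = FALSE)
  bad_steps <- (steps > 0) != (activity == "stepping")
  if (any(bad_steps)) {
    stop("steps must be positive exactly for stepping events", call. = FALSE)
  }

  ord <- order(start)
  start <- start[ord]
  duration_s <- duration_s[ord]
  activity <- activity[ord]
  steps <- steps[ord]
  end <- start + duration_s
  if (length(start) > 1) {
    # timestamps are stored at millisecond precision; sub-5-ms overlaps or
    # gaps are treated as contiguous
    gap_s <- as.numeric(start[-1]) - as.numeric(end[-length(end)])
    if (any(gap_s < -5e-3)) stop("overlapping events", call. = FALSE)
    fill <- which(gap_s > max(nonwear_gap_s, 5e-3))
    if (length(fill)) {
      nw_start <- end[fill]
      nw_dur <- gap_s[fill]
      start <- c(start, nw_start)
      duration_s <- c(duration_s, nw_dur)
      activity <- c(activity, rep("nonwear", length(fill)))
      steps <- c(steps, rep(0, length(fill)))
      ord <- order(start)
      start <- start[ord]
      duration_s <- duration_s[ord]
      activity <- activity[ord]
      steps <- steps[ord]
    }
  }

  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    start = start,
    duration_s = duration_s,
    activity = activity,
    steps = steps,
    cadence = ifelse(activity == "stepping", steps / (duration_s / 60), 0)
  )
  structure(out, class = c("pal_events", class(out)))
}

#' Read an activPAL-style posture-event CSV
#'
#' Dialect: columns `participant_id`, `start_iso`, `duration_s`, `activity`,
#' `steps`. Cadence is derived, not stored.
#'
#' @inheritParams read_fgm_export
#' @param nonwear_gap_s passed to [pal_events()].
#' @return a [pal_events()] series.
#' @export
read_activpal_events <- function(path, participant = NULL, nonwear_gap_s = 0) {
  if (!file.exists(path)) stop("activPAL file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "start_iso", "duration_s", "activity", "steps")
  if (!all(need %in% names(raw))) {
    stop("activPAL file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(participant)) {
    raw <- raw[raw$participant_id == participant, , drop = FALSE]
  }
  ids <- unique(raw$participant_id)
  if (length(ids) != 1L) {
    stop("activPAL file holds ", length(ids),
         " participants; pass `participant` to select one", call. = FALSE)
  }
  pal_events(ids, raw$start_iso, raw$duration_s, raw$activity, raw$steps,
             nonwear_gap_s = nonwear_gap_s)
}

#' Write a posture-event series in the package CSV dialect
#'
#' @param events a [pal_events()] series.
#' @param path output CSV path.
#' @export
write_activpal_events <- function(events, path) {
  out <- tibble::tibble(
    participant_id = events$participant_id,
    start_iso = format(events$start, "%Y-%m-%dT%H:%M:%OS3"),
    duration_s = events$duration_s,
    activity = events$activity,
    steps = events$steps
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Nonwear intervals of an event series
#'
#' @param events a [pal_events()] series.
#' @return tibble with `start` and `end` of each nonwear interval.
#' @export
nonwear_intervals <- function(events) {
  nw <- events[events$activity == "nonwear", , drop = FALSE]
  tibble::tibble(start = nw$start, end = nw$start + nw$duration_s)
}

# Numeric-core clip of an event stream to [a, b] (seconds since epoch);
# durations and steps split pro-rata at the boundaries.
clip_events_num <- function(s, d, act, steps, a, b) {
  e <- s + d
  ov_s <- pmax(s, a)
  ov_e <- pmin(e, b)
  keep <- which(ov_e - ov_s > 1e-9)
  dur <- ov_e[keep] - ov_s[keep]
  list(start = ov_s[keep], duration_s = dur, activity = act[keep],
       steps = steps[keep] * dur / d[keep])
}

# Clip events to [t0, t1); durations and steps are split pro-rata at the
# boundaries. Returns a plain tibble (possibly empty).
clip_events <- function(events, t0, t1) {
  cl <- clip_events_num(as.numeric(events$start), events$duration_s,
                        events$activity, events$steps,
                        as.numeric(t0), as.numeric(t1))
  tibble::new_tibble(list(
    participant_id = rep(events$participant_id[1] %||% NA_character_,
                         length(cl$start)),
    start = lubridate::as_datetime(cl$start, tz = .tz),
    duration_s = cl$duration_s,
    activity = cl$activity,
    steps = cl$steps,
    cadence = ifelse(cl$activity == "stepping",
                     cl$steps / (cl$duration_s / 60), 0)
  ), nrow = length(cl$start))
}

totals_from_clip <- function(cl) {
  sed <- sum(cl$duration_s[cl$activity == "sedentary"]) / 3600
  std <- sum(cl$duration_s[cl$activity == "standing"]) / 3600
  stp <- sum(cl$duration_s[cl$activity == "stepping"]) / 3600
  nw <- sum(cl$duration_s[cl$activity == "nonwear"]) / 3600
  list(sedentary_h = sed, standing_h = std, stepping_h = stp,
       nonwear_h = nw, wear_h = sed + std + stp, steps = sum(cl$steps))
}

#' Daily posture totals
#'
#' Sums hours of sitting/lying, standing and stepping (plus wear time and
#' steps) over one calendar day, optionally restricted to a waking window.
#' Events straddling the day or window boundary are split pro-rata for both
#' duration and steps.
#'
#' @param events a [pal_events()] series.
#' @param day calendar date.
#' @param waking optional [waking_window()] (or list with `wake_time`,
#'   `sleep_time`) restricting the totals.
#' @return one-row tibble: `sedentary_h`, `standing_h`, `stepping_h`,
#'   `wear_h`, `nonwear_h`, `steps`.
#' @export
daily_totals <- function(events, day, waking = NULL) {
  if (is.null(waking)) {
    t0 <- day_start(day)
    t1 <- day_end(day)
  } else {
    # Table-4-style waking-day totals: the window belongs to `day` even when
    # sleep onset falls after midnight.
    t0 <- waking$wake_time
    t1 <- waking$sleep_time
  }
  cl <- clip_events_num(as.numeric(events$start), events$duration_s,
                        events$activity, events$steps,
                        as.numeric(t0), as.numeric(t1))
  tot <- totals_from_clip(cl)
  tibble::new_tibble(tot[c("sedentary_h", "standing_h", "stepping_h",
                           "nonwear_h", "wear_h", "steps")], nrow = 1L)
}
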