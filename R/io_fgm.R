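#' Construct a canonical FGM glucose series
#'
#' A glucose series is a tibble with one row per present 15-minute epoch and
#' columns `participant_id`, `timestamp` (left-labelled epoch start, local
#' clock) and `glucose` (mmol/L). Timestamps are floored to the epoch grid,
#' rows are sorted, duplicate epochs are resolved by `dedup`, and readings
#' outside the physical sensor range (1.1-27.8 mmol/L) are dropped or kept
#' according to `range_action`. Gaps are represented by absent rows, never by
#' zero glucose.
#'
#' @param participant_id single string identifying the wearer.
#' @param timestamp POSIXct (or ISO-8601 strings) sample times.
#' @param glucose numeric interstitial glucose, mmol/L.
#' @param epoch_minutes epoch length of the export; the FGM reader stores one
#'   averaged value per 15 minutes.
#' @param dedup how to resolve two rows mapping to one epoch: keep the first
#'   row, average them, or raise an error.
#' @param range_action `"drop"` removes out-of-range readings (with a count
#'   kept in the `n_out_of_range` attribute); `"error"` fails; `"keep"`
#'   retains them.
#' @return tibble of class `glucose_series`, ordered by strictly increasing
#'   epoch timestamps, with attributes `epoch_minutes`, `n_duplicates`,
#'   `n_out_of_range`.
#' @export
glucose_series <- function(participant_id, timestamp, glucose,
                           epoch_minutes = 15L,
                           dedup = c("keep_first", "mean", "error"),
                           range_action = c("drop", "error", "keep")) {
  dedup <- match.arg(dedup)
  range_action <- match.arg(range_action)
  stopifnot(length(participant_id) == 1L, length(timestamp) == length(glucose))
  timestamp <- floor_epoch(as_clock_time(timestamp), epoch_minutes)
  glucose <- as.numeric(glucose)

  keep <- !is.na(timestamp) & !is.na(glucose)
  timestamp <- timestamp[keep]
  glucose <- glucose[keep]

  out_of_range <- glucose < 1.1 | glucose > 27.8
  n_oor <- sum(out_of_range)
  if (n_oor > 0) {
    if (range_action == "error") {
      stop(n_oor, " glucose value(s) outside the 1.1-27.8 mmol/L sensor range",
           call. = FALSE)
    }
    if (range_action == "drop") {
      timestamp <- timestamp[!out_of_range]
      glucose <- glucose[!out_of_range]
    }
  }

  ord <- order(timestamp)
  timestamp <- timestamp[ord]
  glucose <- glucose[ord]
  dup <- duplicated(timestamp)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    if (dedup == "error") {
      stop(n_dup, " duplicate epoch(s) in glucose series", call. = FALSE)
    }
    if (dedup == "mean") {
      glucose <- as.numeric(tapply(glucose, as.numeric(timestamp), mean))
      timestamp <- unique(timestamp)
    } else {
      timestamp <- timestamp[!dup]
      glucose <- glucose[!dup]
    }
  }

  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    timestamp = timestamp,
    glucose = glucose
  )
  structure(out,
            class = c("glucose_series", class(out)),
            epoch_minutes = as.integer(epoch_minutes),
            n_duplicates = n_dup,
            n_out_of_range = n_oor)
}

#' Read an FGM 15-minute epoch export
#'
#' Expects the package CSV dialect: columns `participant_id`, `timestamp`
#' (ISO-8601 local clock) and `glucose_mmol_l`. Readings in mg/dL can be
#' accepted with `unit = "mg_dl"`, in which case they are converted by
#' 1/18.016. A file may contain several participants; `participant` selects
#' one, otherwise the file must contain exactly one id.
#'
#' @param path CSV file path.
#' @param participant optional participant id to extract.
#' @param unit `"mmol_l"` (default) or `"mg_dl"`.
#' @inheritParams glucose_series
#' @return a [glucose_series()].
#' @export
read_fgm_export <- function(path, participant = NULL, unit = c("mmol_l", "mg_dl"),
                            dedup = "keep_first", range_action = "drop") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("FGM export not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "timestamp", "glucose_mmol_l")
  if (!all(need %in% names(raw))) {
    stop("FGM export must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(participant)) {
    raw <- raw[raw$participant_id == participant, , drop = FALSE]
  }
  ids <- unique(raw$participant_id)
  if (length(ids) != 1L) {
    stop("FGM export holds ", length(ids),
         " participants; pass `participant` to select one", call. = FALSE)
  }
  g <- as.numeric(raw$glucose_mmol_l)
  if (unit == "mg_dl") g <- g / 18.016
  parsed <- !is.na(raw$timestamp) & !is.na(g)
  if (!any(parsed)) stop("no parseable rows in FGM export", call. = FALSE)
  glucose_series(ids, raw$timestamp[parsed], g[parsed],
                 dedup = dedup, range_action = range_action)
}

#' Write a glucose series in the package FGM CSV dialect
#'
#' Lossless counterpart of [read_fgm_export()]: the written file re-reads to
#' an identical series. An empty series produces a header-only file.
#'
#' @param series a [glucose_series()] (or tibble with the same columns).
#' @param path output CSV path.
#' @export
write_fgm_export <- function(series, path) {
  out <- tibble::tibble(
    participant_id = series$participant_id,
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    glucose_mmol_l = series$glucose
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Fraction of a calendar day's epochs present in a glucose series
#'
#' A 24-h day holds 96 15-minute epochs; the valid-day rule requires strictly
#' more than 70% of them to be present.
#'
#' @param series a [glucose_series()].
#' @param day calendar date.
#' @return fraction in \[0, 1\].
#' @export
epoch_coverage <- function(series, day) {
  epm <- attr(series, "epoch_minutes") %||% 15L
  n_epochs <- 1440 / as.numeric(epm)
  t0 <- day_start(day)
  t1 <- day_end(day)
  sum(series$timestamp >= t0 & series$timestamp < t1) / n_epochs
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf(
    "<glucose_series> participant %s: %d epochs (%d-min), %s to %s\n",
    x$participant_id[1] %||% "?", nrow(x),
    attr(x, "epoch_minutes") %||% 15L,
    if (nrow(x)) format(min(x$timestamp)) else "-",
    if (nrow(x)) format(max(x$timestamp)) else "-"
  ))
  NextMethod()
}
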