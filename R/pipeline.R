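#' Pipeline configuration
#'
#' Collects every filtering threshold and analysis rule in one auditable
#' block: FGM coverage (> 0.70 of the 24-h day), activPAL wear-day rules
#' (>= 10 h wear, >= 500 steps, < 95% of wear in one activity), glucose
#' range thresholds, the MVPA cadence threshold (100 steps/min), the
#' waking-window heuristic settings and the 16-h normalisation.
#'
#' @param ... named overrides of any default component.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fgm = list(coverage_min = 0.70, max_gap_min = 60,
               baseline_lookback_min = 60, dedup = "keep_first",
               baseline_rule = "first_waking"),
    glucose = list(tir_range = c(3.9, 10.0), tar_above = 10.0,
                   tbr_below = 3.0, postprandial_window_h = 2),
    activpal = list(wear_min_h = 10, steps_min = 500,
                    max_single_activity = 0.95, cadence_mvpa = 100,
                    nonwear_gap_s = 0),
    waking = list(min_sleep_h = 3, night_anchor = c(22, 10),
                  fallback_window = c(7, 23), normalise_h = 16),
    stats = list(d_method = "pooled")
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]] %||% list(), over[[nm]])
  }
  if (cfg$fgm$coverage_min < 0 || cfg$fgm$coverage_min > 1) {
    stop("fgm coverage threshold must be a fraction in [0, 1]", call. = FALSE)
  }
  if (cfg$activpal$max_single_activity <= 0 ||
      cfg$activpal$max_single_activity > 1) {
    stop("max_single_activity must be a fraction in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

# outcome -> covariate family
.activity_outcomes <- c(
  "sitting_h", "standing_h", "stepping_h", "light_stepping_h",
  "mvpa_stepping_h", "steps", "light_steps", "mvpa_steps",
  "sed_0_30_h", "sed_30_60_h", "sed_ge60_h", "sed_ge30_h",
  "sed_n_0_30", "sed_n_30_60", "sed_n_gt60", "sed_n_gt30", "sed_n_bouts",
  "sit_upright_transitions", "wear_h"
)
.glucose_outcomes <- c(
  "mean_glucose_24h", "cv_24h", "tir_24h", "tar_24h", "tbr_24h",
  "net_iauc_24h", "waking_glucose",
  "mean_glucose_16h", "cv_16h", "tir_16h", "tar_16h", "tbr_16h",
  "net_iauc_16h",
  "iauc_breakfast", "iauc_lunch", "iauc_dinner"
)

#' All outcome names the pipeline can analyse
#' @return character vector.
#' @export
pipeline_outcomes <- function() c(.activity_outcomes, .glucose_outcomes)

needs_glucose <- function(outcomes) {
  any(outcomes %in% .glucose_outcomes)
}

# Per-day metrics for one participant. Returns list(day_metrics, compliance).
participant_day_metrics <- function(glucose, events, meals, regimen_days,
                                    config, outcomes) {
  glu_wanted <- needs_glucose(outcomes)
  pp_wanted <- any(c("iauc_breakfast", "iauc_lunch", "iauc_dinner") %in%
                     outcomes)
  daily24_wanted <- any(outcomes %in% c(
    "mean_glucose_24h", "cv_24h", "tir_24h", "tar_24h", "tbr_24h",
    "net_iauc_24h"
  ))
  daily16_wanted <- any(outcomes %in% c(
    "mean_glucose_16h", "cv_16h", "tir_16h", "tar_16h", "tbr_16h",
    "net_iauc_16h", "waking_glucose"
  ))

  rows <- vector("list", nrow(regimen_days))
  for (i in seq_len(nrow(regimen_days))) {
    date <- regimen_days$date[i]
    regimen <- regimen_days$regimen[i]
    validity <- classify_day(
      glucose, events, date,
      fgm_coverage_min = config$fgm$coverage_min,
      wear_min_h = config$activpal$wear_min_h,
      steps_min = config$activpal$steps_min,
      max_single_activity = config$activpal$max_single_activity
    )
    row <- c(list(regimen = regimen), as.list(validity))
    if (!validity$both_valid || regimen == "WASHOUT") {
      rows[[i]] <- tibble::new_tibble(row, nrow = 1L)
      next
    }
    ww <- withCallingHandlers(
      detect_waking_window(events, date,
                           min_sleep_h = config$waking$min_sleep_h,
                           night_anchor = config$waking$night_anchor,
                           fallback_window = config$waking$fallback_window),
      warning = function(w) invokeRestart("muffleWarning")
    )
    act <- daily_activity(events, date, ww,
                          cadence_threshold = config$activpal$cadence_mvpa)
    row <- c(row, list(
      waking_duration_h = ww$duration_h,
      waking_fallback = ww$fallback,
      sitting_h = act$sedentary_h,
      standing_h = act$standing_h,
      stepping_h = act$stepping_h,
      light_stepping_h = act$light_h,
      mvpa_stepping_h = act$mvpa_h,
      steps_day = act$steps,
      light_steps = act$light_steps,
      mvpa_steps = act$mvpa_steps,
      sed_0_30_h = act$h_0_30,
      sed_30_60_h = act$h_30_60,
      sed_ge60_h = act$h_ge60,
      sed_ge30_h = act$h_ge30,
      sed_n_0_30 = act$n_0_30,
      sed_n_30_60 = act$n_30_60,
      sed_n_gt60 = act$n_gt60,
      sed_n_gt30 = act$n_ge30,
      sed_n_bouts = act$n_bouts,
      sit_upright_transitions = act$sit_upright_transitions,
      waking_wear_h = act$wear_h
    ))

    if (glu_wanted) {
      base <- waking_glucose(glucose, ww, rule = config$fgm$baseline_rule)
      if (daily24_wanted) {
        s24 <- summarise_interval(
          glucose, day_start(date), day_end(date), base,
          max_gap_min = config$fgm$max_gap_min,
          tir_range = config$glucose$tir_range,
          tar_above = config$glucose$tar_above,
          tbr_below = config$glucose$tbr_below
        )
        row <- c(row, list(
          mean_glucose_24h = s24$mean_glucose, cv_24h = s24$cv,
          tir_24h = s24$tir, tar_24h = s24$tar, tbr_24h = s24$tbr,
          total_auc_24h = s24$total_auc, net_iauc_24h = s24$net_iauc
        ))
      }
      if (daily16_wanted) {
        s16 <- summarise_interval(
          glucose, ww$wake_time, ww$sleep_time, base,
          max_gap_min = config$fgm$max_gap_min,
          tir_range = config$glucose$tir_range,
          tar_above = config$glucose$tar_above,
          tbr_below = config$glucose$tbr_below
        )
        row <- c(row, list(
          waking_glucose = base,
          mean_glucose_16h = s16$mean_glucose, cv_16h = s16$cv,
          tir_16h = s16$tir, tar_16h = s16$tar, tbr_16h = s16$tbr,
          net_iauc_16h = normalise_to_16h(s16$net_iauc, ww$duration_h,
                                          config$waking$normalise_h)
        ))
      }
      if (pp_wanted) {
        day_meals <- meals[meals$date == date, , drop = FALSE]
        for (m in c("breakfast", "lunch", "dinner")) {
          mt <- day_meals$time[day_meals$meal == m]
          v <- if (length(mt) == 1) {
            postprandial_iauc(
              glucose, mt,
              window_h = config$glucose$postprandial_window_h,
              baseline_lookback_min = config$fgm$baseline_lookback_min,
              max_gap_min = config$fgm$max_gap_min
            )$iauc
          } else {
            NA_real_
          }
          row[[paste0("iauc_", m)]] <- v
        }
      }
    }
    rows[[i]] <- tibble::new_tibble(row, nrow = 1L)
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline on a trial
#'
#' Executes the stage sequence read -> validate -> waking windows -> daily
#' metrics -> regimen means -> mixed models. Days are analysed when both the
#' FGM and activPAL streams are valid and the day belongs to a regimen
#' (washout days are never analysed). Participants lacking a doubly valid
#' day in either regimen are excluded, with the reason recorded. Posture
#' outcomes are adjusted for activPAL waking wear time; glucose outcomes for
#' BMI.
#'
#' @param trial a [simulate_trial()] / [read_trial_csv()] result, or a
#'   directory path containing trial CSVs.
#' @param config a [pipeline_config()].
#' @param outcomes outcome subset to model (default: all of
#'   [pipeline_outcomes()]).
#' @return list of class `sitless_results`: `day_metrics`,
#'   `regimen_summaries` (participant x regimen means), `effects` (one row
#'   per outcome), `compliance`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(trial, config = pipeline_config(),
                         outcomes = NULL) {
  if (is.character(trial)) trial <- read_trial_csv(trial)
  outcomes <- outcomes %||% pipeline_outcomes()
  bad <- setdiff(outcomes, pipeline_outcomes())
  if (length(bad)) {
    stop("unknown outcome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  glu_split <- split(trial$glucose, trial$glucose$participant_id)
  ev_split <- split(trial$events, trial$events$participant_id)
  meal_split <- split(trial$meals, trial$meals$participant_id)
  rd_split <- split(trial$regimen_days, trial$regimen_days$participant_id)

  day_metrics <- list()
  exclusions <- list()
  for (pid in trial$participants$participant_id) {
    dm <- participant_day_metrics(
      glu_split[[pid]], ev_split[[pid]], meal_split[[pid]], rd_split[[pid]],
      config, outcomes
    )
    dm <- dplyr::bind_cols(tibble::tibble(participant_id = pid), dm)
    n_valid <- tapply(
      dm$both_valid & dm$regimen != "WASHOUT",
      factor(dm$regimen, levels = c("SIT", "SITLESS")), sum
    )
    if (any(is.na(n_valid)) || any(n_valid == 0)) {
      exclusions[[pid]] <- tibble::tibble(
        participant_id = pid,
        reason = "no doubly valid day in at least one regimen"
      )
    }
    day_metrics[[pid]] <- dm
  }
  day_metrics <- dplyr::bind_rows(day_metrics)
  exclusions <- if (length(exclusions)) {
    dplyr::bind_rows(exclusions)
  } else {
    tibble::tibble(participant_id = character(0), reason = character(0))
  }
  analysed <- setdiff(trial$participants$participant_id,
                      exclusions$participant_id)
  if (length(analysed) < 2) stop("no analysable participants", call. = FALSE)

  valid <- day_metrics[
    day_metrics$both_valid & day_metrics$regimen != "WASHOUT" &
      day_metrics$participant_id %in% analysed, , drop = FALSE
  ]

  col_for <- function(outcome) switch(outcome, steps = "steps_day",
                                      wear_h = "waking_wear_h", outcome)
  per_reg <- function(col) {
    stats::aggregate(
      valid[[col]],
      by = list(participant_id = valid$participant_id,
                regimen = valid$regimen),
      FUN = daily_then_regimen_mean
    )$x
  }
  base <- stats::aggregate(
    valid$date, by = list(participant_id = valid$participant_id,
                          regimen = valid$regimen), FUN = length
  )
  summaries <- tibble::tibble(
    participant_id = base$participant_id,
    regimen = base$regimen,
    n_valid_days = base$x
  )
  summaries$wear_h <- per_reg("waking_wear_h")
  for (o in outcomes) summaries[[o]] <- per_reg(col_for(o))
  summaries <- dplyr::left_join(
    summaries, trial$participants[, c("participant_id", "bmi")],
    by = "participant_id"
  )

  effects <- dplyr::bind_rows(lapply(outcomes, function(o) {
    dat <- tibble::tibble(
      participant_id = summaries$participant_id,
      regimen = summaries$regimen,
      value = summaries[[o]],
      wear_h = summaries$wear_h,
      bmi = summaries$bmi
    )
    covar <- if (o %in% .activity_outcomes) "wear_h" else "bmi"
    if (o == "wear_h") covar <- NULL
    res <- fit_regimen_model(dat, covariates = covar,
                             d_method = config$stats$d_method)
    dplyr::bind_cols(tibble::tibble(outcome = o), res)
  }))

  compliance <- NULL
  if (all(c("standing_h", "stepping_h") %in% names(valid))) {
    compliance <- dplyr::bind_rows(lapply(seq_len(nrow(valid)), function(i) {
      dplyr::bind_cols(
        tibble::tibble(participant_id = valid$participant_id[i],
                       date = valid$date[i]),
        check_compliance(valid$standing_h[i], valid$stepping_h[i],
                         valid$regimen[i])
      )
    }))
  }

  structure(list(
    day_metrics = day_metrics,
    regimen_summaries = summaries,
    effects = effects,
    compliance = compliance,
    exclusions = exclusions,
    manifest = list(
      n_participants = length(analysed),
      outcomes = outcomes,
      config = config,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      version = as.character(utils::packageVersion("sitless"))
    )
  ), class = "sitless_results")
}

#' @export
print.sitless_results <- function(x, ...) {
  cat(sprintf(
    "<sitless_results> %d participants analysed, %d outcomes\n",
    x$manifest$n_participants, nrow(x$effects)
  ))
  print(x$effects, ...)
  invisible(x)
}
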