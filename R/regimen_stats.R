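#' Adjusted SITless-SIT contrast from a linear mixed model
#'
#' Fits `value ~ regimen + covariates + (1 | participant)` on
#' participant-by-regimen means. With two conditions per participant the
#' random intercept is exactly the compound-symmetry repeated-measures
#' structure. Inference uses Satterthwaite degrees of freedom (via
#' \pkg{lmerTest}); the 95% CI is Wald, `estimate +/- t(df) * SE`. When the
#' fit is singular or fails, the function falls back to a paired contrast on
#' covariate-adjusted residuals and flags it in `method`.
#'
#' @param data tibble with columns `participant_id`, `regimen` (values
#'   `"SIT"`/`"SITLESS"`), `value`, plus any covariate columns.
#' @param covariates character vector of covariate column names (e.g.
#'   `"wear_h"` for posture outcomes, `"bmi"` for glucose outcomes).
#' @param d_method Cohen's d denominator: pooled SD of the two regimen
#'   distributions (default) or the SD of the paired differences.
#' @return one-row tibble: `estimate` (SITless - SIT), `se`, `df`,
#'   `ci_lo`, `ci_hi`, `p_value`, `cohens_d`, `n_participants`, `method`.
#' @export
fit_regimen_model <- function(data, covariates = NULL,
                              d_method = c("pooled", "diff")) {
  d_method <- match.arg(d_method)
  data <- data[!is.na(data$value), , drop = FALSE]
  data$regimen <- factor(data$regimen, levels = c("SIT", "SITLESS"))
  if (!is.null(covariates)) {
    data <- data[complete.cases(data[, covariates, drop = FALSE]), ,
                 drop = FALSE]
  }
  n_part <- length(unique(data$participant_id))
  if (n_part < 2 || length(unique(data$regimen)) < 2) {
    stop("need >= 2 participants with both regimens", call. = FALSE)
  }

  rhs <- paste(c("regimen", covariates), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lmerTest::lmer(
      form, data = data,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    ))),
    error = function(e) NULL
  )

  if (!is.null(fit) && !lme4::isSingular(fit)) {
    co <- summary(fit)$coefficients["regimenSITLESS", ]
    est <- unname(co["Estimate"])
    se <- unname(co["Std. Error"])
    df <- unname(co["df"])
    p <- unname(co["Pr(>|t|)"])
    method <- "lmm"
  } else {
    pc <- paired_contrast(data, covariates)
    est <- pc$estimate
    se <- pc$se
    df <- pc$df
    p <- pc$p
    method <- "paired_fallback"
  }
  tcrit <- qt(0.975, df)
  tibble::tibble(
    estimate = est, se = se, df = df,
    ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
    p_value = p,
    cohens_d = cohens_d(data, method = d_method),
    n_participants = n_part,
    method = method
  )
}

# participant-matched SIT / SITLESS value pairs (complete pairs only)
regimen_pairs <- function(data) {
  sit <- data[data$regimen == "SIT", c("participant_id", "value")]
  sl <- data[data$regimen == "SITLESS", c("participant_id", "value")]
  m <- match(sit$participant_id, sl$participant_id)
  keep <- !is.na(m) & !is.na(sit$value) & !is.na(sl$value[m])
  list(sit = sit$value[keep], sitless = sl$value[m][keep])
}

# Paired fallback: residualise value on the covariates (pooled OLS), then a
# paired t-type contrast on within-participant SITLESS - SIT differences.
paired_contrast <- function(data, covariates = NULL) {
  if (!is.null(covariates) && length(covariates)) {
    f <- stats::as.formula(paste("value ~", paste(covariates, collapse = "+")))
    data$value <- residuals(lm(f, data = data)) +
      mean(data$value, na.rm = TRUE)
  }
  pairs <- regimen_pairs(data)
  diffs <- pairs$sitless - pairs$sit
  n <- length(diffs)
  if (n < 2) stop("paired contrast needs >= 2 complete pairs", call. = FALSE)
  se <- sd(diffs) / sqrt(n)
  est <- mean(diffs)
  list(estimate = est, se = se, df = n - 1,
       p = 2 * pt(abs(est / se), df = n - 1, lower.tail = FALSE))
}

#' Cohen's d for the regimen contrast
#'
#' `d = mean(SITLESS - SIT paired differences) / SD`, where the denominator
#' is either the pooled SD of the two regimen distributions (default; what a
#' between-condition standardised difference reports) or the SD of the
#' paired differences.
#'
#' @inheritParams fit_regimen_model
#' @param method denominator choice.
#' @return signed effect size; its sign matches the contrast's.
#' @export
cohens_d <- function(data, method = c("pooled", "diff")) {
  method <- match.arg(method)
  pairs <- regimen_pairs(data)
  diffs <- pairs$sitless - pairs$sit
  denom <- if (method == "pooled") {
    sqrt((var(pairs$sit) + var(pairs$sitless)) / 2)
  } else {
    sd(diffs)
  }
  if (!is.finite(denom) || denom == 0) {
    if (all(diffs == 0)) return(0)
    stop("zero SD in Cohen's d denominator", call. = FALSE)
  }
  mean(diffs) / denom
}
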