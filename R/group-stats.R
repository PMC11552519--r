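#' Per-session average task measures
#'
#' Session-level means of the three reports over all 48 trials: average HI
#' attribution (`HIAv`), average self-interest attribution (`SIAv`) and
#' average fairness expectation (`predAv`).
#'
#' @param sessions Sessions tibble (any number of participant-waves).
#' @return Tibble: one row per participant-wave with `HIAv`, `SIAv`,
#'   `predAv` plus the participant covariates.
#' @export
average_measures <- function(sessions) {
  miss <- which(!complete.cases(sessions[, report_cols()]))
  if (length(miss) > 0) {
    stop("missing reports at row(s) ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  sessions |>
    dplyr::group_by(.data$participant_id, .data$wave, .data$drug_group,
                    .data$gender, .data$sses) |>
    dplyr::summarise(
      HIAv = mean(.data$hi_report), SIAv = mean(.data$si_report),
      predAv = mean(.data$expectation_report), .groups = "drop"
    )
}

#' Test-retest stability regression
#'
#' The paper's stability procedure: robust (Huber M-estimation) regression of
#' the follow-up value on the baseline value, controlling for drug group,
#' gender and subjective socioeconomic status; the hypothesis test is based
#' on the t-value of the baseline coefficient. The ordinary-least-squares
#' adjusted R^2 of the same formula is reported alongside.
#'
#' @param data Data frame with one row per participant containing `follow`,
#'   `baseline`, `drug_group`, `gender`, `sses` (or rename via arguments).
#' @param follow,baseline Column names of the two measurements.
#' @return Tibble of coefficients (`term`, `estimate`, `se`, `t`), with the
#'   OLS `adj_r_squared` attached to every row for convenience.
#' @export
stability_regression <- function(data, follow = "follow", baseline = "baseline") {
  covars <- intersect(c("drug_group", "gender", "sses"), names(data))
  rhs <- paste(c(baseline, covars), collapse = " + ")
  fml <- as.formula(paste(follow, "~", rhs))
  X <- stats::model.matrix(fml, data = data)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear column(s) among: ",
         paste(colnames(X)[-1], collapse = ", "), call. = FALSE)
  }
  rfit <- MASS::rlm(fml, data = data, maxit = 100)
  ols <- lm(fml, data = data)
  cf <- summary(rfit)$coefficients
  tibble(
    term = rownames(cf), estimate = unname(cf[, "Value"]),
    se = unname(cf[, "Std. Error"]), t = unname(cf[, "t value"]),
    adj_r_squared = summary(ols)$adj.r.squared
  )
}

#' Outlier screening by OLS diagnostics
#'
#' Fits ordinary least squares of `response` on the design and flags points
#' with Cook's distance strictly greater than 1 or absolute standardized
#' residual strictly greater than 3 (points exactly at a threshold are not
#' flagged). The returned indices are excluded before mixed-effects
#' analyses, per-analysis rather than globally.
#'
#' @param response Numeric response vector.
#' @param design Data frame of covariates (all columns enter additively).
#' @return Integer vector of row indices to exclude (possibly empty).
#' @export
outlier_screen <- function(response, design) {
  design <- as.data.frame(design)
  if (length(response) <= ncol(design) + 1) {
    stop("too few observations for outlier screening (n <= p)", call. = FALSE)
  }
  df <- cbind(.response = response, design)
  fit <- lm(.response ~ ., data = df)
  cd <- cooks.distance(fit)
  sr <- rstandard(fit)
  unname(which(cd > 1 | abs(sr) > 3))
}

#' Wave-by-drug linear mixed model
#'
#' The paper's longitudinal contract: `measure ~ wave * drug + (1 |
#' participant)` with a participant random intercept, reporting the
#' wave-by-drug interaction estimate, standard error and (Satterthwaite)
#' p-value. p-values are uncorrected. With no repeated participants the
#' model degenerates to OLS with a warning.
#'
#' @param data Data frame with columns `value`, `wave`, `drug_group`,
#'   `participant_id` (one row per session).
#' @return Tibble of fixed effects: `term`, `estimate`, `se`, `statistic`,
#'   `p_value` (uncorrected).
#' @export
wave_drug_mixed_model <- function(data) {
  data$wave <- factor(data$wave, levels = c("baseline", "followup"))
  data$drug_group <- factor(data$drug_group, levels = c("placebo", "citalopram"))
  repeated <- any(duplicated(data$participant_id))
  if (!repeated) {
    warning("no repeated participants; falling back to ordinary least squares")
    fit <- lm(value ~ wave * drug_group, data = data)
    cf <- summary(fit)$coefficients
    return(tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                  se = unname(cf[, 2]), statistic = unname(cf[, 3]),
                  p_value = unname(cf[, 4])))
  }
  fit <- suppressMessages(lmerTest::lmer(
    value ~ wave * drug_group + (1 | participant_id), data = data))
  cf <- stats::coef(summary(fit))
  tibble(term = rownames(cf), estimate = unname(cf[, "Estimate"]),
         se = unname(cf[, "Std. Error"]), statistic = unname(cf[, "t value"]),
         p_value = unname(cf[, "Pr(>|t|)"]))
}
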