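#' Discrete report scale
#'
#' The response channels discretize \[0,1\] onto `n_bins` bin values
#' (default 11 equally spaced bins 0, 0.1, ..., 1). Observed reports are
#' snapped to the nearest bin before their likelihood is evaluated.
#'
#' @param n_bins Integer >= 2.
#' @param bin_values Optional explicit strictly increasing values with
#'   first 0 and last 1.
#' @return List of class `"cr_scale"` with `n_bins` and `bin_values`.
#' @export
report_scale <- function(n_bins = 11, bin_values = NULL) {
  if (is.null(bin_values)) bin_values <- seq(0, 1, length.out = n_bins)
  stopifnot(length(bin_values) >= 2, all(diff(bin_values) > 0),
            bin_values[1] == 0, bin_values[length(bin_values)] == 1)
  structure(list(n_bins = length(bin_values), bin_values = bin_values),
            class = "cr_scale")
}

# nearest-bin index (1-based); ties resolve to the lower bin
snap_to_bin <- function(x, scale) {
  vapply(x, function(v) which.min(abs(scale$bin_values - v)), integer(1))
}

#' Ethnicity (POC) reporting bias
#'
#' Attributions reported about non-white dictators are shifted on the logit
#' scale by `poc_bias` (any sign) before entering the report channel; the
#' learning core itself is unbiased. Values at 0 or 1 are clamped to
#' `[1e-6, 1 - 1e-6]` before the logit.
#'
#' @param value Model attribution in \[0,1\] (vectorized).
#' @param poc_bias Logit-scale shift.
#' @param is_nonwhite Logical; bias applies only when `TRUE`.
#' @return Biased value in (0,1) (or `value` unchanged).
#' @export
apply_poc_bias <- function(value, poc_bias, is_nonwhite) {
  if (!isTRUE(is_nonwhite) || poc_bias == 0) return(value)
  logistic(logit(clamp01(value)) + poc_bias)
}

#' Report channel distribution
#'
#' Probability of each report bin given the model's value: a squared-distance
#' softmax, `p(b) ∝ exp(-alpha_prec * (bin_value[b] - model_value)^2)`.
#' `alpha_prec = 0` yields uniform responding; large `alpha_prec`
#' concentrates on the nearest bin.
#'
#' @param model_value Channel's model value in \[0,1\].
#' @param alpha_prec Decision precision (>= 0).
#' @param scale A [report_scale()].
#' @return Probability vector over bins.
#' @export
report_distribution <- function(model_value, alpha_prec, scale = report_scale()) {
  d2 <- (scale$bin_values - model_value)^2
  w <- exp(-alpha_prec * (d2 - min(d2))) # shift for numerical stability
  w / sum(w)
}

channel_names <- function() c("expectation", "HI", "SI")

#' Per-trial report log-likelihood
#'
#' Sum of the three channel log-probabilities for one trial. The fairness
#' expectation is scored against `predict_fair(belief_before)` (it is given
#' before the split is seen); the HI and SI attributions against the
#' POC-bias-adjusted posterior marginals of `belief_after`. Reports are
#' snapped to the nearest bin; channel probabilities are floored at 1e-12.
#'
#' @param belief_before Belief state before the trial's outcome.
#' @param belief_after Belief state after the update.
#' @param trial One-row tibble (or list) with `expectation_report`,
#'   `hi_report`, `si_report`.
#' @param params `cr_params`.
#' @param is_nonwhite Logical ethnicity flag for the dictator.
#' @param scale A [report_scale()].
#' @param channels Channels entering the likelihood (subset of
#'   `c("expectation", "HI", "SI")`).
#' @return Scalar log-likelihood.
#' @export
trial_loglik <- function(belief_before, belief_after, trial, params,
                         is_nonwhite = FALSE, scale = report_scale(),
                         channels = channel_names()) {
  params <- as_agent_params(params)
  m <- marginal_attributions(belief_after)
  vals <- c(expectation = predict_fair(belief_before),
            HI = apply_poc_bias(m[["hi"]], params$POCbias, is_nonwhite),
            SI = apply_poc_bias(m[["si"]], params$POCbias, is_nonwhite))
  reps <- c(expectation = trial$expectation_report,
            HI = trial$hi_report, SI = trial$si_report)
  ll <- 0
  for (ch in channels) {
    p <- report_distribution(vals[[ch]], params$alphaPrec, scale)
    b <- snap_to_bin(reps[[ch]], scale)
    ll <- ll + log(max(p[b], 1e-12))
  }
  ll
}
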