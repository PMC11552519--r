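#' Model specification
#'
#' Defines one member of the model space: family kind, which of the 12
#' parameters are free, fixed (with values) or shared across the sample, and
#' which report channels enter the likelihood.
#'
#' @param name Identifier.
#' @param kind `"classify_refine"` or `"classic"`.
#' @param free Character vector of free parameter names.
#' @param fixed_values Named list of fixed parameter values.
#' @param shared Character vector of parameters fitted once across the whole
#'   sample (affects the BIC complexity penalty).
#' @param channels Report channels in the likelihood.
#' @return List of class `"cr_model_spec"`.
#' @export
model_spec <- function(name, kind = c("classify_refine", "classic"),
                       free = param_names(), fixed_values = list(),
                       shared = character(), channels = channel_names()) {
  kind <- match.arg(kind)
  all_p <- param_names()
  stopifnot(all(free %in% all_p), all(names(fixed_values) %in% all_p),
            all(shared %in% all_p), all(channels %in% channel_names()),
            length(channels) >= 1)
  accounted <- c(free, names(fixed_values), shared)
  if (anyDuplicated(accounted) || !setequal(accounted, all_p)) {
    stop("free, fixed and shared must partition the 12 parameter names", call. = FALSE)
  }
  structure(list(name = name, kind = kind, free = free,
                 fixed_values = fixed_values, shared = shared,
                 channels = channels),
            class = "cr_model_spec")
}

#' @export
print.cr_model_spec <- function(x, ...) {
  cat("<model spec>", x$name, "(", x$kind, ")\n")
  cat("  free  :", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed_values) > 0) {
    cat("  fixed :", paste(sprintf("%s=%g", names(x$fixed_values),
                                   unlist(x$fixed_values)), collapse = ", "), "\n")
  }
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

# merge a free-parameter vector (native space) with a spec's fixed values
spec_params <- function(spec, free_values, base = agent_params()) {
  p <- as.list(base)
  for (nm in names(spec$fixed_values)) p[[nm]] <- spec$fixed_values[[nm]]
  for (nm in names(free_values)) p[[nm]] <- free_values[[nm]]
  do.call(agent_params, p[param_names()])
}

#' Registry of standard model specifications
#'
#' The model space used in the comparisons: the full classify-refine model
#' (all 12 parameters free, including the POC bias), the winning model
#' (`EvRat = 1`, `POCbias = 0`, two parameters fewer than the full model),
#' the winning model with the POC bias restored, lesioned variants without
#' dictator-to-dictator carry-over (`lambda_other = 0`) or without forgetting
#' (`omega = 1`), the attribution-only winning model (expectation channel
#' excluded), and the classic 6x6 fixed-grid learner. Parameters inert in a
#' family (the count-learning parameters for the classic family; `dEv` and
#' `EvRat` for classify-refine, where only the prior means enter the filter)
#' are fixed rather than fitted.
#'
#' @return Named list of [model_spec()] objects.
#' @export
model_registry <- function() {
  winning_free <- setdiff(param_names(), c("EvRat", "POCbias"))
  specs <- list(
    cr_full = model_spec("cr_full", "classify_refine", free = param_names()),
    winning = model_spec("winning", "classify_refine", free = winning_free,
                         fixed_values = list(EvRat = 1, POCbias = 0)),
    winning_poc = model_spec("winning_poc", "classify_refine",
                             free = c(winning_free, "POCbias"),
                             fixed_values = list(EvRat = 1)),
    no_lambda = model_spec("no_lambda", "classify_refine",
                           free = setdiff(winning_free, "lambda_other"),
                           fixed_values = list(EvRat = 1, POCbias = 0, lambda_other = 0)),
    no_omega = model_spec("no_omega", "classify_refine",
                          free = setdiff(winning_free, "omega"),
                          fixed_values = list(EvRat = 1, POCbias = 0, omega = 1)),
    winning_attr = model_spec("winning_attr", "classify_refine",
                              free = winning_free,
                              fixed_values = list(EvRat = 1, POCbias = 0),
                              channels = c("HI", "SI")),
    classic_full = model_spec("classic_full", "classic",
                              free = c("pHI0", "pSI0", "dEv", "EvRat",
                                       "alphaPrec", "wH", "wS", "w0"),
                              fixed_values = list(aEv = 1e6, omega = 1,
                                                  lambda_other = 0, POCbias = 0))
  )
  specs
}

#' Information criteria for a fitted session
#'
#' Per-participant BIC and AIC from the MAP log-likelihood. BIC uses the
#' small-sample (AICc-style) correction `2k(k+1)/(n-k-1)`; the uncorrected
#' BIC is also returned. A parameter fitted once across the whole sample
#' contributes an equivalent per-participant penalty of
#' `ln(n_total)/n_participants`, so the summed penalty over the sample is
#' `ln(n_total)` — consistent with BIC/2 approximating log model evidence.
#'
#' @param fit A `cr_fit` object, a fits tibble (from [fit_sessions()]), or a
#'   numeric log-likelihood.
#' @param spec The [model_spec()] used for the fit.
#' @param n_datapoints Report datapoints per participant (3 channels x 12
#'   trials x 4 blocks = 144 for a complete all-channel session); taken from
#'   the fit when available.
#' @param sample_size_total Total datapoints across the sample (only needed
#'   with shared parameters).
#' @param n_participants Number of participants sharing the shared
#'   parameters.
#' @return Tibble with `bic`, `aic`, `bic_uncorrected`, `k_effective`.
#' @export
information_criteria <- function(fit, spec, n_datapoints = NULL,
                                 sample_size_total = NULL, n_participants = 1) {
  if (inherits(fit, "cr_fit")) {
    loglik <- fit$loglik
    n_datapoints <- n_datapoints %||% fit$n_datapoints
  } else if (is.data.frame(fit)) {
    loglik <- fit$loglik
    n_datapoints <- n_datapoints %||% fit$n_datapoints
  } else {
    loglik <- fit
    if (is.null(n_datapoints)) stop("n_datapoints required", call. = FALSE)
  }
  k_free <- length(spec$free)
  n_shared <- length(spec$shared)
  n_i <- n_datapoints
  if (n_shared > 0 && is.null(sample_size_total)) {
    stop("sample_size_total required with shared parameters", call. = FALSE)
  }
  k_eff <- k_free + if (n_shared > 0) {
    n_shared / n_participants * (log(sample_size_total) / log(n_i))
  } else 0
  if (any(n_i <= k_eff + 1)) {
    stop("small-sample correction undefined: n_datapoints <= k + 1", call. = FALSE)
  }
  bic0 <- k_eff * log(n_i) - 2 * loglik
  corr <- 2 * k_eff * (k_eff + 1) / (n_i - k_eff - 1)
  tibble(bic = bic0 + corr, aic = 2 * k_eff - 2 * loglik,
         bic_uncorrected = bic0, k_effective = k_eff)
}

#' Compare two models across participants
#'
#' Per-participant BIC difference `BIC_A - BIC_B`, medians, two-sided rank
#' tests (both the unpaired rank-sum and, since the samples are paired, the
#' signed-rank test), and counts of participants for whom either model is
#' favored by at least `threshold` BIC points (6 by convention = modest
#' evidence).
#'
#' @param fits_a,fits_b Fit tibbles (from [fit_sessions()] with BIC columns,
#'   see [add_information_criteria()]) for the same participants.
#' @param threshold ΔBIC evidence threshold (default 6).
#' @param names Length-2 character labels for the two models.
#' @return Object of class `"cr_comparison"`: per-participant table, medians,
#'   test statistics, counts.
#' @export
compare_models <- function(fits_a, fits_b, threshold = 6,
                           names = c("A", "B")) {
  key <- intersect(c("participant_id", "wave"), intersect(colnames(fits_a), colnames(fits_b)))
  if (length(key) == 0) {
    stopifnot(nrow(fits_a) == nrow(fits_b))
    fits_a$participant_id <- fits_b$participant_id <- seq_len(nrow(fits_a))
    key <- "participant_id"
  }
  a <- fits_a[, c(key, "bic")]
  b <- fits_b[, c(key, "bic")]
  only_a <- dplyr::anti_join(a, b, by = key)
  only_b <- dplyr::anti_join(b, a, by = key)
  if (nrow(only_a) > 0 || nrow(only_b) > 0) {
    stop("participant mismatch between fits: ",
         paste(unique(c(only_a$participant_id, only_b$participant_id)), collapse = ", "),
         call. = FALSE)
  }
  tab <- dplyr::inner_join(a, b, by = key, suffix = c("_a", "_b")) |>
    dplyr::mutate(delta_bic = .data$bic_a - .data$bic_b)
  identical_fits <- all(tab$delta_bic == 0)
  rank_sum <- if (identical_fits) list(statistic = NA, p.value = 1) else
    suppressWarnings(wilcox.test(tab$bic_a, tab$bic_b, paired = FALSE))
  signed_rank <- if (identical_fits) list(statistic = NA, p.value = 1) else
    suppressWarnings(wilcox.test(tab$bic_a, tab$bic_b, paired = TRUE))
  res <- list(
    names = names, threshold = threshold, table = tab,
    median_bic = c(median(tab$bic_a), median(tab$bic_b)),
    median_delta = median(tab$delta_bic),
    n_favoring_a = sum(tab$delta_bic <= -threshold),
    n_favoring_b = sum(tab$delta_bic >= threshold),
    n_equivocal = sum(abs(tab$delta_bic) < threshold),
    rank_sum_p = rank_sum$p.value, signed_rank_p = signed_rank$p.value
  )
  structure(res, class = "cr_comparison")
}

#' @export
print.cr_comparison <- function(x, ...) {
  cat(sprintf("<model comparison> %s vs %s (n = %d)\n", x$names[1], x$names[2],
              nrow(x$table)))
  cat(sprintf("  median BIC: %s = %.2f, %s = %.2f (median dBIC = %.2f)\n",
              x$names[1], x$median_bic[1], x$names[2], x$median_bic[2],
              x$median_delta))
  cat(sprintf("  |dBIC| >= %g: %d favor %s, %d favor %s, %d equivocal\n",
              x$threshold, x$n_favoring_a, x$names[1], x$n_favoring_b,
              x$names[2], x$n_equivocal))
  cat(sprintf("  rank-sum p = %.3g, signed-rank p = %.3g\n",
              x$rank_sum_p, x$signed_rank_p))
  invisible(x)
}

#' @export
tidy.cr_comparison <- function(x, ...) {
  as_tibble(x$table)
}

#' @export
glance.cr_comparison <- function(x, ...) {
  tibble(
    model_a = x$names[1], model_b = x$names[2], n = nrow(x$table),
    median_bic_a = x$median_bic[1], median_bic_b = x$median_bic[2],
    median_delta_bic = x$median_delta,
    n_favoring_a = x$n_favoring_a, n_favoring_b = x$n_favoring_b,
    n_equivocal = x$n_equivocal,
    rank_sum_p = x$rank_sum_p, signed_rank_p = x$signed_rank_p
  )
}
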