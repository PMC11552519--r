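#' Session log-likelihood
#'
#' Log-likelihood of all of one session's reports under a model spec:
#' iterates the four dictator blocks in order (fresh state priors per block,
#' likelihood-count carry-over between blocks), accumulating the per-trial
#' channel log-probabilities. Fixed parameter values from the spec override
#' entries of `params`. The default engine is the compiled forward pass; the
#' `"r"` engine composes the exported belief operations and is the reference
#' the compiled path is tested against.
#'
#' @param params `cr_params` (or coercible); free parameters for the spec.
#' @param session One participant-wave sessions tibble (or a compiled
#'   session from the internal compiler).
#' @param spec A [model_spec()].
#' @param scale A [report_scale()].
#' @param engine `"cpp"` or `"r"`.
#' @return Scalar log-likelihood.
#' @export
session_loglik <- function(params, session, spec = model_registry()$winning,
                           scale = report_scale(), engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  params <- spec_params(spec, as.list(as_agent_params(params))[spec$free])
  comp <- if (is.data.frame(session)) compile_session(session, scale) else session
  if (engine == "cpp") {
    ll <- .session_loglik_cpp(
      unlist(params[param_names()]), comp$outcomes, comp$nonwhite,
      comp$exp_bin, comp$hi_bin, comp$si_bin, scale$bin_values,
      as.integer(spec$kind == "classic"),
      channel_names() %in% spec$channels
    )
    if (!is.finite(ll)) {
      stop("non-finite session log-likelihood (degenerate beliefs)", call. = FALSE)
    }
    return(ll)
  }
  session_loglik_r(params, comp, spec, scale)
}

# reference implementation composed from the exported belief operations
session_loglik_r <- function(params, comp, spec, scale = report_scale()) {
  belief <- init_beliefs(params, spec$kind)
  ll <- 0
  nB <- nrow(comp$outcomes)
  nT <- ncol(comp$outcomes)
  for (b in seq_len(nB)) {
    if (b > 1) belief <- carry_over(belief, params)
    nonwhite <- comp$nonwhite[b] == 1
    for (t in seq_len(nT)) {
      before <- belief
      outcome <- if (comp$outcomes[b, t] == 1) "fair" else "unfair"
      belief <- update_beliefs(belief, outcome, params)
      trial <- list(
        expectation_report = scale$bin_values[comp$exp_bin[b, t]],
        hi_report = scale$bin_values[comp$hi_bin[b, t]],
        si_report = scale$bin_values[comp$si_bin[b, t]]
      )
      ll <- ll + trial_loglik(before, belief, trial, params,
                              is_nonwhite = nonwhite, scale = scale,
                              channels = spec$channels)
      if (!is.finite(ll)) {
        stop(sprintf("non-finite log-likelihood at block %d trial %d", b, t),
             call. = FALSE)
      }
    }
  }
  ll
}

# datapoints entering the likelihood for a session under a spec
session_n_datapoints <- function(session, spec) {
  n_trials <- if (is.data.frame(session)) nrow(session) else session$n_trials
  length(spec$channels) * n_trials
}
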