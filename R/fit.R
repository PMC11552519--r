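#' Fitting configuration
#'
#' Controls the adaptive multistart coordinate grid search used for MAP
#' fitting. Gradient-based optimizers are deliberately not used: the
#' likelihood surface has local minima, so the optimizer is a derivative-free
#' iterated grid refinement. Each start sweeps the free dimensions in turn,
#' evaluating `n_grid` equally spaced candidates across `2*width` around the
#' current value (transformed space), recentering on the best, then shrinks
#' the widths by `contraction` and repeats until the grid spacing drops below
#' `tol` or `max_sweeps` is reached.
#'
#' @param n_starts Number of initial points: the prior mode plus
#'   `n_starts - 1` seeded draws from the fitting prior.
#' @param n_grid Grid points per dimension per sweep (odd, so the current
#'   value is always a candidate and the objective never decreases).
#' @param contraction Width shrink factor per sweep, in (0,1).
#' @param tol Convergence tolerance on the grid spacing (transformed space).
#' @param max_sweeps Sweep cap per start.
#' @param init_width Initial half-width of the per-dimension grid.
#' @param polish Run a derivative-free simplex (Nelder-Mead) refinement from
#'   the grid-search optimum, keeping it only if it improves the objective.
#'   Coordinate sweeps cannot move diagonally, so ridged likelihood surfaces
#'   (e.g. the retention/typing-confidence trade-off) benefit from this; the
#'   grid search itself is never replaced.
#' @param polish_maxit Simplex iteration cap.
#' @param priors Fitting priors, see [default_priors()].
#' @return List of class `"cr_fit_config"`.
#' @export
fit_config <- function(n_starts = 8, n_grid = 7, contraction = 0.5,
                       tol = 1e-3, max_sweeps = 40, init_width = 2,
                       polish = TRUE, polish_maxit = 2000,
                       priors = default_priors()) {
  stopifnot(n_starts >= 1, n_grid >= 3, n_grid %% 2 == 1,
            contraction > 0, contraction < 1, tol > 0, max_sweeps >= 1)
  structure(list(n_starts = n_starts, n_grid = n_grid,
                 contraction = contraction, tol = tol,
                 max_sweeps = max_sweeps, init_width = init_width,
                 polish = polish, polish_maxit = polish_maxit,
                 priors = priors),
            class = "cr_fit_config")
}

# Fast MAP objective over a spec's free parameters (transformed space).
# Avoids per-evaluation parameter-object construction: identical to
# session_loglik(untransform_params(theta), ...) + log_prior(..., free), and
# tested against that composition.
make_objective <- function(comp, spec, scale, priors) {
  free <- spec$free
  kind <- param_transform_kind()[free]
  par0 <- unlist(spec_params(spec, list())[param_names()])
  free_idx <- match(free, param_names())
  classic <- as.integer(spec$kind == "classic")
  chan <- channel_names() %in% spec$channels
  pr <- priors[free]
  dists <- vapply(pr, function(p) p$dist, character(1))
  pa <- vapply(pr, function(p) p$a, numeric(1))
  pb <- vapply(pr, function(p) p$b, numeric(1))
  is_logit <- kind == "logit"
  is_log <- kind == "log"
  i_beta <- dists == "beta"
  i_gamma <- dists == "gamma"
  i_norm <- dists == "normal"
  function(theta) {
    x <- theta
    x[is_logit] <- plogis(theta[is_logit])
    x[is_log] <- exp(theta[is_log])
    if (any(!is.finite(x))) return(-Inf)
    par <- par0
    par[free_idx] <- x
    ll <- .session_loglik_cpp(par, comp$outcomes, comp$nonwhite, comp$exp_bin,
                              comp$hi_bin, comp$si_bin, scale$bin_values,
                              classic, chan)
    if (!is.finite(ll)) return(-Inf)
    lp <- sum(dbeta(x[i_beta], pa[i_beta], pb[i_beta], log = TRUE)) +
      sum(dgamma(x[i_gamma], shape = pa[i_gamma], scale = pb[i_gamma], log = TRUE)) +
      sum(dnorm(x[i_norm], pa[i_norm], pb[i_norm], log = TRUE))
    if (!is.finite(lp)) return(-Inf)
    ll + lp
  }
}

# Adaptive coordinate grid search maximizer (transformed space).
# fn: function(named numeric vector) -> scalar (may be -Inf).
# Deterministic; monotone in the objective by construction.
grid_search_maximize <- function(fn, start, config) {
  x <- start
  fx <- fn(x)
  d <- length(x)
  width <- rep(config$init_width, d)
  trace <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(config$max_sweeps)) {
    for (j in seq_len(d)) {
      cand <- x[j] + seq(-width[j], width[j], length.out = config$n_grid)
      for (v in cand) {
        if (v == x[j]) next
        xj <- x
        xj[j] <- v
        fv <- fn(xj)
        if (is.finite(fv) && fv > fx) {
          x <- xj
          fx <- fv
        }
      }
    }
    trace <- c(trace, fx)
    width <- width * config$contraction
    spacing <- 2 * width / (config$n_grid - 1)
    if (all(spacing < config$tol)) {
      converged <- TRUE
      break
    }
  }
  list(par = x, value = fx, trace = trace, converged = converged)
}

#' Maximum-a-posteriori fit of one session
#'
#' Maximizes `session_loglik + log_prior` over the spec's free parameters in
#' transformed space by adaptive multistart coordinate grid search. Starts
#' are the prior mode plus seeded draws from the fitting prior; the best
#' final objective across starts wins. Deterministic given `seed`.
#'
#' @param session One participant-wave sessions tibble.
#' @param spec A [model_spec()].
#' @param config A [fit_config()].
#' @param scale A [report_scale()].
#' @param seed Integer seed (start-point draws).
#' @return A `cr_fit` object: `map_params`, `loglik`, `logpost`,
#'   `n_datapoints`, `n_free_params`, `optimizer_trace`, `converged`, `seed`.
#' @export
map_fit <- function(session, spec = model_registry()$winning,
                    config = fit_config(), scale = report_scale(), seed = 1) {
  comp <- if (is.data.frame(session)) compile_session(session, scale) else session
  free <- spec$free
  priors <- config$priors
  n_data <- session_n_datapoints(comp, spec)
  objective <- make_objective(comp, spec, scale, priors)

  if (length(free) == 0) {
    p <- spec_params(spec, list())
    ll <- session_loglik(p, comp, spec, scale)
    return(new_cr_fit(p, ll, ll, n_data, 0L, list(), TRUE, seed, spec))
  }

  starts <- withr::with_seed(seed, {
    s <- list(transform_params(prior_mode_params(priors))[free])
    if (config$n_starts > 1) {
      for (i in seq_len(config$n_starts - 1)) {
        s[[i + 1]] <- transform_params(prior_draw_params(priors))[free]
      }
    }
    s
  })

  best <- NULL
  traces <- list()
  for (i in seq_along(starts)) {
    res <- grid_search_maximize(objective, starts[[i]], config)
    traces[[i]] <- res$trace
    if (is.null(best) || (is.finite(res$value) && res$value > best$value)) {
      best <- res
    }
  }
  if (is.finite(best$value)) {
    # refinement pass: restart the adaptive grid from the incumbent optimum
    # with full widths; monotone, so the objective can only improve, and it
    # lets coordinates trapped by an early sweep escape
    res <- grid_search_maximize(objective, best$par, config)
    traces[[length(traces) + 1]] <- res$trace
    if (is.finite(res$value) && res$value >= best$value) best <- res
    if (isTRUE(config$polish %||% FALSE)) {
      pol <- stats::optim(best$par, function(x) -objective(x),
                          method = "Nelder-Mead",
                          control = list(maxit = config$polish_maxit,
                                         reltol = 1e-10))
      if (is.finite(pol$value) && -pol$value > best$value) {
        best$par <- pol$par
        best$value <- -pol$value
        traces[[length(traces)]] <- c(traces[[length(traces)]], best$value)
      }
    }
  }
  if (!is.finite(best$value)) {
    return(new_cr_fit(spec_params(spec, list()), NA_real_, NA_real_, n_data,
                      length(free), traces, FALSE, seed, spec,
                      failed = TRUE))
  }
  map_params <- untransform_params(setNames(best$par, free))
  map_params <- spec_params(spec, as.list(map_params)[free])
  ll <- session_loglik(map_params, comp, spec, scale)
  new_cr_fit(map_params, ll, best$value, n_data, length(free), traces,
             best$converged, seed, spec)
}

new_cr_fit <- function(map_params, loglik, logpost, n_datapoints,
                       n_free_params, optimizer_trace, converged, seed, spec,
                       failed = FALSE) {
  structure(list(map_params = map_params, loglik = loglik, logpost = logpost,
                 n_datapoints = n_datapoints, n_free_params = n_free_params,
                 optimizer_trace = optimizer_trace, converged = converged,
                 seed = seed, spec = spec, failed = failed),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("<MAP fit> model %s: loglik = %.2f, logpost = %.2f, %d free, %d datapoints%s\n",
              x$spec$name, x$loglik, x$logpost, x$n_free_params,
              x$n_datapoints,
              if (x$failed) " [FAILED]" else if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
tidy.cr_fit <- function(x, ...) {
  est <- unlist(x$map_params)
  tibble(
    term = param_names(), estimate = est[param_names()],
    transformed = transform_params(x$map_params)[param_names()],
    role = dplyr::case_when(
      param_names() %in% x$spec$free ~ "free",
      param_names() %in% names(x$spec$fixed_values) ~ "fixed",
      TRUE ~ "shared"
    )
  )
}

#' @export
glance.cr_fit <- function(x, ...) {
  ic <- information_criteria(x, x$spec)
  tibble(model = x$spec$name, loglik = x$loglik, logpost = x$logpost,
         n_free = x$n_free_params, n_datapoints = x$n_datapoints,
         bic = ic$bic, aic = ic$aic, converged = x$converged)
}

#' Fit every session in a cohort
#'
#' Maps [map_fit()] over participant-wave sessions and binds a tidy fits
#' table: identifiers, MAP parameter estimates (native space), fit metrics
#' and, via [add_information_criteria()], BIC/AIC.
#'
#' @param sessions Sessions tibble (many participants/waves).
#' @param spec A [model_spec()].
#' @param config A [fit_config()].
#' @param scale A [report_scale()].
#' @param seed Integer; per-session seeds are derived deterministically.
#' @param progress Print a dot per session.
#' @return Tibble with one row per participant-wave.
#' @export
fit_sessions <- function(sessions, spec = model_registry()$winning,
                         config = fit_config(), scale = report_scale(),
                         seed = 1, progress = FALSE) {
  parts <- session_split(sessions)
  rows <- purrr::imap(parts, function(s, i) {
    fit <- map_fit(s, spec, config, scale, seed = (seed + i) %% .Machine$integer.max)
    if (progress) cat(".")
    est <- as.list(unlist(fit$map_params))
    tibble(
      participant_id = s$participant_id[1], wave = s$wave[1],
      drug_group = s$drug_group[1], gender = s$gender[1], sses = s$sses[1],
      !!!est,
      loglik = fit$loglik, logpost = fit$logpost,
      n_datapoints = fit$n_datapoints, n_free = fit$n_free_params,
      converged = fit$converged, failed = fit$failed
    )
  })
  if (progress) cat("\n")
  add_information_criteria(dplyr::bind_rows(rows), spec)
}

#' Append BIC/AIC columns to a fits table
#'
#' @param fits Fits tibble from [fit_sessions()].
#' @param spec The [model_spec()] used.
#' @param sample_size_total,n_participants Shared-parameter bookkeeping,
#'   see [information_criteria()].
#' @return `fits` with `bic`, `aic`, `bic_uncorrected` columns.
#' @export
add_information_criteria <- function(fits, spec, sample_size_total = NULL,
                                     n_participants = nrow(fits)) {
  ic <- information_criteria(fits, spec, sample_size_total = sample_size_total,
                             n_participants = n_participants)
  fits$bic <- ic$bic
  fits$aic <- ic$aic
  fits$bic_uncorrected <- ic$bic_uncorrected
  fits
}
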