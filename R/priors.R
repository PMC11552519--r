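#' Weakly informative fitting priors
#'
#' Default priors are defined over native parameter space: Beta(1.2, 1.2) on
#' the probabilities and rates (`pHI0`, `pSI0`, `omega`, `lambda_other`),
#' Gamma(shape 2, scale 2) on the positive scales (`dEv`, `EvRat`,
#' `alphaPrec`, `aEv`), and Normal(0, 2) on the unbounded weights (`wH`,
#' `wS`, `w0`, `POCbias`). They are broad on purpose: the likelihood should
#' dominate wherever the data are informative, while the prior regularizes
#' ridge directions. Any entry can be overridden.
#'
#' @param ... Named overrides, each a list with elements `dist`
#'   (`"beta"`, `"gamma"` or `"normal"`), `a`, `b` (shape1/shape2, shape/scale,
#'   or mean/sd respectively).
#' @return Named list of prior specifications, class `"cr_priors"`.
#' @export
default_priors <- function(...) {
  beta_pr <- list(dist = "beta", a = 1.2, b = 1.2)
  gamma_pr <- list(dist = "gamma", a = 2, b = 2)
  norm_pr <- list(dist = "normal", a = 0, b = 2)
  pr <- list(
    pHI0 = beta_pr, pSI0 = beta_pr, omega = beta_pr, lambda_other = beta_pr,
    dEv = gamma_pr, EvRat = gamma_pr, alphaPrec = gamma_pr, aEv = gamma_pr,
    wH = norm_pr, wS = norm_pr, w0 = norm_pr, POCbias = norm_pr
  )
  dots <- list(...)
  for (nm in names(dots)) pr[[nm]] <- dots[[nm]]
  structure(pr[param_names()], class = "cr_priors")
}

prior_logdens_1 <- function(x, pr) {
  switch(pr$dist,
    beta = dbeta(x, pr$a, pr$b, log = TRUE),
    gamma = dgamma(x, shape = pr$a, scale = pr$b, log = TRUE),
    normal = dnorm(x, pr$a, pr$b, log = TRUE),
    stop("unknown prior distribution: ", pr$dist)
  )
}

prior_mode_1 <- function(pr) {
  switch(pr$dist,
    beta = if (pr$a > 1 && pr$b > 1) (pr$a - 1) / (pr$a + pr$b - 2) else 0.5,
    gamma = if (pr$a >= 1) (pr$a - 1) * pr$b else pr$b,
    normal = pr$a
  )
}

prior_draw_1 <- function(n, pr) {
  switch(pr$dist,
    beta = rbeta(n, pr$a, pr$b),
    gamma = rgamma(n, shape = pr$a, scale = pr$b),
    normal = rnorm(n, pr$a, pr$b)
  )
}

#' Log prior density of an agent parameter vector
#'
#' Sum of independent native-space prior log-densities. With `free` given,
#' only those parameters contribute (the convention used by [map_fit()], so
#' fixed parameters add no constant to the objective).
#'
#' @param params `cr_params` (or coercible).
#' @param priors A [default_priors()] object.
#' @param free Optional character vector of parameter names to include.
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, priors = default_priors(), free = param_names()) {
  p <- as_agent_params(params)
  sum(vapply(free, function(nm) prior_logdens_1(p[[nm]], priors[[nm]]), numeric(1)))
}

# native-space prior mode as a cr_params object (the default optimizer start)
prior_mode_params <- function(priors = default_priors()) {
  vals <- lapply(priors, prior_mode_1)
  # mode of Beta(1.2,1.2) is 0.5; keep strictly interior either way
  vals <- lapply(vals, function(v) if (v <= 0) 1e-3 else v)
  do.call(agent_params, vals[param_names()])
}

# draw one cr_params from the prior (native space); used for multistart
prior_draw_params <- function(priors = default_priors()) {
  vals <- lapply(priors, function(pr) prior_draw_1(1, pr))
  # keep draws strictly inside the valid domain
  for (nm in c("pHI0", "pSI0", "omega", "lambda_other")) {
    vals[[nm]] <- min(max(vals[[nm]], 1e-4), 1 - 1e-4)
  }
  for (nm in c("dEv", "EvRat", "alphaPrec", "aEv")) vals[[nm]] <- max(vals[[nm]], 1e-4)
  do.call(agent_params, vals[param_names()])
}
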