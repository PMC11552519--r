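#' Agent parameter vector
#'
#' Constructs the 12-parameter vector governing one simulated or fitted
#' participant-session. Parameters follow the field's abbreviations:
#'
#' * `pHI0`, `pSI0` — central tendency of the prior belief that the dictator
#'   harbours harmful intent (HI) / self-interest (SI), probabilities in (0,1).
#' * `dEv` — total prior evidence (pseudo-count mass) behind the SI state
#'   prior; `EvRat` — ratio of HI to SI prior evidence (HI evidence is
#'   `dEv * EvRat`). In the two-state classify-refine core only the prior
#'   means enter the filter, so these govern the classic (6x6) family.
#' * `alphaPrec` — decision precision (inverse temperature) of the three
#'   report channels; 0 gives uniform responding.
#' * `wH`, `wS`, `w0` — weights of HI and SI and the intercept in the
#'   dictator's logistic fairness policy `sigma(w0 - wH*hi - wS*si)`.
#' * `lambda_other` — carry-over in \[0,1\] of refined outcome likelihoods
#'   from one dictator to the next.
#' * `aEv` — typing confidence: Dirichlet prior evidence on each state's
#'   outcome likelihood; large values slow refinement.
#' * `omega` — trial-to-trial retention in \[0,1\] of learned likelihood
#'   counts (1 = perfect memory).
#' * `POCbias` — additive logit shift, any sign, applied to attributions
#'   reported about non-white dictators.
#'
#' @param pHI0,pSI0 Prior central tendencies, in (0,1).
#' @param dEv,EvRat,alphaPrec,aEv Positive reals.
#' @param wH,wS,w0,POCbias Unbounded reals.
#' @param lambda_other,omega Rates in \[0,1\].
#' @return A named list of class `"cr_params"`.
#' @examples
#' p <- agent_params(pHI0 = 0.3, wH = 2)
#' transform_params(p)
#' @export
agent_params <- function(pHI0 = 0.3, pSI0 = 0.35, dEv = 2, EvRat = 1,
                         alphaPrec = 30, wH = 2, wS = 1, w0 = 1.5,
                         lambda_other = 0.3, aEv = 3, omega = 0.85,
                         POCbias = 0) {
  p <- list(pHI0 = pHI0, pSI0 = pSI0, dEv = dEv, EvRat = EvRat,
            alphaPrec = alphaPrec, wH = wH, wS = wS, w0 = w0,
            lambda_other = lambda_other, aEv = aEv, omega = omega,
            POCbias = POCbias)
  validate_params(p)
  structure(p, class = "cr_params")
}

#' Canonical parameter names, in fixed order
#' @return Character vector of the 12 parameter names.
#' @export
param_names <- function() {
  c("pHI0", "pSI0", "dEv", "EvRat", "alphaPrec", "wH", "wS", "w0",
    "lambda_other", "aEv", "omega", "POCbias")
}

# which transform each parameter gets (probabilities and rates -> logit,
# positive scales -> log, unbounded weights -> identity)
param_transform_kind <- function() {
  c(pHI0 = "logit", pSI0 = "logit", dEv = "log", EvRat = "log",
    alphaPrec = "log", wH = "identity", wS = "identity", w0 = "identity",
    lambda_other = "logit", aEv = "log", omega = "logit", POCbias = "identity")
}

validate_params <- function(p) {
  stopifnot(setequal(names(p), param_names()))
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid agent params: ", what, call. = FALSE)
  for (nm in c("pHI0", "pSI0")) chk(p[[nm]] > 0 && p[[nm]] < 1, paste(nm, "must be in (0,1)"))
  for (nm in c("dEv", "EvRat", "aEv", "alphaPrec")) chk(p[[nm]] > 0, paste(nm, "must be > 0"))
  for (nm in c("lambda_other", "omega")) chk(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must be in [0,1]"))
  for (nm in c("wH", "wS", "w0", "POCbias")) chk(is.finite(p[[nm]]), paste(nm, "must be finite"))
  invisible(p)
}

#' Coerce to agent parameters
#'
#' Accepts a `cr_params` object, a named list/vector, or a one-row data frame
#' containing the 12 parameter columns.
#' @param x Object to coerce.
#' @return A `cr_params` object.
#' @export
as_agent_params <- function(x) {
  if (inherits(x, "cr_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as.list(x[, param_names()])
  }
  x <- as.list(x)[param_names()]
  do.call(agent_params, x)
}

#' Transform parameters to unconstrained space (and back)
#'
#' Bijection used for fitting and population modelling: logit for `pHI0`,
#' `pSI0`, `omega`, `lambda_other`; log for `dEv`, `EvRat`, `alphaPrec`,
#' `aEv`; identity for `wH`, `wS`, `w0`, `POCbias`. Probabilities are clamped
#' to `[1e-12, 1 - 1e-12]` and positive scales floored at `1e-300` before
#' transforming, so boundary values map to large finite numbers.
#'
#' @param params A `cr_params` object (or coercible).
#' @return `transform_params()`: named numeric vector of length 12.
#' @export
transform_params <- function(params) {
  p <- unlist(as_agent_params(params)[param_names()])
  kind <- param_transform_kind()
  out <- p
  lg <- kind == "logit"
  out[lg] <- logit(pmin(pmax(p[lg], 1e-12), 1 - 1e-12))
  pos <- kind == "log"
  out[pos] <- log(pmax(p[pos], 1e-300))
  out
}

#' @rdname transform_params
#' @param theta Named numeric vector in transformed space (names may be a
#'   subset; missing parameters are taken from `base`).
#' @param base Parameters supplying values for entries absent from `theta`.
#' @return `untransform_params()`: a `cr_params` object.
#' @export
untransform_params <- function(theta, base = agent_params()) {
  p <- as.list(as_agent_params(base))
  kind <- param_transform_kind()
  for (nm in names(theta)) {
    p[[nm]] <- switch(kind[[nm]],
      logit = logistic(theta[[nm]]),
      log = exp(theta[[nm]]),
      identity = theta[[nm]]
    )
  }
  do.call(agent_params, p[param_names()])
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<agent parameters>\n")
  print(round(unlist(x), 4))
  invisible(x)
}

#' @export
as.data.frame.cr_params <- function(x, ...) as.data.frame(unclass(x))
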