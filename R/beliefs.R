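#' Dictator fairness policy
#'
#' The probability that a dictator of attribute levels `(hi, si)` makes a
#' fair split: `sigma(w0 - wH*hi - wS*si)`. Higher harmful intent or
#' self-interest (with positive weights) lowers the fair-split probability.
#'
#' @param hi,si Attribute levels in \[0,1\] (vectorized).
#' @param w0 Intercept (propensity to beneficence).
#' @param wH,wS Weights of HI and SI.
#' @return Fair-split probability.
#' @examples
#' policy_fair_prob(0.95, 0.05, w0 = 2, wH = 4, wS = 1)
#' @export
policy_fair_prob <- function(hi, si, w0, wH, wS) {
  logistic(w0 - wH * hi - wS * si)
}

# fixed grids: classify-refine anchors the two states at 5% and 95%;
# the classic family uses six fixed bin midpoints spanning (0,1)
cr_grid_values <- function() c(0.05, 0.95)
classic_grid_values <- function() (2 * (1:6) - 1) / 12

attribute_grid <- function(kind = c("classify_refine", "classic")) {
  kind <- match.arg(kind)
  v <- if (kind == "classify_refine") cr_grid_values() else classic_grid_values()
  list(kind = kind, hi_values = v, si_values = v)
}

# joint state layout: row-major over (hi index, si index); hi varies slowest
state_layout <- function(grid) {
  nh <- length(grid$hi_values)
  ns <- length(grid$si_values)
  list(
    hi = rep(grid$hi_values, each = ns),
    si = rep(grid$si_values, times = ns),
    hi_high = rep(seq_len(nh) == nh, each = ns), # detrimental HI states
    si_high = rep(seq_len(ns) == ns, times = nh),
    hi_idx = rep(seq_len(nh), each = ns),
    si_idx = rep(seq_len(ns), times = nh)
  )
}

# discretized Beta prior over a fixed grid, parameterized by mean and
# concentration (used by the classic family)
discretized_beta <- function(grid_values, mean, concentration) {
  a <- mean * concentration
  b <- (1 - mean) * concentration
  w <- dbeta(grid_values, a, b)
  if (!all(is.finite(w)) || sum(w) <= 0) {
    # extreme concentrations: fall back to nearest-grid-point mass
    w <- as.numeric(seq_along(grid_values) == which.min(abs(grid_values - mean)))
  }
  w / sum(w)
}

#' Initialize the belief state
#'
#' Builds the joint prior over HI x SI states and the Dirichlet
#' outcome-likelihood counts. For the classify-refine family the two states
#' per dimension start at attribute values 0.05 ("beneficial") and 0.95
#' ("detrimental"); each joint state's likelihood counts are
#' `aEv * (p_fair, 1 - p_fair)` at the state's policy fairness, and learning
#' moves these counts. For the classic family the prior over each dimension
#' is a discretized Beta (mean `pHI0`/`pSI0`, concentration `dEv*EvRat` /
#' `dEv`) on six fixed bins and the likelihood stays at the policy values.
#'
#' @param params `cr_params`.
#' @param kind `"classify_refine"` or `"classic"`.
#' @return A belief state (class `"cr_belief"`): grid, `state_prior`,
#'   `state_posterior`, likelihood `counts` and `baseline_counts` (or fixed
#'   `p_fair` for the classic family).
#' @export
init_beliefs <- function(params, kind = c("classify_refine", "classic")) {
  params <- as_agent_params(params)
  kind <- match.arg(kind)
  grid <- attribute_grid(kind)
  lay <- state_layout(grid)
  if (kind == "classify_refine") {
    hi_marg <- c(1 - params$pHI0, params$pHI0)
    si_marg <- c(1 - params$pSI0, params$pSI0)
  } else {
    hi_marg <- discretized_beta(grid$hi_values, params$pHI0, params$dEv * params$EvRat)
    si_marg <- discretized_beta(grid$si_values, params$pSI0, params$dEv)
  }
  prior <- hi_marg[lay$hi_idx] * si_marg[lay$si_idx]
  prior <- prior / sum(prior)
  pf <- policy_fair_prob(lay$hi, lay$si, params$w0, params$wH, params$wS)
  b <- list(grid = grid, layout = lay, state_prior = prior,
            state_posterior = prior, p_fair_policy = pf)
  if (kind == "classify_refine") {
    counts <- cbind(fair = params$aEv * pf, unfair = params$aEv * (1 - pf))
    b$counts <- counts
    b$baseline_counts <- counts
  }
  structure(b, class = "cr_belief")
}

# row-normalized outcome likelihood p(fair | state)
belief_p_fair <- function(belief) {
  if (belief$grid$kind == "classify_refine") {
    belief$counts[, "fair"] / rowSums(belief$counts)
  } else {
    belief$p_fair_policy
  }
}

#' One-step-ahead predictive fair-split probability
#'
#' `sum_s prior(s) * p(fair | s)` under the current (pre-outcome) state
#' prior — the model's fairness expectation for the coming trial.
#' @param belief A `cr_belief`.
#' @return Probability of a fair split.
#' @export
predict_fair <- function(belief) {
  sum(belief$state_prior * belief_p_fair(belief))
}

#' Update beliefs after observing a split
#'
#' The per-trial recursion of the learning core: (1) Bayes step
#' `posterior(s) ∝ prior(s) * p(outcome | s)`; (2) classify-refine only,
#' credit step — the observed outcome's Dirichlet count for each state is
#' incremented by the posterior mass on that state; (3) classify-refine
#' only, forgetting — counts decay toward their initial values,
#' `counts <- baseline + omega * (counts - baseline)`; (4) the posterior
#' becomes the next trial's prior (dictator character is static within a
#' block, so the HMM is a recursive Bayesian filter).
#'
#' @param belief A `cr_belief`.
#' @param outcome `"fair"` or `"unfair"`.
#' @param params `cr_params`.
#' @return Updated `cr_belief`.
#' @export
update_beliefs <- function(belief, outcome, params) {
  params <- as_agent_params(params)
  stopifnot(outcome %in% c("fair", "unfair"))
  pf <- belief_p_fair(belief)
  lik <- if (outcome == "fair") pf else 1 - pf
  un <- belief$state_prior * lik
  tot <- sum(un)
  if (tot <= 0 || !is.finite(tot)) {
    stop("numerical degeneracy: zero total likelihood in belief update", call. = FALSE)
  }
  post <- un / tot
  belief$state_posterior <- post
  if (belief$grid$kind == "classify_refine") {
    belief$counts[, outcome] <- belief$counts[, outcome] + post
    belief$counts <- belief$baseline_counts +
      params$omega * (belief$counts - belief$baseline_counts)
  }
  belief$state_prior <- post
  belief
}

#' Marginal HI and SI attributions
#'
#' Classify-refine: posterior mass on the detrimental (high) state of each
#' dimension. Classic: posterior-expected attribute value on the grid.
#' @param belief A `cr_belief`.
#' @return Named numeric `c(hi = ..., si = ...)`.
#' @export
marginal_attributions <- function(belief) {
  q <- belief$state_posterior
  lay <- belief$layout
  if (belief$grid$kind == "classify_refine") {
    c(hi = sum(q[lay$hi_high]), si = sum(q[lay$si_high]))
  } else {
    c(hi = sum(q * lay$hi), si = sum(q * lay$si))
  }
}

#' Carry learning over to the next dictator
#'
#' The next block starts with fresh state priors but inherits a fraction
#' `lambda_other` of the refined outcome-likelihood counts:
#' `fresh.baseline + lambda_other * (end.counts - fresh.baseline)`.
#' The baseline (forgetting attractor) stays at the fresh counts. For the
#' classic family (no count learning) this returns the fresh belief.
#'
#' @param end_belief Final belief of the completed block.
#' @param params `cr_params`.
#' @param fresh A freshly initialized belief, `init_beliefs(params, kind)`.
#' @return Starting `cr_belief` for the next block.
#' @export
carry_over <- function(end_belief, params, fresh = NULL) {
  params <- as_agent_params(params)
  if (is.null(fresh)) fresh <- init_beliefs(params, end_belief$grid$kind)
  if (end_belief$grid$kind == "classify_refine") {
    fresh$counts <- fresh$baseline_counts +
      params$lambda_other * (end_belief$counts - fresh$baseline_counts)
  }
  fresh
}

#' Belief trajectory over a session
#'
#' Runs the learning core forward over one session's outcomes (in block
#' order, with carry-over between blocks) and returns a tidy per-trial
#' trajectory: predictive fairness before the outcome, and posterior HI/SI
#' marginals after it.
#'
#' @param params `cr_params`.
#' @param session One participant-wave sessions tibble (48 rows).
#' @param kind Model family.
#' @return Tibble with columns `block_position`, `trial_index`, `outcome`,
#'   `predict_fair`, `hi_marginal`, `si_marginal`, and the posterior state
#'   probabilities `q1..qS`.
#' @export
belief_trajectory <- function(params, session, kind = c("classify_refine", "classic")) {
  params <- as_agent_params(params)
  kind <- match.arg(kind)
  blocks <- sort(unique(session$block_position))
  belief <- init_beliefs(params, kind)
  rows <- list()
  for (b in blocks) {
    bi <- session[session$block_position == b, ]
    bi <- bi[order(bi$trial_index), ]
    for (t in seq_len(nrow(bi))) {
      pf <- predict_fair(belief)
      belief <- update_beliefs(belief, bi$outcome[t], params)
      m <- marginal_attributions(belief)
      rows[[length(rows) + 1]] <- tibble(
        block_position = b, trial_index = bi$trial_index[t],
        outcome = bi$outcome[t], predict_fair = pf,
        hi_marginal = m[["hi"]], si_marginal = m[["si"]],
        !!!setNames(as.list(belief$state_posterior),
                    paste0("q", seq_along(belief$state_posterior)))
      )
    }
    if (b != blocks[length(blocks)]) belief <- carry_over(belief, params)
  }
  dplyr::bind_rows(rows)
}
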