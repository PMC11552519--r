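# Shared fixtures and independent oracles for the test suite.
# Oracles are written with explicit scalar loops and closed forms, never by
# calling the package's own belief/likelihood functions.

# small simulated cohort (validated sessions tibble)
make_cohort <- function(n = 2, seed = 11, n_followup = 0, kind = "classify_refine") {
  cfg <- population_config(n_participants = n, n_drug = floor(n / 2),
                           n_followup = n_followup, kind = kind)
  tab <- sample_population_params(cfg, seed = seed)
  simulate_cohort(tab, cfg, seed = seed + 1)
}

one_session <- function(cohort, id = NULL, wave = "baseline") {
  id <- id %||% cohort$participant_id[1]
  cohort[cohort$participant_id == id & cohort$wave == wave, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built single-block session data frame (not necessarily a valid
# 4-block design; used directly with session_loglik / belief_trajectory)
toy_session <- function(outcomes, expectation, hi, si,
                        ethnicity = "white", fairness = 0.8) {
  n <- length(outcomes)
  tibble::tibble(
    participant_id = "T1", wave = "baseline", drug_group = "placebo",
    gender = "female", sses = 5, block_position = 1, dictator_id = "D1",
    fairness_level = fairness, ethnicity = ethnicity, trial_index = seq_len(n),
    outcome = outcomes, expectation_report = expectation, hi_report = hi,
    si_report = si, question_order = rep("HI_first", n)
  )
}

# ---- independent oracle: naive classify-refine forward pass -----------------
# Scalar-loop reimplementation of the learning core for one block sequence.
# Returns per-trial predictive fair, posterior, and HI/SI marginals.
oracle_cr_forward <- function(par, outcome_blocks) {
  sigma <- function(x) 1 / (1 + exp(-x))
  hv <- c(0.05, 0.95)
  sv <- c(0.05, 0.95)
  # state order: hi slowest, si fastest -> (L,L),(L,H),(H,L),(H,H)
  states <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  pol <- numeric(4)
  prior0 <- numeric(4)
  for (s in 1:4) {
    ih <- states[[s]][1]; is <- states[[s]][2]
    pol[s] <- sigma(par$w0 - par$wH * hv[ih] - par$wS * sv[is])
    ph <- if (ih == 2) par$pHI0 else 1 - par$pHI0
    ps <- if (is == 2) par$pSI0 else 1 - par$pSI0
    prior0[s] <- ph * ps
  }
  cf <- par$aEv * pol
  cu <- par$aEv * (1 - pol)
  bf <- cf; bu <- cu
  out <- list()
  for (b in seq_along(outcome_blocks)) {
    prior <- prior0
    if (b > 1) {
      for (s in 1:4) {
        cf[s] <- bf[s] + par$lambda_other * (cf[s] - bf[s])
        cu[s] <- bu[s] + par$lambda_other * (cu[s] - bu[s])
      }
    }
    for (t in seq_along(outcome_blocks[[b]])) {
      pf <- numeric(4)
      for (s in 1:4) pf[s] <- cf[s] / (cf[s] + cu[s])
      pred <- 0
      for (s in 1:4) pred <- pred + prior[s] * pf[s]
      fair <- outcome_blocks[[b]][t] == "fair"
      post <- numeric(4)
      for (s in 1:4) post[s] <- prior[s] * (if (fair) pf[s] else 1 - pf[s])
      post <- post / sum(post)
      for (s in 1:4) {
        if (fair) cf[s] <- cf[s] + post[s] else cu[s] <- cu[s] + post[s]
        cf[s] <- bf[s] + par$omega * (cf[s] - bf[s])
        cu[s] <- bu[s] + par$omega * (cu[s] - bu[s])
      }
      hi_m <- post[3] + post[4]
      si_m <- post[2] + post[4]
      out[[length(out) + 1]] <- c(block = b, trial = t, pred = pred,
                                  hi = hi_m, si = si_m, post)
      prior <- post
    }
  }
  do.call(rbind, out)
}

# ---- independent oracle: product-form Bayes for fixed likelihoods ----------
# For a filter with fixed p(fair|s), the posterior after a sequence is
# prior(s) * p^k * (1-p)^(n-k) normalized (closed form, order-free).
oracle_fixed_posterior <- function(prior, p_fair, outcomes) {
  k <- sum(outcomes == "fair")
  n <- length(outcomes)
  un <- prior * p_fair^k * (1 - p_fair)^(n - k)
  un / sum(un)
}

# squared-distance softmax channel probability of one bin, by hand
oracle_channel_prob <- function(value, alpha, bins, bin_index) {
  w <- exp(-alpha * (bins - value)^2)
  w[bin_index] / sum(w)
}

random_cr_params <- function() {
  agent_params(
    pHI0 = runif(1, 0.1, 0.9), pSI0 = runif(1, 0.1, 0.9),
    dEv = runif(1, 0.5, 4), EvRat = 1, alphaPrec = runif(1, 1, 50),
    wH = runif(1, 0, 3), wS = runif(1, 0, 3), w0 = runif(1, -1, 2),
    lambda_other = runif(1), aEv = runif(1, 0.5, 8), omega = runif(1, 0.3, 1),
    POCbias = 0
  )
}
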