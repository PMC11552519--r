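test_that("session likelihood collapses to uniform channels at zero precision", {
  cohort <- make_cohort(n = 1, seed = 31)
  p <- agent_params(alphaPrec = 1e-14)
  expect_equal(session_loglik(p, cohort, model_registry()$winning),
               144 * log(1 / 11), tolerance = 1e-6)
  expect_equal(session_loglik(p, cohort, model_registry()$winning_attr),
               96 * log(1 / 11), tolerance = 1e-6)
})

test_that("a 1-block 2-trial toy session matches the hand-enumerated likelihood", {
  p <- agent_params(pHI0 = 0.4, pSI0 = 0.6, alphaPrec = 6, wH = 2, wS = 1,
                    w0 = 1, aEv = 2, omega = 0.8, lambda_other = 0.5)
  sc <- report_scale()
  session <- toy_session(c("fair", "unfair"), c(0.5, 0.7), c(0.3, 0.6),
                         c(0.4, 0.5))

  # hand composition with the scalar-loop oracle
  orc <- oracle_cr_forward(p, list(c("fair", "unfair")))
  ll <- 0
  reps <- list(c(0.5, 0.3, 0.4), c(0.7, 0.6, 0.5))
  for (t in 1:2) {
    vals <- c(orc[t, "pred"], orc[t, "hi"], orc[t, "si"])
    bins <- round(reps[[t]] * 10) + 1
    for (ch in 1:3) {
      ll <- ll + log(oracle_channel_prob(vals[ch], 6, sc$bin_values, bins[ch]))
    }
  }
  expect_equal(session_loglik(p, session, model_registry()$winning, engine = "r"),
               ll, tolerance = 1e-10)
  expect_equal(session_loglik(p, session, model_registry()$winning, engine = "cpp"),
               ll, tolerance = 1e-10)
})

test_that("compiled and reference likelihood engines agree", {
  withr::with_seed(303, {
    cohort <- make_cohort(n = 2, seed = 32)
    reg <- model_registry()
    for (s in session_split(cohort)) {
      for (spec in list(reg$winning, reg$cr_full, reg$classic_full,
                        reg$winning_attr)) {
        p <- random_cr_params()
        expect_equal(session_loglik(p, s, spec, engine = "cpp"),
                     session_loglik(p, s, spec, engine = "r"),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("log prior has its mode at the documented values and is symmetric", {
  pr <- default_priors()
  mode <- classifyrefine:::prior_mode_params(pr)
  grid <- seq(0.05, 0.95, 0.05)
  dens_mode <- log_prior(mode, pr)
  for (v in grid) {
    p <- mode
    p$pHI0 <- v
    expect_lte(log_prior(p, pr), dens_mode + 1e-12)
  }
  # symmetric Beta prior: invariant under p -> 1 - p
  a <- mode; a$pHI0 <- 0.2
  b <- mode; b$pHI0 <- 0.8
  expect_equal(log_prior(a, pr), log_prior(b, pr), tolerance = 1e-12)
  # closed-form sum of per-term densities
  p <- agent_params(pHI0 = 0.3, pSI0 = 0.6, dEv = 1.5, EvRat = 2,
                    alphaPrec = 10, wH = 1, wS = -0.5, w0 = 2,
                    lambda_other = 0.25, aEv = 4, omega = 0.9, POCbias = 0.3)
  expected <- sum(dbeta(c(0.3, 0.6, 0.25, 0.9), 1.2, 1.2, log = TRUE)) +
    sum(dgamma(c(1.5, 2, 10, 4), shape = 2, scale = 2, log = TRUE)) +
    sum(dnorm(c(1, -0.5, 2, 0.3), 0, 2, log = TRUE))
  expect_equal(log_prior(p, pr), expected, tolerance = 1e-12)
})

test_that("the grid search finds a known quadratic optimum", {
  target <- c(a = 0.7, b = -1.3, c = 2.1)
  fn <- function(x) -sum((x - target)^2)
  cfg <- fit_config(n_grid = 7, contraction = 0.5, tol = 1e-5,
                    max_sweeps = 60, init_width = 2)
  res <- classifyrefine:::grid_search_maximize(fn, c(a = 0, b = 0, c = 0), cfg)
  expect_true(res$converged)
  expect_equal(res$par, target, tolerance = 1e-4)
  expect_gt(res$value, -1e-7)
  # monotone refinement: the objective never decreases across sweeps
  expect_true(all(diff(res$trace) >= 0))
})

test_that("the MAP objective matches the documented composition", {
  cohort <- make_cohort(n = 1, seed = 33)
  spec <- model_registry()$winning
  sc <- report_scale()
  comp <- classifyrefine:::compile_session(cohort, sc)
  obj <- classifyrefine:::make_objective(comp, spec, sc, default_priors())
  withr::with_seed(404, {
    for (i in 1:5) {
      p <- random_cr_params()
      th <- transform_params(p)[spec$free]
      expect_equal(obj(th),
                   session_loglik(p, cohort, spec) +
                     log_prior(p, free = spec$free),
                   tolerance = 1e-8)
    }
  })
})

test_that("an all-fixed spec yields a zero-free-parameter fit", {
  cohort <- make_cohort(n = 1, seed = 34)
  fixed_vals <- as.list(unlist(agent_params()))
  spec <- model_spec("all_fixed", "classify_refine", free = character(),
                     fixed_values = fixed_vals)
  f <- map_fit(cohort, spec)
  expect_equal(f$n_free_params, 0)
  expect_equal(f$loglik, session_loglik(agent_params(), cohort, spec))
  expect_equal(f$logpost, f$loglik)
  expect_true(f$converged)
})

test_that("MAP fit satisfies its invariants on a real session", {
  cohort <- make_cohort(n = 1, seed = 35)
  spec <- model_registry()$winning
  f <- map_fit(cohort, spec, fit_config(n_starts = 2, max_sweeps = 12), seed = 1)
  expect_equal(f$n_datapoints, 144)
  expect_equal(f$logpost,
               f$loglik + log_prior(f$map_params, free = spec$free),
               tolerance = 1e-8)
  expect_true(all(unlist(lapply(f$optimizer_trace, function(tr) diff(tr) >= 0))))
  # deterministic given the seed
  f2 <- map_fit(cohort, spec, fit_config(n_starts = 2, max_sweeps = 12), seed = 1)
  expect_equal(unlist(f$map_params), unlist(f2$map_params))
  # fitting is invariant to row order
  shuffled <- withr::with_seed(7, cohort[sample(nrow(cohort)), ])
  f3 <- map_fit(shuffled, spec, fit_config(n_starts = 2, max_sweeps = 12), seed = 1)
  expect_equal(unlist(f3$map_params), unlist(f$map_params))
})

test_that("more starts never find a worse optimum", {
  cohort <- make_cohort(n = 2, seed = 36)
  spec <- model_registry()$winning
  for (s in session_split(cohort)) {
    f1 <- map_fit(s, spec, fit_config(n_starts = 1, max_sweeps = 10), seed = 2)
    f8 <- map_fit(s, spec, fit_config(n_starts = 8, max_sweeps = 10), seed = 2)
    expect_gte(f8$logpost, f1$logpost)
  }
})

test_that("longer blocks shrink the recovery error (consistency smoke test)", {
  # two free parameters, everything else fixed at the generating values
  base <- agent_params()
  spec <- model_spec("w0_alpha", "classify_refine",
                     free = c("w0", "alphaPrec"),
                     fixed_values = as.list(unlist(base))[
                       setdiff(param_names(), c("w0", "alphaPrec"))])
  err <- sapply(c(12, 120), function(nt) {
    cfg <- population_config(n_participants = 4, n_drug = 0, n_followup = 0,
                             n_trials = nt, contam_prob = 0,
                             sd_t = setNames(rep(0, 12), param_names()))
    tab <- sample_population_params(cfg, seed = 41)
    ses <- simulate_cohort(tab, cfg, seed = 42)
    fits <- fit_sessions(ses, spec, fit_config(n_starts = 2, max_sweeps = 12),
                         seed = 43)
    gen_t <- transform_params(as_agent_params(tab[1, param_names()]))
    rec_t <- t(apply(fits[, param_names()], 1,
                     function(r) transform_params(as.list(r))))
    mean(abs(rec_t[, "w0"] - gen_t[["w0"]])) +
      mean(abs(rec_t[, "alphaPrec"] - gen_t[["alphaPrec"]]))
  })
  expect_lt(err[2], err[1])
})
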