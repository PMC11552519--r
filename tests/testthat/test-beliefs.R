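test_that("policy fairness follows the logistic in the documented convention", {
  expect_equal(policy_fair_prob(0, 0, w0 = 0, wH = 1, wS = 1), 0.5)
  expect_equal(policy_fair_prob(0.95, 0.05, w0 = 2, wH = 4, wS = 1),
               plogis(-1.85), tolerance = 1e-12)
  expect_equal(policy_fair_prob(0.95, 0.05, w0 = 2, wH = 4, wS = 1),
               0.1358729, tolerance = 1e-6)
  # weights zero: same fairness for every state
  expect_equal(policy_fair_prob(c(0, 0.5, 1), c(1, 0.5, 0), 3, 0, 0),
               rep(plogis(3), 3))
  expect_equal(plogis(3), 0.9525741, tolerance = 1e-6)
  # monotone decreasing in hi and si for positive weights
  expect_true(all(diff(policy_fair_prob(seq(0, 1, 0.1), 0.5, 1, 2, 1)) < 0))
})

test_that("initial beliefs factorize and set Dirichlet counts from the policy", {
  p <- agent_params(pHI0 = 0.5, pSI0 = 0.5)
  b <- init_beliefs(p)
  expect_equal(b$state_prior, rep(0.25, 4))

  p <- agent_params(pHI0 = 0.9, pSI0 = 0.5)
  b <- init_beliefs(p)
  hi_high <- sum(b$state_prior[b$layout$hi_high])
  expect_equal(hi_high, 0.9)
  expect_equal(b$state_prior[b$layout$hi_high & b$layout$si_high], 0.45)

  p <- agent_params(aEv = 10, w0 = 1, wH = 1, wS = 1)
  b <- init_beliefs(p)
  pf <- plogis(1 - 1 * b$layout$hi - 1 * b$layout$si)
  expect_equal(unname(b$counts[, "fair"]), 10 * pf)
  expect_equal(unname(b$counts[, "unfair"]), 10 * (1 - pf))
  expect_equal(b$baseline_counts, b$counts)
})

test_that("classic priors are discretized Betas on the fixed six-bin grid", {
  p <- agent_params(pHI0 = 0.3, pSI0 = 0.6, dEv = 3, EvRat = 2)
  b <- init_beliefs(p, "classic")
  expect_length(b$state_prior, 36)
  grid <- (2 * (1:6) - 1) / 12
  wh <- dbeta(grid, 0.3 * 6, 0.7 * 6); wh <- wh / sum(wh)
  ws <- dbeta(grid, 0.6 * 3, 0.4 * 3); ws <- ws / sum(ws)
  joint <- rep(wh, each = 6) * rep(ws, 6) # hi slowest
  expect_equal(b$state_prior, joint, tolerance = 1e-12)
})

test_that("the update applies Bayes, posterior-weighted credit and forgetting", {
  # Bayes with uniform prior: posterior proportional to the likelihood row
  p <- agent_params(pHI0 = 0.5, pSI0 = 0.5, omega = 1)
  b <- init_beliefs(p)
  pf <- b$counts[, "fair"] / rowSums(b$counts)
  b2 <- update_beliefs(b, "fair", p)
  expect_equal(b2$state_posterior, unname(pf / sum(pf)), tolerance = 1e-12)
  expect_equal(sum(b2$state_posterior), 1, tolerance = 1e-12)

  # unit credit with a degenerate prior and no forgetting
  p <- agent_params(omega = 1)
  b <- init_beliefs(p)
  b$state_prior <- c(1, 0, 0, 0)
  b$counts[1, ] <- c(fair = 8, unfair = 2)
  b2 <- update_beliefs(b, "fair", p)
  expect_equal(b2$state_posterior[1], 1)
  expect_equal(unname(b2$counts[1, "fair"]), 9)

  # forgetting decays credited counts toward baseline
  p <- agent_params(omega = 0.5)
  b <- init_beliefs(p)
  b$state_prior <- c(1, 0, 0, 0)
  b$baseline_counts[1, "fair"] <- 10
  b$counts[1, "fair"] <- 13 # +1 credit -> 14, then 10 + 0.5 * 4 = 12
  b2 <- update_beliefs(b, "fair", p)
  expect_equal(unname(b2$counts[1, "fair"]), 12)
})

test_that("carry-over interpolates counts between baseline and end state", {
  p0 <- agent_params(lambda_other = 0)
  b <- init_beliefs(p0)
  b$counts[1, "fair"] <- b$counts[1, "fair"] + 4
  expect_equal(carry_over(b, p0)$counts, init_beliefs(p0)$counts)

  p1 <- agent_params(lambda_other = 1)
  expect_equal(carry_over(b, p1)$counts, b$counts)

  ph <- agent_params(lambda_other = 0.5)
  fresh <- init_beliefs(ph)
  fresh$counts[1, "fair"] <- 10
  fresh$baseline_counts[1, "fair"] <- 10
  bend <- fresh
  bend$counts[1, "fair"] <- 14
  expect_equal(unname(carry_over(bend, ph, fresh)$counts[1, "fair"]), 12)
  # state prior resets to the fresh prior
  bend$state_prior <- c(1, 0, 0, 0)
  expect_equal(carry_over(bend, ph, fresh)$state_prior, fresh$state_prior)
})

test_that("trajectories match the naive scalar-loop oracle (<=4 states, <=4 trials)", {
  withr::with_seed(101, {
    for (case in 1:25) {
      p <- random_cr_params()
      n_blocks <- sample(1:2, 1)
      blocks <- lapply(seq_len(n_blocks), function(b) {
        sample(c("fair", "unfair"), sample(2:4, 1), replace = TRUE)
      })
      session <- dplyr::bind_rows(lapply(seq_along(blocks), function(b) {
        n <- length(blocks[[b]])
        toy <- toy_session(blocks[[b]], rep(0.5, n), rep(0.5, n), rep(0.5, n))
        toy$block_position <- b
        toy
      }))
      traj <- belief_trajectory(p, session)
      orc <- oracle_cr_forward(p, blocks)
      expect_equal(traj$predict_fair, unname(orc[, "pred"]), tolerance = 1e-10)
      expect_equal(traj$hi_marginal, unname(orc[, "hi"]), tolerance = 1e-10)
      expect_equal(traj$si_marginal, unname(orc[, "si"]), tolerance = 1e-10)
      expect_equal(unname(as.matrix(traj[, c("q1", "q2", "q3", "q4")])),
                   unname(orc[, 6:9]), tolerance = 1e-10)
    }
  })
})

test_that("classic posterior equals the closed-form product Bayes", {
  p <- agent_params(pHI0 = 0.4, pSI0 = 0.5, dEv = 2, EvRat = 1,
                    wH = 2, wS = 1, w0 = 1)
  outcomes <- c("fair", "unfair", "fair", "fair")
  b <- init_beliefs(p, "classic")
  prior <- b$state_prior
  pf <- b$p_fair_policy
  for (o in outcomes) b <- update_beliefs(b, o, p)
  expect_equal(b$state_posterior, oracle_fixed_posterior(prior, pf, outcomes),
               tolerance = 1e-12)
})

test_that("beliefs stay normalized along any trajectory (property)", {
  withr::with_seed(202, {
    for (case in 1:10) {
      p <- random_cr_params()
      b <- init_beliefs(p)
      for (t in 1:12) {
        b <- update_beliefs(b, sample(c("fair", "unfair"), 1), p)
        expect_equal(sum(b$state_posterior), 1, tolerance = 1e-12)
        expect_true(all(b$counts > 0))
      }
    }
  })
})

test_that("single-state counts reduce to exact Dirichlet-multinomial tallies", {
  # with a point-mass prior, omega = 1 and lambda = 0, credited counts are
  # plain outcome tallies: predictive = (a0*p0 + n_fair) / (a0 + n)
  p <- agent_params(aEv = 2, omega = 1, lambda_other = 0,
                    w0 = 0, wH = 0, wS = 0) # all states p_fair = 0.5
  b <- init_beliefs(p)
  b$state_prior <- c(1, 0, 0, 0)
  outcomes <- c("fair", "fair", "unfair", "fair")
  for (o in outcomes) b <- update_beliefs(b, o, p)
  expect_equal(unname(b$counts[1, "fair"]), 2 * 0.5 + 3)
  expect_equal(predict_fair(b), (2 * 0.5 + 3) / (2 + 4), tolerance = 1e-12)
})

test_that("a fair observation strictly increases p(fair|s) for credited states", {
  p <- agent_params(omega = 1)
  b <- init_beliefs(p)
  pf_before <- b$counts[, "fair"] / rowSums(b$counts)
  b2 <- update_beliefs(b, "fair", p)
  pf_after <- b2$counts[, "fair"] / rowSums(b2$counts)
  credited <- b2$state_posterior > 0
  expect_true(all(pf_after[credited] > pf_before[credited]))
})

test_that("classic expected HI attribution is non-increasing after fair splits", {
  p <- agent_params(wH = 2, wS = 0.5, w0 = 1)
  b <- init_beliefs(p, "classic")
  prev <- sum(b$state_prior * b$layout$hi)
  for (t in 1:6) {
    b <- update_beliefs(b, "fair", p)
    cur <- marginal_attributions(b)[["hi"]]
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("omega=1 and lambda=0 give independent per-block learning", {
  p <- agent_params(omega = 1, lambda_other = 0)
  b <- init_beliefs(p)
  for (o in c("fair", "unfair", "fair")) b <- update_beliefs(b, o, p)
  b2 <- carry_over(b, p)
  expect_equal(b2$counts, init_beliefs(p)$counts)
  expect_equal(b2$state_prior, init_beliefs(p)$state_prior)
})

test_that("huge typing confidence converges to the fixed-likelihood filter", {
  p <- agent_params(aEv = 1e6)
  outcomes <- list(c("fair", "unfair", rep("fair", 10)))
  b <- init_beliefs(p)
  prior <- b$state_prior
  pf0 <- b$counts[, "fair"] / rowSums(b$counts) # initial policy values
  for (o in outcomes[[1]]) b <- update_beliefs(b, o, p)
  expect_equal(b$state_posterior,
               oracle_fixed_posterior(prior, pf0, outcomes[[1]]),
               tolerance = 1e-4)
})
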