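test_that("average measures are per-session report means", {
  cohort <- make_cohort(n = 2, seed = 61)
  av <- average_measures(cohort)
  expect_equal(nrow(av), 2)
  one <- one_session(cohort)
  expect_equal(av$HIAv[av$participant_id == one$participant_id[1]],
               mean(one$hi_report))
  expect_equal(av$predAv[av$participant_id == one$participant_id[1]],
               mean(one$expectation_report))
  # constant reports give that constant
  const <- dplyr::mutate(cohort, hi_report = 0.4)
  expect_true(all(average_measures(const)$HIAv == 0.4))
  broken <- cohort
  broken$si_report[3] <- NA
  expect_error(average_measures(broken), "missing reports.*3")
})

test_that("average attributions order with the generating prior", {
  base_sd <- setNames(rep(0, 12), param_names())
  mk <- function(pHI0) {
    cfg <- population_config(n_participants = 1, n_drug = 0, n_followup = 0,
                             mean_t = c(pHI0 = qlogis(pHI0), alphaPrec = log(1e9)),
                             sd_t = base_sd, wave_noise_sd = 0, contam_prob = 0)
    tab <- sample_population_params(cfg, seed = 62)
    average_measures(simulate_cohort(tab, cfg, seed = 63))$HIAv
  }
  expect_gt(mk(0.9), mk(0.1))
})

test_that("stability regression recovers the identity and known slopes", {
  n <- 66
  withr::with_seed(64, {
    df <- tibble::tibble(
      baseline = rnorm(n), drug_group = sample(c("p", "c"), n, TRUE),
      gender = sample(c("f", "m"), n, TRUE), sses = sample(1:10, n, TRUE)
    )
    # identity relation: slope 1, enormous t
    df$follow <- df$baseline
    out <- suppressWarnings(stability_regression(df))
    expect_equal(out$estimate[out$term == "baseline"], 1, tolerance = 1e-8)
    expect_gt(abs(out$t[out$term == "baseline"]), 1e6)
    expect_gt(out$adj_r_squared[1], 0.999)
    # independent follow-up: slope near 0, modest t
    df$follow <- rnorm(n)
    out <- stability_regression(df)
    expect_lt(abs(out$t[out$term == "baseline"]), 3)
    # known slope 0.5 with known noise: recovered within 2 SE
    df$follow <- 0.5 * df$baseline + rnorm(n, 0, 0.3)
    out <- stability_regression(df)
    b <- out[out$term == "baseline", ]
    expect_lt(abs(b$estimate - 0.5), 2 * b$se)
  })
  # collinear design errors
  withr::with_seed(68, {
    df2 <- tibble::tibble(baseline = rnorm(10), follow = rnorm(10))
    df2$sses <- 2 * df2$baseline
  })
  expect_error(stability_regression(df2), "collinear|rank")
})

test_that("outlier screening applies the strict Cook's/residual thresholds", {
  withr::with_seed(65, {
    x <- seq(0, 1, length.out = 40)
    y <- 2 + x + rnorm(40, 0, 0.05)
    expect_length(outlier_screen(y, data.frame(x = x)), 0)

    # one gross leverage point; verify Cook's distance by its closed form
    x2 <- c(x, 5)
    y2 <- c(y, -20)
    X <- cbind(1, x2)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    fit <- lm(y2 ~ x2)
    e <- stats::resid(fit)
    p <- 2
    s2 <- sum(e^2) / (length(y2) - p)
    h <- diag(H)
    cook <- e^2 / (p * s2) * h / (1 - h)^2
    expect_gt(cook[41], 1)
    expect_equal(outlier_screen(y2, data.frame(x = x2)), 41)

    # permutation invariance (up to relabeling)
    perm <- c(41, 1:40)
    expect_equal(outlier_screen(y2[perm], data.frame(x = x2[perm])), 1)
  })
  expect_error(outlier_screen(c(1, 2), data.frame(a = c(1, 2), b = c(2, 1))),
               "n <= p")
})

test_that("points exactly at the thresholds are not flagged", {
  # synthetic diagnostics exercised through a crafted regression: build data
  # whose max |standardized residual| is just below/above 3
  withr::with_seed(66, {
    x <- rnorm(200)
    y <- x + rnorm(200, 0, 1)
    fit <- lm(y ~ x)
    sr <- rstandard(fit)
    flagged <- outlier_screen(y, data.frame(x = x))
    expect_setequal(flagged, which(abs(sr) > 3 | cooks.distance(fit) > 1))
  })
})

test_that("the mixed model reproduces a noiseless difference-in-differences", {
  n <- 20
  delta <- -0.7
  df <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:n),
                           wave = c("baseline", "followup"))
  df$drug_group <- ifelse(as.integer(sub("p", "", df$participant_id)) <= n / 2,
                          "citalopram", "placebo")
  df$value <- 1 + 0.2 * (df$wave == "followup") +
    delta * (df$wave == "followup") * (df$drug_group == "citalopram")
  out <- suppressWarnings(wave_drug_mixed_model(df))
  inter <- out[grepl("wavefollowup:drug_groupcitalopram", out$term), ]
  expect_equal(inter$estimate, delta, tolerance = 1e-6)
})

test_that("without repeated participants the mixed model degrades to OLS", {
  df <- tibble::tibble(participant_id = sprintf("p%d", 1:30),
                       wave = rep(c("baseline", "followup"), 15),
                       drug_group = rep(c("placebo", "citalopram"), each = 15),
                       value = rnorm(30))
  expect_warning(out <- wave_drug_mixed_model(df), "ordinary least squares")
  expect_true("wavefollowup:drug_groupcitalopram" %in% out$term)
})

test_that("the synthetic drug effect surfaces as a negative aEv interaction", {
  cfg <- population_config(n_participants = 30, n_drug = 15, n_followup = 30,
                           contam_prob = 0, wave_noise_sd = 0.1)
  tab <- sample_population_params(cfg, seed = 67)
  df <- tibble::tibble(participant_id = tab$participant_id, wave = tab$wave,
                       drug_group = tab$drug_group, value = log(tab$aEv))
  out <- wave_drug_mixed_model(df)
  inter <- out[grepl(":", out$term), ]
  expect_lt(inter$estimate, 0)
  expect_equal(inter$estimate, -1.18, tolerance = 0.15)
})
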