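test_that("per-trial standardization centers and scales exactly", {
  set.seed(61)
  d <- expand.grid(participant = sprintf("p%02d", 1:30), trial = 1:8)
  d$task <- "piano"
  d$eta <- rnorm(nrow(d), 30, 5) + d$trial
  z <- standardize_by_trial(d)
  for (tt in 1:8) {
    v <- z$z[z$trial == tt]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
  # idempotence: re-standardizing the z column changes nothing
  z2 <- standardize_by_trial(z, value = "z")
  expect_equal(z2$z, z$z, tolerance = 1e-12)
})

test_that("two participants standardize to the hand-computed two-point values", {
  d <- data.frame(participant = c("a", "b"), trial = 1, eta = c(20, 30))
  z <- standardize_by_trial(d)
  expect_equal(z$z, c(-sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
})

test_that("degenerate trials are rejected by name", {
  d <- data.frame(participant = c("a", "b"), trial = c(4, 4), eta = c(5, 5))
  expect_error(standardize_by_trial(d), "trial group")
  expect_error(standardize_by_trial(d[1, ]), "fewer than 2")
})

test_that("a coupled ability produces positive trial-wise coefficients", {
  cfg <- association_dip_config(n_participants = 60, trials = 12)
  st <- simulate_study(cfg, seed = 62, keylog = FALSE)
  fit <- suppressWarnings(fit_learning_curves(st$scores, task = "piano",
                                              config = mcmc_config(1, 1200, 400),
                                              seed = 11))
  zt <- standardize_by_trial(fitted(fit))
  ie <- individual_estimates(fit)
  ac <- suppressWarnings(
    trialwise_association(zt, st$truth$factors[c("participant", "PM")], ie,
                          config = mcmc_config(1, 1200, 400), seed = 12))
  # the generator couples PM to baseline and asymptote: coefficients are
  # clearly positive on average (replication-level calibration of the null
  # is exercised in the acceptance suite)
  expect_gt(mean(ac$table$b_mean), 0.1)
  expect_equal(nrow(ac$table), 12)
  expect_true(all(ac$table$b_low <= ac$table$b_mean &
                    ac$table$b_mean <= ac$table$b_high))
})

test_that("predictors missing for most participants are refused", {
  z <- data.frame(participant = rep(sprintf("p%02d", 1:10), 2),
                  trial = rep(1:2, each = 10), task = "piano",
                  z = rnorm(20))
  pred <- data.frame(participant = sprintf("p%02d", 1:10),
                     WM = c(rnorm(3), rep(NA, 7)))
  rates <- data.frame(participant = sprintf("p%02d", 1:10), gamma = rnorm(10))
  expect_error(trialwise_association(z, pred, rates), "missing for more than 50%")
})

test_that("association profiles classify shapes correctly", {
  mono <- data.frame(trial = 1:20, b_mean = seq(0.1, 0.5, length.out = 20))
  pr <- association_profile(mono)
  expect_equal(pr$argmin_trial, 1)
  expect_false(pr$dip_rebound)
  expect_equal(pr$plateau, mean(mono$b_mean[18:20]))

  dip <- data.frame(trial = 1:20,
                    b_mean = c(0.3, 0.1, seq(0.15, 0.45, length.out = 18)))
  pr2 <- association_profile(dip)
  expect_equal(pr2$argmin_trial, 2)
  expect_true(pr2$dip_rebound)

  flat <- data.frame(trial = 1:20, b_mean = rep(0.25, 20))
  pr3 <- association_profile(flat)
  expect_equal(pr3$initial, pr3$plateau)
  expect_false(pr3$dip_rebound)
})

test_that("correlation tables match the closed-form computation", {
  est <- data.frame(participant = c("a", "b", "c", "d", "e"),
                    gamma = c(-2.1, -1.5, -1.9, -0.8, -1.2))
  ab <- data.frame(participant = c("a", "b", "c", "d", "e"),
                   DX = c(0.3, 0.8, -0.2, 1.4, 0.9))
  tab <- rate_ability_correlations(est, ab)
  x <- est$gamma; y <- ab$DX
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab$r, r_manual, tolerance = 1e-12)
  expect_equal(tab$n, 5)
  # perfect correlation edge
  ab2 <- data.frame(participant = est$participant, self = est$gamma)
  expect_equal(rate_ability_correlations(est, ab2)$r, 1)
})

test_that("too few paired observations are refused", {
  est <- data.frame(participant = c("a", "b"), gamma = c(1, 2))
  ab <- data.frame(participant = c("a", "b"), DX = c(1, 2))
  expect_error(rate_ability_correlations(est, ab), "fewer than 3")
})

test_that("independent pairs give a null correlation distribution", {
  set.seed(64)
  rs <- replicate(400, cor(rnorm(86), rnorm(86)))
  expect_lt(abs(mean(rs)), 0.05)
})
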