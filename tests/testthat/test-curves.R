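test_that("the exponential curve anchors at alpha and approaches beta", {
  expect_equal(curve_value(10, 40, 0.3, 1), 10)
  expect_equal(curve_value(10, 40, -50, 15), 10, tolerance = 1e-10)
  # frozen from independent scalar evaluation: 40 + (10-40) exp(-2)
  expect_equal(curve_value(10, 40, 0, 3), 35.93994150290162)
  expect_equal(curve_value(10, 40, 2, 1e4), 40)
  # monotone for alpha != beta, constant for alpha == beta
  tt <- 1:30
  v <- curve_value(10, 40, -1, tt)
  expect_true(all(diff(v) > 0))
  expect_true(all(curve_value(25, 25, -1, tt) == 25))
})

test_that("near-degenerate shared-parameter data recover the population means", {
  sc <- noiseless_scores(n = 12, trials = 10, alpha = 15, beta = 40, gamma = -1)
  sc$correct <- sc$correct + rnorm(nrow(sc), 0, 0.05)
  fit <- suppressWarnings(
    fit_learning_curves(sc, config = mcmc_config(2, 1500, 500), seed = 3))
  co <- coef(fit)
  expect_equal(unname(co["mu_alpha"]), 15, tolerance = 0.02 * 15)
  expect_equal(unname(co["mu_beta"]), 40, tolerance = 0.02 * 40)
  expect_equal(unname(co["mu_gamma"]), -1, tolerance = 0.05)
  ind <- individual_estimates(fit)
  expect_equal(ind$alpha, rep(15, 12), tolerance = 0.05 * 15)
  expect_equal(ind$beta, rep(40, 12), tolerance = 0.05 * 40)
})

test_that("fitted curves stay inside the data envelope on synthetic data", {
  cfg <- tiny_config(n = 15, trials = 12)
  st <- simulate_study(cfg, seed = 41, keylog = FALSE)
  sc <- st$scores[st$scores$task == "piano", ]
  fit <- suppressWarnings(
    fit_learning_curves(sc, config = mcmc_config(1, 1200, 400), seed = 4))
  fe <- fitted(fit)
  sig <- coef(fit)[["sigma"]]
  expect_true(all(fe$eta >= min(sc$correct) - 3 * sig))
  expect_true(all(fe$eta <= max(sc$correct) + 3 * sig))
  s <- summary(fit)
  corr <- s[grepl("^cor_", s$parameter), ]
  expect_true(all(corr$mean >= -1 & corr$mean <= 1))
})

test_that("seeded fits are bit-reproducible", {
  sc <- noiseless_scores(n = 6, trials = 8)
  sc$correct <- sc$correct + rep(c(-0.3, 0.4), length.out = nrow(sc))
  cfgm <- mcmc_config(1, 700, 300)
  f1 <- suppressWarnings(fit_learning_curves(sc, config = cfgm, seed = 9))
  f2 <- suppressWarnings(fit_learning_curves(sc, config = cfgm, seed = 9))
  expect_identical(f1$run$draws, f2$run$draws)
})

test_that("non-finite performance values are rejected and flat data warn", {
  sc <- noiseless_scores(n = 4, trials = 6)
  sc$correct[3] <- NA
  expect_error(fit_learning_curves(sc), "non-finite")
  flat <- noiseless_scores(n = 4, trials = 6, alpha = 20, beta = 20)
  expect_warning(
    try(fit_learning_curves(flat, config = mcmc_config(1, 400, 300), seed = 1),
        silent = TRUE),
    "identical")
})

test_that("permuting participant labels destroys cross-task correlation", {
  cfg <- tiny_config(n = 30, trials = 10)
  st <- simulate_study(cfg, seed = 42, keylog = FALSE)
  cfgm <- mcmc_config(1, 1000, 400)
  f_pia <- suppressWarnings(fit_learning_curves(st$scores, task = "piano",
                                                config = cfgm, seed = 5))
  f_pad <- suppressWarnings(fit_learning_curves(st$scores, task = "pad",
                                                config = cfgm, seed = 6))
  e1 <- individual_estimates(f_pia)
  e2 <- individual_estimates(f_pad)
  r_aligned <- cor(e1$beta, e2$beta[match(e1$participant, e2$participant)])
  set.seed(7)
  perm <- sample(nrow(e2))
  r_perm <- cor(e1$beta, e2$beta[perm])
  expect_gt(r_aligned, 0.3)   # generator couples asymptotes across tasks
  expect_lt(abs(r_perm), 0.45)
  expect_lt(abs(r_perm), r_aligned)
})
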