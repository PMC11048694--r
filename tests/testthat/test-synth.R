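test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- tiny_config()
  a <- simulate_study(cfg, seed = 7)
  b <- simulate_study(cfg, seed = 7)
  expect_identical(a$battery, b$battery)
  expect_identical(a$scores, b$scores)
  expect_identical(a$events, b$events)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$musicality, b$musicality)
  c_ <- simulate_study(cfg, seed = 8)
  expect_false(identical(a$scores, c_$scores))
})

test_that("battery indicator correlations reproduce the measurement truth", {
  L <- list(F1 = c(i1 = 0.7, i2 = 0.7, i3 = 0.7, i4 = 0.7),
            F2 = c(i5 = 0.7, i6 = 0.7, i7 = 0.7, i8 = 0.7))
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("F1", "F2"),
                                                         c("F1", "F2")))
  cfg <- synth_config(n_participants = 4000, loadings = L, factor_corr = Phi,
                      coupling = matrix(0, 3, 2), missing_bs_r = 0)
  fa <- gen_factors(cfg, seed = 3)
  z <- scale(as.matrix(fa$battery[, -1]))
  emp <- cor(z)
  Lm <- fa$truth$lambda
  implied <- Lm %*% Phi %*% t(Lm) + diag(fa$truth$theta)
  expect_lt(max(abs(emp - implied)), 0.05)
})

test_that("noise-free unit-loading indicators equal the factors", {
  L <- list(F1 = c(i1 = 1), F2 = c(i2 = 1))
  Phi <- diag(2); dimnames(Phi) <- list(c("F1", "F2"), c("F1", "F2"))
  cfg <- synth_config(n_participants = 50, loadings = L, factor_corr = Phi,
                      coupling = matrix(0, 3, 2), missing_bs_r = 0)
  fa <- gen_factors(cfg, seed = 4)
  # communality 1 means zero residual: standardized indicator == factor
  z1 <- scale(fa$battery[[2]])
  expect_gt(abs(cor(z1, fa$factors$F1)), 0.999999)
})

test_that("ability coupling induces the configured parameter correlation", {
  cp <- matrix(0, 3, 4, dimnames = list(c("alpha", "beta", "gamma"),
                                        c("WM", "PS", "PM", "DX")))
  cp["beta", "WM"] <- 0.5
  Phi <- diag(4)
  dimnames(Phi) <- list(c("WM", "PS", "PM", "DX"), c("WM", "PS", "PM", "DX"))
  cfg <- synth_config(n_participants = 1000, coupling = cp,
                      factor_corr = Phi, missing_bs_r = 0)
  fa <- gen_factors(cfg, seed = 5)
  pf <- gen_performance(cfg, fa$factors, seed = 5)
  # 0.5 SD shift per ability SD -> r = 0.5 / sqrt(1.25) ~ 0.447
  r <- cor(fa$factors$WM, pf$params$piano$beta)
  expect_gt(r, 0.35)
  expect_lt(r, 0.55)
})

test_that("zero noise and zero coupling give exactly the rounded population curve", {
  cv <- default_curve_truth()
  for (tk in names(cv)) {
    cv[[tk]]$sd[] <- 1e-12
    cv[[tk]]$sigma <- 1e-12
  }
  cfg <- synth_config(n_participants = 5, coupling = matrix(0, 3, 4),
                      curve = cv, missing_bs_r = 0)
  fa <- gen_factors(cfg, seed = 6)
  pf <- gen_performance(cfg, fa$factors, seed = 6)
  pia <- pf$scores[pf$scores$task == "piano", ]
  mu <- cv$piano$mu
  expect_equal(pia$correct,
               as.integer(round(curve_value(mu[1], mu[2], mu[3], pia$trial))))
})

test_that("noise-free gaze counts follow the hinge exactly and vanish past tau", {
  cfg <- tiny_config(n = 8, trials = 12)
  for (tk in cfg$tasks) {
    cfg$gaze[[tk]]$tau_mean <- 6
    cfg$gaze[[tk]]$tau_logit_sd <- 1e-12
    cfg$gaze[[tk]]$a_sdlog <- 1e-12
    cfg$gaze[[tk]]$sigma <- 1e-12
  }
  cfg$missing_gaze <- 0
  gz <- gen_gaze(cfg, seed = 9)
  pia <- gz$gaze[gz$gaze$task == "piano", ]
  tau <- gz$truth$piano$tau[1]
  a <- gz$truth$piano$a[1]
  expect_equal(tau, 6, tolerance = 1e-6)
  hinge <- round(a * pmax(0, (tau - pia$trial) / (tau - 1)))
  expect_equal(pia$gaze_changes, as.integer(hinge))
  expect_true(all(pia$gaze_changes[pia$trial >= 6] == 0))
})

test_that("trial scores conserve counts and carry the configured missingness", {
  cfg <- synth_config()
  st <- simulate_study(cfg, seed = 10, keylog = FALSE)
  expect_equal(st$scores$total,
               st$scores$correct + st$scores$wrong_key + st$scores$wrong_order)
  expect_equal(sum(is.na(st$battery$BS_R)), round(22 / 86 * 86))
  expect_equal(length(unique(st$gaze$participant)), 86 - round(12 / 86 * 86))
  # full generation stays desk-fast and schema-compatible downstream
  expect_true(all(c("participant", "task", "trial", "correct", "wrong_key",
                    "wrong_order", "total", "error_rate") %in% names(st$scores)))
})

test_that("impossible key-log targets are rejected", {
  seqs <- default_sequences()
  tg <- data.frame(participant = "p1", task = "piano", trial = 1,
                   correct = -1, wrong_key = 0, wrong_order = 0)
  expect_error(gen_keylog(tg, seqs), "nonnegative")
})
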