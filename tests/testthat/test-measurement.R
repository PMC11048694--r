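test_that("indicator preparation standardizes and orients scores", {
  b <- data.frame(participant = c("a", "b"), C = c(10, 20), ZVT = c(30, 60))
  z <- prepare_indicators(b)
  # two-point column standardizes to -sqrt(2)/2, +sqrt(2)/2 under the
  # sample (n-1) SD convention
  expect_equal(as.numeric(z[, "C"]), c(-sqrt(2) / 2, sqrt(2) / 2))
  # the slower (larger) time maps to the lower standardized score
  expect_lt(z["b", "ZVT"], z["a", "ZVT"])
  expect_equal(colMeans(z), c(C = 0, ZVT = 0))
  expect_equal(apply(z, 2, sd), c(C = 1, ZVT = 1))
})

test_that("zero-variance indicators are rejected by name", {
  b <- data.frame(participant = c("a", "b"), C = c(10, 20), ZVT = c(30, 30))
  expect_error(prepare_indicators(b), "'ZVT' has zero variance")
})

test_that("an (almost) noise-free two-factor structure is recovered", {
  set.seed(31)
  n <- 400
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  f <- matrix(rnorm(n * 2), n, 2) %*% chol(Phi)
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- c(0.9, 0.8, 0.7)
  L[4:6, 2] <- c(0.9, 0.8, 0.6)
  # residual noise tiny (exactly zero would make S singular and the ML
  # discrepancy undefined); structure is then identified almost exactly
  x <- f %*% t(L) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  colnames(x) <- paste0("i", 1:6)
  mod <- cfa_model(list(F1 = c("i1", "i2", "i3"), F2 = c("i4", "i5", "i6")))
  fit <- suppressWarnings(fit_cfa(x, mod))
  expect_equal(unname(fit$lambda[1:3, "F1"]), c(0.9, 0.8, 0.7),
               tolerance = 0.05)
  expect_equal(unname(fit$lambda[4:6, "F2"]), c(0.9, 0.8, 0.6),
               tolerance = 0.05)
  expect_lt(abs(fit$phi["F1", "F2"] - 0.3), 0.06)
  # the implied covariance reproduces S essentially perfectly
  expect_lt(fit$F_min, 0.05)
})

test_that("fit indices match the closed-form oracle on toy covariances", {
  set.seed(32)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    S <- cov2cor(crossprod(A) + diag(3))
    n <- 120
    # single-factor model on 3 indicators (just-identified, df 0 edge is
    # avoided by adding a 4th indicator)
    B <- matrix(rnorm(16), 4, 4)
    S4 <- cov2cor(crossprod(B) + diag(4))
    colnames(S4) <- rownames(S4) <- paste0("i", 1:4)
    x <- MASS::mvrnorm(n, rep(0, 4), S4)
    colnames(x) <- paste0("i", 1:4)
    mod <- cfa_model(list(F1 = c("i1", "i2", "i3", "i4")))
    fit <- suppressWarnings(fit_cfa(scale(x), mod))
    fi <- fit$fit
    orc <- oracle_fit_indices(fi$chi2_model, fi$df_model,
                              fi$chi2_baseline, fi$df_baseline, n)
    expect_equal(fi$CFI, orc$CFI, tolerance = 1e-8)
    expect_equal(fi$TLI, orc$TLI, tolerance = 1e-8)
    expect_equal(fi$IFI, orc$IFI, tolerance = 1e-8)
    expect_equal(fi$RMSEA, orc$RMSEA, tolerance = 1e-8)
    # chi2 equals (n-1) times the independently evaluated discrepancy
    Sigma <- fitted(fit)
    expect_equal(fi$chi2_model,
                 (n - 1) * oracle_discrepancy(fit$S, Sigma), tolerance = 1e-6)
  }
})

test_that("the saturated limit gives a zero discrepancy and perfect indices", {
  set.seed(33)
  # a 3-indicator single factor is just-identified: Sigma reproduces S
  x <- MASS::mvrnorm(200, rep(0, 3),
                     matrix(c(1, .5, .4, .5, 1, .45, .4, .45, 1), 3))
  colnames(x) <- paste0("i", 1:3)
  fit <- suppressWarnings(fit_cfa(scale(x), cfa_model(list(F1 = paste0("i", 1:3)))))
  expect_lt(fit$fit$chi2_model, 1e-4)
  expect_equal(fit$fit$CFI, 1)
  expect_equal(fit$fit$RMSEA, 0, tolerance = 1e-4)
  expect_lt(fit$fit$SRMR, 1e-3)
})

test_that("battery-structure parameters are recovered from a seeded sample", {
  cfg <- synth_config(n_participants = 500)
  fa <- gen_factors(cfg, seed = 34)
  fit <- fit_cfa(fa$battery)
  L_true <- fa$truth$lambda
  L_hat <- fit$lambda[rownames(L_true), colnames(L_true)]
  free <- L_true != 0
  expect_lt(max(abs(L_hat[free] - L_true[free])), 0.1)
  expect_lt(max(abs(L_hat[!free])), 1e-8)
  # factor correlations within +-0.1, including the WM-PS value
  expect_lt(max(abs(fit$phi - cfg$factor_corr)), 0.1)
  expect_equal(fit$phi["WM", "PS"], 0.44, tolerance = 0.1)
  expect_true(isSymmetric(fit$phi))
  expect_equal(unname(diag(fit$phi)), rep(1, 4))
})

test_that("loading estimates are unbiased over seeded replications", {
  cfg <- synth_config(n_participants = 500)
  bias <- matrix(NA_real_, 15, 0)
  errs <- c()
  for (r in 1:25) {
    fa <- gen_factors(cfg, seed = 340 + r)
    fit <- suppressWarnings(fit_cfa(fa$battery))
    L_true <- fa$truth$lambda
    free <- L_true != 0
    errs <- c(errs, mean(fit$lambda[rownames(L_true), colnames(L_true)][free] -
                           L_true[free]))
  }
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("orthogonal specifications yield an identity factor correlation", {
  set.seed(35)
  n <- 300
  f <- matrix(rnorm(n * 2), n, 2)
  x <- cbind(f[, 1] %o% c(1, 1, 1) * 0.7, f[, 2] %o% c(1, 1, 1) * 0.7) +
    matrix(rnorm(n * 6, 0, sqrt(0.51)), n, 6)
  x <- x[, c(1:3, 4:6)]
  colnames(x) <- paste0("i", 1:6)
  mod <- cfa_model(list(F1 = c("i1", "i2", "i3"), F2 = c("i4", "i5", "i6")),
                   fixed_zero = "F1~F2")
  fit <- suppressWarnings(fit_cfa(scale(x), mod))
  expect_equal(unname(fit$phi), diag(2))
  fc <- factor_correlations(fit)
  expect_true(all(is.na(fc$se[upper.tri(fc$se)])))
})

test_that("factor scores recover the latent abilities and respect missingness", {
  cfg <- synth_config(n_participants = 500)
  fa <- gen_factors(cfg, seed = 36)
  fit <- fit_cfa(fa$battery)
  fs <- factor_scores(fit)
  truth <- fa$truth
  for (f in c("WM", "PS", "PM", "DX")) {
    r <- cor(fs[[f]], fa$factors[[f]], use = "complete.obs")
    expect_gt(r, 0.8)
    expect_lt(abs(mean(fs[[f]], na.rm = TRUE)), 0.1)
  }
  # participants lacking the Corsi span are scored from the remaining
  # working-memory indicators and flagged as partial
  miss <- fa$battery$participant[is.na(fa$battery$BS_R)]
  expect_true(all(miss %in% attr(fs, "partial")))
  expect_false(any(is.na(fs$WM)))
})

test_that("a perfectly loading single indicator reproduces itself as score", {
  set.seed(37)
  x <- matrix(rnorm(100), 100, 1)
  x <- scale(x)
  colnames(x) <- "i1"
  fit <- structure(list(lambda = matrix(1, 1, 1, dimnames = list("i1", "F1")),
                        phi = matrix(1, 1, 1, dimnames = list("F1", "F1")),
                        theta = c(i1 = 1e-8),
                        layout = list(inds = "i1", fac = "F1", k = 1, p = 1),
                        model = cfa_model(list(F1 = "i1")),
                        data = x),
                   class = "cfa_fit")
  fs <- factor_scores(fit)
  expect_equal(fs$F1, as.numeric(x), tolerance = 1e-6)
})

test_that("a participant with no indicators of a factor gets a missing score", {
  cfg <- synth_config(n_participants = 60)
  fa <- gen_factors(cfg, seed = 38)
  bat <- fa$battery
  wm_cols <- c("DSP_F", "DSP_R", "DSP_S", "BS_R")
  bat[1, wm_cols] <- NA
  fit <- suppressWarnings(fit_cfa(bat))
  fs <- factor_scores(fit, bat)
  expect_true(is.na(fs$WM[1]))
  expect_false(is.na(fs$PS[1]))
})
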