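#' Exponential learning-curve value
#'
#' The expected performance at trial `t` follows
#' `eta(t) = beta + (alpha - beta) * exp(-exp(gamma) * (t - 1))`:
#' `alpha` is the baseline (the trial-1 mean exactly, since the exponent
#' uses `t - 1`), `beta` the asymptote approached as practice continues, and
#' `gamma` the log learning rate, unconstrained so that negative values mean
#' slow learning. `beta < alpha` is admissible and signals non-learning.
#'
#' @param alpha,beta,gamma curve parameters (vectorized).
#' @param t trial index, `>= 1`.
#' @return expected performance, recycled to the common length.
#' @examples
#' curve_value(10, 40, 0, t = 3)  # 40 - 30 * exp(-2)
#' @export
curve_value <- function(alpha, beta, gamma, t) {
  stopifnot(all(t >= 1))
  beta + (alpha - beta) * exp(-exp(gamma) * (t - 1))
}

jags_exponential_model <- "
model {
  for (n in 1:N) {
    y[n] ~ dnorm(eta[n], tau_y)
    eta[n] <- beta[pid[n]] + (alpha[pid[n]] - beta[pid[n]]) *
              exp(-exp(gamma[pid[n]]) * (t[n] - 1))
  }
  # triangular (Cholesky-regression) parameterization of correlated
  # individual effects: beta conditions on alpha, gamma on both
  for (i in 1:P) {
    alpha[i] ~ dnorm(mu_a, prec_a)
    beta[i]  ~ dnorm(mu_b + b_ba * (alpha[i] - mu_a), prec_b)
    gamma[i] ~ dnorm(mu_g + b_ga * (alpha[i] - mu_a) +
                     b_gb * (beta[i] - mu_b - b_ba * (alpha[i] - mu_a)), prec_g)
  }
  mu_a ~ dnorm(pm_a, 1 / (ps_a^2))
  mu_b ~ dnorm(pm_b, 1 / (ps_b^2))
  mu_g ~ dnorm(0, 1 / (pg_sd^2))
  sd_a ~ dnorm(0, 1 / (ps_a^2)) T(0,)
  sd_b ~ dnorm(0, 1 / (ps_b^2)) T(0,)
  sd_g ~ dnorm(0, 1 / (pg_sd^2)) T(0,)
  prec_a <- 1 / (sd_a^2); prec_b <- 1 / (sd_b^2); prec_g <- 1 / (sd_g^2)
  b_ba ~ dnorm(0, 1 / (b_scale^2))
  b_ga ~ dnorm(0, 1 / (g_slope_sd^2))
  b_gb ~ dnorm(0, 1 / (g_slope_sd^2))
  sigma ~ dnorm(0, 1 / (ps_y^2)) T(0,)
  tau_y <- 1 / (sigma^2)
}
"

jags_polynomial_model <- "
model {
  for (n in 1:N) {
    y[n] ~ dnorm(inprod(X[n, ], theta[pid[n], ]), tau_y)
  }
  for (i in 1:P) {
    theta[i, 1:D] ~ dmnorm(mu[], Omega[, ])
  }
  mu[1:D] ~ dmnorm(mu0[], prec0[, ])
  Omega[1:D, 1:D] ~ dwish(W[, ], D + 1)
  sigma ~ dnorm(0, 1 / (ps_y^2)) T(0,)
  tau_y <- 1 / (sigma^2)
}
"

poly_degree <- c(linear = 1L, quadratic = 2L, cubic = 3L)

prep_curve_data <- function(scores, task) {
  if (!is.null(task)) {
    if (!"task" %in% names(scores)) stop("'scores' has no task column")
    scores <- scores[scores$task == task, , drop = FALSE]
    if (!nrow(scores)) stop("no rows for task ", task)
  }
  need <- c("participant", "trial", "correct")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores lack column(s): ", paste(miss, collapse = ", "))
  y <- scores$correct
  if (any(!is.finite(y))) stop("non-finite performance values in 'correct'")
  ids <- sort(unique(as.character(scores$participant)))
  pid <- match(as.character(scores$participant), ids)
  n_per <- table(pid)
  if (any(n_per < 2)) stop("every participant needs at least 2 trials")
  list(y = as.numeric(y), t = as.numeric(scores$trial), pid = pid, ids = ids)
}

#' Fit a hierarchical Bayesian learning-curve model
#'
#' Fits per-trial performance counts with a Gaussian likelihood around an
#' exponential learning curve (default) or a polynomial alternative, with
#' all curve parameters varying across participants and correlating with
#' each other. The exponential model estimates population means, SDs and the
#' 3x3 correlation matrix of individual baseline (alpha), asymptote (beta)
#' and log learning rate (gamma); polynomial families give each participant
#' a correlated coefficient vector of the matching degree. Sampling is MCMC
#' via JAGS; a convergence warning is raised when any monitored parameter
#' has split-Rhat above 1.01.
#'
#' @param scores trial-score table with columns `participant`, `trial`,
#'   `correct` (and `task` if `task` is given).
#' @param task optional task label to filter on.
#' @param family `"exponential"` (default), `"linear"`, `"quadratic"` or
#'   `"cubic"`.
#' @param config an [mcmc_config()]; defaults to the full 4 x 5000 / 2000
#'   profile.
#' @param priors optional named list overriding the weakly informative,
#'   scale-adapted defaults of the exponential model: `pm_a`/`ps_a`
#'   (baseline mean prior location/scale, default trial-1 mean and twice its
#'   SD), `pm_b`/`ps_b` (asymptote, from the last trial), `pg_sd` (log-rate
#'   prior SD, default 1.5), `b_scale`, `g_slope_sd` (triangular regression
#'   slopes), `ps_y` (residual-SD prior scale).
#' @param seed integer seed driving all chains.
#' @return An object of class `"learning_curves"`.
#' @export
fit_learning_curves <- function(scores, task = NULL, family = "exponential",
                                config = mcmc_config(), priors = list(),
                                seed = 1L) {
  family <- match.arg(family, c("exponential", names(poly_degree)))
  d <- prep_curve_data(scores, task)
  if (stats::sd(d$y) < .Machine$double.eps)
    warning("all performance values identical; curve parameters (and the SD of gamma) are unidentified")
  P <- length(d$ids)
  if (family == "exponential") {
    y1 <- d$y[d$t == min(d$t)]; yT <- d$y[d$t == max(d$t)]
    pr <- list(pm_a = mean(y1), ps_a = max(2 * stats::sd(y1), 1),
               pm_b = mean(yT), ps_b = max(2 * stats::sd(yT), 1),
               pg_sd = 1.5, b_scale = 2, g_slope_sd = 0.5,
               ps_y = max(stats::sd(d$y), 1))
    pr[names(priors)] <- priors
    data <- c(list(y = d$y, t = d$t, pid = d$pid, N = length(d$y), P = P), pr)
    monitor <- c("mu_a", "mu_b", "mu_g", "sd_a", "sd_b", "sd_g",
                 "b_ba", "b_ga", "b_gb", "sigma", "alpha", "beta", "gamma")
    run <- run_jags(jags_exponential_model, data, monitor, config, seed)
  } else {
    D <- poly_degree[[family]] + 1L
    tc <- (d$t - mean(d$t)) / stats::sd(d$t)
    X <- stats::poly(tc, degree = D - 1L, raw = TRUE)
    X <- cbind(1, X)
    v <- stats::var(d$y)
    data <- list(y = d$y, X = X, pid = d$pid, N = length(d$y), P = P, D = D,
                 mu0 = c(mean(d$y), rep(0, D - 1)),
                 prec0 = diag(1 / (4 * v), D),
                 W = diag((D + 1) * v, D),
                 ps_y = max(stats::sd(d$y), 1))
    monitor <- c("mu", "theta", "sigma")
    run <- run_jags(jags_polynomial_model, data, monitor, config, seed)
    attr(run, "X") <- X
  }
  obj <- structure(list(family = family, task = task, run = run,
                        data = d, priors = if (family == "exponential") pr else NULL,
                        X = if (family == "exponential") NULL else attr(run, "X"),
                        config = config, seed = seed),
                   class = "learning_curves")
  nb <- warn_rhat(pop_rhat(obj), paste0("learning curves (", family, ")"))
  obj$n_bad_rhat <- nb
  obj
}

# Rhat of the population-level parameters only (individual effects excluded).
pop_rhat <- function(object) {
  r <- object$run$rhat
  r[!grepl("\\[", names(r)) | grepl("^mu\\[", names(r))]
}

ind_draw_matrix <- function(object, what) {
  cols <- grep(paste0("^", what, "\\["), colnames(object$run$draws))
  m <- object$run$draws[, cols, drop = FALSE]
  idx <- as.integer(sub(".*\\[(\\d+)\\]", "\\1", colnames(m)))
  m[, order(idx), drop = FALSE]
}

# Population covariance entries implied by the triangular parameterization,
# computed per draw.
exp_population_draws <- function(object) {
  dr <- object$run$draws
  va <- dr[, "sd_a"]^2
  cab <- dr[, "b_ba"] * va
  vb <- dr[, "sd_b"]^2 + dr[, "b_ba"]^2 * va
  cag <- dr[, "b_ga"] * va
  cbg <- dr[, "b_ba"] * dr[, "b_ga"] * va + dr[, "b_gb"] * dr[, "sd_b"]^2
  vg <- dr[, "b_ga"]^2 * va + dr[, "b_gb"]^2 * dr[, "sd_b"]^2 + dr[, "sd_g"]^2
  cbind(mu_alpha = dr[, "mu_a"], mu_beta = dr[, "mu_b"], mu_gamma = dr[, "mu_g"],
        sd_alpha = sqrt(va), sd_beta = sqrt(vb), sd_gamma = sqrt(vg),
        cor_alpha_beta = cab / sqrt(va * vb),
        cor_alpha_gamma = cag / sqrt(va * vg),
        cor_beta_gamma = cbg / sqrt(vb * vg),
        sigma = dr[, "sigma"])
}

#' Population-level posterior summary of a learning-curve fit
#'
#' @param object a `"learning_curves"` fit.
#' @param prob credible-interval probability (default 0.95).
#' @param ... unused.
#' @return data frame with posterior mean, SD and credible bounds for the
#'   population means, SDs, individual-effect correlations and residual SD
#'   (exponential family), or the population coefficients (polynomials),
#'   plus Rhat.
#' @export
summary.learning_curves <- function(object, prob = 0.95, ...) {
  dr <- if (object$family == "exponential") exp_population_draws(object)
        else object$run$draws[, grep("^mu\\[|^sigma$", colnames(object$run$draws)),
                              drop = FALSE]
  s <- post_summary(dr, prob)
  rh <- pop_rhat(object)
  s$rhat <- NA_real_
  direct <- intersect(s$parameter, names(rh))
  s$rhat[match(direct, s$parameter)] <- rh[direct]
  # derived quantities inherit the worst Rhat of their ingredients
  s$rhat[is.na(s$rhat)] <- max(rh, na.rm = TRUE)
  remap <- c(mu_alpha = "mu_a", mu_beta = "mu_b", mu_gamma = "mu_g",
             sd_alpha = "sd_a", sd_beta = "sd_b")
  for (nm in intersect(s$parameter, names(remap)))
    s$rhat[s$parameter == nm] <- rh[remap[[nm]]]
  s
}

#' @export
print.learning_curves <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian learning curves (%s family)\n", x$family))
  if (!is.null(x$task)) cat("  task:", x$task, "\n")
  cat(sprintf("  %d participants, %d observations; %d chains x %d iter (%d warmup)\n",
              length(x$data$ids), length(x$data$y), x$config$chains,
              x$config$iter, x$config$warmup))
  s <- summary(x)
  keep <- s$parameter %in% c("mu_alpha", "mu_beta", "mu_gamma", "sigma") |
    grepl("^mu\\[", s$parameter)
  print(s[keep, ], digits = 3, row.names = FALSE)
  cat(sprintf("  max split-Rhat (population): %.3f; divergences: %d (%s)\n",
              max(pop_rhat(x), na.rm = TRUE), x$run$divergences,
              x$run$sampler))
  invisible(x)
}

#' @export
coef.learning_curves <- function(object, ...) {
  s <- summary(object)
  stats::setNames(s$mean, s$parameter)
}

#' Posterior-mean individual curve parameters
#'
#' One (alpha, beta, gamma) triple per participant (exponential family),
#' used downstream as the learning-rate covariate and for cross-task
#' correlations.
#'
#' @param fit a `"learning_curves"` fit of the exponential family.
#' @return data frame: participant, alpha, beta, gamma (posterior means).
#' @export
individual_estimates <- function(fit) {
  stopifnot(inherits(fit, "learning_curves"))
  if (fit$family != "exponential")
    stop("individual estimates are defined for the exponential family")
  data.frame(participant = fit$data$ids,
             alpha = colMeans(ind_draw_matrix(fit, "alpha")),
             beta = colMeans(ind_draw_matrix(fit, "beta")),
             gamma = colMeans(ind_draw_matrix(fit, "gamma")))
}

# S x N pointwise conditional mean matrix for the fit's own observations.
eta_draws <- function(object) {
  d <- object$data
  if (object$family == "exponential") {
    al <- ind_draw_matrix(object, "alpha")
    be <- ind_draw_matrix(object, "beta")
    ga <- ind_draw_matrix(object, "gamma")
    eta <- matrix(NA_real_, nrow(al), length(d$y))
    for (tt in unique(d$t)) {
      sel <- which(d$t == tt)
      eta[, sel] <- (be + (al - be) * exp(-exp(ga) * (tt - 1)))[, d$pid[sel]]
    }
    eta
  } else {
    dr <- object$run$draws
    P <- length(d$ids); D <- ncol(object$X)
    eta <- matrix(0, nrow(dr), length(d$y))
    for (k in seq_len(D)) {
      thk <- dr[, paste0("theta[", seq_len(P), ",", k, "]"), drop = FALSE]
      eta <- eta + thk[, d$pid, drop = FALSE] *
        matrix(object$X[, k], nrow(dr), length(d$y), byrow = TRUE)
    }
    eta
  }
}

#' @export
fitted.learning_curves <- function(object, ...) {
  d <- object$data
  data.frame(participant = d$ids[d$pid],
             task = if (is.null(object$task)) NA_character_ else object$task,
             trial = d$t, eta = colMeans(eta_draws(object)))
}

# Pointwise log-likelihood matrix (draws x observations) for PSIS-LOO.
loglik_matrix <- function(object) {
  eta <- eta_draws(object)
  sig <- object$run$draws[, "sigma"]
  y <- object$data$y
  ll <- matrix(NA_real_, nrow(eta), ncol(eta))
  for (i in seq_len(ncol(eta)))
    ll[, i] <- stats::dnorm(y[i], eta[, i], sig, log = TRUE)
  ll
}

#' @export
plot.learning_curves <- function(x, n_show = 20, ...) {
  d <- x$data
  fe <- fitted(x)
  show <- d$ids[seq_len(min(n_show, length(d$ids)))]
  plot(NULL, xlim = range(d$t), ylim = range(d$y),
       xlab = "trial", ylab = "correct presses",
       main = paste0("Learning curves (", x$family,
                     if (!is.null(x$task)) paste0(", ", x$task), ")"))
  for (id in show) {
    sel <- d$ids[d$pid] == id
    graphics::points(d$t[sel], d$y[sel], col = "grey60", pch = 16, cex = 0.5)
    o <- order(fe$trial[sel])
    graphics::lines(fe$trial[sel][o], fe$eta[sel][o], col = "steelblue")
  }
  s <- summary(x)
  if (x$family == "exponential") {
    mu <- s$mean[match(c("mu_alpha", "mu_beta", "mu_gamma"), s$parameter)]
    tt <- seq(min(d$t), max(d$t), length.out = 100)
    graphics::lines(tt, curve_value(mu[1], mu[2], mu[3], tt), lwd = 2.5)
  }
  invisible(x)
}

#' Compare learning-curve families by PSIS-LOO elpd
#'
#' Fits each candidate family to the same data (same per-participant
#' correlated-coefficient random-effects structure) and compares their
#' expected log pointwise predictive densities, estimated by
#' Pareto-smoothed importance-sampling leave-one-out cross-validation.
#'
#' @param scores,task,config,seed as in [fit_learning_curves()].
#' @param families candidate families.
#' @return An object of class `"elpd_comparison"`: per-model elpd with SE,
#'   the pairwise elpd-difference matrix (row minus column) with SEs, and a
#'   reliability flag when more than 10% of points have Pareto k > 0.7.
#' @export
compare_models <- function(scores, task = NULL,
                           families = c("linear", "quadratic", "cubic", "exponential"),
                           config = reduced_config(), seed = 1L) {
  labels <- make.unique(families)
  fits <- list(); loos <- list()
  for (i in seq_along(families)) {
    fits[[labels[i]]] <- fit_learning_curves(scores, task = task,
                                             family = families[i],
                                             config = config, seed = seed)
    loos[[labels[i]]] <- psis_loo(loglik_matrix(fits[[labels[i]]]))
  }
  k <- length(families)
  diff <- matrix(0, k, k, dimnames = list(labels, labels))
  diff_se <- matrix(0, k, k, dimnames = list(labels, labels))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    di <- loos[[a]]$elpd_i - loos[[b]]$elpd_i
    diff[a, b] <- sum(di)
    diff_se[a, b] <- sqrt(length(di) * stats::var(di))
  }
  structure(list(
    table = data.frame(family = families,
                       elpd = vapply(loos, `[[`, numeric(1), "elpd"),
                       se = vapply(loos, `[[`, numeric(1), "se"),
                       p_loo = vapply(loos, `[[`, numeric(1), "p_loo"),
                       frac_high_k = vapply(loos, `[[`, numeric(1), "frac_high_k"),
                       row.names = NULL),
    diff = diff, diff_se = diff_se,
    unreliable = any(vapply(loos, `[[`, logical(1), "unreliable")),
    loos = loos, task = task),
    class = "elpd_comparison")
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat("Learning-curve family comparison (PSIS-LOO)\n")
  if (!is.null(x$task)) cat("  task:", x$task, "\n")
  tb <- x$table[order(-x$table$elpd), ]
  print(tb, digits = 4, row.names = FALSE)
  best <- tb$family[1]
  cat("  elpd differences vs", best, "(negative = worse):\n")
  d <- x$diff[, best] ; s <- x$diff_se[, best]
  for (f in setdiff(rownames(x$diff), best))
    cat(sprintf("    %-12s %8.1f (SE %.1f)\n", f, d[f], s[f]))
  if (isTRUE(x$unreliable))
    cat("  note: comparison flagged unreliable (high Pareto-k fraction)\n")
  invisible(x)
}
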