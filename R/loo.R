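# Pareto-smoothed importance sampling leave-one-out cross-validation.
#
# Given an S x N pointwise log-likelihood matrix (S posterior draws, N
# observations), leave-one-out predictive densities are estimated by
# importance sampling with raw log-ratios -ll; the largest 20% of the
# weights of each observation are stabilized by replacing them with order
# statistics of a generalized Pareto distribution fitted to the weight tail.
# The tail-shape estimate k diagnoses reliability (k > 0.7 is untrustworthy).

# Zhang & Stephens (2009)-style profile-posterior fit of the generalized
# Pareto distribution to exceedances x > 0, with the usual weakly
# informative shrinkage of the shape towards 0.5 for small tails.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# Smooth one observation's raw log-weights; returns the smoothed log-weights
# (unnormalized) and the Pareto tail-shape diagnostic.
psis_smooth <- function(lr) {
  S <- length(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lr, k = NA_real_))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids] - cutoff) - 1  # exceedances on the weight scale
  if (all(exc <= 0) || length(unique(exc)) < 2) return(list(lw = lr, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  p <- (seq_len(M) - 0.5) / M
  smoothed <- cutoff + log1p(gpd_quantile(p, fit$k, fit$sigma))
  smoothed <- pmin(smoothed, max(lr))     # never exceed the raw maximum
  lw <- lr
  lw[tail_ids[order(lr[tail_ids])]] <- smoothed
  list(lw = lw, k = fit$k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' @param ll S x N matrix of pointwise log-likelihood values (rows are
#'   posterior draws).
#' @return list of class `"psis_loo"`: `elpd` and its `se`, `p_loo`
#'   (effective parameter count), pointwise `elpd_i`, Pareto shape
#'   diagnostics `pareto_k`, and `unreliable` (`TRUE` when more than 10% of
#'   observations have k > 0.7).
#' @export
psis_loo <- function(ll) {
  stopifnot(is.matrix(ll), nrow(ll) > 10)
  S <- nrow(ll); N <- ncol(ll)
  elpd_i <- numeric(N); k <- numeric(N); lpd_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - log_sum_exp(sm$lw)
    elpd_i[i] <- log_sum_exp(lw + ll[, i])
    lpd_i[i] <- log_sum_exp(ll[, i]) - log(S)
    k[i] <- sm$k
  }
  bad <- mean(k > 0.7, na.rm = TRUE)
  structure(list(elpd = sum(elpd_i), se = sqrt(N * stats::var(elpd_i)),
                 p_loo = sum(lpd_i - elpd_i), elpd_i = elpd_i, pareto_k = k,
                 unreliable = isTRUE(bad > 0.1), frac_high_k = bad),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE %.1f), p_loo = %.1f\n",
              x$elpd, x$se, x$p_loo))
  if (isTRUE(x$unreliable))
    cat(sprintf("  warning: %.0f%% of observations have Pareto k > 0.7\n",
                100 * x$frac_high_k))
  invisible(x)
}
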