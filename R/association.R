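#' Standardize fitted performance within each trial
#'
#' Model-fitted performance is standardized per task x trial (1 unit = 1 SD
#' of that trial's distribution across participants) so that regression
#' coefficients are comparable across the learning phase.
#'
#' @param fitted data frame with columns `participant`, `trial`, a value
#'   column (default `eta`), and optionally `task`.
#' @param value name of the value column.
#' @return the input with a `z` column; within each task x trial `z` has
#'   mean 0 and SD 1 (sample, n-1, convention).
#' @export
standardize_by_trial <- function(fitted, value = "eta") {
  stopifnot(is.data.frame(fitted), value %in% names(fitted))
  if (!"task" %in% names(fitted)) fitted$task <- "task"
  key <- interaction(fitted$task, fitted$trial, drop = TRUE)
  z <- numeric(nrow(fitted))
  for (g in levels(key)) {
    sel <- key == g
    v <- fitted[[value]][sel]
    if (length(v) < 2)
      stop("fewer than 2 participants at trial group ", g)
    s <- stats::sd(v)
    if (!is.finite(s) || s < .Machine$double.eps)
      stop("zero between-participant SD at trial group ", g,
           "; standardization undefined")
    z[sel] <- (v - mean(v)) / s
  }
  fitted$z <- z
  fitted
}

# Model text assembled from parts: the learning-rate control enters either
# with one coefficient per trial or a single global one, and the participant
# random intercept is optional. Scale parameters carry a small lower
# truncation so the precision can never degenerate.
jags_trialwise_model <- function(per_trial_rate, random_intercept) {
  paste0("
model {
  for (n in 1:N) {
    z[n] ~ dnorm(delta[t[n]] + b[t[n]] * x[pid[n]] + ", if (per_trial_rate)
      "ct[t[n]]" else "c_global", " * g[pid[n]]", if (random_intercept)
      " + u[pid[n]]" else "", ", tau_e)
  }
  for (tt in 1:NT) {
    delta[tt] ~ dnorm(0, 1)
    b[tt] ~ dnorm(0, 1)\n",
  if (per_trial_rate) "    ct[tt] ~ dnorm(0, 1)\n" else "", "  }\n",
  if (!per_trial_rate) "  c_global ~ dnorm(0, 1)\n" else "",
  if (random_intercept) "
  for (i in 1:P) { u[i] ~ dnorm(0, prec_u) }
  sd_u ~ dnorm(0, 1) T(0.01,)
  prec_u <- 1 / (sd_u^2)\n" else "", "
  sigma ~ dnorm(0, 1) T(0.01,)
  tau_e <- 1 / (sigma^2)
}
")
}

#' Trial-wise performance-ability association model
#'
#' Regresses per-trial standardized performance on one standardized
#' predictor, treating trials as factors so that every trial gets its own
#' coefficient `b_t`, while controlling for the individual learning rate
#' (its own trial-indexed coefficient by default) and a participant random
#' intercept. Fitted by MCMC; each `b_t` is reported with its posterior
#' mean and 95% credible interval.
#'
#' @param z output of [standardize_by_trial()] for one task.
#' @param predictor data frame `participant`, value column (second column
#'   used), e.g. one latent factor score, musical sophistication or practice
#'   hours; standardized internally.
#' @param rates data frame `participant`, `gamma` (individual learning-rate
#'   estimates from [individual_estimates()]); standardized internally.
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @param rate_control `"per_trial"` (default; the learning rate gets its
#'   own coefficient in every trial) or `"global"` (one shared coefficient).
#' @param random_intercept include the participant random intercept
#'   (default `TRUE`).
#' @return object of class `"association_curve"` with `table` (trial,
#'   b_mean, b_low, b_high), the rate-control coefficients, Rhat
#'   diagnostics and metadata.
#' @export
trialwise_association <- function(z, predictor, rates, config = mcmc_config(),
                                  seed = 1L, rate_control = c("per_trial", "global"),
                                  random_intercept = TRUE) {
  rate_control <- match.arg(rate_control)
  stopifnot(is.data.frame(z), "z" %in% names(z))
  pred_name <- names(predictor)[2]
  ids <- sort(unique(as.character(z$participant)))
  x <- predictor[[2]][match(ids, as.character(predictor$participant))]
  if (mean(is.na(x)) > 0.5)
    stop("predictor '", pred_name, "' missing for more than 50% of participants")
  g <- rates$gamma[match(ids, as.character(rates$participant))]
  keep_ids <- ids[!is.na(x) & !is.na(g)]
  zz <- z[as.character(z$participant) %in% keep_ids, , drop = FALSE]
  pid <- match(as.character(zz$participant), keep_ids)
  xs <- as.numeric(scale(x[match(keep_ids, ids)]))
  gs <- as.numeric(scale(g[match(keep_ids, ids)]))
  trials <- sort(unique(zz$trial))
  tidx <- match(zz$trial, trials)
  per_trial <- rate_control == "per_trial"
  data <- list(z = zz$z, x = xs, g = gs, pid = pid, t = tidx,
               N = nrow(zz), P = length(keep_ids), NT = length(trials))
  if (!random_intercept) data$P <- NULL
  monitor <- c("b", if (per_trial) "ct" else "c_global", "delta",
               if (random_intercept) "sd_u", "sigma")
  run <- run_jags(jags_trialwise_model(per_trial, random_intercept),
                  data, monitor, config, seed,
                  inits = list(sigma = max(stats::sd(zz$z), 0.2)))
  bcols <- paste0("b[", seq_along(trials), "]")
  bs <- post_summary(run$draws[, bcols, drop = FALSE])
  tab <- data.frame(trial = trials, b_mean = bs$mean,
                    b_low = bs$lower, b_high = bs$upper)
  rhat_b <- run$rhat[bcols]
  warn_rhat(rhat_b, paste0("trial-wise association (", pred_name, ")"))
  rate_cols <- grep(if (per_trial) "^ct\\[" else "^c_global$",
                    colnames(run$draws))
  structure(list(predictor = pred_name, table = tab,
                 rate_coef = post_summary(run$draws[, rate_cols, drop = FALSE]),
                 rhat = run$rhat, config = config, seed = seed,
                 rate_control = rate_control,
                 random_intercept = random_intercept,
                 n_participants = length(keep_ids)),
            class = "association_curve")
}

#' @export
print.association_curve <- function(x, ...) {
  cat(sprintf("Trial-wise association of performance with '%s' (n = %d)\n",
              x$predictor, x$n_participants))
  print(x$table, digits = 3, row.names = FALSE)
  pr <- association_profile(x)
  cat(sprintf("  trial-1 coefficient %.2f; minimum %.2f at trial %d; plateau %.2f%s\n",
              pr$initial, pr$minimum, pr$argmin_trial, pr$plateau,
              if (pr$dip_rebound) " (dip-rebound pattern)" else ""))
  invisible(x)
}

#' @export
plot.association_curve <- function(x, ...) {
  tb <- x$table
  plot(tb$trial, tb$b_mean, type = "b", pch = 16, ylim = range(tb$b_low, tb$b_high, 0),
       xlab = "trial", ylab = "standardized coefficient",
       main = paste("Performance ~", x$predictor), ...)
  graphics::arrows(tb$trial, tb$b_low, tb$trial, tb$b_high,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Shape summary of an association trajectory
#'
#' Reports the trial-1 coefficient, the weakest association (value and
#' trial), the plateau (mean of the last three trials) and whether the
#' trajectory shows the dip-then-rebound pattern (a minimum after trial 1
#' that is later exceeded).
#'
#' @param curve an `"association_curve"` (or a data frame with `trial` and
#'   `b_mean`).
#' @return list: `initial`, `argmin_trial`, `minimum`, `plateau`,
#'   `plateau_trials`, `dip_rebound`.
#' @export
association_profile <- function(curve) {
  tb <- if (inherits(curve, "association_curve")) curve$table else curve
  stopifnot(all(c("trial", "b_mean") %in% names(tb)))
  tb <- tb[order(tb$trial), ]
  amin <- which.min(tb$b_mean)
  last3 <- utils::tail(tb, 3)
  plateau <- mean(last3$b_mean)
  list(initial = tb$b_mean[1],
       argmin_trial = tb$trial[amin],
       minimum = tb$b_mean[amin],
       plateau = plateau,
       plateau_trials = last3$trial,
       dip_rebound = amin > 1 && plateau > tb$b_mean[amin] + 1e-12)
}

#' Pearson correlations between individual estimates and abilities
#'
#' Pairwise Pearson correlations (with two-sided p-values) between one
#' column of individual estimates (e.g. the learning rate) and each ability
#' or musicality column, on pairwise-complete observations.
#'
#' @param estimates data frame `participant` plus one numeric column (or
#'   name one via `column`).
#' @param abilities data frame `participant` plus numeric columns (factor
#'   scores, Gold-MSI total, practice hours, ...).
#' @param column which estimates column to correlate (default the first
#'   numeric one).
#' @return data frame: variable, r, p, n.
#' @export
rate_ability_correlations <- function(estimates, abilities, column = NULL) {
  stopifnot(is.data.frame(estimates), is.data.frame(abilities))
  num <- setdiff(names(estimates)[vapply(estimates, is.numeric, logical(1))],
                 "participant")
  if (is.null(column)) column <- num[1]
  x <- estimates[[column]][match(as.character(abilities$participant),
                                 as.character(estimates$participant))]
  vars <- setdiff(names(abilities)[vapply(abilities, is.numeric, logical(1))],
                  "participant")
  rows <- lapply(vars, function(v) {
    y <- abilities[[v]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      stop("fewer than 3 paired observations for ", v)
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, rows)
}
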