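#' Gaze changes per key press
#'
#' @param records data frame with `gaze_changes` and `key_presses` columns.
#' @return the input with a `gaze_per_press` column (`NA` where
#'   `key_presses` is 0 or missing).
#' @export
gaze_rate <- function(records) {
  stopifnot(all(c("gaze_changes", "key_presses") %in% names(records)))
  records$gaze_per_press <- ifelse(!is.na(records$key_presses) &
                                     records$key_presses > 0,
                                   records$gaze_changes / records$key_presses,
                                   NA_real_)
  records
}

jags_changepoint_model <- "
model {
  for (n in 1:N) {
    g[n] ~ dnorm(mu[n], tau_g) T(0,)
    mu[n] <- a[pid[n]] * ((cp[pid[n]] - t[n]) / (cp[pid[n]] - 1)) *
             step(cp[pid[n]] - t[n])
  }
  for (i in 1:P) {
    l[i] ~ dnorm(mu_l, prec_l)
    # lower guard keeps the hinge denominator away from 0
    cp[i] <- cp_min + (Tmax - cp_min) * ilogit(l[i])
    a[i] ~ dlnorm(mu_la, prec_la)
  }
  mu_l ~ dnorm(0, 1 / (1.5^2))
  sd_l ~ dnorm(0, 1) T(0,)
  prec_l <- 1 / (sd_l^2)
  mu_la ~ dnorm(pm_a, 1 / (ps_a^2))
  sd_la ~ dnorm(0, 1) T(0,)
  prec_la <- 1 / (sd_la^2)
  # counts are integers: noise SD below the rounding resolution is
  # meaningless and would let all-zero data send the likelihood to a spike
  sigma_g ~ dnorm(0, 1 / (ps_g^2)) T(sg_min,)
  tau_g <- 1 / (sigma_g^2)
  pop_tau <- cp_min + (Tmax - cp_min) * ilogit(mu_l)
}
"

#' Fit the piecewise gaze change-point model
#'
#' Gaze-change counts are modelled as a linear decline on the count scale
#' that reaches zero at an individual change point `tau_i` and stays zero
#' afterwards (a hinge), with zero-truncated Gaussian noise. `tau_i` is the
#' trial at which visual control becomes negligible for that participant; it
#' is continuous on `[1, Tmax]` via a logit-scaled hierarchical prior. The
#' population change point is reported with a 95% credible interval.
#'
#' @param records gaze table with `participant`, `trial`, `gaze_changes`
#'   (and `task` if `task` is given).
#' @param task optional task label to filter on.
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @param t_max upper bound of the change point (default the largest
#'   observed trial).
#' @return object of class `"changepoint_fit"`: `population` (posterior
#'   mean, SD, CrI of the population change point), `individual`
#'   (per-participant tau with CrI; participants whose counts are all zero
#'   are flagged, their tau concentrating at the lower bound), `sigma`,
#'   Rhat diagnostics.
#' @export
fit_gaze_changepoint <- function(records, task = NULL, config = mcmc_config(),
                                 seed = 1L, t_max = NULL) {
  if (!is.null(task)) {
    records <- records[records$task == task, , drop = FALSE]
    if (!nrow(records)) stop("no gaze rows for task ", task)
  }
  need <- c("participant", "trial", "gaze_changes")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("gaze records lack: ", paste(miss, collapse = ", "))
  g <- records$gaze_changes
  if (any(g < 0)) stop("negative gaze-change counts")
  ids <- sort(unique(as.character(records$participant)))
  pid <- match(as.character(records$participant), ids)
  if (any(table(pid) < 5)) stop("every participant needs at least 5 trials")
  if (is.null(t_max)) t_max <- max(records$trial)
  all_zero <- ids[tapply(g, pid, function(v) all(v == 0))]
  g1 <- g[records$trial == min(records$trial)]
  data <- list(g = as.numeric(g), t = as.numeric(records$trial), pid = pid,
               N = length(g), P = length(ids), Tmax = t_max, cp_min = 1.1,
               sg_min = 0.05,
               pm_a = log(mean(g1) + 1), ps_a = 1.5,
               ps_g = max(stats::sd(g), 1))
  monitor <- c("pop_tau", "mu_l", "sd_l", "mu_la", "sd_la", "sigma_g", "cp", "a")
  a_init <- pmax(tapply(data$g, pid, max), 0.5)
  run <- run_jags(jags_changepoint_model, data, monitor, config, seed,
                  inits = function(ch) list(l = rep(0, length(ids)),
                                            a = as.numeric(a_init),
                                            sigma_g = max(stats::sd(g), 0.5)))
  pop <- post_summary(run$draws[, "pop_tau", drop = FALSE])
  cp_cols <- paste0("cp[", seq_along(ids), "]")
  ind <- post_summary(run$draws[, cp_cols, drop = FALSE])
  ind <- data.frame(participant = ids, tau = ind$mean, tau_low = ind$lower,
                    tau_high = ind$upper,
                    a = colMeans(run$draws[, paste0("a[", seq_along(ids), "]"),
                                           drop = FALSE]),
                    all_zero = ids %in% all_zero)
  warn_rhat(run$rhat[c("pop_tau", "mu_l", "sd_l", "sigma_g")], "gaze change point")
  structure(list(population = pop, individual = ind,
                 sigma = mean(run$draws[, "sigma_g"]),
                 rhat = run$rhat[!grepl("\\[", names(run$rhat))],
                 all_zero = all_zero, task = task, config = config,
                 seed = seed, t_max = t_max),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("Piecewise gaze change-point model")
  if (!is.null(x$task)) cat(" -", x$task)
  cat("\n")
  cat(sprintf("  visual control negligible at around trial %.2f [%.2f, %.2f]\n",
              x$population$mean, x$population$lower, x$population$upper))
  cat(sprintf("  %d participants; count noise SD %.2f; max Rhat %.3f\n",
              nrow(x$individual), x$sigma, max(x$rhat, na.rm = TRUE)))
  if (length(x$all_zero))
    cat("  all-zero gaze counts (tau at lower bound):",
        paste(x$all_zero, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.changepoint_fit <- function(object, ...) {
  c(pop_tau = object$population$mean, sigma_g = object$sigma)
}

#' @export
summary.changepoint_fit <- function(object, ...) {
  list(population = object$population, individual = object$individual,
       rhat = object$rhat)
}
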