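#' Configuration of the synthetic cognito-motor learning study
#'
#' Bundles every "truth" the generator needs: the four-factor measurement
#' model behind the test battery, the exponential learning-curve populations
#' of both sequence tasks (baseline alpha, asymptote beta, log learning rate
#' gamma, correlated within participant and across tasks), the coupling of
#' latent abilities onto the curve parameters, the gaze change-point
#' population, and the error-rate trajectory used to synthesize key-press
#' logs. Defaults emulate a single-session study of 86 older adults learning
#' a piano-related and a response-pad sequence over 20 trials of 20 s.
#'
#' @param n_participants number of participants (default 86).
#' @param trials number of trials per task (default 20).
#' @param tasks task labels; the first is the piano-related task.
#' @param loadings named list `factor -> named numeric vector` of nonzero
#'   standardized loadings. The default follows the retained-battery
#'   structure: working memory (WM) from digit spans and reversed Corsi
#'   block span, processing speed (PS) from coding, symbol search, number
#'   connection and trail-making times plus a sequential-digit-span
#'   cross-loading, psychomotor speed (PM) from clicking speed, dexterity
#'   (DX) from the Purdue Pegboard conditions.
#' @param factor_corr 4x4 factor correlation matrix (order WM, PS, PM, DX).
#' @param curve named list per task with elements `mu` (alpha, beta, gamma
#'   means), `sd`, `corr` (3x3 within-task correlation of individual
#'   parameters) and `sigma` (residual SD of trial performance).
#' @param cross_task_corr cross-task correlations of the individual alpha,
#'   beta, gamma effects.
#' @param coupling 3x4 matrix (rows alpha, beta, gamma; columns WM, PS, PM,
#'   DX) of ability effects on curve parameters in parameter-SD units: each
#'   individual parameter mean is shifted by `sd_param * coupling %*% f_i`.
#' @param error_rate named list per task `c(start, end)`: expected error
#'   rate at trial 1 and trial `trials`, declining exponentially between.
#' @param wrong_key_frac fraction of errors that are wrong-key presses (the
#'   rest are wrong-order).
#' @param gaze named list per task with `tau_mean` (population change-point
#'   trial), `tau_logit_sd`, `a_mean`/`a_sdlog` (initial gaze-change level,
#'   lognormal) and `sigma` (count noise SD).
#' @param missing_bs_r fraction of participants with a missing reversed
#'   Corsi block span (the test could not be administered to everyone).
#' @param missing_gaze fraction of participants without usable gaze video.
#' @param musicality list with Gold-MSI mean/sd and the fraction of
#'   participants with prior piano experience plus lognormal practice-hours
#'   parameters; musicality is generated independent of ability and
#'   performance.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_participants = 86L,
                         trials = 20L,
                         tasks = c("piano", "pad"),
                         loadings = default_loadings(),
                         factor_corr = default_factor_corr(),
                         curve = default_curve_truth(),
                         cross_task_corr = c(alpha = 0.44, beta = 0.69, gamma = 0.37),
                         coupling = default_coupling(),
                         error_rate = list(piano = c(start = 0.1504, end = 0.0668),
                                           pad   = c(start = 0.1050, end = 0.0235)),
                         wrong_key_frac = 0.4,
                         gaze = list(piano = list(tau_mean = 7.06, tau_logit_sd = 0.35,
                                                  a_mean = 14, a_sdlog = 0.35, sigma = 1.5),
                                     pad   = list(tau_mean = 4.92, tau_logit_sd = 0.30,
                                                  a_mean = 11, a_sdlog = 0.35, sigma = 1.2)),
                         missing_bs_r = 22 / 86,
                         missing_gaze = 12 / 86,
                         musicality = list(msi_mean = 56.8, msi_sd = 17.1,
                                           exp_frac = 37 / 86,
                                           hours_meanlog = log(900), hours_sdlog = 0.7,
                                           hours_max = 4000)) {
  stopifnot(n_participants >= 2, trials >= 2, length(tasks) >= 1)
  factor_corr <- as.matrix(factor_corr)
  check_corr(factor_corr, "factor_corr")
  if (!is.matrix(coupling) || nrow(coupling) != 3L || ncol(coupling) != nrow(factor_corr))
    stop("'coupling' must be a 3 x ", nrow(factor_corr), " matrix (alpha/beta/gamma x factors)")
  if (is.null(rownames(coupling))) rownames(coupling) <- c("alpha", "beta", "gamma")
  if (is.null(colnames(coupling))) colnames(coupling) <- names(loadings)
  if (is.null(dimnames(factor_corr)))
    dimnames(factor_corr) <- list(names(loadings), names(loadings))
  for (tk in tasks) {
    if (is.null(curve[[tk]])) stop("no curve truth for task ", tk)
    check_corr(curve[[tk]]$corr, paste0("curve$", tk, "$corr"))
    if (curve[[tk]]$sigma <= 0) stop("curve sigma must be positive")
    er <- error_rate[[tk]]
    if (is.null(er) || any(er < 0) || any(er > 1)) stop("error rates must lie in [0,1]")
    gz <- gaze[[tk]]
    if (gz$tau_mean < 1 || gz$tau_mean > trials)
      stop("gaze tau_mean must lie in [1, trials]")
  }
  if (length(tasks) > 1 && any(abs(cross_task_corr) > 1))
    stop("cross-task correlations must lie in [-1, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 trials = as.integer(trials), tasks = tasks,
                 loadings = loadings, factor_corr = factor_corr,
                 curve = curve, cross_task_corr = cross_task_corr,
                 coupling = coupling, error_rate = error_rate,
                 wrong_key_frac = wrong_key_frac, gaze = gaze,
                 missing_bs_r = missing_bs_r, missing_gaze = missing_gaze,
                 musicality = musicality),
            class = "synth_config")
}

check_corr <- function(R, what) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8) || any(abs(diag(R) - 1) > 1e-8))
    stop(what, " must be a symmetric correlation matrix with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(what, " is not positive semi-definite")
  invisible(TRUE)
}

#' @rdname synth_config
#' @export
default_loadings <- function() {
  list(WM = c(DSP_F = 0.7, DSP_R = 0.7, DSP_S = 0.5, BS_R = 0.7),
       PS = c(C = 0.7, SS = 0.7, ZVT = 0.7, TMT_A = 0.7, DSP_S = 0.4),
       PM = c(Click_R = 0.7, Click_L = 0.7, Click_B = 0.7),
       DX = c(PP_R = 0.7, PP_L = 0.7, PP_B = 0.7, PP_A = 0.7))
}

#' @rdname synth_config
#' @export
default_factor_corr <- function() {
  R <- diag(4)
  dimnames(R) <- list(c("WM", "PS", "PM", "DX"), c("WM", "PS", "PM", "DX"))
  R["WM", "PS"] <- R["PS", "WM"] <- 0.44
  R["WM", "PM"] <- R["PM", "WM"] <- 0.10
  R["WM", "DX"] <- R["DX", "WM"] <- 0.10
  R["PS", "PM"] <- R["PM", "PS"] <- 0.60
  R["PS", "DX"] <- R["DX", "PS"] <- 0.55
  R["PM", "DX"] <- R["DX", "PM"] <- 0.60
  R
}

#' @rdname synth_config
#' @export
default_curve_truth <- function() {
  corr <- matrix(c(1, 0.5, 0.25,
                   0.5, 1, 0.40,
                   0.25, 0.40, 1), 3, 3,
                 dimnames = list(c("alpha", "beta", "gamma"),
                                 c("alpha", "beta", "gamma")))
  list(piano = list(mu = c(alpha = 21, beta = 47, gamma = -1.98),
                    sd = c(alpha = 6, beta = 9, gamma = 0.6),
                    corr = corr, sigma = 3),
       pad   = list(mu = c(alpha = 28, beta = 58, gamma = -1.10),
                    sd = c(alpha = 7, beta = 10, gamma = 0.45),
                    corr = corr, sigma = 3))
}

#' @rdname synth_config
#' @export
default_coupling <- function() {
  m <- matrix(0, 3, 4, dimnames = list(c("alpha", "beta", "gamma"),
                                       c("WM", "PS", "PM", "DX")))
  # effects sit mainly on the asymptote and the learning rate; the baseline
  # inherits a share through the within-person parameter correlations plus a
  # modest direct effect, which yields the dip-then-rise association profile
  m["alpha", ] <- c(0.10, 0.20, 0.22, 0.20)
  m["beta", ]  <- c(0.12, 0.26, 0.30, 0.26)
  m["gamma", ] <- c(0.04, 0.08, 0.10, 0.08)
  m
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  participants:", x$n_participants, " trials:", x$trials,
      " tasks:", paste(x$tasks, collapse = ", "), "\n")
  for (tk in x$tasks)
    cat(sprintf("  %s curve mu: alpha=%.1f beta=%.1f gamma=%.2f (sigma=%.1f)\n",
                tk, x$curve[[tk]]$mu[1], x$curve[[tk]]$mu[2],
                x$curve[[tk]]$mu[3], x$curve[[tk]]$sigma))
  invisible(x)
}

# Assemble the full-loading matrix (indicators x factors) implied by the
# sparse per-factor lists; indicator order is fixed by first appearance.
loading_matrix <- function(loadings) {
  inds <- unique(unlist(lapply(loadings, names)))
  L <- matrix(0, length(inds), length(loadings),
              dimnames = list(inds, names(loadings)))
  for (f in names(loadings)) L[names(loadings[[f]]), f] <- loadings[[f]]
  L
}

# Observed score scales used to dress standardized indicators up as raw
# battery columns. `flip` marks time scores where lower raw values are better.
battery_scales <- function() {
  data.frame(
    indicator = c("Click_R", "Click_L", "Click_B", "PP_R", "PP_L", "PP_B", "PP_A",
                  "C", "SS", "ZVT", "TMT_A", "DSP_F", "DSP_R", "DSP_S", "BS_R"),
    mean = c(85, 82, 78, 13, 12.5, 10.3, 21, 45, 25, 95, 48, 8, 7, 7, 7),
    sd   = c(13, 13, 12, 2, 2, 1.8, 5, 10, 6, 20, 15, 2, 2, 2, 2),
    flip = c(rep(FALSE, 9), TRUE, TRUE, rep(FALSE, 4)),
    digits = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma)
  sweep(matrix(stats::rnorm(n * p), n, p) %*% L, 2, mu, `+`)
}

#' Generate true latent abilities and the observed test battery
#'
#' Draws per-participant factor scores from a multivariate normal with the
#' configured factor correlations, then builds the 15 battery indicators as
#' `loading * factor + residual`, rescales them to realistic raw test scales
#' (time scores oriented so that lower is better) and blanks the reversed
#' Corsi block span for the configured fraction of participants.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `factors` (participant + true WM/PS/PM/DX),
#'   `battery` (raw-scale indicator table with missing cells),
#'   `truth` (generating `lambda`, `phi`, `theta`).
#' @export
gen_factors <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  n <- cfg$n_participants
  L <- loading_matrix(cfg$loadings)
  Phi <- cfg$factor_corr
  comm <- rowSums((L %*% Phi) * L)
  if (any(comm > 1 + 1e-8))
    stop("loading/correlation configuration implies communality > 1 for: ",
         paste(rownames(L)[comm > 1 + 1e-8], collapse = ", "))
  Theta <- pmax(1 - comm, 0)
  f <- rmvnorm_chol(n, rep(0, ncol(L)), Phi)
  colnames(f) <- colnames(L)
  z <- f %*% t(L) + sweep(matrix(stats::rnorm(n * nrow(L)), n, nrow(L)), 2,
                          sqrt(Theta), `*`)
  sc <- battery_scales()
  sc <- sc[match(rownames(L), sc$indicator), ]
  # indicators without a named raw scale stay standardized
  unknown <- is.na(sc$indicator)
  sc$mean[unknown] <- 0; sc$sd[unknown] <- 1
  sc$flip[unknown] <- FALSE; sc$digits[unknown] <- 3
  raw <- sweep(sweep(z, 2, ifelse(sc$flip, -sc$sd, sc$sd), `*`), 2, sc$mean, `+`)
  for (j in seq_len(ncol(raw))) raw[, j] <- round(raw[, j], sc$digits[j])
  battery <- data.frame(participant = sprintf("p%03d", seq_len(n)), raw,
                        check.names = FALSE)
  n_miss <- round(cfg$missing_bs_r * n)
  if (n_miss > 0 && "BS_R" %in% names(battery))
    battery$BS_R[sample.int(n, n_miss)] <- NA
  list(factors = data.frame(participant = battery$participant, f,
                            check.names = FALSE),
       battery = battery,
       truth = list(lambda = L, phi = Phi, theta = Theta))
}

#' Generate per-trial performance and the true learning-curve parameters
#'
#' Individual (alpha, beta, gamma) triples are drawn jointly across both
#' tasks: within a task they follow the configured 3x3 correlation, across
#' tasks each parameter shares the configured cross-task correlation, and
#' each parameter's mean is shifted by `sd * (coupling %*% ability)` so that
#' more able participants start higher, plateau higher and/or learn faster.
#' Trial performance is `round(max(0, eta + noise))` with exponential-curve
#' mean `eta` and Gaussian noise.
#'
#' @param cfg a [synth_config()].
#' @param factors data frame of true factor scores from [gen_factors()]
#'   (column order after `participant` must match the coupling columns).
#' @param seed integer seed.
#' @return list with `scores` (participant, task, trial, correct),
#'   `params` (true individual alpha/beta/gamma per task) and `eta`
#'   (noise-free curve values).
#' @export
gen_performance <- function(cfg, factors, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed + 1L)
  n <- cfg$n_participants
  K <- length(cfg$tasks)
  f <- as.matrix(factors[, colnames(cfg$coupling), drop = FALSE])
  if (nrow(f) != n) stop("factor table does not match n_participants")
  # joint 3K x 3K correlation of individual effects (parameter-major blocks)
  R <- diag(3 * K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    R[(a - 1) * 3 + 1:3, (b - 1) * 3 + 1:3] <-
      if (a == b) cfg$curve[[cfg$tasks[a]]]$corr else diag(cfg$cross_task_corr)
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ev$values) < 1e-8)  # nudge to the nearest PSD correlation
    R <- cov2cor(ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors))
  zz <- rmvnorm_chol(n, rep(0, 3 * K), (R + t(R)) / 2)
  shift <- f %*% t(cfg$coupling)           # n x 3, in SD units
  params <- list(); scores <- list(); etas <- list()
  for (a in seq_len(K)) {
    tk <- cfg$tasks[a]
    cv <- cfg$curve[[tk]]
    th <- sweep(sweep(zz[, (a - 1) * 3 + 1:3, drop = FALSE] + shift, 2,
                      cv$sd, `*`), 2, cv$mu, `+`)
    colnames(th) <- c("alpha", "beta", "gamma")
    params[[tk]] <- data.frame(participant = factors$participant, th,
                               check.names = FALSE)
    t_ <- rep(seq_len(cfg$trials), times = n)
    pid <- rep(seq_len(n), each = cfg$trials)
    eta <- curve_value(th[pid, 1], th[pid, 2], th[pid, 3], t_)
    y <- round(pmax(0, eta + stats::rnorm(length(eta), 0, cv$sigma)))
    scores[[tk]] <- data.frame(participant = factors$participant[pid],
                               task = tk, trial = t_, correct = as.integer(y))
    etas[[tk]] <- data.frame(participant = factors$participant[pid],
                             task = tk, trial = t_, eta = eta)
  }
  list(scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
       params = params,
       eta = do.call(rbind, c(etas, list(make.row.names = FALSE))))
}

#' Attach error counts to a performance table
#'
#' Expands per-trial correct-press counts into full trial scores by drawing
#' an error rate that declines exponentially across trials (with
#' participant-trial overdispersion on the logit scale) and splitting errors
#' into wrong-key and wrong-order presses.
#'
#' @param cfg a [synth_config()].
#' @param scores output `scores` element of [gen_performance()].
#' @param seed integer seed.
#' @return data frame participant, task, trial, correct, wrong_key,
#'   wrong_order, total, error_rate.
#' @export
gen_errors <- function(cfg, scores, seed = 1L) {
  set.seed(seed + 2L)
  out <- scores
  er <- cfg$error_rate
  rate <- numeric(nrow(out))
  for (tk in cfg$tasks) {
    i <- out$task == tk
    r <- er[[tk]]["end"] + (er[[tk]]["start"] - er[[tk]]["end"]) *
      exp(-0.25 * (out$trial[i] - 1))
    rate[i] <- stats::plogis(stats::qlogis(r) + stats::rnorm(sum(i), 0, 0.6))
  }
  errors <- round(rate / (1 - rate) * out$correct)
  # a trial with zero correct presses can still contain a few stray errors
  errors[out$correct == 0] <- stats::rpois(sum(out$correct == 0), 2)
  wrong_key <- rbinom_int(errors, cfg$wrong_key_frac)
  out$wrong_key <- wrong_key
  out$wrong_order <- errors - wrong_key
  out$total <- out$correct + errors
  out$error_rate <- ifelse(out$total > 0, errors / out$total, NA_real_)
  out
}

rbinom_int <- function(size, prob) {
  as.integer(stats::rbinom(length(size), size, prob))
}

#' Generate a key-press log matching target trial scores exactly
#'
#' Inverse of the scorer: emits, for each trial, an ordered press stream
#' whose pointer-automaton score reproduces the target correct / wrong-key /
#' wrong-order counts exactly. Wrong-key presses use keys outside the
#' sequence alphabet; a wrong-order press hits the in-sequence key one
#' position ahead of the expected one (after which the pointer resumes past
#' it). Error presses are interspersed at random positions. Timestamps fill
#' the 20 s trial roughly uniformly with jitter.
#'
#' @param targets data frame with participant, task, trial, correct,
#'   wrong_key, wrong_order.
#' @param seqs named list of [sequence_spec()] per task.
#' @param seed integer seed.
#' @param trial_ms trial duration in milliseconds (default 20000).
#' @return events data frame: participant, task, trial, press_index, key,
#'   time_ms.
#' @export
gen_keylog <- function(targets, seqs, seed = 1L, trial_ms = 20000) {
  need <- c("participant", "task", "trial", "correct", "wrong_key", "wrong_order")
  miss <- setdiff(need, names(targets))
  if (length(miss)) stop("targets lack column(s): ", paste(miss, collapse = ", "))
  if (any(targets$correct < 0 | targets$wrong_key < 0 | targets$wrong_order < 0))
    stop("target counts must be nonnegative")
  set.seed(seed + 3L)
  res <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    tg <- targets[r, ]
    sq <- seqs[[as.character(tg$task)]]
    if (is.null(sq)) stop("no sequence spec for task ", tg$task)
    if (tg$wrong_order > 0 && length(sq$keys) < 2)
      stop("wrong-order errors impossible with a sequence of fewer than 2 keys")
    n_ev <- tg$correct + tg$wrong_key + tg$wrong_order
    if (n_ev == 0) { res[[r]] <- NULL; next }
    lab <- sample(rep(c("c", "wk", "wo"),
                      c(tg$correct, tg$wrong_key, tg$wrong_order)))
    keys <- character(n_ev)
    off_keys <- paste0("x", 1:4)          # alphabet outside any sequence
    p <- 1L
    for (i in seq_len(n_ev)) {
      if (lab[i] == "c") {
        keys[i] <- sq$keys[p]; p <- (p %% 4L) + 1L
      } else if (lab[i] == "wk") {
        keys[i] <- sample(off_keys, 1L)   # pointer unchanged
      } else {
        j <- (p %% 4L) + 1L               # one position ahead of expected
        keys[i] <- sq$keys[j]
        p <- (j %% 4L) + 1L               # resynchronize past the slip
      }
    }
    tms <- sort(round(stats::runif(n_ev, 0, trial_ms - 1)))
    res[[r]] <- data.frame(participant = tg$participant, task = tg$task,
                           trial = tg$trial, press_index = seq_len(n_ev),
                           key = keys, time_ms = tms)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Generate gaze-change counts with individual change points
#'
#' Counts follow a linear decline that reaches zero at an individual change
#' point `tau_i` and stays at zero afterwards (a hinge), with truncated
#' Gaussian noise, floored at zero and rounded. `tau_i` is logit-scaled on
#' `[1, trials]` around the configured population change point.
#'
#' @param cfg a [synth_config()].
#' @param scores optional trial-score table supplying `total` key presses per
#'   trial (for the gaze-per-press rate); if absent, presses are omitted.
#' @param seed integer seed.
#' @return list with `gaze` (participant, task, trial, gaze_changes,
#'   key_presses) and `truth` (per-task true tau_i and slope level a_i).
#'   Participants in the configured missing fraction are absent entirely.
#' @export
gen_gaze <- function(cfg, scores = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed + 4L)
  n <- cfg$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  n_miss <- round(cfg$missing_gaze * n)
  missing_ids <- if (n_miss > 0) sample(ids, n_miss) else character(0)
  keep <- setdiff(ids, missing_ids)
  out <- list(); truth <- list()
  for (tk in cfg$tasks) {
    gz <- cfg$gaze[[tk]]
    if (gz$tau_mean < 1 || gz$tau_mean > cfg$trials)
      stop("gaze tau_mean outside [1, trials]")
    l <- stats::rnorm(n, stats::qlogis((gz$tau_mean - 1) / (cfg$trials - 1)),
                      gz$tau_logit_sd)
    tau <- 1 + (cfg$trials - 1) * stats::plogis(l)
    a <- stats::rlnorm(n, log(gz$a_mean), gz$a_sdlog)
    t_ <- rep(seq_len(cfg$trials), times = n)
    pid <- rep(seq_len(n), each = cfg$trials)
    mu <- a[pid] * pmax(0, (tau[pid] - t_) / (tau[pid] - 1))
    g <- as.integer(round(pmax(0, mu + stats::rnorm(length(mu), 0, gz$sigma))))
    df <- data.frame(participant = ids[pid], task = tk, trial = t_,
                     gaze_changes = g)
    out[[tk]] <- df[df$participant %in% keep, ]
    truth[[tk]] <- data.frame(participant = ids, tau = tau, a = a)
  }
  gaze <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(scores)) {
    m <- match(interaction(gaze$participant, gaze$task, gaze$trial),
               interaction(scores$participant, scores$task, scores$trial))
    gaze$key_presses <- scores$total[m]
  } else gaze$key_presses <- NA_integer_
  rownames(gaze) <- NULL
  list(gaze = gaze, truth = truth, missing = missing_ids)
}

#' Generate musicality covariates unrelated to ability and performance
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return data frame participant, gold_msi_total, piano_hours.
#' @export
gen_musicality <- function(cfg, seed = 1L) {
  set.seed(seed + 5L)
  n <- cfg$n_participants
  mu <- cfg$musicality
  msi <- round(pmin(126, pmax(18, stats::rnorm(n, mu$msi_mean, mu$msi_sd))))
  has_exp <- stats::runif(n) < mu$exp_frac
  hours <- ifelse(has_exp,
                  pmin(mu$hours_max,
                       round(stats::rlnorm(n, mu$hours_meanlog, mu$hours_sdlog), 1)),
                  0)
  data.frame(participant = sprintf("p%03d", seq_len(n)),
             gold_msi_total = msi, piano_hours = hours)
}

#' Default looped sequences of the two tasks
#' @return named list of [sequence_spec()] objects.
#' @export
default_sequences <- function() {
  list(piano = sequence_spec(c("d4", "a3", "g4", "c3"),
                             c("right ring", "left middle", "right thumb", "left thumb")),
       pad   = sequence_spec(c("b3", "b6", "b1", "b8"),
                             c("right index", "left index", "right index", "left index")))
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage with sub-seeds derived from one root seed and
#' returns all tables a pipeline run consumes, together with the generating
#' truth. With the defaults this is an 86-participant, 2-task, 20-trial
#' study.
#'
#' @param cfg a [synth_config()].
#' @param seed root integer seed (keep below 2^31 - 10).
#' @param keylog if `TRUE` (default) also synthesize the raw key-press event
#'   log that scores back to the trial table.
#' @return list with `battery`, `scores`, `events` (or `NULL`), `gaze`,
#'   `musicality`, `sequences` and `truth` (factors, curve params, gaze
#'   change points, measurement matrices).
#' @export
simulate_study <- function(cfg = synth_config(), seed = 1L, keylog = TRUE) {
  fa <- gen_factors(cfg, seed)
  pf <- gen_performance(cfg, fa$factors, seed)
  scores <- gen_errors(cfg, pf$scores, seed)
  seqs <- default_sequences()[cfg$tasks]
  events <- if (keylog) gen_keylog(scores, seqs, seed) else NULL
  gz <- gen_gaze(cfg, scores, seed)
  mus <- gen_musicality(cfg, seed)
  list(battery = fa$battery, scores = scores, events = events,
       gaze = gz$gaze, musicality = mus, sequences = seqs,
       truth = list(factors = fa$factors, measurement = fa$truth,
                    curve_params = pf$params, eta = pf$eta,
                    gaze = gz$truth, gaze_missing = gz$missing),
       config = cfg, seed = seed)
}

#' Write a synthetic study to CSV files
#'
#' Emits `battery.csv`, `trial_scores.csv`, `events.csv` (if present),
#' `gaze.csv`, `musicality.csv` and `truth.json` into a directory.
#'
#' @param study output of [simulate_study()].
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$battery, file.path(dir, "battery.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study$scores, file.path(dir, "trial_scores.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(study$events))
    utils::write.csv(study$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  utils::write.csv(study$gaze, file.path(dir, "gaze.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study$musicality, file.path(dir, "musicality.csv"),
                   row.names = FALSE)
  truth <- list(
    curve_params = lapply(study$truth$curve_params, function(d)
      as.list(d[setdiff(names(d), "participant")])),
    gaze_tau = lapply(study$truth$gaze, function(d) d$tau),
    seed = study$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Demonstration scenario with a dip-then-plateau association profile
#'
#' A generator configuration whose ability-performance coupling induces, in
#' the large-sample truth, a trial-wise association profile with a strong
#' trial-1 association, the weakest association at trial 2 and a subsequent
#' rise to a plateau: abilities load on both baseline and asymptote while
#' the learning rate is fast (population log rate -0.3) and heterogeneous
#' (SD 1) but ability-independent, so rate variability dilutes the
#' association exactly in the early transition trials. Used to validate
#' shape recovery of [association_profile()].
#'
#' @param n_participants,trials passed to [synth_config()].
#' @return a [synth_config()].
#' @export
association_dip_config <- function(n_participants = 86L, trials = 20L) {
  cp <- default_coupling()
  cp["alpha", ] <- c(0.12, 0.24, 0.27, 0.24)
  cp["beta", ]  <- c(0.14, 0.30, 0.35, 0.30)
  cp["gamma", ] <- 0
  cv <- default_curve_truth()
  for (tk in names(cv)) {
    cv[[tk]]$mu["gamma"] <- -0.3
    cv[[tk]]$sd["gamma"] <- 1.0
  }
  synth_config(n_participants = n_participants, trials = trials,
               coupling = cp, curve = cv)
}

#' Large-sample trial-wise association truth implied by a configuration
#'
#' Computes the per-trial standardized association between noise-free curve
#' values and one latent ability (partialling out the true individual log
#' learning rate) at a large generated sample, i.e. the population profile
#' an estimator of the trial-wise coefficients is trying to recover.
#'
#' @param cfg a [synth_config()].
#' @param factor ability column name (default `"PM"`).
#' @param task task label.
#' @param n sample size of the truth computation (default 20000).
#' @param seed integer seed.
#' @return data frame `trial`, `b_mean` (consumable by
#'   [association_profile()]).
#' @export
true_association_profile <- function(cfg, factor = "PM", task = "piano",
                                     n = 20000L, seed = 990L) {
  cfg$n_participants <- as.integer(n)
  cfg$missing_bs_r <- 0
  fa <- gen_factors(cfg, seed)
  pf <- gen_performance(cfg, fa$factors, seed)
  eta <- pf$eta[pf$eta$task == task, ]
  x <- as.numeric(scale(fa$factors[[factor]]))
  g <- as.numeric(scale(pf$params[[task]]$gamma))
  b <- vapply(seq_len(cfg$trials), function(tt) {
    e <- eta$eta[eta$trial == tt]
    z <- (e - mean(e)) / stats::sd(e)
    unname(stats::coef(stats::lm(z ~ x + g))[2])
  }, numeric(1))
  data.frame(trial = seq_len(cfg$trials), b_mean = b)
}
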