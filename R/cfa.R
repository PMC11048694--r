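#' Specify a confirmatory factor model
#'
#' Defines the loading sparsity pattern (which indicator loads on which
#' factor; an indicator listed under two factors cross-loads) and which
#' factor correlations are fixed to zero. Factors are standardized (unit
#' variance), so all loadings are free and the factor covariance matrix is a
#' correlation matrix.
#'
#' @param factors named list `factor -> character vector of indicators`;
#'   each factor needs at least one indicator and (for identification of a
#'   stand-alone factor) at least three are expected.
#' @param fixed_zero character vector of factor pairs whose correlation is
#'   fixed to 0, written `"A~B"`.
#' @return object of class `"cfa_model"`.
#' @export
cfa_model <- function(factors, fixed_zero = character()) {
  stopifnot(is.list(factors), length(names(factors)) == length(factors))
  for (f in names(factors))
    if (!length(factors[[f]])) stop("factor ", f, " has no indicators")
  for (pz in fixed_zero) {
    ab <- strsplit(pz, "~", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% names(factors)))
      stop("fixed_zero entries must be 'A~B' with known factors: ", pz)
  }
  structure(list(factors = factors, fixed_zero = fixed_zero),
            class = "cfa_model")
}

#' The retained four-factor test-battery model
#'
#' Working memory (digit spans forward/reversed/sequential, reversed Corsi
#' block span), processing speed (coding, symbol search, number connection
#' test, trail-making A, plus a sequential-digit-span cross-loading),
#' psychomotor speed (three clicking-speed conditions) and dexterity (four
#' Purdue Pegboard conditions). All factor correlations are free by
#' default; `constrain_wm = TRUE` fixes the two correlations of working
#' memory with the motor factors to zero.
#'
#' @param constrain_wm fix WM~PM and WM~DX to zero.
#' @return a [cfa_model()].
#' @export
battery_model <- function(constrain_wm = FALSE) {
  cfa_model(
    factors = list(
      WM = c("DSP_F", "DSP_R", "DSP_S", "BS_R"),
      PS = c("C", "SS", "ZVT", "TMT_A", "DSP_S"),
      PM = c("Click_R", "Click_L", "Click_B"),
      DX = c("PP_R", "PP_L", "PP_B", "PP_A")),
    fixed_zero = if (constrain_wm) c("WM~PM", "WM~DX") else character())
}

#' Prepare battery indicators for factor analysis
#'
#' Sign-flips time-based scores (where a larger value means a worse
#' performance) and z-standardizes every column with the sample (n-1) SD on
#' available cases, so that higher always means better and each indicator
#' has mean 0, SD 1.
#'
#' @param battery data frame with a `participant` column and numeric
#'   indicator columns; missing cells allowed.
#' @param time_scored columns measured as times, to be negated before
#'   standardization (default `ZVT`, `TMT_A`).
#' @return numeric matrix (participants x indicators, rownames =
#'   participant ids) with attribute `"flipped"`.
#' @export
prepare_indicators <- function(battery, time_scored = c("ZVT", "TMT_A")) {
  stopifnot(is.data.frame(battery))
  ids <- if ("participant" %in% names(battery))
    as.character(battery$participant) else as.character(seq_len(nrow(battery)))
  num <- battery[setdiff(names(battery), "participant")]
  num <- num[vapply(num, is.numeric, logical(1))]
  x <- as.matrix(num)
  rownames(x) <- ids
  flip <- intersect(time_scored, colnames(x))
  x[, flip] <- -x[, flip]
  for (j in colnames(x)) {
    v <- stats::sd(x[, j], na.rm = TRUE)
    if (!is.finite(v) || v < .Machine$double.eps)
      stop("indicator '", j, "' has zero variance")
    x[, j] <- (x[, j] - mean(x[, j], na.rm = TRUE)) / v
  }
  attr(x, "flipped") <- flip
  x
}

# Assemble Lambda / Phi / Theta from the free-parameter vector.
cfa_unpack <- function(par, layout) {
  L <- layout$L0
  L[layout$lambda_idx] <- par[seq_along(layout$lambda_idx)]
  Phi <- diag(layout$k)
  np <- length(layout$lambda_idx)
  if (length(layout$phi_idx)) {
    Phi[layout$phi_idx] <- par[np + seq_along(layout$phi_idx)]
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  }
  Theta <- exp(par[np + length(layout$phi_idx) + seq_len(layout$p)])
  list(L = L, Phi = Phi, Theta = Theta)
}

cfa_layout <- function(model, indicators) {
  fac <- names(model$factors)
  inds <- unique(unlist(model$factors))
  miss <- setdiff(inds, indicators)
  if (length(miss))
    stop("model indicators absent from data: ", paste(miss, collapse = ", "))
  inds <- intersect(indicators, inds)
  L0 <- matrix(0, length(inds), length(fac), dimnames = list(inds, fac))
  free <- matrix(FALSE, length(inds), length(fac))
  for (f in fac) free[match(model$factors[[f]], inds), match(f, fac)] <- TRUE
  phi_free <- upper.tri(diag(length(fac)))
  for (pz in model$fixed_zero) {
    ab <- match(strsplit(pz, "~", fixed = TRUE)[[1]], fac)
    phi_free[min(ab), max(ab)] <- FALSE
  }
  list(L0 = L0, lambda_idx = which(free), phi_idx = which(phi_free),
       p = length(inds), k = length(fac), inds = inds, fac = fac)
}

# Maximum-likelihood discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p.
cfa_discrepancy <- function(par, layout, S, logdetS) {
  m <- cfa_unpack(par, layout)
  ev <- eigen(m$Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) return(1e10 - min(ev) * 1e10)
  Sigma <- m$L %*% m$Phi %*% t(m$L) + diag(m$Theta, nrow = length(m$Theta))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  logdet + tr - logdetS - layout$p
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` with implied covariance
#' `Sigma = Lambda Phi Lambda' + Theta` over the free loadings, factor
#' correlations and residual variances. With missing cells the sample
#' covariance `S` is computed from pairwise-available cases. Residual
#' variances are bounded below at a small positive floor; solutions hitting
#' it are reported as Heywood cases with a warning.
#'
#' @param data raw battery data frame (passed through
#'   [prepare_indicators()]) or an already standardized indicator matrix.
#' @param model a [cfa_model()]; default [battery_model()].
#' @param n sample size; defaults to `nrow(data)`.
#' @param heywood_floor lower bound for residual variances (default 1e-4).
#' @param time_scored passed to [prepare_indicators()] for raw input.
#' @return object of class `"cfa_fit"` with elements `lambda`, `phi`,
#'   `theta`, `S`, `n`, `F_min`, `fit` (see [fit_indices()]), `vcov`,
#'   `convergence`.
#' @export
fit_cfa <- function(data, model = battery_model(), n = NULL,
                    heywood_floor = 1e-4, time_scored = c("ZVT", "TMT_A")) {
  x <- if (is.data.frame(data)) prepare_indicators(data, time_scored) else as.matrix(data)
  layout <- cfa_layout(model, colnames(x))
  x <- x[, layout$inds, drop = FALSE]
  for (f in layout$fac) {
    obs <- colSums(!is.na(x[, model$factors[[f]], drop = FALSE]))
    if (all(obs == 0)) stop("no observed indicators for factor ", f)
  }
  if (is.null(n)) n <- nrow(x)
  S <- stats::cov(x, use = "pairwise.complete.obs")
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("pairwise sample covariance matrix is not positive definite")
  logdetS <- 2 * sum(log(diag(ch)))
  # residual variances are optimized on the log scale (stable when they
  # approach the Heywood floor)
  start <- c(rep(0.7, length(layout$lambda_idx)),
             rep(0.3, length(layout$phi_idx)),
             rep(log(0.5), layout$p))
  lower <- c(rep(-Inf, length(layout$lambda_idx)),
             rep(-0.995, length(layout$phi_idx)),
             rep(log(heywood_floor), layout$p))
  upper <- c(rep(Inf, length(layout$lambda_idx)),
             rep(0.995, length(layout$phi_idx)),
             rep(Inf, layout$p))
  ctrl <- list(iter.max = 2000, eval.max = 4000)
  opt <- stats::nlminb(start, cfa_discrepancy, layout = layout, S = S,
                       logdetS = logdetS, lower = lower, upper = upper,
                       control = ctrl)
  # one polishing restart from the incumbent
  opt2 <- stats::nlminb(opt$par, cfa_discrepancy, layout = layout, S = S,
                        logdetS = logdetS, lower = lower, upper = upper,
                        control = ctrl)
  if (opt2$objective <= opt$objective) opt <- opt2
  grad <- num_grad(function(p) cfa_discrepancy(p, layout, S, logdetS), opt$par)
  active <- opt$par <= lower + 1e-10 | opt$par >= upper - 1e-10
  gnorm <- sqrt(sum(grad[!active]^2))
  converged <- opt$convergence == 0 || gnorm < 1e-4
  if (!converged)
    warning("CFA did not fully converge (nlminb code ", opt$convergence,
            ", free-gradient norm ", signif(gnorm, 3),
            "); best iterate returned")
  m <- cfa_unpack(opt$par, layout)
  heywood <- which(m$Theta <= heywood_floor * 1.001)
  if (length(heywood))
    warning("Heywood case: residual variance bounded at the floor for ",
            paste(layout$inds[heywood], collapse = ", "))
  # orient every factor so its loading sum is positive
  flip <- colSums(m$L) < 0
  if (any(flip)) {
    m$L[, flip] <- -m$L[, flip]
    m$Phi[flip, ] <- -m$Phi[flip, ]
    m$Phi[, flip] <- -m$Phi[, flip]
    diag(m$Phi) <- 1
  }
  dimnames(m$Phi) <- list(layout$fac, layout$fac)
  names(m$Theta) <- layout$inds
  H <- num_hessian(function(p) (n - 1) / 2 *
                     cfa_discrepancy(p, layout, S, logdetS), opt$par)
  V <- tryCatch(solve(H), error = function(e) matrix(NA, length(opt$par),
                                                     length(opt$par)))
  obj <- structure(list(lambda = m$L, phi = m$Phi, theta = m$Theta,
                        S = S, n = n, F_min = opt$objective,
                        layout = layout, model = model, par = opt$par,
                        vcov = V, grad_norm = gnorm, converged = converged,
                        heywood = layout$inds[heywood],
                        data = x),
                   class = "cfa_fit")
  obj$fit <- fit_indices(obj)
  obj
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- numeric(p); ei[i] <- h
    ej <- numeric(p); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h * h)
  }
  H
}

#' Fit indices of a confirmatory factor model
#'
#' Computes the chi-square of the fitted and the independence (baseline)
#' model and the derived indices, with the conventional definitions:
#' `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_B - df_B, chi2_M - df_M, 0)`,
#' `TLI = ((chi2_B/df_B) - (chi2_M/df_M)) / ((chi2_B/df_B) - 1)`,
#' `IFI = (chi2_B - chi2_M) / (chi2_B - df_M)`,
#' `RMSEA = sqrt(max(chi2_M - df_M, 0) / (df_M (n-1)))`, and SRMR as the
#' root-mean-square standardized residual covariance. `chi2 = (n-1) F` at
#' the optimum. CFI/TLI/IFI are clipped to [0, 1].
#'
#' @param object a `"cfa_fit"`.
#' @param S sample covariance (defaults to the fit's).
#' @param n sample size (defaults to the fit's).
#' @return list of class `"fit_indices"`: `chi2_model`, `df_model`,
#'   `chi2_baseline`, `df_baseline`, `CFI`, `TLI`, `IFI`, `RMSEA`, `SRMR`.
#' @export
fit_indices <- function(object, S = object$S, n = object$n) {
  stopifnot(inherits(object, "cfa_fit"))
  p <- object$layout$p
  df_b <- p * (p - 1) / 2
  if (df_b <= 0) stop("baseline degrees of freedom must be positive")
  nfree <- length(object$par)
  df_m <- p * (p + 1) / 2 - nfree
  chi2_m <- (n - 1) * object$F_min
  F_b <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  chi2_b <- (n - 1) * F_b
  Sigma <- object$lambda %*% object$phi %*% t(object$lambda) +
    diag(object$theta, nrow = length(object$theta))
  d <- sqrt(diag(S))
  res <- (S - Sigma) / tcrossprod(d)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  clip01 <- function(z) min(max(z, 0), 1)
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else clip01(1 - num / den)
  tli <- clip01(((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1))
  ifi <- clip01((chi2_b - chi2_m) / (chi2_b - df_m))
  rmsea <- if (df_m > 0) sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1))) else 0
  structure(list(chi2_model = chi2_m, df_model = df_m,
                 chi2_baseline = chi2_b, df_baseline = df_b,
                 CFI = cfi, TLI = tli, IFI = ifi, RMSEA = rmsea, SRMR = srmr),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f; baseline chi2(%d) = %.2f\n",
              x$df_model, x$chi2_model, x$df_baseline, x$chi2_baseline))
  cat(sprintf("CFI = %.3f, TLI = %.3f, IFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$CFI, x$TLI, x$IFI, x$RMSEA, x$SRMR))
  invisible(x)
}

#' Regression-method factor scores
#'
#' Scores each participant as `Fhat = Phi Lambda' Sigma^-1 x`, using the
#' submatrix of the implied covariance restricted to that participant's
#' observed indicators (available-case scoring). A factor's score is set
#' missing when none of its indicators were observed.
#'
#' @param fit a `"cfa_fit"`.
#' @param data optional new battery data frame or standardized matrix;
#'   defaults to the estimation sample.
#' @return data frame: participant plus one standardized score column per
#'   factor; participants scored from a reduced indicator set are listed in
#'   `attr(x, "partial")`.
#' @export
factor_scores <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  x <- if (is.null(data)) fit$data else if (is.data.frame(data))
    prepare_indicators(data) else as.matrix(data)
  x <- x[, fit$layout$inds, drop = FALSE]
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  Sigma <- fit$lambda %*% fit$phi %*% t(fit$lambda) +
    diag(fit$theta, nrow = length(fit$theta))
  A_full <- fit$phi %*% t(fit$lambda) %*% solve(Sigma)
  k <- fit$layout$k
  out <- matrix(NA_real_, nrow(x), k, dimnames = list(rownames(x), fit$layout$fac))
  partial <- character()
  for (i in seq_len(nrow(x))) {
    obs <- which(!is.na(x[i, ]))
    if (!length(obs)) next
    if (length(obs) == ncol(x)) {
      out[i, ] <- A_full %*% x[i, ]
    } else {
      partial <- c(partial, rownames(x)[i])
      A <- fit$phi %*% t(fit$lambda[obs, , drop = FALSE]) %*%
        solve(Sigma[obs, obs, drop = FALSE])
      out[i, ] <- A %*% x[i, obs]
    }
    for (f in seq_len(k)) {
      f_inds <- match(fit$model$factors[[fit$layout$fac[f]]], colnames(x))
      if (!any(f_inds %in% obs)) out[i, f] <- NA_real_
    }
  }
  res <- data.frame(participant = rownames(x), out, check.names = FALSE,
                    row.names = NULL)
  attr(res, "partial") <- unique(partial)
  res
}

#' @export
predict.cfa_fit <- function(object, newdata = NULL, ...) {
  factor_scores(object, newdata)
}

#' Estimated factor correlations with standard errors
#'
#' @param fit a `"cfa_fit"`.
#' @return list with `phi` (correlation matrix; entries fixed to zero by the
#'   model spec stay zero) and `se` (delta-method standard errors from the
#'   observed information; `NA` for fixed entries).
#' @export
factor_correlations <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  se <- matrix(NA_real_, fit$layout$k, fit$layout$k,
               dimnames = dimnames(fit$phi))
  np <- length(fit$layout$lambda_idx)
  if (length(fit$layout$phi_idx)) {
    v <- diag(fit$vcov)[np + seq_along(fit$layout$phi_idx)]
    se_vals <- sqrt(pmax(v, 0))
    tmp <- matrix(NA_real_, fit$layout$k, fit$layout$k)
    tmp[fit$layout$phi_idx] <- se_vals
    tmp[lower.tri(tmp)] <- t(tmp)[lower.tri(tmp)]
    se <- tmp
    dimnames(se) <- dimnames(fit$phi)
  }
  list(phi = fit$phi, se = se)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("Confirmatory factor analysis (ML), %d indicators, %d factors, n = %d\n",
              x$layout$p, x$layout$k, x$n))
  cat(sprintf("  discrepancy F = %.4f, free parameters = %d%s\n",
              x$F_min, length(x$par),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$fit)
  invisible(x)
}

#' @export
summary.cfa_fit <- function(object, ...) {
  res <- list(loadings = object$lambda, phi = factor_correlations(object),
              theta = object$theta, fit = object$fit, n = object$n,
              heywood = object$heywood, converged = object$converged)
  class(res) <- "summary.cfa_fit"
  res
}

#' @export
print.summary.cfa_fit <- function(x, ...) {
  cat("Standardized loadings:\n")
  print(round(x$loadings, 3))
  cat("\nFactor correlations (SE):\n")
  print(round(x$phi$phi, 3))
  cat("\nResidual variances:\n")
  print(round(x$theta, 3))
  cat("\n")
  print(x$fit)
  if (length(x$heywood))
    cat("Heywood-bounded indicators:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cfa_fit <- function(object, ...) object$par

#' @export
fitted.cfa_fit <- function(object, ...) {
  object$lambda %*% object$phi %*% t(object$lambda) +
    diag(object$theta, nrow = length(object$theta))
}
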