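#' MCMC sampler configuration
#'
#' The headline configuration is 4 chains of 5000 iterations each with a
#' 2000-iteration warm-up. [reduced_config()] is a desk-scale profile
#' (2 chains x 1500 iterations, 500 warm-up) used for tests and simulation
#' studies; [mcmc_config()] with defaults is the full profile.
#'
#' @param chains number of chains.
#' @param iter total iterations per chain, warm-up included.
#' @param warmup warm-up (burn-in) iterations discarded per chain; the JAGS
#'   adaptation phase runs inside this budget.
#' @param thin thinning interval.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4L, iter = 5000L, warmup = 2000L, thin = 1L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
reduced_config <- function(chains = 2L, iter = 1500L, warmup = 500L, thin = 1L) {
  mcmc_config(chains, iter, warmup, thin)
}

# Split potential-scale-reduction factor, computed on post-warmup draws by
# halving every chain. Works for any chain count >= 1.
split_rhat <- function(samples) {
  x <- lapply(samples, as.matrix)
  halves <- list()
  for (ch in x) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W < .Machine$double.eps] <- 1  # constant (e.g. fixed) quantities
  names(rhat) <- colnames(halves[[1]])
  rhat
}

# Run a JAGS model and return stacked post-warmup draws plus diagnostics.
# Chain RNGs are seeded deterministically from `seed`.
run_jags <- function(model_string, data, monitor, config, seed = 1L,
                     inits = NULL) {
  if (!"glm" %in% rjags::list.modules())
    try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  adapt <- min(500L, config$warmup)
  burn <- config$warmup - adapt
  init_list <- lapply(seq_len(config$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed + 1000L * ch))
    if (is.function(inits)) c(ini, inits(ch)) else if (is.list(inits))
      c(ini, inits) else ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = init_list, n.chains = config$chains,
                          n.adapt = adapt, quiet = TRUE)
  if (burn > 0) update(jm, burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitor,
                                 n.iter = config$iter - config$warmup,
                                 thin = config$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(samples, as.matrix))
  rhat <- split_rhat(samples)
  list(samples = samples, draws = draws, rhat = rhat, config = config,
       seed = seed,
       sampler = "JAGS (Gibbs/slice); divergent transitions not applicable",
       divergences = 0L)
}

# Posterior mean / sd / central credible interval table for draw columns.
post_summary <- function(draws, prob = 0.95) {
  a <- (1 - prob) / 2
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = apply(draws, 2, stats::quantile, probs = a),
             upper = apply(draws, 2, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

warn_rhat <- function(rhat, what, limit = 1.01) {
  bad <- rhat[is.finite(rhat) & rhat > limit]
  if (length(bad))
    warning(what, ": Rhat > ", limit, " for ",
            paste0(names(bad)[seq_len(min(5, length(bad)))], collapse = ", "),
            if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5),
            "; consider more iterations", call. = FALSE)
  invisible(length(bad))
}
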