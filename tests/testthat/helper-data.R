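# Small fixtures built in code.

tiny_config <- function(n = 20L, trials = 12L, tasks = c("piano", "pad")) {
  synth_config(n_participants = n, trials = trials, tasks = tasks)
}

# A small noise-free score table following known curve parameters exactly.
noiseless_scores <- function(n = 12L, trials = 10L,
                             alpha = 15, beta = 40, gamma = -1) {
  pid <- rep(seq_len(n), each = trials)
  t_ <- rep(seq_len(trials), times = n)
  data.frame(participant = sprintf("p%02d", pid), task = "piano", trial = t_,
             correct = curve_value(alpha, beta, gamma, t_))
}

test_config <- function() reduced_config()

# cheap single-chain profile for replication studies inside tests
quick_config <- function() mcmc_config(chains = 1L, iter = 1700L, warmup = 500L)
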