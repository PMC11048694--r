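test_that("a perfect looped performance scores all presses correct", {
  s <- sequence_spec(c("k1", "k2", "k3", "k4"))
  sc <- score_trial(rep(c("k1", "k2", "k3", "k4"), 3), s)
  expect_equal(sc$correct, 12)
  expect_equal(sc$wrong_key, 0)
  expect_equal(sc$wrong_order, 0)
  expect_equal(sc$error_rate, 0)
})

test_that("an empty trial yields zero counts and an undefined error rate", {
  s <- sequence_spec(c("k1", "k2", "k3", "k4"))
  sc <- score_trial(data.frame(key = character(0)), s)
  expect_equal(sc$correct, 0)
  expect_equal(sc$total, 0)
  expect_true(is.na(sc$error_rate))
})

test_that("error classification and pointer resynchronization follow the oracle", {
  s <- sequence_spec(c("k1", "k2", "k3", "k4"))
  # value frozen from the brute-force pointer oracle: k1 correct, k9 wrong
  # key, k2 correct, k4 wrong order (resync past k4), k1 correct
  sc <- score_trial(c("k1", "k9", "k2", "k4", "k1"), s)
  expect_equal(sc$correct, 3)
  expect_equal(sc$wrong_key, 1)
  expect_equal(sc$wrong_order, 1)
  orc <- oracle_score_keys(c("k1", "k9", "k2", "k4", "k1"), s$keys)
  expect_equal(sc$correct, orc$correct)
  expect_equal(sc$wrong_key, orc$wrong_key)
  expect_equal(sc$wrong_order, orc$wrong_order)
})

test_that("scorer matches the brute-force oracle on random logs and conserves counts", {
  s <- sequence_spec(c("a", "b", "c", "d"))
  alphabet <- c(s$keys, "e", "f", "g", "h")
  set.seed(11)
  for (rep in 1:300) {
    keys <- sample(alphabet, sample(0:60, 1), replace = TRUE)
    sc <- score_trial(data.frame(key = keys), s)
    orc <- oracle_score_keys(keys, s$keys)
    expect_equal(c(sc$correct, sc$wrong_key, sc$wrong_order),
                 c(orc$correct, orc$wrong_key, orc$wrong_order))
    expect_equal(sc$correct + sc$wrong_key + sc$wrong_order, sc$total)
  }
})

test_that("appending the expected key increments correct and leaves errors unchanged", {
  s <- sequence_spec(c("a", "b", "c", "d"))
  set.seed(12)
  for (rep in 1:50) {
    keys <- sample(c(s$keys, "x", "y"), sample(1:30, 1), replace = TRUE)
    before <- score_trial(data.frame(key = keys), s)
    # replay to find the pointer, then append the expected key
    orc <- oracle_score_keys(keys, s$keys)
    p <- 1
    for (k in keys) {
      if (k %in% s$keys) {
        if (k == s$keys[p]) p <- p %% 4 + 1 else p <- which(s$keys == k) %% 4 + 1
      }
    }
    after <- score_trial(data.frame(key = c(keys, s$keys[p])), s)
    expect_equal(after$correct, before$correct + 1)
    expect_equal(after$wrong_key, before$wrong_key)
    expect_equal(after$wrong_order, before$wrong_order)
  }
})

test_that("invalid sequences and unrepresentable keys are rejected", {
  expect_error(sequence_spec(c("a", "b", "c")), "exactly 4")
  expect_error(sequence_spec(c("a", "b", "c", "a")), "unique")
  s <- sequence_spec(c("a", "b", "c", "d"))
  expect_error(score_trial(data.frame(key = c("a", NA, "b")), s),
               "unrepresentable key")
  expect_error(
    score_trial(data.frame(key = c("a", "b"), trial = c(1, 2)), s),
    "share one trial")
})

test_that("score_dataset scores every observed cell and reports missing trials", {
  s <- list(piano = sequence_spec(c("a", "b", "c", "d")))
  ev <- expand.grid(press_index = 1:8, trial = 1:2,
                    participant = c("p1", "p2"),
                    stringsAsFactors = FALSE)
  ev$task <- "piano"
  ev$key <- rep(c("a", "b", "c", "d"), 8)
  sc <- score_dataset(ev, s, trials = 1:2)
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$error_rate == 0))
  expect_true(all(sc$correct == 8))

  # drop trial 2 of p2 entirely: 3 rows remain and the gap is reported
  ev2 <- ev[!(ev$participant == "p2" & ev$trial == 2), ]
  expect_warning(sc2 <- score_dataset(ev2, s, trials = 1:2),
                 "missing from the log")
  expect_equal(nrow(sc2), 3)
  mt <- attr(sc2, "missing_trials")
  expect_equal(mt$participant, "p2")
  expect_equal(mt$trial, 2)
})

test_that("duplicate press indices are rejected", {
  s <- list(piano = sequence_spec(c("a", "b", "c", "d")))
  ev <- data.frame(participant = "p1", task = "piano", trial = 1,
                   press_index = c(1, 1), key = c("a", "b"))
  expect_error(score_dataset(ev, s), "duplicate press")
})

test_that("generated key logs round-trip through the scorer exactly", {
  set.seed(21)
  seqs <- default_sequences()
  targets <- data.frame(
    participant = sprintf("p%02d", 1:60),
    task = sample(c("piano", "pad"), 60, replace = TRUE),
    trial = sample(1:20, 60, replace = TRUE),
    correct = sample(0:50, 60, replace = TRUE),
    wrong_key = sample(0:6, 60, replace = TRUE),
    wrong_order = sample(0:6, 60, replace = TRUE))
  ev <- gen_keylog(targets, seqs, seed = 5)
  sc <- suppressWarnings(score_dataset(ev, seqs))
  m <- merge(targets, sc, by = c("participant", "task", "trial"),
             suffixes = c("_target", ""))
  nonzero <- m$correct_target + m$wrong_key_target + m$wrong_order_target > 0
  expect_equal(sum(nonzero), nrow(sc))
  expect_equal(m$correct[nonzero], m$correct_target[nonzero])
  expect_equal(m$wrong_key[nonzero], m$wrong_key_target[nonzero])
  expect_equal(m$wrong_order[nonzero], m$wrong_order_target[nonzero])
})
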