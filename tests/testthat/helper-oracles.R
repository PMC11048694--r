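# Independent brute-force oracles, written before and apart from the package
# implementations they check.

# Pointer-automaton scorer, transliterated rule by rule: walk the looped
# 4-key sequence; a matching press advances the pointer, an out-of-alphabet
# press leaves it, an in-sequence mismatch re-synchronizes to just after the
# pressed key.
oracle_score_keys <- function(presses, sequence) {
  expected_pos <- 1
  n_correct <- 0
  n_wrong_key <- 0
  n_wrong_order <- 0
  for (press in presses) {
    if (!(press %in% sequence)) {
      n_wrong_key <- n_wrong_key + 1
    } else if (identical(press, sequence[expected_pos])) {
      n_correct <- n_correct + 1
      expected_pos <- expected_pos + 1
      if (expected_pos > length(sequence)) expected_pos <- 1
    } else {
      n_wrong_order <- n_wrong_order + 1
      hit <- which(sequence == press)
      expected_pos <- hit + 1
      if (expected_pos > length(sequence)) expected_pos <- 1
    }
  }
  list(correct = n_correct, wrong_key = n_wrong_key,
       wrong_order = n_wrong_order)
}

# Fit-index formulas coded directly from their textbook definitions.
oracle_fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n) {
  cfi <- 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)
  tli <- ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  ifi <- (chi2_b - chi2_m) / (chi2_b - df_m)
  rmsea <- sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1)))
  list(CFI = min(max(cfi, 0), 1), TLI = min(max(tli, 0), 1),
       IFI = min(max(ifi, 0), 1), RMSEA = rmsea)
}

# ML discrepancy evaluated directly (no reuse of package internals).
oracle_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(determinant(Sigma)$modulus) + sum(diag(S %*% solve(Sigma))) -
    as.numeric(determinant(S)$modulus) - p
}
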