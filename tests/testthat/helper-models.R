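# Shared fixtures: small reference models and a brute-force SRC oracle.

ref_case_i <- function() {
  renewal_model(refractory_params(2, 2), exp_excitation(0.05))
}

ref_case_iii <- function() {
  renewal_model(refractory_params(2, 2),
                two_exp_mix_excitation(0.6, 0.025, 0.005))
}

# Brute-force serial correlation: explicit loop over lagged pairs with
# global population moments, independent of the vectorized implementation.
src_oracle <- function(x, lag) {
  m <- mean(x)
  v <- mean((x - m)^2)
  acc <- 0
  for (k in seq_len(length(x) - lag)) {
    acc <- acc + (x[k + lag] - m) * (x[k] - m)
  }
  (acc / (length(x) - lag)) / v
}

# Kolmogorov-Smirnov critical value at level alpha for sample size n
ks_crit <- function(n, alpha = 0.01) {
  sqrt(-log(alpha / 2) / (2 * n))
}
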