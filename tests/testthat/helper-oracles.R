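# Independent brute-force oracle for the instability proportion: fraction
# of a uniform grid of growth rates under which the burden decreases.
brute_instability <- function(P, r_max = 3.5, n = 1e6) {
  r <- seq(0, r_max, length.out = n)
  mean(r * P * (1 - P) < P)
}

# Closed-form stationary distribution of the two-state chain, used as the
# oracle against the eigen-solver.
stationary_oracle <- function(p_su, p_us) {
  c(S = p_us, U = p_su) / (p_su + p_us)
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# 0/1 sample sequence.
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- n %/% n_batches
  m <- matrix(x[seq_len(bs * n_batches)], nrow = bs)
  stats::sd(colMeans(m)) / sqrt(n_batches)
}

# Small homogeneous grid with every covariate constant.
homogeneous_grid <- function(height, width, value = 1, states = NULL) {
  m <- matrix(value, height, width)
  plaque_grid(m, m, m, m, states = states)
}
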