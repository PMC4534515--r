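# Shared fixtures: all data built in code at test time.

# Small moderately-separable dataset + CV objective.
tiny_dataset <- function(n_per_class = 50L, n_bits = 64L, effect = 0.4,
                         seed = 42L) {
  generate_dataset(
    fingerprint_spec(n_bits, 0.1, max(4L, n_bits %/% 8L), effect),
    dataset_shape(n_per_class, n_per_class), seed = seed)
}

# Noise-free linearly separable dataset (the spec's separability regime).
separable_dataset <- function(n_per_class = 100L, seed = 1L) {
  generate_dataset(fingerprint_spec(64L, 0, 10L, 1),
                   dataset_shape(n_per_class, n_per_class), seed = seed)
}

# Independent brute-force GP oracle: dense solve with base::solve, no
# Cholesky, sharing only the kernel definition.
gp_oracle_predict <- function(points, values, kernel, space, query) {
  norm1 <- function(p) c(
    (p$log10_C - space$log10_C_min) / (space$log10_C_max - space$log10_C_min),
    (p$log10_gamma - space$log10_gamma_min) /
      (space$log10_gamma_max - space$log10_gamma_min))
  U <- t(vapply(points, norm1, numeric(2)))
  q <- norm1(query)
  kf <- function(u, v) kernel$signal_variance *
    exp(-sum((u - v)^2 / (2 * kernel$length_scales^2)))
  n <- nrow(U)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- kf(U[i, ], U[j, ])
  K <- K + diag(kernel$noise_variance + kernel$jitter, n)
  ks <- vapply(seq_len(n), function(i) kf(q, U[i, ]), numeric(1))
  pm <- mean(values)
  Kinv <- solve(K)
  mu <- pm + sum(ks * (Kinv %*% (values - pm)))
  var <- kernel$signal_variance - as.numeric(t(ks) %*% Kinv %*% ks)
  list(mean = mu, sd = sqrt(max(var, 0)))
}

# Deterministic trace built directly from values (for curve/summary tests).
trace_from_values <- function(values, name = "fixed") {
  m <- cbind(seq_along(values) * 0.1, seq_along(values) * -0.1)
  svmtune:::new_trace(m, values, name, NULL, length(values))
}
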