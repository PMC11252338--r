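# Builders for small deterministic datasets used across the test files.

# Exactly linear response: y = 1 + 2*a - 0.5*b, no noise.
toy_exact_dataset <- function(n = 12, n_test = 3) {
  set.seed(42)
  df <- data.frame(
    label = sprintf("c%02d", seq_len(n)),
    subset = rep(c("train", "test"), c(n - n_test, n_test)),
    a = runif(n, -2, 2),
    b = runif(n, 0, 10),
    pic50_obs = NA_real_
  )
  df$pic50_obs <- 1 + 2 * df$a - 0.5 * df$b
  qsar_dataset(df, c("a", "b"))
}

# Orthogonal centered descriptors (balanced +/-1 design), noisy response.
toy_orthogonal_dataset <- function() {
  df <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  df <- rbind(df, df)  # 16 rows, still orthogonal and centered
  set.seed(7)
  df$label <- sprintf("o%02d", seq_len(nrow(df)))
  df$subset <- "train"
  df$pic50_obs <- 4 + 0.5 * df$a + rnorm(nrow(df), 0, 0.3)
  qsar_dataset(df, c("a", "b", "c"))
}

# Study-structure synthetic data with known generating coefficients.
toy_synthetic <- function(seed = 1, ...) {
  simulate_qsar(generator_config(seed = seed, ...))
}

published_coefs <- c(-10.12, 1.64, -5.69e-05, 1.48, -1.37, -0.36)
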