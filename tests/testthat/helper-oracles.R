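# Independent oracles used across tests. Each is a deliberately naive
# implementation (explicit double loops / exhaustive enumeration) kept
# separate from the package's vectorized code paths.

# GIP kernel by explicit double loop over profile rows.
oracle_gip <- function(profiles, gamma_prime) {
  n <- nrow(profiles)
  norms <- numeric(n)
  for (i in seq_len(n)) norms[i] <- sum(profiles[i, ]^2)
  bw <- gamma_prime / mean(norms)
  K <- matrix(NA_real_, n, n)
  for (x in seq_len(n)) for (y in seq_len(n))
    K[x, y] <- exp(-bw * sum((profiles[x, ] - profiles[y, ])^2))
  K
}

# Cohesiveness by explicit edge enumeration.
oracle_cohesiveness <- function(members, W, penalty) {
  n <- nrow(W)
  c_in <- 0; c_bound <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    w <- W[i, j]
    if (w == 0) next
    ini <- i %in% members; inj <- j %in% members
    if (ini && inj) c_in <- c_in + w
    else if (ini || inj) c_bound <- c_bound + w
  }
  denom <- c_in + c_bound + penalty * length(members)
  if (denom == 0) 0 else c_in / denom
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Random symmetric nonnegative integer weight matrix with zero diagonal.
random_weight_matrix <- function(n, p_edge = 0.5, max_w = 4) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- sample.int(max_w, 1)
  }
  W
}

# A small, fast synthetic world for end-to-end property tests.
small_fixture <- function(seed = 42L) {
  generate_synthetic(synth_spec(
    n_drugs = 40, n_diseases = 24, n_modules = 3,
    p_in = 0.4, p_out = 0.03, fp_bits = 32, fp_flip_noise = 0.05,
    ds_in = 0.6, ds_out = 0.1, ds_jitter = 0.05, seed = seed))
}

# A cheap config for end-to-end tests (smaller networks, fewer epochs).
fast_config <- function(...) {
  run_config(ae_hidden_dim = 16L, ae_epochs = 60L, fc_width = 32L,
             refiner_epochs = 25L, n_trees = 50L, cv_folds = 5L, ...)
}
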