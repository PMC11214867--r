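# Temperature at which kT = 1 kcal/mol ("natural units" fixtures)
T_NATURAL <- 1 / 0.0019872041

# Short-but-honest sampling budget for module tests
quick_run <- function(seed, n_steps = 5000, windows = NULL) {
  run_spec(timestep_fs = 4, friction = 1, n_steps = n_steps,
           exchange_interval = 250, sample_interval = 50,
           anneal_steps = 1100, seed = seed)
}

# Two-state 1D Gaussian reweighting problem: state 1 has spring k1, state 2
# spring k2, kT = 1; the reduced bias of a sample x at state k is k x^2 / 2.
# Exact free energy difference: 0.5 * log(k2 / k1).
gaussian_two_state_samples <- function(n, seed, k1 = 1, k2 = 4) {
  set.seed(seed)
  x1 <- rnorm(n, 0, 1 / sqrt(k1))
  x2 <- rnorm(n, 0, 1 / sqrt(k2))
  xall <- c(x1, x2)
  states <- lapply(c(0, 0.5), alchemical_state)
  ps <- perturbation_samples(list(x1, x2), states, kT = 1)
  ps$bias_matrix <- rbind(0.5 * k1 * xall^2, 0.5 * k2 * xall^2)
  ps
}

# Random perturbation network with known truth (tibble of edges + truth)
random_network_edges <- function(n_nodes, seed, sigma_lo = 0.2, sigma_hi = 1) {
  set.seed(seed)
  g_true <- rnorm(n_nodes, 0, 2)
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- sort(sample.int(nrow(pairs), max(n_nodes, ceiling(nrow(pairs) * 0.7))))
  pk <- pairs[keep, , drop = FALSE]
  ids <- sprintf("L%02d", seq_len(n_nodes))
  edges <- tibble::tibble(
    ligand_i = ids[pk[, 1]], ligand_j = ids[pk[, 2]],
    ddg_calc = g_true[pk[, 2]] - g_true[pk[, 1]] + rnorm(nrow(pk), 0, 0.3),
    sigma_calc = runif(nrow(pk), sigma_lo, sigma_hi),
    ddg_exp = g_true[pk[, 2]] - g_true[pk[, 1]])
  list(edges = edges, truth = stats::setNames(g_true, ids))
}
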