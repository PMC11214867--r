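triangle_net <- function(ddg, sigma = rep(0.5, 3)) {
  perturbation_network(tibble::tibble(
    ligand_i = c("A", "B", "A"), ligand_j = c("B", "C", "C"),
    ddg_calc = ddg, sigma_calc = sigma))
}

test_that("connectivity reports components largest-first with singletons", {
  full <- make_edge_network(4, 1, 0, seed = 1)
  expect_length(check_connectivity(full), 1)
  two <- perturbation_network(tibble::tibble(
    ligand_i = c("A", "C"), ligand_j = c("B", "D"),
    ddg_calc = c(1, 2), sigma_calc = c(0.5, 0.5)))
  expect_length(check_connectivity(two), 2)
  empty <- perturbation_network(
    tibble::tibble(ligand_i = character(), ligand_j = character(),
                   ddg_calc = numeric(), sigma_calc = numeric()),
    nodes = tibble::tibble(ligand = c("A", "B", "C")))
  expect_equal(lengths(check_connectivity(empty)), c(1, 1, 1))
})

test_that("single-edge network matches the hand-worked Laplacian solution", {
  net <- perturbation_network(tibble::tibble(
    ligand_i = "A", ligand_j = "B", ddg_calc = 1.0, sigma_calc = 0.5))
  est <- mle_absolute_dg(net)
  est <- est[order(est$ligand), ]
  expect_equal(est$dg, c(-0.5, 0.5))
  expect_equal(est$sigma, c(0.25, 0.25))
  # sd of the difference reproduces the edge sigma:
  # var(gB - gA) = L+_AA + L+_BB - 2 L+_AB = 1/16 + 1/16 + 2/16 = 1/4
  expect_equal(sqrt(0.25^2 + 0.25^2 + 2 * 1 / 16), 0.5)
})

test_that("consistent cycles are recovered exactly; inconsistent ones split evenly", {
  # noise-free triangle: exact recovery up to the gauge constant
  net <- triangle_net(ddg = c(1, 2, 3))     # g = (0, 1, 3) - mean
  est <- mle_absolute_dg(net)
  g <- setNames(est$dg, est$ligand)
  expect_equal(g[["B"]] - g[["A"]], 1, tolerance = 1e-10)
  expect_equal(g[["C"]] - g[["B"]], 2, tolerance = 1e-10)
  expect_equal(sum(est$dg), 0, tolerance = 1e-10)
  # cycle closure c spreads evenly: residual c/3 per edge for equal sigmas
  cc <- 0.9
  net2 <- triangle_net(ddg = c(1, 2, 3 + cc))
  est2 <- mle_absolute_dg(net2)
  g2 <- setNames(est2$dg, est2$ligand)
  resid <- c(1 - (g2[["B"]] - g2[["A"]]),
             2 - (g2[["C"]] - g2[["B"]]),
             (3 + cc) - (g2[["C"]] - g2[["A"]]))
  expect_equal(abs(unname(resid)), rep(cc / 3, 3), tolerance = 1e-10)
})

test_that("maximum-likelihood estimates equal generic weighted least squares", {
  for (seed in 1:25) {
    n_nodes <- sample(3:8, 1)
    rn <- random_network_edges(n_nodes, seed = 1000 + seed)
    net <- perturbation_network(rn$edges)
    est <- mle_absolute_dg(net)
    oracle <- network_ls_oracle(rn$edges)
    expect_lt(max(abs(setNames(est$dg, est$ligand)[names(oracle)] - oracle)), 1e-8)
  }
})

test_that("normal equations hold at the optimum", {
  rn <- random_network_edges(6, seed = 77)
  net <- perturbation_network(rn$edges)
  est <- mle_absolute_dg(net)
  g <- setNames(est$dg, est$ligand)
  # gradient of the weighted objective wrt each node must vanish
  grad <- setNames(rep(0, length(g)), names(g))
  for (r in seq_len(nrow(rn$edges))) {
    e <- rn$edges[r, ]
    res <- (e$ddg_calc - (g[[e$ligand_j]] - g[[e$ligand_i]])) / e$sigma_calc^2
    grad[[e$ligand_i]] <- grad[[e$ligand_i]] + res
    grad[[e$ligand_j]] <- grad[[e$ligand_j]] - res
  }
  expect_lt(max(abs(grad)), 1e-8)
})

test_that("components are estimated separately and never mixed", {
  e <- tibble::tibble(
    ligand_i = c("A", "B", "X"), ligand_j = c("B", "C", "Y"),
    ddg_calc = c(1, 1, 2), sigma_calc = rep(0.5, 3))
  net <- perturbation_network(e, nodes = tibble::tibble(
    ligand = c("A", "B", "C", "X", "Y", "Z"), dg_exp = c(-10, -9, -8, -7, -6, NA)))
  est <- mle_absolute_dg(net)
  expect_equal(sort(unique(est$component)), 1:2)
  # zero-mean gauge within each component
  for (ci in 1:2) expect_equal(sum(est$dg[est$component == ci]), 0, tolerance = 1e-10)
  # singleton Z gets no estimate
  expect_false("Z" %in% est$ligand)
  zero_sig <- perturbation_network(tibble::tibble(
    ligand_i = "A", ligand_j = "B", ddg_calc = 1, sigma_calc = 1))
  zero_sig$edges$sigma_calc <- 0
  expect_error(mle_absolute_dg(zero_sig), class = "atmkit_invalid_parameter")
})

test_that("experiment anchoring shifts components onto the experimental mean", {
  net <- perturbation_network(
    tibble::tibble(ligand_i = "A", ligand_j = "B", ddg_calc = 1.0, sigma_calc = 0.5),
    nodes = tibble::tibble(ligand = c("A", "B"), dg_exp = c(-10, -9)))
  est <- center_to_experiment(mle_absolute_dg(net), net)
  est <- est[order(est$ligand), ]
  expect_equal(est$dg, c(-10, -9))
  expect_equal(est$sigma, c(0.25, 0.25))   # sigmas unchanged
  # idempotence
  expect_equal(center_to_experiment(est, net)$dg, est$dg)
  # anchoring on a single annotated node matches that node exactly
  net1 <- perturbation_network(
    tibble::tibble(ligand_i = "A", ligand_j = "B", ddg_calc = 1.0, sigma_calc = 0.5),
    nodes = tibble::tibble(ligand = c("A", "B"), dg_exp = c(-10, NA)))
  est1 <- center_to_experiment(mle_absolute_dg(net1), net1)
  expect_equal(est1$dg[est1$ligand == "A"], -10)
  # unanchored component warns and stays put
  net0 <- perturbation_network(
    tibble::tibble(ligand_i = "A", ligand_j = "B", ddg_calc = 1.0, sigma_calc = 0.5))
  expect_warning(out <- center_to_experiment(mle_absolute_dg(net0), net0),
                 "no experimental anchor")
  expect_equal(sort(out$dg), c(-0.5, 0.5))
})

test_that("recovery error shrinks with network size as sigma/sqrt(n-1)", {
  rmse_for <- function(n_nodes, seeds) {
    mean(vapply(seeds, function(s) {
      net <- make_edge_network(n_nodes, 1, noise_sigma = 0.5, seed = s)
      est <- mle_absolute_dg(net)
      tru <- attr(net, "true_dgs")[est$ligand]
      tru <- tru - mean(tru)
      sqrt(mean((est$dg - tru)^2))
    }, numeric(1)))
  }
  r4 <- rmse_for(4, 1:30)
  r10 <- rmse_for(10, 1:30)
  # expected ratio sqrt(3/9) ~ 0.58; allow generous Monte-Carlo slack
  expect_lt(r10, r4)
  expect_lt(abs(r10 / r4 - sqrt(3 / 9)), 0.25)
})
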