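test_that("Lennard-Jones pair has its root at sigma and minimum at 2^(1/6) sigma", {
  terms <- list(lennard_jones_pair(1, 2, eps = 0.3, sigma = 3))
  at <- function(r) mm_energy(rbind(c(0, 0, 0), c(r, 0, 0)), terms)
  expect_equal(at(3)$energy, 0, tolerance = 1e-12)
  mn <- at(2^(1 / 6) * 3)
  expect_equal(mn$energy, -0.3, tolerance = 1e-12)
  expect_equal(max(abs(mn$gradient)), 0, tolerance = 1e-10)
  expect_error(at(1e-8), class = "atmkit_singular_geometry")
})

test_that("analytic gradients match finite differences for every term kind", {
  set.seed(41)
  coords <- matrix(rnorm(15, 0, 1), 5, 3) * 1.5 +
    matrix(c(0, 1.4, 2.9, 4.1, 5.6), 5, 3)
  terms <- list(
    harmonic_bond(1, 2, k = 80, r0 = 1.4),
    harmonic_tether(3, k = 5, center = c(1, -1, 2)),
    harmonic_tether(4, k = 2, center = c(0, 0, 0), r0 = 2),
    lennard_jones_pair(2, 5, eps = 0.2, sigma = 2.5),
    coulomb_pair(1, 5, qi = 0.3, qj = -0.4),
    torsion_cosine(1, 2, 3, 4, amplitude = 1.2, periodicity = 3, phase = 0.4),
    double_well_tether(5, 2, 1, c(0, 0, 0), c(8, 0, 0), kT = 0.6)
  )
  ev <- mm_energy(coords, terms)
  fd <- fd_gradient(function(x) mm_energy(x, terms)$energy, coords)
  expect_lt(max(abs(ev$gradient - fd)) / max(abs(ev$gradient)), 1e-6)
})

test_that("surrogate potential is zero for one bead and rigid-motion invariant", {
  sp <- surrogate_params(seed = 4)
  one <- surrogate_energy(matrix(c(1, 2, 3), 1, 3), sp)
  expect_equal(one$energy, 0)
  expect_equal(max(abs(one$gradient)), 0)
  set.seed(12)
  lig <- matrix(rnorm(9, 0, 1), 3, 3) + matrix(c(0, 1.5, 3), 3, 3)
  e0 <- surrogate_energy(lig, sp)$energy
  # translation
  expect_equal(surrogate_energy(lig + 5, sp)$energy, e0, tolerance = 1e-12)
  # random rotations
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    expect_equal(surrogate_energy(lig %*% q, sp)$energy, e0, tolerance = 1e-9)
  }
  # gradient matches finite differences
  ev <- surrogate_energy(lig, sp)
  fd <- fd_gradient(function(x) surrogate_energy(x, sp)$energy, lig)
  expect_lt(max(abs(ev$gradient - fd)), 1e-6)
  # deterministic weights for a fixed seed
  expect_identical(surrogate_params(7)$weights, surrogate_params(7)$weights)
})

test_that("hybrid decomposition replaces exactly the ligand-internal terms", {
  sys <- make_lj_ligand_system(3, 2, seed = 9)
  sp <- surrogate_params(9)
  x <- sys$coords
  hy <- hybrid_energy(x, sys, "hybrid", sp)
  mm <- hybrid_energy(x, sys, "mm")
  # decomposition identity: hybrid - mm = sum_ligands (surrogate - mm_intra)
  expect_equal(hy$energy - mm$energy,
               (hy$components$surrogate_A - hy$components$intra_mm_A) +
               (hy$components$surrogate_B - hy$components$intra_mm_B),
               tolerance = 1e-12)
  # ligand-environment and environment components identical between modes
  expect_identical(hy$components$env, mm$components$env)
  expect_identical(hy$components$ligand_env, mm$components$ligand_env)
  # moving only environment particles changes both modes by the same amount
  x2 <- x
  env <- setdiff(seq_len(sys$n), c(sys$ligand_a, sys$ligand_b))
  x2[env, ] <- x2[env, ] + 0.3
  d_mm <- hybrid_energy(x2, sys, "mm")$energy - mm$energy
  d_hy <- hybrid_energy(x2, sys, "hybrid", sp)$energy - hy$energy
  expect_equal(d_mm, d_hy, tolerance = 1e-10)
  # hybrid gradient passes finite differences
  fd <- fd_gradient(function(z) hybrid_energy(z, sys, "hybrid", sp)$energy, x)
  expect_lt(max(abs(hy$gradient - fd)) / max(abs(hy$gradient)), 1e-5)
})

test_that("single-bead ligands make hybrid and mm modes identical", {
  sys <- make_harmonic_host_guest(4, 1, 2, 1, temperature = 300)
  x <- sys$coords + matrix(rnorm(6, 0, 0.5), 2, 3)
  expect_identical(hybrid_energy(x, sys, "hybrid")$energy,
                   hybrid_energy(x, sys, "mm")$energy)
})

test_that("terms spanning both ligand groups are rejected", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  terms <- list(harmonic_bond(1, 2, 10, 1.5))
  expect_error(
    toy_system(coords, terms, ligand_a = 1, ligand_b = 2,
               site_center = c(0, 0, 0), bulk_center = c(10, 0, 0),
               temperature = 300),
    class = "atmkit_classification_error")
})

test_that("compiled sampler energy path agrees with the reference path", {
  sys <- make_lj_ligand_system(4, 2, seed = 21)
  sp <- surrogate_params(21)
  st <- alchemical_state(0.3, lam1 = 0.35, lam2 = 0.25, alpha = 0.1, u0 = 20)
  fn_mm <- atmkit:::build_alch_fn(sys, st, "mm")
  fn_hy <- atmkit:::build_alch_fn(sys, st, "hybrid", sp)
  set.seed(77)
  for (i in 1:5) {
    x <- sys$coords + matrix(rnorm(3 * sys$n, 0, 0.15), sys$n, 3)
    for (cfg in list(list(fn = fn_mm, mode = "mm"), list(fn = fn_hy, mode = "hybrid"))) {
      a <- cfg$fn(x)
      b <- total_alchemical_energy(x, sys, st, cfg$mode, sp)
      expect_equal(a$energy, b$energy, tolerance = 1e-12)
      expect_equal(a$u, b$u, tolerance = 1e-12)
      expect_equal(a$gradient, b$gradient, tolerance = 1e-12)
    }
  }
})

test_that("energy decomposition formats as labelled kcal/mol lines", {
  sys <- make_harmonic_host_guest()
  comp <- hybrid_energy(sys$coords, sys, "mm")$components
  lines <- format_energy_decomposition(comp)
  expect_length(lines, length(comp))
  expect_true(all(grepl("kcal/mol", lines)))
})
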