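test_that("swap transform is an exact involution that exchanges site and bulk", {
  sys <- make_harmonic_host_guest(4, 1, 1, 1, temperature = 300)
  set.seed(8)
  for (i in 1:10) {
    x <- sys$coords + matrix(rnorm(6, 0, 1), 2, 3)
    # involution up to one rounding of the translated coordinate: a rigid
    # translation shifts the floating-point exponent, so the round trip is
    # exact to the ulp of the displaced position
    expect_equal(swap_transform(swap_transform(x, sys), sys), x,
                 tolerance = 1e-14)
  }
  # single-particle A at the site center lands exactly on the bulk center
  x <- rbind(sys$site_center, sys$bulk_center)
  xs <- swap_transform(x, sys)
  expect_equal(xs[1, ], sys$bulk_center)
  expect_equal(xs[2, ], sys$site_center)
  # environment particles never move
  lj <- make_lj_ligand_system(2, 2, seed = 1)
  env <- setdiff(seq_len(lj$n), c(lj$ligand_a, lj$ligand_b))
  xs <- swap_transform(lj$coords, lj)
  expect_identical(xs[env, ], lj$coords[env, ])
})

test_that("perturbation energy is antisymmetric and matches the worked example", {
  sys <- make_harmonic_host_guest(2, 1, 2, 1, temperature = T_NATURAL)
  set.seed(13)
  for (i in 1:10) {
    x <- sys$coords + matrix(rnorm(6, 0, 1), 2, 3)
    u <- perturbation_energy(x, sys)
    expect_equal(perturbation_energy(swap_transform(x, sys), sys), -u,
                 tolerance = 1e-12)
  }
  # A displaced 1 A from the site center, B exactly at the bulk center:
  # E = k_site/2 * 1 = 1, swapped E = k_bulk/2 * 1 = 0.5, u = -0.5
  x <- sys$coords
  x[1, ] <- sys$site_center + c(1, 0, 0)
  expect_equal(hybrid_energy(x, sys, "mm")$energy, 1.0, tolerance = 1e-10)
  expect_equal(perturbation_energy(x, sys), -0.5, tolerance = 1e-10)
  # equal springs with both ligands exactly on-center: u = 0
  sym <- make_harmonic_host_guest(1, 1, 1, 1, temperature = T_NATURAL)
  expect_equal(perturbation_energy(sym$coords, sym), 0, tolerance = 1e-12)
})

test_that("soft-core is identity below uc, C1 at the joint, and capped at umax", {
  sc <- softcore_params(umax = 200, uc = 100, a = 1 / 16)
  expect_identical(softcore(-50, sc), -50)
  expect_identical(softcore(100, sc), 100)
  expect_lt(abs(softcore(1e6, sc) - 200), 1e-3)
  # one-sided difference quotients at the joint both within 1e-4 of 1
  h <- 1e-5
  expect_lt(abs((softcore(100 + h, sc) - softcore(100, sc)) / h - 1), 1e-4)
  expect_lt(abs((softcore(100, sc) - softcore(100 - h, sc)) / h - 1), 1e-4)
  # strictly increasing where double precision resolves the cap, and
  # bounded above everywhere
  u <- seq(-100, 2000, length.out = 2000)
  usc <- softcore(u, sc)
  expect_true(all(diff(usc) > 0))
  expect_true(all(softcore(seq(-100, 1e6, length.out = 500), sc) <= 200))
  expect_error(softcore_params(umax = 50, uc = 100), class = "atmkit_invalid_parameter")
})

test_that("softplus bias reduces to linear coupling and matches the closed form", {
  lin <- alchemical_state(0.5, w0 = 0)
  expect_equal(alchemical_bias(3.0, lin), 1.5)
  u <- seq(-500, 500, length.out = 501)
  expect_lt(max(abs(alchemical_bias(u, lin) - 0.5 * u)), 1e-12)
  # direct evaluation of the softplus form
  st <- alchemical_state(0.15, lam1 = 0.2, lam2 = 0.1, alpha = 0.1, u0 = 0, w0 = 0)
  expect_equal(alchemical_bias(0, st), (0.1 / 0.1) * log(2), tolerance = 1e-12)
  # large-u asymptote: W -> lam2 * u + w0
  expect_lt(abs(alchemical_bias(1e4, st) - 0.1 * 1e4), 1e-10)
  # bias monotone non-decreasing in u_sc for non-negative slopes
  w <- alchemical_bias(u, st)
  expect_true(all(diff(w) >= -1e-10))
  expect_error(alchemical_state(0.2, lam1 = 0.3, lam2 = 0.1, alpha = 0),
               class = "atmkit_invalid_parameter")
})

test_that("total alchemical potential recovers E at lambda 0 and has exact gradients", {
  sys <- make_harmonic_host_guest(4, 1, 2, 1, temperature = T_NATURAL)
  set.seed(3)
  x <- sys$coords + matrix(rnorm(6, 0, 0.8), 2, 3)
  st0 <- alchemical_state(0)
  ev <- total_alchemical_energy(x, sys, st0)
  expect_equal(ev$energy, hybrid_energy(x, sys, "mm")$energy, tolerance = 1e-12)
  st <- alchemical_state(0.35, lam1 = 0.4, lam2 = 0.3, alpha = 0.1, u0 = 5)
  ev <- total_alchemical_energy(x, sys, st)
  fd <- fd_gradient(function(z) total_alchemical_energy(z, sys, st)$energy, x)
  expect_lt(max(abs(ev$gradient - fd)) / max(abs(ev$gradient)), 1e-5)
  # symmetric system at the linear lambda = 1/2 state: U(swap x) = U(x)
  sym <- make_harmonic_host_guest(1, 1, 1, 1, temperature = T_NATURAL)
  half <- alchemical_state(0.5)
  for (i in 1:5) {
    x <- sym$coords + matrix(rnorm(6, 0, 1), 2, 3)
    expect_equal(total_alchemical_energy(swap_transform(x, sym), sym, half)$energy,
                 total_alchemical_energy(x, sym, half)$energy, tolerance = 1e-9)
  }
})

test_that("lambda schedules are evenly spaced and meet at the intermediate", {
  s11 <- lambda_schedule(11, leg = 1)
  expect_equal(vapply(s11, function(s) s$lam, numeric(1)), seq(0, 0.5, by = 0.05))
  s2 <- lambda_schedule(2)
  expect_equal(vapply(s2, function(s) s$lam, numeric(1)), c(0, 0.5))
  # both legs share the grid and differ only in the direction flag
  l1 <- lambda_schedule(5, leg = 1)
  l2 <- lambda_schedule(5, leg = 2)
  expect_equal(vapply(l1, function(s) s$lam, numeric(1)),
               vapply(l2, function(s) s$lam, numeric(1)))
  expect_true(all(vapply(l2, function(s) s$leg, integer(1)) == 2L))
  # softplus family: endpoints at plain potential and symmetric intermediate
  sp <- lambda_schedule(6, family = "softplus-defaults")
  expect_equal(sp[[1]]$lam1, 0); expect_equal(sp[[1]]$lam2, 0)
  expect_equal(sp[[6]]$lam1, 0.5); expect_equal(sp[[6]]$lam2, 0.5)
  expect_error(lambda_schedule(1), class = "atmkit_invalid_parameter")
})
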