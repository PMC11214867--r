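# single tethered particle, kT = 1 kcal/mol, used by the integrator tests
one_particle_system <- function(k = 1) {
  toy_system(matrix(0, 1, 3), list(harmonic_tether(1, k = k, center = c(0, 0, 0))),
             ligand_a = 1L, ligand_b = integer(0),
             site_center = c(0, 0, 0), bulk_center = c(10, 0, 0),
             temperature = T_NATURAL)
}

test_that("Langevin steps are deterministic under a fixed seed", {
  sys <- one_particle_system()
  efn <- function(x) mm_energy(x, sys$terms)
  traj <- function(seed) {
    withr::with_seed(seed, {
      x <- matrix(c(1, 0, 0), 1, 3); v <- matrix(0, 1, 3); g <- efn(x)$gradient
      out <- numeric(50)
      for (i in 1:50) {
        st <- langevin_step(x, v, efn, sys$masses, 4, 1, 1, grad = g)
        x <- st$coords; v <- st$velocities; g <- st$grad
        out[i] <- x[1, 1]
      }
      out
    })
  }
  expect_identical(traj(99), traj(99))
  expect_false(identical(traj(99), traj(100)))
})

test_that("zero-temperature overdamped dynamics descends a convex well", {
  sys <- one_particle_system(k = 2)
  efn <- function(x) mm_energy(x, sys$terms)
  withr::with_seed(1, {
    x <- matrix(c(3, -2, 1), 1, 3); v <- matrix(0, 1, 3); g <- efn(x)$gradient
    es <- numeric(200)
    for (i in 1:200) {
      st <- langevin_step(x, v, efn, sys$masses, 4, friction = 500, kT = 0, grad = g)
      x <- st$coords; v <- st$velocities; g <- st$grad
      es[i] <- st$energy
    }
    expect_true(all(diff(es) <= 1e-10))
    expect_lt(es[200], es[1])
  })
})

test_that("harmonic oscillator satisfies equipartition within Monte-Carlo error", {
  sys <- one_particle_system(k = 1)   # kT/k = 1 A^2 per component
  efn <- atmkit:::build_hybrid_fn(sys, "mm")
  withr::with_seed(17, {
    x <- matrix(0, 1, 3)
    v <- atmkit:::draw_velocities(1, sys$masses, 1)
    g <- efn(x)$gradient
    n_chunks <- 400
    xs <- matrix(0, n_chunks, 3)
    for (i in seq_len(n_chunks)) {
      seg <- atmkit:::run_segment(x, v, g, 250, efn, sys$masses, 0.004, 1, 1)
      x <- seg$coords; v <- seg$vel; g <- seg$grad
      xs[i, ] <- x
    }
    x2 <- rowMeans(xs^2)
    se <- sd(x2) / sqrt(n_chunks / atmkit:::statistical_inefficiency(x2))
    expect_lt(abs(mean(x2) - 1), 3 * se)
  })
})

frozen_ensemble <- function(u, states) {
  structure(list(states = states,
                 replicas = vector("list", length(u)),
                 state_of_replica = seq_along(u),
                 u = u,
                 attempts = integer(length(u) - 1),
                 accepts = integer(length(u) - 1)),
            class = "replica_ensemble")
}

test_that("swap of identical states is always accepted", {
  states <- list(alchemical_state(0.25), alchemical_state(0.25))
  ens <- frozen_ensemble(c(3.7, -1.2), states)
  withr::with_seed(5, {
    for (i in 1:200) {
      ens$state_of_replica <- 1:2
      ens <- replica_exchange_sweep(ens, kT = 1)
    }
  })
  expect_equal(ens$accepts[1], ens$attempts[1])
})

test_that("fixed-energy-gap swaps accept at the Metropolis rate", {
  # lambda 0 vs 1/2 linear coupling, u difference 4 kT -> Delta = 2 kT
  states <- list(alchemical_state(0), alchemical_state(0.5))
  ens <- frozen_ensemble(c(4, 0), states)
  n <- 10000
  withr::with_seed(11, {
    for (i in seq_len(n)) {
      ens$state_of_replica <- 1:2
      ens <- replica_exchange_sweep(ens, kT = 1)
    }
  })
  p <- exp(-2)
  expect_equal(ens$attempts[1], n)
  expect_lt(abs(ens$accepts[1] / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("frozen two-replica chain reaches the exact Boltzmann occupancy", {
  states <- list(alchemical_state(0), alchemical_state(0.5))
  ua <- 2; ub <- 0
  ens <- frozen_ensemble(c(ua, ub), states)
  # configuration X: (ua at state1, ub at state2), bias energy 0.5*ub = 0
  # configuration Y: swapped, bias energy 0.5*ua = 1  =>  pi_Y/pi_X = e^-1
  n <- 10000
  occ_Y <- 0
  withr::with_seed(23, {
    for (i in seq_len(n)) {
      ens <- replica_exchange_sweep(ens, kT = 1)
      if (ens$state_of_replica[1] == 2L) occ_Y <- occ_Y + 1
    }
  })
  p_acc_XY <- exp(-1); p_acc_YX <- 1
  p_Y <- exp(-1) / (1 + exp(-1))
  rho <- 1 - p_acc_XY - p_acc_YX      # lag-1 autocorrelation of the flip chain
  se <- sqrt(p_Y * (1 - p_Y) * (1 + rho) / (1 - rho) / n)
  expect_lt(abs(occ_Y / n - p_Y), 3 * se)
})

test_that("annealing validates its schedule and is deterministic", {
  sys <- make_harmonic_host_guest(4, 1, 1, 1, temperature = T_NATURAL)
  run <- quick_run(31)
  bad <- lambda_schedule(4)[1:3]   # ends below 1/2
  expect_error(anneal_to_intermediate(sys, bad, 50, run),
               class = "atmkit_invalid_schedule")
  # single state at lambda = 0 is plain equilibration
  x0 <- anneal_to_intermediate(sys, lambda_schedule(2)[1], 100, run)
  expect_true(all(is.finite(x0)))
  sched <- lambda_schedule(5)
  a <- anneal_to_intermediate(sys, sched, 100, run)
  b <- anneal_to_intermediate(sys, sched, 100, run)
  expect_identical(a, b)
  # annealed configuration has finite energy at every window of both legs
  for (leg in 1:2) {
    for (st in lambda_schedule(6, leg = leg)) {
      expect_true(is.finite(total_alchemical_energy(a, sys, st)$energy))
    }
  }
})

test_that("ATM legs return per-replicate samples with healthy exchange", {
  sys <- make_harmonic_host_guest(4, 1, 1, 1, temperature = T_NATURAL)
  run <- run_spec(n_steps = 2000, exchange_interval = 250, sample_interval = 50,
                  anneal_steps = 600, replicate_count = 3, seed = 71)
  lr <- run_atm_leg(sys, leg = 1, run = run, mode = "mm", n_windows = 6)
  expect_length(lr$samples, 3)
  # distinct rng streams -> distinct sample series
  expect_false(identical(lr$samples[[1]]$u_by_state, lr$samples[[2]]$u_by_state))
  expect_false(identical(lr$samples[[2]]$u_by_state, lr$samples[[3]]$u_by_state))
  # every window sampled
  for (s in lr$samples) expect_true(all(s$sample_counts > 0))
  # rerun is bit-identical, including exchange decisions
  lr2 <- run_atm_leg(sys, leg = 1, run = run, mode = "mm", n_windows = 6)
  expect_identical(lapply(lr$samples, function(s) s$u_by_state),
                   lapply(lr2$samples, function(s) s$u_by_state))
  expect_identical(lr$acceptance, lr2$acceptance)
})

test_that("symmetric system samples have zero-mean u at the intermediate", {
  sym <- make_harmonic_host_guest(2, 2, 2, 2, temperature = T_NATURAL)
  run <- run_spec(n_steps = 4000, exchange_interval = 250, sample_interval = 25,
                  anneal_steps = 900, seed = 19)
  lr <- run_atm_leg(sym, leg = 1, run = run, mode = "mm", n_windows = 5)
  u_half <- lr$samples[[1]]$u_by_state[[5]]
  se <- sd(u_half) / sqrt(length(u_half) / atmkit:::statistical_inefficiency(u_half))
  expect_lt(abs(mean(u_half)), 3 * max(se, 1e-6))
})

test_that("neighbour exchange on the harmonic fixture accepts but not always", {
  sys <- make_harmonic_host_guest(4, 1, 1, 1, temperature = T_NATURAL)
  run <- run_spec(n_steps = 5000, exchange_interval = 250, sample_interval = 50,
                  anneal_steps = 1100, seed = 3)
  lr <- run_atm_leg(sys, leg = 1, run = run, mode = "mm", n_windows = 6)
  rate <- sum(lr$acceptance$accepts) / sum(lr$acceptance$attempts)
  expect_gt(rate, 0)
  expect_lt(rate, 1)
})

test_that("run specifications validate their intervals", {
  expect_error(run_spec(n_steps = 1000, exchange_interval = 300),
               class = "atmkit_invalid_parameter")
  expect_error(run_spec(n_steps = 1000, sample_interval = 300),
               class = "atmkit_invalid_parameter")
  expect_error(run_spec(timestep_fs = 0), class = "atmkit_invalid_parameter")
})
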