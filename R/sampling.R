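#' Run specification for sampling
#'
#' @param timestep_fs integration step, femtoseconds.
#' @param friction Langevin friction, 1/ps.
#' @param n_steps production steps per replica.
#' @param exchange_interval steps between replica exchange sweeps; must
#'   divide `n_steps`.
#' @param sample_interval steps between recorded perturbation-energy samples;
#'   must divide `n_steps`.
#' @param anneal_steps total steps of the annealing pass from lambda 0 to the
#'   symmetric intermediate.
#' @param replicate_count independent repeats (the benchmark protocol runs
#'   ligand pairs in triplicate).
#' @param seed integer seed; every stream in the run derives from it.
#' @return a `run_spec` object.
#' @export
run_spec <- function(timestep_fs = 4, friction = 1, n_steps = 20000,
                     exchange_interval = 250, sample_interval = 50,
                     anneal_steps = 2200, replicate_count = 1, seed = 1) {
  check_positive(timestep_fs, "timestep_fs")
  check_positive(friction, "friction")
  check_positive(n_steps, "n_steps")
  if (n_steps %% exchange_interval != 0) {
    abort_invalid("`exchange_interval` must divide `n_steps`")
  }
  if (n_steps %% sample_interval != 0) {
    abort_invalid("`sample_interval` must divide `n_steps`")
  }
  structure(list(timestep_fs = timestep_fs, friction = friction,
                 n_steps = as.integer(n_steps),
                 exchange_interval = as.integer(exchange_interval),
                 sample_interval = as.integer(sample_interval),
                 anneal_steps = as.integer(anneal_steps),
                 replicate_count = as.integer(replicate_count),
                 seed = as.integer(seed)),
            class = "run_spec")
}

# Maxwell-Boltzmann velocities, A/ps
draw_velocities <- function(n, masses, kT) {
  sd_v <- sqrt(kT * KCAL_TO_AMU_A2_PS2 / masses)
  matrix(rnorm(3 * n), n, 3) * sd_v
}

#' One BAOAB Langevin step
#'
#' Splitting B-A-O-A-B: half kick, half drift, Ornstein-Uhlenbeck velocity
#' refresh, half drift, half kick. Deterministic given the ambient RNG
#' stream (the run drivers wrap everything in a seeded stream).
#'
#' @param coords,velocities N x 3 matrices (A, A/ps).
#' @param energy_fn function(coords) returning at least `gradient`
#'   (kcal/mol/A) and `energy`.
#' @param masses particle masses, amu.
#' @param timestep_fs step in femtoseconds.
#' @param friction 1/ps.
#' @param kT thermal energy, kcal/mol.
#' @param grad optional gradient at `coords` (saves one evaluation).
#' @return list with `coords`, `velocities`, `grad` (at the new coords),
#'   `energy`, and any extra fields the energy function returned.
#' @export
langevin_step <- function(coords, velocities, energy_fn, masses, timestep_fs,
                          friction, kT, grad = NULL) {
  dt <- timestep_fs * 1e-3   # ps
  if (is.null(grad)) grad <- energy_fn(coords)$gradient
  if (any(!is.finite(grad))) {
    abort("non-finite gradient in Langevin step", class = "atmkit_integration_failure")
  }
  inv_m <- KCAL_TO_AMU_A2_PS2 / masses
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  sd_v <- sqrt(kT * KCAL_TO_AMU_A2_PS2 / masses)
  v <- velocities - (dt / 2) * grad * inv_m
  x <- coords + (dt / 2) * v
  v <- c1 * v + c2 * sd_v * matrix(rnorm(length(v)), nrow(v), 3)
  x <- x + (dt / 2) * v
  ev <- energy_fn(x)
  if (any(!is.finite(ev$gradient)) || !is.finite(ev$energy)) {
    abort("non-finite energy/gradient after Langevin step",
          class = "atmkit_integration_failure")
  }
  v <- v - (dt / 2) * ev$gradient * inv_m
  out <- ev
  out$coords <- x
  out$velocities <- v
  out$grad <- ev$gradient
  out
}

# Tight inner loop: n steps of BAOAB, recording `u` every `record_every`
# steps (0 = no recording). Returns final state and recorded samples.
run_segment <- function(coords, vel, grad, n, energy_fn, masses, dt_ps,
                        friction, kT, record_every = 0L, step_offset = 0L) {
  inv_m <- KCAL_TO_AMU_A2_PS2 / masses
  c1 <- exp(-friction * dt_ps)
  c2 <- sqrt(1 - c1^2)
  sd_v <- sqrt(kT * KCAL_TO_AMU_A2_PS2 / masses)
  half <- dt_ps / 2
  np <- nrow(coords)
  samples <- numeric(0)
  sample_steps <- integer(0)
  u_last <- NA_real_
  for (s in seq_len(n)) {
    vel <- vel - half * grad * inv_m
    coords <- coords + half * vel
    vel <- c1 * vel + c2 * sd_v * matrix(rnorm(3 * np), np, 3)
    coords <- coords + half * vel
    ev <- energy_fn(coords)
    grad <- ev$gradient
    if (any(!is.finite(grad))) {
      abort(sprintf("non-finite gradient at step %d", step_offset + s),
            class = "atmkit_integration_failure")
    }
    vel <- vel - half * grad * inv_m
    u_last <- ev$u %||% NA_real_
    if (record_every > 0L && (step_offset + s) %% record_every == 0L) {
      samples <- c(samples, u_last)
      sample_steps <- c(sample_steps, step_offset + s)
    }
  }
  list(coords = coords, vel = vel, grad = grad, u = u_last,
       samples = samples, sample_steps = sample_steps)
}

#' Anneal a system to the symmetric alchemical intermediate
#'
#' Runs Langevin dynamics while stepping lambda through the supplied
#' schedule (which must end at the symmetric intermediate, lambda = 1/2);
#' the returned configuration seeds all replicas of a leg.
#'
#' @param system a [toy_system].
#' @param schedule list of [alchemical_state()], lambda non-decreasing.
#' @param steps_per_state Langevin steps spent at each schedule entry.
#' @param run a [run_spec()] (timestep, friction, seed).
#' @param mode,surrogate as in [hybrid_energy()].
#' @param coords optional starting coordinates (default: the system's).
#' @return the final N x 3 configuration.
#' @export
anneal_to_intermediate <- function(system, schedule, steps_per_state, run,
                                   mode = "mm", surrogate = NULL,
                                   coords = NULL) {
  lams <- vapply(schedule, function(s) s$lam, numeric(1))
  if (length(schedule) > 1 && abs(lams[length(lams)] - 0.5) > 1e-12) {
    abort("annealing schedule must end at lambda = 1/2",
          class = "atmkit_invalid_schedule")
  }
  coords <- as_coord_matrix(coords %||% system$coords)
  kT <- system$kT
  dt <- run$timestep_fs * 1e-3
  with_stream(derive_seed(run$seed, 555L), {
    vel <- draw_velocities(system$n, system$masses, kT)
    for (st in schedule) {
      efn <- build_alch_fn(system, st, mode, surrogate)
      ev <- efn(coords)
      seg <- run_segment(coords, vel, ev$gradient, steps_per_state, efn,
                         system$masses, dt, run$friction, kT)
      coords <- seg$coords
      vel <- seg$vel
    }
    coords
  })
}

#' One Hamiltonian replica exchange sweep
#'
#' Attempts nearest-neighbour state swaps, alternating even and odd pairs
#' between consecutive sweeps. A swap of the replicas at states i and j with
#' current (uncapped) perturbation energies `u_i`, `u_j` is accepted with
#' probability `min(1, exp(-[W_i(u_j) + W_j(u_i) - W_i(u_i) - W_j(u_j)]/kT))`
#' where `W` is applied to the soft-core capped energy.
#'
#' @param ensemble a `replica_ensemble` (see [run_atm_leg()]); also accepts
#'   the minimal list structure used in the tests.
#' @param kT thermal energy, kcal/mol.
#' @param parity 0 or 1: attempt pairs starting at odd or even state index.
#' @return the updated ensemble (state assignments and swap statistics).
#' @export
replica_exchange_sweep <- function(ensemble, kT, parity = 0L) {
  K <- length(ensemble$states)
  if (K < 2) abort_invalid("replica exchange needs at least 2 states")
  state_of <- ensemble$state_of_replica
  replica_at <- order(state_of)   # replica index occupying each state
  first <- 1L + (parity %% 2L)
  ks <- seq.int(first, K - 1L, by = 2L)
  for (k in ks) {
    ri <- replica_at[k]
    rj <- replica_at[k + 1L]
    ui <- ensemble$u[ri]
    uj <- ensemble$u[rj]
    si <- ensemble$states[[k]]
    sj <- ensemble$states[[k + 1L]]
    usc_i <- softcore(ui, si$softcore)
    usc_j <- softcore(uj, sj$softcore)
    delta <- (alchemical_bias(usc_j, si) + alchemical_bias(usc_i, sj) -
              alchemical_bias(usc_i, si) - alchemical_bias(usc_j, sj)) / kT
    ensemble$attempts[k] <- ensemble$attempts[k] + 1L
    if (delta <= 0 || runif(1) < exp(-delta)) {
      ensemble$accepts[k] <- ensemble$accepts[k] + 1L
      state_of[ri] <- k + 1L
      state_of[rj] <- k
      replica_at[k] <- rj
      replica_at[k + 1L] <- ri
    }
  }
  ensemble$state_of_replica <- state_of
  ensemble
}

new_replica_ensemble <- function(states, coords, vel, grad, u) {
  K <- length(states)
  structure(list(
    states = states,
    replicas = lapply(seq_len(K), function(i) {
      list(coords = coords, vel = vel[[i]], grad = grad)
    }),
    state_of_replica = seq_len(K),
    u = rep(u, K),
    attempts = integer(K - 1),
    accepts = integer(K - 1)
  ), class = "replica_ensemble")
}

#' Run one ATM leg: anneal, replica exchange, collect samples
#'
#' The full sampling protocol for one transfer leg: anneal from the leg's
#' physical basin (leg 1: A bound / B solvated; leg 2: the swapped basin) to
#' the symmetric intermediate, seed one replica per lambda window, then
#' alternate Langevin dynamics segments with neighbour exchange sweeps,
#' recording the perturbation energy of the replica at each state every
#' `sample_interval` steps. Repeats `replicate_count` times with independent
#' derived streams.
#'
#' @param system a [toy_system].
#' @param leg 1 or 2.
#' @param run a [run_spec()].
#' @param mode,surrogate as in [hybrid_energy()].
#' @param n_windows lambda windows per leg.
#' @param family schedule family, see [lambda_schedule()].
#' @param softcore shared [softcore_params()].
#' @return an `atm_leg_result`: list with `samples` (list of
#'   [perturbation_samples] objects, one per replicate), `acceptance`
#'   (tibble of per-neighbour-pair swap statistics per replicate), `leg`,
#'   and `mode`.
#' @export
run_atm_leg <- function(system, leg = 1L, run = run_spec(), mode = "mm",
                        surrogate = NULL, n_windows = 11,
                        family = "linear", softcore = softcore_params()) {
  schedule <- lambda_schedule(n_windows, leg = leg, family = family,
                              softcore = softcore)
  kT <- system$kT
  dt <- run$timestep_fs * 1e-3
  start <- system$coords
  if (leg == 2L) start <- swap_transform(start, system)
  steps_per_state <- max(1L, run$anneal_steps %/% length(schedule))
  seeded <- anneal_to_intermediate(
    system, schedule, steps_per_state,
    run_spec(timestep_fs = run$timestep_fs, friction = run$friction,
             n_steps = run$n_steps, exchange_interval = run$exchange_interval,
             sample_interval = run$sample_interval,
             anneal_steps = run$anneal_steps, seed = derive_seed(run$seed, 10L * leg)),
    mode = mode, surrogate = surrogate, coords = start)
  K <- length(schedule)
  n_sweeps <- run$n_steps %/% run$exchange_interval
  reps <- lapply(seq_len(run$replicate_count), function(rep_id) {
    with_stream(derive_seed(run$seed, 100L * leg + rep_id), {
      efns <- lapply(schedule, function(st) build_alch_fn(system, st, mode, surrogate))
      vel0 <- lapply(seq_len(K), function(i) draw_velocities(system$n, system$masses, kT))
      ev0 <- efns[[1]](seeded)
      ens <- new_replica_ensemble(schedule, seeded, vel0, ev0$gradient, ev0$u)
      u_by_state <- vector("list", K)
      for (k in seq_len(K)) u_by_state[[k]] <- numeric(0)
      for (sweep in seq_len(n_sweeps)) {
        off <- (sweep - 1L) * run$exchange_interval
        for (r in seq_len(K)) {
          st_idx <- ens$state_of_replica[r]
          repl <- ens$replicas[[r]]
          seg <- run_segment(repl$coords, repl$vel, repl$grad,
                             run$exchange_interval, efns[[st_idx]],
                             system$masses, dt, run$friction, kT,
                             record_every = run$sample_interval,
                             step_offset = off)
          ens$replicas[[r]] <- list(coords = seg$coords, vel = seg$vel,
                                    grad = seg$grad)
          ens$u[r] <- seg$u
          if (length(seg$samples) > 0) {
            u_by_state[[st_idx]] <- c(u_by_state[[st_idx]], seg$samples)
          }
        }
        ens <- replica_exchange_sweep(ens, kT, parity = sweep %% 2L)
        # exchanging states changes each replica's surface: refresh gradients
        for (r in seq_len(K)) {
          st_idx <- ens$state_of_replica[r]
          ev <- efns[[st_idx]](ens$replicas[[r]]$coords)
          ens$replicas[[r]]$grad <- ev$gradient
          ens$u[r] <- ev$u
        }
      }
      if (any(lengths(u_by_state) == 0)) {
        abort("a lambda window recorded zero samples; increase n_steps",
              class = "atmkit_incomplete_sampling")
      }
      list(samples = perturbation_samples(u_by_state, schedule, kT,
                                          leg = leg, replicate = rep_id),
           acceptance = tibble(
             replicate = rep_id,
             pair = paste0(seq_len(K - 1), "-", seq.int(2L, K)),
             attempts = ens$attempts,
             accepts = ens$accepts,
             rate = ifelse(ens$attempts > 0, ens$accepts / ens$attempts, NA_real_)))
    })
  })
  structure(list(
    samples = lapply(reps, `[[`, "samples"),
    acceptance = dplyr::bind_rows(lapply(reps, `[[`, "acceptance")),
    leg = as.integer(leg), mode = mode
  ), class = "atm_leg_result")
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 sum_t (1 - t/N) rho_t`, accumulating autocorrelations until
#' they first go non-positive. `N/g` is the effective number of independent
#' samples.
#'
#' @param x numeric series.
#' @return g >= 1.
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(1)
  x <- x - mean(x)
  v <- sum(x^2) / n
  g <- 1
  for (t in seq_len(n - 1)) {
    rho <- sum(x[seq_len(n - t)] * x[seq.int(t + 1, n)]) / ((n - t) * v)
    if (rho <= 0) break
    g <- g + 2 * (1 - t / n) * rho
  }
  max(1, g)
}
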