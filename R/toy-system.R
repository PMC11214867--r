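#' Toy host-guest systems
#'
#' A `toy_system` is the desk-scale analogue of a protein-ligand complex used
#' throughout atmkit: a small set of particles, a list of potential terms,
#' two disjoint "ligand" index groups A and B, a binding-site center and a
#' bulk (solvent) center, and the rigid displacement vector
#' `bulk_center - site_center` along which the Alchemical Transfer Method
#' swaps the two ligands.
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param terms list of [potential_terms].
#' @param ligand_a,ligand_b disjoint 1-based particle index vectors.
#' @param site_center,bulk_center length-3 centers (A).
#' @param temperature Kelvin.
#' @param masses particle masses (amu); default 12 amu per particle.
#' @param analytic_ddg optional exact transfer free energy (kcal/mol) for
#'   generators with a closed form; `NA` otherwise.
#' @return a `toy_system` object.
#' @export
toy_system <- function(coords, terms, ligand_a, ligand_b, site_center,
                       bulk_center, temperature, masses = NULL,
                       analytic_ddg = NA_real_) {
  coords <- as_coord_matrix(coords)
  dimnames(coords) <- NULL
  n <- nrow(coords)
  ligand_a <- as.integer(ligand_a)
  ligand_b <- as.integer(ligand_b)
  if (length(intersect(ligand_a, ligand_b)) > 0) {
    abort_classification("ligand index groups must be disjoint")
  }
  if (any(c(ligand_a, ligand_b) < 1L) || any(c(ligand_a, ligand_b) > n)) {
    abort_invalid("ligand indices out of range")
  }
  check_positive(temperature, "temperature")
  if (length(site_center) != 3 || length(bulk_center) != 3) {
    abort_invalid("centers must have length 3")
  }
  if (!is.na(analytic_ddg)) check_finite(analytic_ddg, "analytic_ddg")
  masses <- masses %||% rep(12, n)
  check_positive(masses, "masses")
  if (length(masses) != n) abort_invalid("`masses` must have one entry per particle")
  term_class <- vapply(terms, classify_term, character(1),
                       lig_a = ligand_a, lig_b = ligand_b)
  structure(list(
    n = n, coords = coords, terms = terms,
    ligand_a = ligand_a, ligand_b = ligand_b,
    site_center = as.numeric(site_center),
    bulk_center = as.numeric(bulk_center),
    displacement = as.numeric(bulk_center) - as.numeric(site_center),
    temperature = temperature,
    kT = KB_KCAL * temperature,
    masses = as.numeric(masses),
    analytic_ddg = analytic_ddg,
    term_class = term_class
  ), class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system> %d particles, %d terms, T = %.2f K (kT = %.4f kcal/mol)\n",
              x$n, length(x$terms), x$temperature, x$kT))
  cat(sprintf("  ligand A: %s | ligand B: %s\n",
              paste(x$ligand_a, collapse = ","), paste(x$ligand_b, collapse = ",")))
  cat(sprintf("  displacement: (%.2f, %.2f, %.2f) A\n",
              x$displacement[1], x$displacement[2], x$displacement[3]))
  if (!is.na(x$analytic_ddg)) {
    cat(sprintf("  analytic ddG: %.6f kcal/mol\n", x$analytic_ddg))
  }
  invisible(x)
}

#' Exact transfer free energy of two 3D harmonic "ligands"
#'
#' Closed form for swapping ligand A (site well `k_site_A`, bulk well
#' `k_bulk_A`) with ligand B (`k_site_B`, `k_bulk_B`) between binding site
#' and bulk. Each well is an isotropic 3D harmonic potential `k/2 |r - c|^2`
#' whose configurational integral is `(2 pi kT / k)^(3/2)`, so
#'
#' \deqn{\Delta\Delta G = \frac{3}{2} kT \left[\ln\frac{k_{bulk,A}}{k_{site,A}}
#'   - \ln\frac{k_{bulk,B}}{k_{site,B}}\right].}
#'
#' @param k_site_A,k_bulk_A,k_site_B,k_bulk_B spring constants, kcal/mol/A^2.
#' @param kT thermal energy, kcal/mol.
#' @return the exact ddG in kcal/mol.
#' @export
analytic_transfer_ddg <- function(k_site_A, k_bulk_A, k_site_B, k_bulk_B, kT) {
  for (nm in c("k_site_A", "k_bulk_A", "k_site_B", "k_bulk_B", "kT")) {
    check_positive(get(nm), nm)
  }
  1.5 * kT * (log(k_bulk_A / k_site_A) - log(k_bulk_B / k_site_B))
}

#' Harmonic host-guest system with a closed-form transfer free energy
#'
#' Two single-particle "ligands": A sits in the binding-site well (spring
#' `k_site`) and B in the bulk well (spring `k_bulk_B`) in the physical
#' state. Each ligand feels a smooth double-well tether (softmin of its site
#' and bulk wells, see [potential_terms]), so the swapped state -- A in bulk
#' with `k_bulk`, B in site with `k_site_B` -- is part of the same potential
#' and the exact ddG is [analytic_transfer_ddg()]. The wells are separated
#' far enough that basin overlap is below 1e-12 relative.
#'
#' @param k_site,k_bulk site/bulk spring constants of ligand A (kcal/mol/A^2).
#' @param k_site_B,k_bulk_B site/bulk spring constants of ligand B.
#' @param temperature Kelvin.
#' @param separation distance between site and bulk centers (A).
#' @return a [toy_system] with `analytic_ddg` set.
#' @export
make_harmonic_host_guest <- function(k_site = 4, k_bulk = 1, k_site_B = 1,
                                     k_bulk_B = 1, temperature = 300,
                                     separation = 16) {
  for (nm in c("k_site", "k_bulk", "k_site_B", "k_bulk_B", "temperature",
               "separation")) {
    check_positive(get(nm), nm)
  }
  kT <- KB_KCAL * temperature
  site <- c(0, 0, 0)
  bulk <- c(separation, 0, 0)
  coords <- rbind(site, bulk)
  terms <- list(
    double_well_tether(1L, k_site = k_site, k_bulk = k_bulk,
                       site_center = site, bulk_center = bulk, kT = kT),
    double_well_tether(2L, k_site = k_site_B, k_bulk = k_bulk_B,
                       site_center = site, bulk_center = bulk, kT = kT)
  )
  toy_system(coords, terms, ligand_a = 1L, ligand_b = 2L,
             site_center = site, bulk_center = bulk, temperature = temperature,
             analytic_ddg = analytic_transfer_ddg(k_site, k_bulk, k_site_B,
                                                  k_bulk_B, kT))
}

#' Bead-chain ligands in a Lennard-Jones site cavity
#'
#' A non-analytic stress-test system: two ligands of 1-4 beads connected by
#' harmonic bonds (plus a cosine torsion for 4-bead chains and a Coulomb
#' pair across the chain ends for 3+ beads), each held by a double-well
#' tether on its first bead, with a small cage of fixed host beads around
#' the binding site interacting with ligand beads through Lennard-Jones
#' pairs. Deterministic for a fixed seed; no closed-form ddG.
#'
#' @param n_beads_A,n_beads_B beads per ligand, 1-4.
#' @param seed integer seed.
#' @param temperature Kelvin.
#' @return a [toy_system] with `analytic_ddg = NA`.
#' @export
make_lj_ligand_system <- function(n_beads_A, n_beads_B, seed,
                                  temperature = 300) {
  for (nb in c(n_beads_A, n_beads_B)) {
    if (!is.numeric(nb) || nb < 1 || nb > 4 || nb != round(nb)) {
      abort_invalid("bead counts must be integers in [1, 4]")
    }
  }
  kT <- KB_KCAL * temperature
  site <- c(0, 0, 0)
  bulk <- c(18, 0, 0)
  # fixed host cage: 8 beads at cube corners around the site
  cage <- as.matrix(expand.grid(c(-3.2, 3.2), c(-3.2, 3.2), c(-3.2, 3.2)))
  colnames(cage) <- NULL
  n_env <- nrow(cage)
  build_chain <- function(n_beads, origin, jitter_seed) {
    base <- sweep(t(vapply(seq_len(n_beads) - 1,
                           function(m) c(1.5 * m, 0.3 * (m %% 2), 0),
                           numeric(3))), 2, origin, "+")
    jit <- with_stream(jitter_seed, matrix(rnorm(3 * n_beads, 0, 0.05), n_beads, 3))
    base + jit
  }
  ca <- build_chain(n_beads_A, site + c(-0.6 * (n_beads_A - 1), 0, 0),
                    derive_seed(seed, 11L))
  cb <- build_chain(n_beads_B, bulk + c(-0.6 * (n_beads_B - 1), 0, 0),
                    derive_seed(seed, 13L))
  coords <- rbind(cage, ca, cb)
  idx_a <- n_env + seq_len(n_beads_A)
  idx_b <- n_env + n_beads_A + seq_len(n_beads_B)
  terms <- list()
  add <- function(tm) terms[[length(terms) + 1]] <<- tm
  # host cage is rigidly tethered in place
  for (i in seq_len(n_env)) add(harmonic_tether(i, k = 50, center = cage[i, ]))
  chain_terms <- function(idx) {
    nb <- length(idx)
    if (nb >= 2) {
      for (m in seq_len(nb - 1)) add(harmonic_bond(idx[m], idx[m + 1], k = 100, r0 = 1.5))
    }
    if (nb >= 3) add(coulomb_pair(idx[1], idx[nb], qi = 0.1, qj = -0.1))
    if (nb == 4) add(torsion_cosine(idx[1], idx[2], idx[3], idx[4],
                                    amplitude = 0.5, periodicity = 3L))
  }
  chain_terms(idx_a)
  chain_terms(idx_b)
  # double-well tether anchors the first bead of each ligand
  for (idx in list(idx_a, idx_b)) {
    add(double_well_tether(idx[1], k_site = 2, k_bulk = 1,
                           site_center = site, bulk_center = bulk, kT = kT))
  }
  # ligand beads feel the cage through LJ (site side only matters)
  for (i in c(idx_a, idx_b)) {
    for (j in seq_len(n_env)) add(lennard_jones_pair(i, j, eps = 0.05, sigma = 3.0))
  }
  toy_system(coords, terms, ligand_a = idx_a, ligand_b = idx_b,
             site_center = site, bulk_center = bulk, temperature = temperature)
}
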