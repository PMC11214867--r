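#' Potential term constructors
#'
#' Toy molecular-mechanics terms. Coordinates are N x 3 matrices in Angstrom,
#' energies in kcal/mol, gradients in kcal/mol/A. Particle indices are 1-based.
#'
#' * `harmonic_bond()`: `E = k/2 (|r_i - r_j| - r0)^2`.
#' * `harmonic_tether()`: `E = k/2 (|r_i - center| - r0)^2` (r0 = 0 by
#'   default, giving the non-singular quadratic well `k/2 |r - c|^2`).
#' * `lennard_jones_pair()`: `E = 4 eps ((sigma/r)^12 - (sigma/r)^6)`.
#' * `coulomb_pair()`: `E = 332.0637 q_i q_j / (eps_r r)`.
#' * `torsion_cosine()`: `E = amplitude (1 + cos(periodicity * phi - phase))`.
#' * `double_well_tether()`: smooth softmin of a site well and a bulk well,
#'   `E = -kT log(exp(-E_site/kT) + exp(-E_bulk/kT))` with
#'   `E_site = k_site/2 |r - c_site|^2`, `E_bulk = k_bulk/2 |r - c_bulk|^2`.
#'   Its configurational integral is exactly the sum of the two Gaussian well
#'   integrals, which keeps the transfer free energy of the harmonic
#'   host-guest systems in closed form (see [analytic_transfer_ddg()]).
#'
#' @param i,j,k_,l 1-based particle indices.
#' @param k spring constant, kcal/mol/A^2.
#' @param r0 equilibrium length, A.
#' @param center,site_center,bulk_center anchor points, length-3, A.
#' @param eps LJ well depth, kcal/mol. @param sigma LJ diameter, A.
#' @param qi,qj partial charges, e. @param eps_r relative dielectric.
#' @param amplitude kcal/mol. @param periodicity integer. @param phase radians.
#' @param k_site,k_bulk spring constants of the two wells, kcal/mol/A^2.
#' @param kT thermal energy used by the softmin, kcal/mol.
#' @return a `potential_term` list.
#' @name potential_terms
NULL

new_term <- function(kind, idx, params) {
  structure(list(kind = kind, idx = as.integer(idx), params = params),
            class = "potential_term")
}

#' @rdname potential_terms
#' @export
harmonic_bond <- function(i, j, k, r0) {
  check_finite(k, "k"); check_finite(r0, "r0")
  if (k < 0) abort_invalid("bond `k` must be >= 0")
  if (i == j) abort_invalid("bond endpoints must differ")
  new_term("harmonic_bond", c(i, j), list(k = k, r0 = r0))
}

#' @rdname potential_terms
#' @export
harmonic_tether <- function(i, k, center, r0 = 0) {
  check_finite(k, "k"); check_finite(center, "center")
  if (k < 0) abort_invalid("tether `k` must be >= 0")
  if (length(center) != 3) abort_invalid("`center` must have length 3")
  new_term("harmonic_tether", i, list(k = k, r0 = r0, center = as.numeric(center)))
}

#' @rdname potential_terms
#' @export
lennard_jones_pair <- function(i, j, eps, sigma) {
  if (eps < 0) abort_invalid("LJ `eps` must be >= 0")
  check_positive(sigma, "sigma")
  if (i == j) abort_invalid("LJ pair endpoints must differ")
  new_term("lennard_jones_pair", c(i, j), list(eps = eps, sigma = sigma))
}

#' @rdname potential_terms
#' @export
coulomb_pair <- function(i, j, qi, qj, eps_r = 1) {
  check_finite(qi, "qi"); check_finite(qj, "qj"); check_positive(eps_r, "eps_r")
  if (i == j) abort_invalid("Coulomb pair endpoints must differ")
  new_term("coulomb_pair", c(i, j), list(qi = qi, qj = qj, eps_r = eps_r))
}

#' @rdname potential_terms
#' @export
torsion_cosine <- function(i, j, k_, l, amplitude, periodicity = 1L, phase = 0) {
  if (length(unique(c(i, j, k_, l))) != 4) abort_invalid("torsion needs 4 distinct particles")
  check_finite(amplitude, "amplitude")
  new_term("torsion_cosine", c(i, j, k_, l),
           list(amplitude = amplitude, periodicity = as.integer(periodicity),
                phase = phase))
}

#' @rdname potential_terms
#' @export
double_well_tether <- function(i, k_site, k_bulk, site_center, bulk_center, kT) {
  check_positive(k_site, "k_site"); check_positive(k_bulk, "k_bulk")
  check_positive(kT, "kT")
  new_term("double_well_tether", i,
           list(k_site = k_site, k_bulk = k_bulk,
                site_center = as.numeric(site_center),
                bulk_center = as.numeric(bulk_center), kT = kT))
}

# ---- term evaluation ---------------------------------------------------

eval_term <- function(term, coords) {
  p <- term$params
  switch(term$kind,
    harmonic_bond = {
      i <- term$idx[1]; j <- term$idx[2]
      dvec <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(dvec^2))
      if (r < 1e-10 && p$r0 != 0) abort_singular("coincident particles in bond with r0 > 0")
      e <- 0.5 * p$k * (r - p$r0)^2
      g <- matrix(0, 2, 3)
      if (r > 1e-10) {
        f <- p$k * (r - p$r0) / r
        g[1, ] <- f * dvec
        g[2, ] <- -f * dvec
      }
      list(energy = e, grad = g, idx = term$idx)
    },
    harmonic_tether = {
      i <- term$idx[1]
      dvec <- coords[i, ] - p$center
      r2 <- sum(dvec^2)
      if (p$r0 == 0) {
        list(energy = 0.5 * p$k * r2, grad = matrix(p$k * dvec, 1, 3), idx = term$idx)
      } else {
        r <- sqrt(r2)
        if (r < 1e-10) abort_singular("particle at tether center with r0 > 0")
        e <- 0.5 * p$k * (r - p$r0)^2
        list(energy = e, grad = matrix(p$k * (r - p$r0) / r * dvec, 1, 3), idx = term$idx)
      }
    },
    lennard_jones_pair = {
      i <- term$idx[1]; j <- term$idx[2]
      dvec <- coords[i, ] - coords[j, ]
      r2 <- sum(dvec^2)
      if (r2 < 1e-12) abort_singular("coincident particles in Lennard-Jones pair")
      sr2 <- p$sigma^2 / r2
      sr6 <- sr2^3
      e <- 4 * p$eps * (sr6^2 - sr6)
      # dE/dr * 1/r
      f_over_r <- 24 * p$eps * (sr6 - 2 * sr6^2) / r2
      g <- matrix(0, 2, 3)
      g[1, ] <- f_over_r * dvec
      g[2, ] <- -f_over_r * dvec
      list(energy = e, grad = g, idx = term$idx)
    },
    coulomb_pair = {
      i <- term$idx[1]; j <- term$idx[2]
      dvec <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(dvec^2))
      if (r < 1e-6) abort_singular("coincident particles in Coulomb pair")
      pref <- COULOMB_KCAL * p$qi * p$qj / p$eps_r
      e <- pref / r
      f_over_r <- -pref / r^3
      g <- matrix(0, 2, 3)
      g[1, ] <- f_over_r * dvec
      g[2, ] <- -f_over_r * dvec
      list(energy = e, grad = g, idx = term$idx)
    },
    torsion_cosine = {
      eval_torsion(term, coords)
    },
    double_well_tether = {
      i <- term$idx[1]
      ds <- coords[i, ] - p$site_center
      db <- coords[i, ] - p$bulk_center
      es <- 0.5 * p$k_site * sum(ds^2)
      eb <- 0.5 * p$k_bulk * sum(db^2)
      # softmin with Boltzmann weights; stable around the smaller energy
      m <- min(es, eb)
      ws <- exp(-(es - m) / p$kT)
      wb <- exp(-(eb - m) / p$kT)
      z <- ws + wb
      e <- m - p$kT * log(z)
      gs <- p$k_site * ds
      gb <- p$k_bulk * db
      g <- matrix((ws * gs + wb * gb) / z, 1, 3)
      list(energy = e, grad = g, idx = term$idx)
    },
    abort_invalid(sprintf("unknown potential term kind '%s'", term$kind))
  )
}

# torsion angle energy/gradient (standard cross-product formulation)
eval_torsion <- function(term, coords) {
  p <- term$params
  idx <- term$idx
  r1 <- coords[idx[1], ]; r2 <- coords[idx[2], ]
  r3 <- coords[idx[3], ]; r4 <- coords[idx[4], ]
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  b2n <- sqrt(sum(b2^2))
  if (n1sq < 1e-12 || n2sq < 1e-12 || b2n < 1e-10) {
    abort_singular("collinear geometry in torsion")
  }
  cosphi <- sum(n1 * n2) / sqrt(n1sq * n2sq)
  sinphi <- sum(n1 * (c(n2[2] * b2[3] - n2[3] * b2[2],
                        n2[3] * b2[1] - n2[1] * b2[3],
                        n2[1] * b2[2] - n2[2] * b2[1]))) / (sqrt(n1sq * n2sq) * b2n)
  # equivalently phi = atan2(|b2| b1 . n2, n1 . n2)
  phi <- atan2(sum(b1 * n2) * b2n, sum(n1 * n2))
  e <- p$amplitude * (1 + cos(p$periodicity * phi - p$phase))
  dEdphi <- -p$amplitude * p$periodicity * sin(p$periodicity * phi - p$phase)
  dphi1 <- -(b2n / n1sq) * n1
  dphi4 <- (b2n / n2sq) * n2
  c12 <- sum(b1 * b2) / b2n^2
  c32 <- sum(b3 * b2) / b2n^2
  dphi2 <- -(1 + c12) * dphi1 + c32 * dphi4
  dphi3 <- c12 * dphi1 - (1 + c32) * dphi4   # translation invariance
  g <- rbind(dphi1, dphi2, dphi3, dphi4) * dEdphi
  list(energy = e, grad = g, idx = idx)
}

#' Molecular-mechanics energy and gradient
#'
#' Sums the supplied potential terms at the given coordinates and returns the
#' total energy together with its exact analytic gradient.
#'
#' @param coords N x 3 numeric matrix of coordinates (A).
#' @param terms list of [potential_terms].
#' @param subset optional integer vector of particle indices: only terms whose
#'   participants all lie in `subset` are evaluated.
#' @return list with `energy` (kcal/mol) and `gradient` (N x 3, kcal/mol/A).
#' @export
mm_energy <- function(coords, terms, subset = NULL) {
  coords <- as_coord_matrix(coords)
  if (any(!is.finite(coords))) abort_invalid("`coords` must be finite")
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    terms <- Filter(function(tm) all(tm$idx %in% subset), terms)
  }
  e <- 0
  g <- matrix(0, nrow(coords), 3)
  for (tm in terms) {
    if (any(tm$idx < 1L | tm$idx > nrow(coords))) {
      abort_invalid("term participant index out of range")
    }
    ev <- eval_term(tm, coords)
    e <- e + ev$energy
    g[ev$idx, ] <- g[ev$idx, ] + ev$grad
  }
  list(energy = e, gradient = g)
}

as_coord_matrix <- function(coords) {
  if (is.matrix(coords)) {
    if (ncol(coords) != 3) abort_invalid("`coords` matrix must have 3 columns")
    return(coords)
  }
  if (length(coords) %% 3 != 0) abort_invalid("`coords` length must be a multiple of 3")
  matrix(coords, ncol = 3, byrow = TRUE)
}

# ---- surrogate intramolecular potential --------------------------------

#' Surrogate intramolecular potential parameters
#'
#' A fixed, seeded, smooth stand-in for a neural network potential over a
#' ligand's internal geometry: a weighted Gaussian radial basis over all
#' intra-ligand pairwise distances. It honours the contract an NNP provides
#' in a hybrid NNP/MM scheme -- smooth (C-infinity), invariant to rigid
#' translation and rotation, gradient-bearing -- without any training.
#'
#' @param seed integer; fixes the basis weights.
#' @param n_basis number of radial basis functions.
#' @param centers basis centers (A); defaults to an even grid on `[1, 6]` A.
#' @param width common Gaussian width (A).
#' @param weight_scale standard deviation of the seeded weights (kcal/mol).
#' @param cutoff pair-distance cutoff (A); pairs beyond it contribute nothing.
#' @return a `surrogate_params` object.
#' @export
surrogate_params <- function(seed, n_basis = 8, centers = NULL, width = 0.75,
                             weight_scale = 0.5, cutoff = Inf) {
  check_positive(width, "width")
  centers <- centers %||% seq(1, 6, length.out = n_basis)
  weights <- with_stream(derive_seed(seed, 71L), rnorm(length(centers), 0, weight_scale))
  structure(list(seed = as.integer(seed), centers = as.numeric(centers),
                 width = width, weights = weights, cutoff = cutoff),
            class = "surrogate_params")
}

#' Surrogate (NNP-style) energy of a ligand's internal geometry
#'
#' @param lig_coords M x 3 coordinates of the ligand's particles (A).
#' @param params a [surrogate_params()] object.
#' @return list with `energy` (kcal/mol) and `gradient` (M x 3).
#' @export
surrogate_energy <- function(lig_coords, params) {
  lig_coords <- as_coord_matrix(lig_coords)
  if (any(!is.finite(lig_coords))) abort_invalid("`lig_coords` must be finite")
  m <- nrow(lig_coords)
  e <- 0
  g <- matrix(0, m, 3)
  if (m < 2) return(list(energy = 0, gradient = g))
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      dvec <- lig_coords[i, ] - lig_coords[j, ]
      d <- sqrt(sum(dvec^2))
      if (d > params$cutoff || d < 1e-10) next
      z <- (d - params$centers) / params$width
      phi <- exp(-0.5 * z^2)
      e <- e + sum(params$weights * phi)
      dEdd <- sum(params$weights * phi * (-z / params$width))
      g[i, ] <- g[i, ] + dEdd * dvec / d
      g[j, ] <- g[j, ] - dEdd * dvec / d
    }
  }
  list(energy = e, gradient = g)
}

# ---- hybrid decomposition ----------------------------------------------

# ligand-intramolecular: every participant in one ligand group AND the term
# does not anchor to a fixed point in space (tethers model the environment).
INTERNAL_KINDS <- c("harmonic_bond", "lennard_jones_pair", "coulomb_pair",
                    "torsion_cosine")

classify_term <- function(term, lig_a, lig_b) {
  in_a <- term$idx %in% lig_a
  in_b <- term$idx %in% lig_b
  if (any(in_a) && any(in_b)) {
    abort_classification("potential term spans both ligand groups")
  }
  if (term$kind %in% INTERNAL_KINDS) {
    if (all(in_a)) return("intra_A")
    if (all(in_b)) return("intra_B")
  }
  if (any(in_a) || any(in_b)) return("ligand_env")
  "env"
}

#' Hybrid (surrogate/MM) energy of a toy system
#'
#' In `mm` mode this is the plain MM energy of all terms. In `hybrid` mode
#' each ligand's intramolecular MM terms are replaced by the surrogate
#' potential of its internal geometry -- the NNP/MM-style mechanical
#' embedding: environment and ligand-environment terms stay MM and are
#' bit-identical between modes.
#'
#' @param coords N x 3 coordinates (A); defaults to the system's own.
#' @param system a [toy_system].
#' @param mode `"mm"` or `"hybrid"`.
#' @param surrogate a [surrogate_params()] object, or a list with elements
#'   `A` and `B` for per-ligand surrogates. Required in hybrid mode only if a
#'   ligand has intramolecular terms or more than one particle.
#' @param components if `TRUE` (default) also return the energy breakdown;
#'   the force path inside the samplers switches it off.
#' @return list with `energy`, `gradient`, and (optionally) a `components`
#'   breakdown (env, ligand_env, intra mm per ligand, surrogate per ligand),
#'   kcal/mol.
#' @export
hybrid_energy <- function(coords, system, mode = c("mm", "hybrid"),
                          surrogate = NULL, components = TRUE) {
  mode <- match.arg(mode)
  coords <- as_coord_matrix(coords)
  cls <- system$term_class %||%
    vapply(system$terms, classify_term, character(1),
           lig_a = system$ligand_a, lig_b = system$ligand_b)
  full <- mm_energy(coords, system$terms)
  intra <- list(A = which(cls == "intra_A"), B = which(cls == "intra_B"))
  comp <- if (components) list(
    env = sum_terms(coords, system$terms[cls == "env"]),
    ligand_env = sum_terms(coords, system$terms[cls == "ligand_env"]),
    intra_mm_A = sum_terms(coords, system$terms[intra$A]),
    intra_mm_B = sum_terms(coords, system$terms[intra$B])
  )
  if (mode == "mm") {
    out <- list(energy = full$energy, gradient = full$gradient)
    if (components) out$components <- c(comp, list(surrogate_A = 0, surrogate_B = 0))
    return(out)
  }
  e <- full$energy
  g <- full$gradient
  surr <- list(A = 0, B = 0)
  for (lig in c("A", "B")) {
    idx <- if (lig == "A") system$ligand_a else system$ligand_b
    has_internal <- length(intra[[lig]]) > 0 || length(idx) > 1
    if (!has_internal) next
    sp <- surrogate_for(surrogate, lig)
    if (is.null(sp)) abort_invalid(
      sprintf("hybrid mode requires a surrogate for multi-particle ligand %s", lig))
    mm_in <- mm_energy(coords, system$terms[intra[[lig]]])
    su <- surrogate_energy(coords[idx, , drop = FALSE], sp)
    e <- e - mm_in$energy + su$energy
    g <- g - mm_in$gradient
    g[idx, ] <- g[idx, ] + su$gradient
    surr[[lig]] <- su$energy
  }
  out <- list(energy = e, gradient = g)
  if (components) {
    out$components <- c(comp, list(surrogate_A = surr$A, surrogate_B = surr$B))
  }
  out
}

surrogate_for <- function(surrogate, lig) {
  if (is.null(surrogate)) return(NULL)
  if (inherits(surrogate, "surrogate_params")) return(surrogate)
  surrogate[[lig]]
}

sum_terms <- function(coords, terms) {
  if (length(terms) == 0) return(0)
  mm_energy(coords, terms)$energy
}

#' Text dump of an energy decomposition
#'
#' @param decomp the `components` element returned by [hybrid_energy()].
#' @return a character vector, one `component = value kcal/mol` line each.
#' @export
format_energy_decomposition <- function(decomp) {
  vapply(names(decomp), function(nm) {
    sprintf("%-12s %14.6f kcal/mol", nm, decomp[[nm]])
  }, character(1))
}
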