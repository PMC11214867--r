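#' Soft-core parameters
#'
#' @param umax upper bound of the capped perturbation energy (kcal/mol).
#' @param uc onset of the cap (kcal/mol); below it the soft-core is the
#'   identity.
#' @param a dimensionless sharpness exponent.
#' @return a `softcore_params` list.
#' @export
softcore_params <- function(umax = 200, uc = 100, a = 1 / 16) {
  check_finite(umax, "umax"); check_finite(uc, "uc"); check_positive(a, "a")
  if (umax <= uc) abort_invalid("`umax` must exceed `uc`")
  structure(list(umax = umax, uc = uc, a = a), class = "softcore_params")
}

#' Alchemical state (one lambda window)
#'
#' One window of the ATM lambda path. With `lam1 == lam2 == lam` the bias is
#' linear coupling `W = lam * u + w0`; otherwise the softplus form of
#' [alchemical_bias()] is used. `leg` records the transfer direction: leg 1
#' starts from the physical basin (A bound, B solvated), leg 2 from the
#' swapped basin.
#'
#' @param lam lambda in `[0, 1/2]`.
#' @param leg 1 or 2.
#' @param lam1,lam2 softplus slopes (dimensionless).
#' @param alpha softplus steepness, 1/(kcal/mol), >= 0.
#' @param u0 softplus midpoint (kcal/mol). @param w0 offset (kcal/mol).
#' @param softcore a [softcore_params()] object.
#' @return an `alchemical_state` object.
#' @export
alchemical_state <- function(lam, leg = 1L, lam1 = lam, lam2 = lam,
                             alpha = 0.1, u0 = 110, w0 = 0,
                             softcore = softcore_params()) {
  if (lam < 0 || lam > 0.5) abort_invalid("`lam` must be in [0, 1/2]")
  if (!leg %in% c(1L, 2L)) abort_invalid("`leg` must be 1 or 2")
  if (alpha < 0) abort_invalid("`alpha` must be >= 0")
  if (alpha == 0 && lam1 != lam2) {
    abort_invalid("`alpha` = 0 with lam1 != lam2 has no well-defined limit")
  }
  structure(list(lam = lam, leg = as.integer(leg), lam1 = lam1, lam2 = lam2,
                 alpha = alpha, u0 = u0, w0 = w0, softcore = softcore),
            class = "alchemical_state")
}

#' Swap transform: exchange ligands between site and bulk
#'
#' Rigidly translates the ligand group currently nearer the binding site by
#' `+displacement` (site to bulk) and the other group by `-displacement`
#' (bulk to site); environment particles are untouched. Because the roles are
#' assigned by proximity, applying the transform twice restores the input
#' exactly (an involution), which makes the perturbation energy antisymmetric.
#'
#' @param coords N x 3 coordinates (A).
#' @param system a [toy_system].
#' @return transformed N x 3 coordinates.
#' @export
swap_transform <- function(coords, system) {
  coords <- as_coord_matrix(coords)
  a <- system$ligand_a
  b <- system$ligand_b
  if (length(intersect(a, b)) > 0) abort_classification("overlapping ligand groups")
  cen_a <- colMeans(coords[a, , drop = FALSE])
  cen_b <- colMeans(coords[b, , drop = FALSE])
  d <- system$displacement
  da <- sum((cen_a - system$site_center)^2)
  db <- sum((cen_b - system$site_center)^2)
  out <- coords
  if (da <= db) {  # A occupies the site: A -> bulk, B -> site
    out[a, ] <- sweep(coords[a, , drop = FALSE], 2, d, "+")
    out[b, ] <- sweep(coords[b, , drop = FALSE], 2, d, "-")
  } else {
    out[a, ] <- sweep(coords[a, , drop = FALSE], 2, d, "-")
    out[b, ] <- sweep(coords[b, , drop = FALSE], 2, d, "+")
  }
  out
}

#' ATM perturbation energy
#'
#' The single collective variable the Alchemical Transfer Method biases:
#' `u(x) = E(swap(x)) - E(x)`, the energy change of rigidly swapping the two
#' ligands between site and bulk, evaluated in `mm` or `hybrid` mode.
#'
#' @inheritParams hybrid_energy
#' @param gradient if `TRUE`, also return the gradient of `u`.
#' @return the scalar `u` (kcal/mol), or a list `(u, gradient)` if
#'   `gradient = TRUE`.
#' @export
perturbation_energy <- function(coords, system, mode = c("mm", "hybrid"),
                                surrogate = NULL, gradient = FALSE) {
  mode <- match.arg(mode)
  coords <- as_coord_matrix(coords)
  swapped <- swap_transform(coords, system)
  e0 <- hybrid_energy(coords, system, mode, surrogate, components = FALSE)
  e1 <- hybrid_energy(swapped, system, mode, surrogate, components = FALSE)
  if (!gradient) return(e1$energy - e0$energy)
  # swap is a per-particle constant translation, so d/dx E(swap(x)) is the
  # gradient of E evaluated at the swapped coordinates
  list(u = e1$energy - e0$energy, gradient = e1$gradient - e0$gradient)
}

#' Soft-core capping of the perturbation energy
#'
#' Identity below `uc`; above it, a strictly increasing C1 rational transform
#' bounded by `umax`:
#' `u_sc = uc + (umax - uc) (z^(1/a) - 1)/(z^(1/a) + 1)` with
#' `z = 1 + 2 y + 2 y^2` and `y = a (u - uc)/(umax - uc)`. The joint at
#' `u = uc` has slope exactly 1 on both sides.
#'
#' @param u perturbation energies (kcal/mol), vectorized.
#' @param sc a [softcore_params()] object.
#' @return capped energies `u_sc` (kcal/mol).
#' @export
softcore <- function(u, sc = softcore_params()) {
  out <- u
  hi <- which(u > sc$uc)
  if (length(hi) > 0) {
    y <- sc$a * (u[hi] - sc$uc) / (sc$umax - sc$uc)
    # f = (z^(1/a)-1)/(z^(1/a)+1) = tanh(log(z)/(2a)); stable for huge z
    f <- tanh(log1p(2 * y + 2 * y^2) / (2 * sc$a))
    out[hi] <- sc$uc + (sc$umax - sc$uc) * f
  }
  out
}

# d u_sc / d u, vectorized
softcore_deriv <- function(u, sc = softcore_params()) {
  out <- rep(1, length(u))
  hi <- which(u > sc$uc)
  if (length(hi) > 0) {
    y <- sc$a * (u[hi] - sc$uc) / (sc$umax - sc$uc)
    z <- 1 + 2 * y + 2 * y^2
    f <- tanh(log(z) / (2 * sc$a))
    # d f/d y = (1 - f^2) * z'/(2 a z)
    out[hi] <- (1 - f^2) * (2 + 4 * y) / (2 * z)
  }
  out
}

#' Softplus alchemical bias
#'
#' The ATM coupling function
#' `W(u) = lam2 u + ((lam1 - lam2)/alpha) log(1 + exp(-alpha (u - u0))) + w0`,
#' computed with an overflow-safe softplus. When `lam1 == lam2 == lam` it
#' reduces exactly to linear coupling `W = lam u + w0`.
#'
#' @param u_sc (soft-core capped) perturbation energies, kcal/mol; vectorized.
#' @param state an [alchemical_state()].
#' @return bias energies W (kcal/mol).
#' @export
alchemical_bias <- function(u_sc, state) {
  if (state$lam1 == state$lam2) {
    return(state$lam2 * u_sc + state$w0)
  }
  sp <- softplus(-state$alpha * (u_sc - state$u0))
  state$lam2 * u_sc + (state$lam1 - state$lam2) / state$alpha * sp + state$w0
}

# d W / d u_sc, vectorized: the softplus term differentiates to
# -alpha * plogis(-alpha (u - u0)), so the slope runs from 2 lam2 - lam1
# (u -> -Inf) to lam2 (u -> +Inf)
alchemical_bias_deriv <- function(u_sc, state) {
  if (state$lam1 == state$lam2) return(rep(state$lam2, length(u_sc)))
  state$lam2 - (state$lam1 - state$lam2) *
    stats::plogis(-state$alpha * (u_sc - state$u0))
}

#' Total alchemical potential and gradient
#'
#' `U_lambda(x) = E(x) + W(softcore(u(x)))`; the gradient follows by the
#' chain rule. At `lam1 = lam2 = 0`, `w0 = 0` this is the plain potential.
#'
#' @inheritParams perturbation_energy
#' @param state an [alchemical_state()].
#' @return list with `energy`, `gradient`, and the uncapped perturbation
#'   energy `u` (all kcal/mol-based).
#' @export
total_alchemical_energy <- function(coords, system, state,
                                    mode = c("mm", "hybrid"), surrogate = NULL) {
  mode <- match.arg(mode)
  coords <- as_coord_matrix(coords)
  swapped <- swap_transform(coords, system)
  e0 <- hybrid_energy(coords, system, mode, surrogate, components = FALSE)
  e1 <- hybrid_energy(swapped, system, mode, surrogate, components = FALSE)
  u <- e1$energy - e0$energy
  gu <- e1$gradient - e0$gradient
  usc <- softcore(u, state$softcore)
  w <- alchemical_bias(usc, state)
  dw <- alchemical_bias_deriv(usc, state) * softcore_deriv(u, state$softcore)
  list(energy = e0$energy + w,
       gradient = e0$gradient + dw * gu,
       u = u)
}

#' Lambda schedules for the two ATM legs
#'
#' Evenly spaced lambda values from 0 to the symmetric intermediate 1/2,
#' inclusive. `family = "linear"` sets `lam1 = lam2 = lam` (linear coupling);
#' `family = "softplus-defaults"` uses the softplus ladder `lam1 =
#' min(2 lam, 1/2)`, `lam2 = max(0, 2 lam - 1/2)` with the standard ATM
#' parameters `alpha = 0.1`, `u0 = 110`, `w0 = 0`. Both legs share the same
#' grid and differ only in the direction flag.
#'
#' @param n_windows number of windows (>= 2).
#' @param leg 1 or 2.
#' @param family `"linear"` or `"softplus-defaults"`.
#' @param softcore a [softcore_params()] object shared by all windows.
#' @return list of [alchemical_state()] objects, lambda increasing.
#' @export
lambda_schedule <- function(n_windows = 11, leg = 1L,
                            family = c("linear", "softplus-defaults"),
                            softcore = softcore_params()) {
  family <- match.arg(family)
  if (n_windows < 2) abort_invalid("`n_windows` must be >= 2")
  lams <- seq(0, 0.5, length.out = n_windows)
  lapply(lams, function(l) {
    if (family == "linear") {
      alchemical_state(l, leg = leg, softcore = softcore)
    } else {
      alchemical_state(l, leg = leg, lam1 = min(2 * l, 0.5),
                       lam2 = max(0, 2 * l - 0.5), softcore = softcore)
    }
  })
}
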