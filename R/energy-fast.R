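# Compiled-closure energy path used by the samplers.
#
# The exported mm_energy()/hybrid_energy()/total_alchemical_energy() are the
# readable reference implementations; the Langevin loop calls closures built
# here, which unpack term parameters once instead of on every step. A
# property test asserts both paths agree to machine precision.

compile_term <- function(term) {
  p <- term$params
  idx <- term$idx
  switch(term$kind,
    harmonic_bond = {
      i <- idx[1]; j <- idx[2]; k <- p$k; r0 <- p$r0
      function(coords) {
        dvec <- coords[i, ] - coords[j, ]
        r <- sqrt(sum(dvec^2))
        f <- if (r > 1e-10) k * (r - r0) / r else 0
        list(e = 0.5 * k * (r - r0)^2, g = rbind(f * dvec, -f * dvec), idx = idx)
      }
    },
    harmonic_tether = {
      i <- idx[1]; k <- p$k; r0 <- p$r0; cen <- p$center
      if (r0 == 0) {
        function(coords) {
          dvec <- coords[i, ] - cen
          list(e = 0.5 * k * sum(dvec^2), g = matrix(k * dvec, 1, 3), idx = idx)
        }
      } else {
        function(coords) {
          dvec <- coords[i, ] - cen
          r <- sqrt(sum(dvec^2))
          if (r < 1e-10) abort_singular("particle at tether center with r0 > 0")
          list(e = 0.5 * k * (r - r0)^2,
               g = matrix(k * (r - r0) / r * dvec, 1, 3), idx = idx)
        }
      }
    },
    lennard_jones_pair = {
      i <- idx[1]; j <- idx[2]; eps <- p$eps; sig2 <- p$sigma^2
      function(coords) {
        dvec <- coords[i, ] - coords[j, ]
        r2 <- sum(dvec^2)
        if (r2 < 1e-12) abort_singular("coincident particles in Lennard-Jones pair")
        sr6 <- (sig2 / r2)^3
        f_over_r <- 24 * eps * (sr6 - 2 * sr6^2) / r2
        list(e = 4 * eps * (sr6^2 - sr6),
             g = rbind(f_over_r * dvec, -f_over_r * dvec), idx = idx)
      }
    },
    coulomb_pair = {
      i <- idx[1]; j <- idx[2]
      pref <- COULOMB_KCAL * p$qi * p$qj / p$eps_r
      function(coords) {
        dvec <- coords[i, ] - coords[j, ]
        r <- sqrt(sum(dvec^2))
        if (r < 1e-6) abort_singular("coincident particles in Coulomb pair")
        f_over_r <- -pref / r^3
        list(e = pref / r, g = rbind(f_over_r * dvec, -f_over_r * dvec), idx = idx)
      }
    },
    torsion_cosine = {
      force(term)
      function(coords) {
        ev <- eval_torsion(term, coords)
        list(e = ev$energy, g = ev$grad, idx = idx)
      }
    },
    double_well_tether = {
      i <- idx[1]; ks <- p$k_site; kb <- p$k_bulk
      cs <- p$site_center; cb <- p$bulk_center; kT <- p$kT
      function(coords) {
        ds <- coords[i, ] - cs
        db <- coords[i, ] - cb
        es <- 0.5 * ks * sum(ds^2)
        eb <- 0.5 * kb * sum(db^2)
        m <- if (es < eb) es else eb
        ws <- exp(-(es - m) / kT)
        wb <- exp(-(eb - m) / kT)
        z <- ws + wb
        list(e = m - kT * log(z),
             g = matrix((ws * ks * ds + wb * kb * db) / z, 1, 3), idx = idx)
      }
    },
    abort_invalid(sprintf("unknown potential term kind '%s'", term$kind))
  )
}

# function(coords) -> list(energy, gradient) for the requested mode
build_hybrid_fn <- function(system, mode = "mm", surrogate = NULL) {
  fns <- lapply(system$terms, compile_term)
  n <- system$n
  if (mode == "mm") {
    return(function(coords) {
      e <- 0
      g <- matrix(0, n, 3)
      for (fn in fns) {
        ev <- fn(coords)
        e <- e + ev$e
        g[ev$idx, ] <- g[ev$idx, ] + ev$g
      }
      list(energy = e, gradient = g)
    })
  }
  cls <- system$term_class
  spec <- list()
  for (lig in c("A", "B")) {
    idx <- if (lig == "A") system$ligand_a else system$ligand_b
    intra <- which(cls == paste0("intra_", lig))
    if (length(intra) == 0 && length(idx) < 2) next
    sp <- surrogate_for(surrogate, lig)
    if (is.null(sp)) abort_invalid(
      sprintf("hybrid mode requires a surrogate for multi-particle ligand %s", lig))
    spec[[lig]] <- list(idx = idx, intra_fns = lapply(system$terms[intra], compile_term),
                        sp = sp)
  }
  function(coords) {
    e <- 0
    g <- matrix(0, n, 3)
    for (fn in fns) {
      ev <- fn(coords)
      e <- e + ev$e
      g[ev$idx, ] <- g[ev$idx, ] + ev$g
    }
    for (s in spec) {
      for (fn in s$intra_fns) {
        ev <- fn(coords)
        e <- e - ev$e
        g[ev$idx, ] <- g[ev$idx, ] - ev$g
      }
      su <- surrogate_energy(coords[s$idx, , drop = FALSE], s$sp)
      e <- e + su$energy
      g[s$idx, ] <- g[s$idx, ] + su$gradient
    }
    list(energy = e, gradient = g)
  }
}

# function(coords) -> list(energy, gradient, u) for one alchemical state
build_alch_fn <- function(system, state, mode = "mm", surrogate = NULL) {
  hfn <- build_hybrid_fn(system, mode, surrogate)
  a <- system$ligand_a
  b <- system$ligand_b
  d <- system$displacement
  site <- system$site_center
  na <- length(a); nb <- length(b)
  sc <- state$softcore
  da_mat <- matrix(d, na, 3, byrow = TRUE)
  db_mat <- matrix(d, nb, 3, byrow = TRUE)
  function(coords) {
    ca <- .colMeans(coords[a, , drop = FALSE], na, 3)
    cb <- .colMeans(coords[b, , drop = FALSE], nb, 3)
    sa <- sum((ca - site)^2) <= sum((cb - site)^2)
    swapped <- coords
    if (sa) {
      swapped[a, ] <- coords[a, , drop = FALSE] + da_mat
      swapped[b, ] <- coords[b, , drop = FALSE] - db_mat
    } else {
      swapped[a, ] <- coords[a, , drop = FALSE] - da_mat
      swapped[b, ] <- coords[b, , drop = FALSE] + db_mat
    }
    e0 <- hfn(coords)
    e1 <- hfn(swapped)
    u <- e1$energy - e0$energy
    # scalar soft-core + bias with chain-rule factor
    if (u <= sc$uc) {
      usc <- u
      dusc <- 1
    } else {
      y <- sc$a * (u - sc$uc) / (sc$umax - sc$uc)
      z <- 1 + 2 * y + 2 * y^2
      f <- tanh(log(z) / (2 * sc$a))
      usc <- sc$uc + (sc$umax - sc$uc) * f
      dusc <- (1 - f^2) * (2 + 4 * y) / (2 * z)
    }
    if (state$lam1 == state$lam2) {
      w <- state$lam2 * usc + state$w0
      dw <- state$lam2
    } else {
      t <- -state$alpha * (usc - state$u0)
      sp <- if (t > 0) t + log1p(exp(-t)) else log1p(exp(t))
      w <- state$lam2 * usc + (state$lam1 - state$lam2) / state$alpha * sp + state$w0
      dw <- state$lam2 - (state$lam1 - state$lam2) * stats::plogis(t)
    }
    list(energy = e0$energy + w,
         gradient = e0$gradient + (dw * dusc) * (e1$gradient - e0$gradient),
         u = u)
  }
}
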