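# Independent oracles, written without reference to the package internals.

# Multistate-reweighting oracle: direct maximisation of the pooled-sample
# log-likelihood L(f) = sum_k N_k f_k - sum_n log sum_l N_l exp(f_l - B_ln)
# by quasi-Newton on the free components, no self-consistent iteration.
uwham_oracle <- function(B, N) {
  K <- nrow(B)
  nll <- function(ffree) {
    f <- c(0, ffree)
    tot <- 0
    for (n in seq_len(ncol(B))) {
      a <- log(N) + f - B[, n]
      m <- max(a)
      tot <- tot + m + log(sum(exp(a - m)))
    }
    tot - sum(N * f)
  }
  gr <- function(ffree) {
    f <- c(0, ffree)
    acc <- numeric(K)
    for (n in seq_len(ncol(B))) {
      a <- log(N) + f - B[, n]
      m <- max(a)
      w <- exp(a - m)
      acc <- acc + w / sum(w)
    }
    (acc - N)[-1]
  }
  f0 <- numeric(K - 1)
  opt <- stats::optim(f0, nll, gr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  opt2 <- stats::optim(opt$par, nll, gr, method = "BFGS",
                       control = list(maxit = 5000, reltol = 1e-16))
  c(0, opt2$par)
}

# 3D harmonic partition function by numerical radial quadrature
z_harmonic_quadrature <- function(k, kT) {
  stats::integrate(function(r) 4 * pi * r^2 * exp(-0.5 * k * r^2 / kT),
                   0, Inf, rel.tol = 1e-12)$value
}

ddg_quadrature <- function(k_site_A, k_bulk_A, k_site_B, k_bulk_B, kT) {
  lz <- function(k) log(z_harmonic_quadrature(k, kT))
  -kT * (lz(k_bulk_A) + lz(k_site_B) - lz(k_site_A) - lz(k_bulk_B))
}

# Exhaustive O(n^2) Kendall tau-b
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(vapply(table(x), function(m) m * (m - 1) / 2, numeric(1)))
  ty <- sum(vapply(table(y), function(m) m * (m - 1) / 2, numeric(1)))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Generic weighted least squares for the node free energies: design matrix
# with one row per edge (-1 at i, +1 at j), augmented with a sum-to-zero
# gauge row, solved by QR -- no Laplacian pseudo-inverse involved.
network_ls_oracle <- function(edges) {
  ids <- sort(unique(c(edges$ligand_i, edges$ligand_j)))
  m <- length(ids)
  X <- matrix(0, nrow(edges), m)
  X[cbind(seq_len(nrow(edges)), match(edges$ligand_i, ids))] <- -1
  X[cbind(seq_len(nrow(edges)), match(edges$ligand_j, ids))] <- 1
  w <- 1 / edges$sigma_calc^2
  Xa <- rbind(sqrt(w) * X, rep(1, m))
  ya <- c(sqrt(w) * edges$ddg_calc, 0)
  stats::setNames(as.numeric(qr.solve(Xa, ya)), ids)
}

# Central finite-difference gradient of a scalar energy function
fd_gradient <- function(efn, coords, h = 1e-6) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + h
      xm <- coords; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (efn(xp) - efn(xm)) / (2 * h)
    }
  }
  g
}
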