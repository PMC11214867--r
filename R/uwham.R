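#' Perturbation-energy samples for multistate reweighting
#'
#' Packages per-state perturbation-energy time series into the cross
#' evaluated reduced bias-energy matrix UWHAM consumes:
#' `bias_matrix[k, n] = W_k(softcore(u_n)) / kT` for every recorded sample n
#' and every lambda state k. The configurational part of the potential is
#' common to all states for a given sample and cancels from the estimator
#' (a per-sample constant column shift), so only the bias enters.
#'
#' @param u_by_state list of numeric vectors: the uncapped perturbation
#'   energies recorded while the system occupied each state, kcal/mol.
#' @param states list of [alchemical_state()] of the same length.
#' @param kT thermal energy, kcal/mol.
#' @param leg,replicate identifiers carried along.
#' @return a `perturbation_samples` object with fields `bias_matrix` (K x N),
#'   `sample_counts`, `u_by_state`, `lambda`, `kT`, `leg`, `replicate`.
#' @export
perturbation_samples <- function(u_by_state, states, kT, leg = 1L,
                                 replicate = 1L) {
  K <- length(states)
  if (length(u_by_state) != K) {
    abort_invalid("`u_by_state` must have one entry per state")
  }
  u_all <- unlist(u_by_state, use.names = FALSE)
  if (any(!is.finite(u_all))) abort_invalid("perturbation energies must be finite")
  counts <- lengths(u_by_state)
  B <- matrix(0, K, length(u_all))
  for (k in seq_len(K)) {
    st <- states[[k]]
    B[k, ] <- alchemical_bias(softcore(u_all, st$softcore), st) / kT
  }
  structure(list(
    bias_matrix = B,
    sample_counts = as.integer(counts),
    u_by_state = u_by_state,
    lambda = vapply(states, function(s) s$lam, numeric(1)),
    states = states,
    kT = kT, leg = as.integer(leg), replicate = as.integer(replicate)
  ), class = "perturbation_samples")
}

#' Thin correlated samples by their statistical inefficiency
#'
#' Estimates the statistical inefficiency g of each state's perturbation
#' energy series and keeps every ceiling(g)-th sample, so the UWHAM
#' asymptotic error bar (which assumes independent samples) stays calibrated
#' for correlated dynamics output.
#'
#' @param samples a [perturbation_samples] object.
#' @return a thinned `perturbation_samples`.
#' @export
subsample_samples <- function(samples, ...) {
  thinned <- lapply(samples$u_by_state, function(u) {
    g <- statistical_inefficiency(u)
    u[seq.int(1L, length(u), by = max(1L, ceiling(g)))]
  })
  perturbation_samples(thinned, samples$states, samples$kT,
                       leg = samples$leg, replicate = samples$replicate)
}

#' UWHAM: multistate free energy estimation
#'
#' Solves the Unbinned Weighted Histogram Analysis Method self-consistent
#' equations
#' \deqn{f_k = -\ln \sum_n \frac{e^{-B_{kn}}}{\sum_l N_l e^{f_l - B_{ln}}}}
#' (log-sum-exp stabilised, gauge `f_1 = 0`) for the reduced free energy of
#' every lambda state, switching to direct quasi-Newton maximisation of the
#' UWHAM log-likelihood if self-consistent iteration stalls. The free energy
#' difference of the leg is `dG = kT (f_K - f_1)`; its uncertainty comes
#' from the asymptotic (information-matrix) covariance of the estimator.
#'
#' States with zero samples of their own are allowed (they are estimated by
#' reweighting only, as in the one-sided exponential-average limit).
#'
#' @param samples a [perturbation_samples] object.
#' @param tol convergence tolerance on the self-consistent residual
#'   (max abs change of f per iteration, reduced units).
#' @param max_iter iteration cap.
#' @return an `fe_result`: list with `f` (reduced free energies, `f[1] = 0`),
#'   `dg`, `sigma` (kcal/mol), `kT`, `iterations`, `residual`, `converged`,
#'   `overlap_warning`, `leg`, `replicate`.
#' @export
uwham_solve <- function(samples, tol = 1e-10, max_iter = 5000L) {
  B <- samples$bias_matrix
  N <- samples$sample_counts
  K <- nrow(B)
  n_tot <- ncol(B)
  if (K < 2) abort_invalid("UWHAM needs at least 2 states")
  if (sum(N) != n_tot) abort_invalid("sample counts do not match the bias matrix")
  logN <- ifelse(N > 0, log(N), -Inf)
  f <- numeric(K)
  sc_update <- function(f) {
    # log denominator per sample: logsumexp_l (logN_l + f_l - B_ln)
    logD <- col_logsumexp(logN + f - B)
    fn <- vapply(seq_len(K), function(k) {
      x <- -B[k, ] - logD
      mm <- max(x)
      -(mm + log(sum(exp(x - mm))))
    }, numeric(1))
    fn - fn[1]
  }
  negll <- function(ffree) {
    f <- c(0, ffree)
    -(sum(N * f) - sum(col_logsumexp(logN + f - B)))
  }
  negll_grad <- function(ffree) {
    f <- c(0, ffree)
    C <- weight_matrix(B, N, f)
    -(N - rowSums(C))[-1]
  }
  iter <- 0L
  residual <- Inf
  used_direct <- FALSE
  prev_residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    fn <- sc_update(f)
    residual <- max(abs(fn - f))
    f <- fn
    if (residual < tol) break
    # stall detection: residual barely shrinking -> direct minimisation
    if (iter %% 200L == 0L) {
      if (residual > 0.5 * prev_residual && K >= 2) {
        opt <- optim(f[-1], negll, negll_grad, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
        f <- c(0, opt$par)
        used_direct <- TRUE
        fn <- sc_update(f)
        residual <- max(abs(fn - f))
        f <- fn
        if (residual < tol) break
      }
      prev_residual <- residual
    }
  }
  converged <- residual < tol
  if (!converged) {
    abort_convergence(sprintf(
      "UWHAM did not converge in %d iterations (residual %.3e)", iter, residual),
      residual = residual)
  }
  C <- weight_matrix(B, N, f)
  s <- rowSums(C)
  overlap_warning <- any(N > 0 & s < 1e-3)
  if (overlap_warning) {
    warn("at least one state has near-zero effective overlap with the pooled samples")
  }
  theta <- uwham_covariance(B, N, f)
  var_dg <- theta[K, K] + theta[1, 1] - 2 * theta[K, 1]
  structure(list(
    f = f,
    dg = samples$kT * (f[K] - f[1]),
    sigma = samples$kT * sqrt(max(var_dg, 0)),
    kT = samples$kT,
    lambda = samples$lambda,
    iterations = iter,
    residual = residual,
    converged = converged,
    used_direct = used_direct,
    overlap_warning = overlap_warning,
    leg = samples$leg,
    replicate = samples$replicate
  ), class = "fe_result")
}

# Asymptotic covariance of the reduced free energies: the multistate
# reweighting result Theta = W^T (I_N - W diag(N) W^T)^+ W with
# W[n, k] = exp(f_k - B_kn) / sum_l N_l exp(f_l - B_ln), evaluated through
# the thin SVD of W so only K x K matrices are inverted.
uwham_covariance <- function(B, N, f) {
  K <- nrow(B)
  logN <- ifelse(N > 0, log(N), -Inf)
  logD <- col_logsumexp(logN + f - B)
  W <- t(exp(sweep(f - B, 2, logD)))   # N x K, columns sum to 1
  sv <- svd(W)
  M <- diag(K) - (sv$d * t(sv$v)) %*% (N * sv$v) * rep(sv$d, each = K)
  # M = I - Sigma V^T diag(N) V Sigma; its gauge mode is analytically
  # singular but lands at ~1e-16 numerically, so cut well above that
  inner <- pinv(M, tol = K * max(abs(M)) * 1e-10)
  V <- sv$v
  theta <- V %*% (sv$d * inner * rep(sv$d, each = K)) %*% t(V)
  (theta + t(theta)) / 2
}

# C[k, n] = N_k exp(f_k - B_kn) / sum_l N_l exp(f_l - B_ln)
weight_matrix <- function(B, N, f) {
  logN <- ifelse(N > 0, log(N), -Inf)
  A <- logN + f - B
  C <- exp(sweep(A, 2, col_logsumexp(A)))
  C[N == 0, ] <- 0
  C
}

# columnwise log-sum-exp of a K x N matrix without apply() overhead
col_logsumexp <- function(A) {
  m <- A[1, ]
  K <- nrow(A)
  if (K > 1) for (k in 2:K) m <- pmax(m, A[k, ])
  m + log(colSums(exp(A - rep(m, each = K))))
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> leg %d replicate %d: dG = %.4f +/- %.4f kcal/mol (%d states, %d iter)\n",
              x$leg, x$replicate, x$dg, x$sigma, length(x$f), x$iterations))
  invisible(x)
}

#' @method tidy fe_result
#' @export
tidy.fe_result <- function(x, ...) {
  tibble(state = seq_along(x$f), lambda = x$lambda, f = x$f,
         g_kcal = x$kT * x$f)
}

#' @method glance fe_result
#' @export
glance.fe_result <- function(x, ...) {
  tibble(dg = x$dg, sigma = x$sigma, n_states = length(x$f),
         iterations = x$iterations, residual = x$residual,
         converged = x$converged, leg = x$leg, replicate = x$replicate)
}

#' Block uncertainty of a UWHAM leg estimate
#'
#' The asymptotic UWHAM error bar assumes independent samples. For replica
#' exchange output the samples of a state are a stitched time series and
#' neighbouring states share replica trajectories, which the asymptotic
#' formula cannot see. This estimator splits every state's series into
#' contiguous time blocks, solves UWHAM per block, and reports the standard
#' error of the block estimates -- capturing all within- and cross-state
#' correlation at the cost of a few extra small solves.
#'
#' @param samples a [perturbation_samples] object (untreated time series).
#' @param n_blocks contiguous blocks (reduced automatically if a state has
#'   too few samples; at least 3 are required).
#' @return standard error of the leg free energy, kcal/mol.
#' @export
uwham_block_sigma <- function(samples, n_blocks = 8) {
  n_blocks <- min(n_blocks, min(samples$sample_counts))
  if (n_blocks < 3) return(NA_real_)
  dgs <- vapply(seq_len(n_blocks), function(b) {
    chunk <- lapply(samples$u_by_state, function(u) {
      n <- length(u)
      lo <- floor((b - 1) * n / n_blocks) + 1
      hi <- floor(b * n / n_blocks)
      u[lo:hi]
    })
    ps <- perturbation_samples(chunk, samples$states, samples$kT,
                               leg = samples$leg, replicate = samples$replicate)
    uwham_solve(ps, tol = 1e-8)$dg
  }, numeric(1))
  sd(dgs) / sqrt(n_blocks)
}

#' Combine the two ATM legs into a relative binding free energy
#'
#' `ddG = dG_leg1 - dG_leg2` (both legs end at the shared symmetric
#' intermediate, so the intermediate's free energy cancels); the uncertainty
#' adds in quadrature.
#'
#' @param leg1,leg2 converged `fe_result` objects.
#' @return list with `ddg` and `sigma` (kcal/mol).
#' @export
ddg_from_legs <- function(leg1, leg2) {
  for (r in list(leg1, leg2)) {
    if (!isTRUE(r$converged)) {
      abort_convergence("ddg_from_legs requires converged leg estimates")
    }
  }
  list(ddg = leg1$dg - leg2$dg, sigma = sqrt(leg1$sigma^2 + leg2$sigma^2))
}

#' Combine replicate ddG estimates
#'
#' With two or more replicates, returns the unweighted mean and the standard
#' error of the mean (the triplicate protocol's uncertainty); a single
#' replicate passes through its own estimator sigma.
#'
#' @param values list of `(ddg, sigma)` lists (as from [ddg_from_legs()]),
#'   or a numeric vector of ddG values.
#' @return list with `ddg`, `sigma`, `n`.
#' @export
combine_replicates <- function(values) {
  if (is.numeric(values)) values <- lapply(values, function(v) list(ddg = v, sigma = 0))
  if (length(values) == 0) abort_invalid("no replicate values supplied")
  ddgs <- vapply(values, function(v) v$ddg, numeric(1))
  n <- length(ddgs)
  if (n == 1) {
    return(list(ddg = ddgs[1], sigma = values[[1]]$sigma, n = 1L))
  }
  list(ddg = mean(ddgs), sigma = sd(ddgs) / sqrt(n), n = n)
}
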