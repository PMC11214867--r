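# Physical constants (Amber-style units: kcal/mol, Angstrom, ps, Kelvin, amu)
KB_KCAL <- 0.0019872041          # Boltzmann constant, kcal/mol/K
KCAL_TO_AMU_A2_PS2 <- 418.4      # 1 kcal/mol in amu * A^2 / ps^2
COULOMB_KCAL <- 332.0637128      # Coulomb constant, kcal * A / (mol * e^2)

abort_invalid <- function(msg) abort(msg, class = "atmkit_invalid_parameter")
abort_singular <- function(msg) abort(msg, class = "atmkit_singular_geometry")
abort_classification <- function(msg) abort(msg, class = "atmkit_classification_error")
abort_convergence <- function(msg, residual = NA_real_) {
  abort(msg, class = "atmkit_convergence_error", residual = residual)
}
abort_parse <- function(msg) abort(msg, class = "atmkit_parse_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_invalid(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must be finite numeric", name))
  }
  invisible(x)
}

#' Derive a child seed from a parent seed and a stream id
#'
#' Named-stream seeding: every stochastic operation in atmkit draws from its
#' own stream, derived deterministically from the user seed, so reruns are
#' bit-identical and no global RNG state leaks between calls.
#'
#' @param seed integer parent seed.
#' @param stream integer stream identifier (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(stream) * 7919 + 12345) %% 2147483647
  as.integer(x %% 2147483646 + 1)
}

# Evaluate `code` under a private RNG stream, restoring global state after.
with_stream <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(t)) without overflow
softplus <- function(t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- t[pos] + log1p(exp(-t[pos]))
  out[!pos] <- log1p(exp(t[!pos]))
  out
}

# Moore-Penrose pseudo-inverse via SVD (base R, no extra deps)
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  tol <- tol %||% (max(dim(A)) * max(s$d) * .Machine$double.eps)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
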