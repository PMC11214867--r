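#' Error statistics of calculated vs experimental free energies
#'
#' @param calc,exp equal-length numeric vectors, kcal/mol.
#' @return list with `mae` (mean absolute error) and `rmse`.
#' @export
error_stats <- function(calc, exp) {
  if (length(calc) != length(exp) || length(calc) == 0) {
    abort_invalid("`calc` and `exp` must be equal-length and non-empty")
  }
  d <- calc - exp
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau; equals `(C - D) / (n (n-1) / 2)` for tie-free
#' input. Rank correlation is the standard relative measure for ddG
#' benchmarks (Pearson correlation of ddG values depends on the arbitrary
#' choice of ligand pairs and is deliberately not part of default reports).
#'
#' @param calc,exp equal-length numeric vectors, length >= 2.
#' @return tau in `[-1, 1]`.
#' @export
kendall_tau <- function(calc, exp) {
  if (length(calc) != length(exp) || length(calc) < 2) {
    abort_invalid("`calc` and `exp` must be equal-length with >= 2 entries")
  }
  if (sd(calc) == 0 || sd(exp) == 0) {
    abort("Kendall tau undefined for all-constant input",
          class = "atmkit_undefined_correlation")
  }
  cor(calc, exp, method = "kendall")
}

#' Pair-bootstrap uncertainty of a benchmark statistic
#'
#' Resamples ligand pairs with replacement and reports the standard
#' deviation of the statistic over resamples. Resamples on which the
#' statistic is undefined (e.g. Kendall tau on an all-tie draw) are skipped
#' and counted.
#'
#' @param stat_fn function(calc, exp) returning a scalar.
#' @param calc,exp paired values.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed (deterministic).
#' @return list with `stat` (full-sample value), `sigma`, `n_degenerate`.
#' @export
bootstrap_uncertainty <- function(stat_fn, calc, exp, n_boot = 1000, seed = 1) {
  if (n_boot < 100) abort_invalid("`n_boot` must be >= 100")
  n <- length(calc)
  stat <- stat_fn(calc, exp)
  draws <- with_stream(derive_seed(seed, 37L), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(stat_fn(calc[idx], exp[idx]), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- !is.na(draws)
  list(stat = stat, sigma = if (sum(ok) > 1) sd(draws[ok]) else 0,
       n_degenerate = sum(!ok))
}

#' Fraction of pairs predicted within error thresholds
#'
#' For each threshold t, the fraction of pairs with `|calc - exp| < t`
#' (the benchmark's accuracy-threshold summary at 1 and 1.5 kcal/mol).
#'
#' @param calc,exp paired values, kcal/mol.
#' @param thresholds positive thresholds, kcal/mol.
#' @return named numeric vector of fractions.
#' @export
fraction_within <- function(calc, exp, thresholds = c(1, 1.5)) {
  check_positive(thresholds, "thresholds")
  err <- abs(calc - exp)
  setNames(vapply(thresholds, function(t) mean(err < t), numeric(1)),
           format(thresholds))
}

#' Benchmark statistics for a set of ddG edges
#'
#' MAE, RMSE and Kendall tau of calculated vs experimental values, each
#' with a pair-bootstrap uncertainty, plus accuracy-threshold fractions.
#'
#' @param data tibble/data.frame of edges with calculated and experimental
#'   columns, or a [perturbation_network()].
#' @param calc,exp column names, default `ddg_calc` / `ddg_exp`.
#' @param thresholds accuracy thresholds, kcal/mol.
#' @param n_boot,seed bootstrap controls, see [bootstrap_uncertainty()].
#' @return a one-row tibble (class `benchmark_stats`) with `n_pairs`,
#'   `mae`, `mae_sigma`, `rmse`, `rmse_sigma`, `tau`, `tau_sigma`, and one
#'   `frac_within_*` column per threshold.
#' @export
benchmark_stats <- function(data, calc = "ddg_calc", exp = "ddg_exp",
                            thresholds = c(1, 1.5), n_boot = 1000, seed = 1) {
  if (inherits(data, "perturbation_network")) data <- data$edges
  data <- as_tibble(data)
  x <- data[[calc]]
  y <- data[[exp]]
  if (is.null(x) || is.null(y)) abort_invalid("calc/exp columns not found")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) abort_invalid("no complete calc/exp pairs")
  es <- error_stats(x, y)
  mae_b <- bootstrap_uncertainty(function(a, b) error_stats(a, b)$mae,
                                 x, y, n_boot, derive_seed(seed, 1L))
  rmse_b <- bootstrap_uncertainty(function(a, b) error_stats(a, b)$rmse,
                                  x, y, n_boot, derive_seed(seed, 2L))
  tau <- tryCatch(kendall_tau(x, y), error = function(e) NA_real_)
  tau_b <- if (is.na(tau)) list(sigma = NA_real_, n_degenerate = NA_integer_) else {
    bootstrap_uncertainty(kendall_tau, x, y, n_boot, derive_seed(seed, 3L))
  }
  fw <- fraction_within(x, y, thresholds)
  out <- tibble(n_pairs = length(x),
                mae = es$mae, mae_sigma = mae_b$sigma,
                rmse = es$rmse, rmse_sigma = rmse_b$sigma,
                tau = tau, tau_sigma = tau_b$sigma)
  for (i in seq_along(fw)) {
    out[[paste0("frac_within_", gsub("\\s", "", names(fw)[i]))]] <- fw[[i]]
  }
  class(out) <- c("benchmark_stats", class(out))
  out
}

#' Side-by-side method comparison table
#'
#' Computes the benchmark statistics of several methods on the same edge
#' set and flags the best method per column (highest tau, lowest MAE and
#' RMSE) -- the layout of a force-field comparison table.
#'
#' @param runs named list of edge tibbles (one per method), each with the
#'   same ligand pairs, or a single tibble with a `method` column.
#' @param ... passed to [benchmark_stats()].
#' @return a tibble with one row per method, statistic columns, and logical
#'   `best_tau` / `best_mae` / `best_rmse` flags (class
#'   `method_comparison`).
#' @export
method_comparison_table <- function(runs, ...) {
  if (is.data.frame(runs)) {
    if (!"method" %in% names(runs)) abort_invalid("tibble input needs a `method` column")
    runs <- split(as_tibble(runs), runs$method)
  }
  if (length(runs) == 0) abort_invalid("no methods supplied")
  keys <- lapply(runs, function(e) {
    sort(paste(pmin(e$ligand_i, e$ligand_j), pmax(e$ligand_i, e$ligand_j)))
  })
  for (k in seq_along(keys)) {
    if (!identical(keys[[k]], keys[[1]])) {
      abort_invalid("methods do not share the same edge set; statistics not comparable")
    }
  }
  rows <- purrr::imap(runs, function(e, nm) {
    st <- benchmark_stats(e, ...)
    dplyr::bind_cols(tibble(method = nm), st)
  })
  out <- dplyr::bind_rows(rows)
  out$best_tau <- out$tau == max(out$tau, na.rm = TRUE)
  out$best_mae <- out$mae == min(out$mae, na.rm = TRUE)
  out$best_rmse <- out$rmse == min(out$rmse, na.rm = TRUE)
  class(out) <- c("method_comparison", class(out))
  out
}

#' Plain-text benchmark report
#'
#' @param comparison output of [method_comparison_table()] or
#'   [benchmark_stats()].
#' @return character vector of fixed-format report lines.
#' @export
format_benchmark_report <- function(comparison) {
  if (!"method" %in% names(comparison)) {
    comparison <- dplyr::bind_cols(tibble(method = "calc"), comparison)
    comparison$best_tau <- comparison$best_mae <- comparison$best_rmse <- NA
  }
  hdr <- sprintf("%-12s %18s %18s %18s %8s", "method", "Kendall (tau)",
                 "MAE", "RMSE", "pairs")
  lines <- vapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    mark <- function(flag) if (isTRUE(flag)) "*" else " "
    sprintf("%-12s %14.2f +/- %.2f%s %11.2f +/- %.2f%s %11.2f +/- %.2f%s %7d",
            r$method, r$tau, r$tau_sigma, mark(r$best_tau),
            r$mae, r$mae_sigma, mark(r$best_mae),
            r$rmse, r$rmse_sigma, mark(r$best_rmse), r$n_pairs)
  }, character(1))
  c(hdr, lines)
}
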