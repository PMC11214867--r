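#' Perturbation networks of ligand-pair free energy differences
#'
#' A `perturbation_network` holds ligands (nodes) and relative binding free
#' energy measurements (edges). The edge convention is
#' `ddg_calc = dG(ligand_j) - dG(ligand_i)` in kcal/mol; `sigma_calc` is the
#' 1-sigma uncertainty of the calculated value; `ddg_exp` is the experimental
#' reference difference where available.
#'
#' @param edges tibble/data.frame with columns `ligand_i`, `ligand_j`,
#'   `ddg_calc`, `sigma_calc` and optionally `ddg_exp`, `method`.
#' @param nodes optional tibble with columns `ligand` and `dg_exp`
#'   (experimental absolute binding free energies, kcal/mol).
#' @return a `perturbation_network` object (list of tibbles).
#' @export
perturbation_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  required <- c("ligand_i", "ligand_j", "ddg_calc", "sigma_calc")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort_parse(sprintf("edge table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"ddg_exp" %in% names(edges)) edges$ddg_exp <- NA_real_
  if (nrow(edges) > 0) {
    bad <- which(!is.finite(edges$sigma_calc) | edges$sigma_calc <= 0)
    if (length(bad) > 0) {
      abort_parse(sprintf("sigma_calc must be > 0 (edge row %d)", bad[1]))
    }
    self <- which(edges$ligand_i == edges$ligand_j)
    if (length(self) > 0) {
      abort_parse(sprintf("self-edge not allowed (edge row %d)", self[1]))
    }
    key <- paste(pmin(edges$ligand_i, edges$ligand_j),
                 pmax(edges$ligand_i, edges$ligand_j))
    if (anyDuplicated(key)) {
      abort_parse(sprintf("duplicate unordered ligand pair (edge row %d)",
                          which(duplicated(key))[1]))
    }
  }
  all_ids <- unique(c(edges$ligand_i, edges$ligand_j,
                      if (!is.null(nodes)) nodes$ligand))
  if (is.null(nodes)) {
    nodes <- tibble(ligand = all_ids, dg_exp = NA_real_)
  } else {
    nodes <- as_tibble(nodes)
    if (!"dg_exp" %in% names(nodes)) nodes$dg_exp <- NA_real_
    if (anyDuplicated(nodes$ligand)) abort_parse("duplicate node ligand ids")
    extra <- setdiff(all_ids, nodes$ligand)
    if (length(extra) > 0) {
      nodes <- dplyr::bind_rows(nodes, tibble(ligand = extra, dg_exp = NA_real_))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "perturbation_network")
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat(sprintf("<perturbation_network> %d ligands, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  comps <- check_connectivity(x)
  if (length(comps) > 1) {
    cat(sprintf("  ! %d connected components (sizes: %s)\n", length(comps),
                paste(lengths(comps), collapse = ", ")))
  }
  invisible(x)
}

#' Synthetic ligand-pair ddG networks
#'
#' Draws true per-ligand binding free energies, selects a random subset of
#' ligand pairs, and emits edges whose calculated ddG is the true difference
#' plus Gaussian noise while the experimental ddG is the exact difference.
#' This emulates a benchmark's deposited free energy table: the random pair
#' subset mirrors how only part of all possible pairs is simulated.
#'
#' @param n_ligands number of ligands (>= 2).
#' @param edge_fraction fraction of all `choose(n, 2)` pairs to keep.
#' @param noise_sigma Gaussian noise on calculated edges, kcal/mol (>= 0).
#' @param seed integer seed (deterministic replay).
#' @param dg_spread standard deviation of true node dG values, kcal/mol.
#' @param dg_offset mean of true node dG values, kcal/mol (typical binding
#'   affinities are around -9 kcal/mol).
#' @return a [perturbation_network()] with the generating truth attached as
#'   attribute `true_dgs` and node `dg_exp` set to the truth; attribute
#'   `underconnected` flags fewer than `n_ligands - 1` edges.
#' @export
make_edge_network <- function(n_ligands, edge_fraction = 1, noise_sigma = 0.5,
                              seed = 1, dg_spread = 1.5, dg_offset = -9) {
  if (n_ligands < 2) abort_invalid("`n_ligands` must be >= 2")
  if (noise_sigma < 0) abort_invalid("`noise_sigma` must be >= 0")
  if (edge_fraction < 0 || edge_fraction > 1) {
    abort_invalid("`edge_fraction` must be in [0, 1]")
  }
  ids <- sprintf("lig%02d", seq_len(n_ligands))
  pairs <- t(utils::combn(n_ligands, 2))
  net <- with_stream(derive_seed(seed, 29L), {
    g <- rnorm(n_ligands, dg_offset, dg_spread)
    n_keep <- round(edge_fraction * nrow(pairs))
    keep <- sort(sample.int(nrow(pairs), n_keep))
    pk <- pairs[keep, , drop = FALSE]
    ddg_true <- g[pk[, 2]] - g[pk[, 1]]
    ddg_calc <- ddg_true + rnorm(length(ddg_true), 0, noise_sigma)
    list(g = g,
         edges = tibble(
           ligand_i = ids[pk[, 1]], ligand_j = ids[pk[, 2]],
           ddg_calc = ddg_calc,
           sigma_calc = rep(max(noise_sigma, 0.05), length(ddg_true)),
           ddg_exp = ddg_true))
  })
  out <- perturbation_network(net$edges,
                              nodes = tibble(ligand = ids, dg_exp = net$g))
  attr(out, "true_dgs") <- setNames(net$g, ids)
  attr(out, "underconnected") <- nrow(net$edges) < n_ligands - 1
  if (attr(out, "underconnected")) {
    warn("edge network has fewer edges than ligands - 1; it cannot be connected")
  }
  out
}
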