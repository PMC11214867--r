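#' Connected components of a perturbation network
#'
#' Absolute binding free energies can only be reconstructed within a
#' connected component of the ddG graph: a poorly connected perturbation
#' network leaves ligand groups mutually incomparable.
#'
#' @param net a [perturbation_network()].
#' @return list of character vectors of ligand ids, largest component first;
#'   isolated ligands are singleton components.
#' @export
check_connectivity <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("ligand_i", "ligand_j")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$ligand))
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- unname(comps[order(-lengths(comps))])
  lapply(comps, as.character)
}

#' Maximum-likelihood absolute free energies from a ddG network
#'
#' Within each connected component, minimises
#' `sum_edges (ddG_ij - (g_j - g_i))^2 / sigma_ij^2` under the gauge
#' `sum g = 0`, solved through the pseudo-inverse of the weighted graph
#' Laplacian; per-node uncertainties are the square roots of the
#' pseudo-inverse diagonal. Components are never mixed: singleton components
#' get no estimate and ddG comparisons across components are meaningless.
#'
#' @param net a [perturbation_network()]; every edge must have
#'   `sigma_calc > 0`.
#' @return a tibble (class `atm_node_estimates`) with columns `ligand`,
#'   `dg`, `sigma`, `dg_exp`, `component`.
#' @export
mle_absolute_dg <- function(net) {
  if (any(net$edges$sigma_calc <= 0)) abort_invalid("zero-sigma edge")
  comps <- check_connectivity(net)
  rows <- list()
  for (ci in seq_along(comps)) {
    ids <- comps[[ci]]
    if (length(ids) < 2) next
    e <- net$edges[net$edges$ligand_i %in% ids | net$edges$ligand_j %in% ids, ]
    if (nrow(e) == 0) next
    m <- length(ids)
    i_idx <- match(e$ligand_i, ids)
    j_idx <- match(e$ligand_j, ids)
    w <- 1 / e$sigma_calc^2
    X <- matrix(0, nrow(e), m)
    X[cbind(seq_len(nrow(e)), i_idx)] <- -1
    X[cbind(seq_len(nrow(e)), j_idx)] <- 1
    L <- t(X) %*% (w * X)
    rhs <- as.numeric(t(X) %*% (w * e$ddg_calc))
    Lp <- pinv(L)
    g <- as.numeric(Lp %*% rhs)    # min-norm solution => sum(g) = 0
    sig <- sqrt(pmax(diag(Lp), 0))
    rows[[length(rows) + 1]] <- tibble(
      ligand = ids, dg = g, sigma = sig,
      dg_exp = net$nodes$dg_exp[match(ids, net$nodes$ligand)],
      component = ci)
  }
  if (length(rows) == 0) {
    out <- tibble(ligand = character(), dg = numeric(), sigma = numeric(),
                  dg_exp = numeric(), component = integer())
  } else {
    out <- dplyr::bind_rows(rows)
  }
  class(out) <- c("atm_node_estimates", class(out))
  out
}

#' Anchor network estimates to experimental absolute free energies
#'
#' Shifts each component's estimates by a constant so the mean estimated dG
#' over experimentally annotated ligands equals the mean experimental dG
#' (the usual anchoring convention for correlation plots of absolute
#' binding free energies); sigmas are unchanged. Components with no
#' experimental anchor are skipped with a warning.
#'
#' @param estimates output of [mle_absolute_dg()].
#' @param net the [perturbation_network()] carrying `dg_exp` node
#'   annotations (defaults to the annotations already on `estimates`).
#' @return the shifted estimates tibble.
#' @export
center_to_experiment <- function(estimates, net = NULL) {
  if (!is.null(net)) {
    estimates$dg_exp <- net$nodes$dg_exp[match(estimates$ligand, net$nodes$ligand)]
  }
  for (ci in unique(estimates$component)) {
    sel <- estimates$component == ci
    anchored <- sel & !is.na(estimates$dg_exp)
    if (!any(anchored)) {
      warn(sprintf("component %s has no experimental anchor; left unshifted", ci))
      next
    }
    shift <- mean(estimates$dg_exp[anchored]) - mean(estimates$dg[anchored])
    estimates$dg[sel] <- estimates$dg[sel] + shift
  }
  estimates
}
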