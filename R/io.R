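#' Edge CSV input/output
#'
#' The edge file format mirrors a deposited free-energy table: a mandatory
#' `# units: kcal/mol` comment line, a header, and one row per ligand pair
#' with columns `ligand_i, ligand_j, ddg_calc, sigma_calc[, ddg_exp, method]`.
#' `ddg_calc` follows the convention `dG(ligand_j) - dG(ligand_i)`. Files
#' are UTF-8 with period decimal separators regardless of locale.
#'
#' @param net a [perturbation_network()] (or an edge tibble) to write.
#' @param path file path.
#' @param nodes_path optional node CSV (`ligand, dg_exp`) giving
#'   experimental absolute free energies.
#' @return `read_edges_csv()` returns a [perturbation_network()];
#'   `write_edges_csv()` returns `path` invisibly.
#' @name edges_csv
NULL

#' @rdname edges_csv
#' @export
write_edges_csv <- function(net, path) {
  edges <- if (inherits(net, "perturbation_network")) net$edges else as_tibble(net)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# units: kcal/mol", con)
  cols <- intersect(c("ligand_i", "ligand_j", "ddg_calc", "sigma_calc",
                      "ddg_exp", "method"), names(edges))
  utils::write.table(format_num_df(edges[, cols]), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 12, format = "g")
  }
  df
}

#' @rdname edges_csv
#' @export
read_edges_csv <- function(path, nodes_path = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*units:\\s*kcal/mol", first)) {
    abort_parse("edge file must start with a '# units: kcal/mol' line")
  }
  edges <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE, locale = readr::locale(decimal_mark = "."))
  required <- c("ligand_i", "ligand_j", "ddg_calc", "sigma_calc")
  miss <- setdiff(required, names(edges))
  if (length(miss) > 0) {
    abort_parse(sprintf("edge file missing column(s): %s", paste(miss, collapse = ", ")))
  }
  for (nm in c("ddg_calc", "sigma_calc", "ddg_exp")) {
    if (!nm %in% names(edges) || is.numeric(edges[[nm]])) next
    if (is.logical(edges[[nm]]) && all(is.na(edges[[nm]]))) {
      edges[[nm]] <- as.numeric(edges[[nm]])   # empty or all-NA column
      next
    }
    vals <- suppressWarnings(as.numeric(edges[[nm]]))
    bad <- which(is.na(vals) & !is.na(edges[[nm]]))
    if (length(bad) > 0) {
      abort_parse(sprintf("non-numeric %s (edge row %d)", nm, bad[1]))
    }
    edges[[nm]] <- vals
  }
  edges$ligand_i <- as.character(edges$ligand_i)
  edges$ligand_j <- as.character(edges$ligand_j)
  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- readr::read_csv(nodes_path, comment = "#", show_col_types = FALSE,
                             progress = FALSE)
    nodes$ligand <- as.character(nodes$ligand)
  }
  perturbation_network(edges, nodes = nodes)
}

#' Write node estimates to CSV
#'
#' @param estimates output of [mle_absolute_dg()].
#' @param path file path.
#' @export
write_nodes_csv <- function(estimates, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# units: kcal/mol", con)
  utils::write.table(format_num_df(as_tibble(estimates)), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' XYZ coordinate files
#'
#' Minimal plain-text XYZ: atom count, comment, then `name x y z` rows (A).
#'
#' @param coords N x 3 matrix (A). @param path file path.
#' @param names atom labels. @param comment second-line comment.
#' @name xyz_io
NULL

#' @rdname xyz_io
#' @export
write_xyz <- function(coords, path, names = NULL, comment = "atmkit toy system") {
  coords <- as_coord_matrix(coords)
  names <- names %||% rep("C", nrow(coords))
  lines <- c(as.character(nrow(coords)), comment,
             sprintf("%-4s %16.8f %16.8f %16.8f", names,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname xyz_io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rows <- strsplit(trimws(lines[seq.int(3, 2 + n)]), "\\s+")
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  attr(coords, "names_xyz") <- vapply(rows, `[[`, character(1), 1)
  coords
}

#' Toy system (de)serialization
#'
#' Round-trippable structured config: particles (coordinates, masses),
#' potential terms, ligand index groups (1-based), centers, temperature.
#'
#' @param system a [toy_system]. @param path YAML file path.
#' @name system_io
NULL

#' @rdname system_io
#' @export
write_system_yaml <- function(system, path) {
  obj <- list(
    temperature = system$temperature,
    site_center = system$site_center,
    bulk_center = system$bulk_center,
    ligand_a = system$ligand_a,
    ligand_b = system$ligand_b,
    masses = system$masses,
    analytic_ddg = if (is.na(system$analytic_ddg)) NULL else system$analytic_ddg,
    coordinates = as.numeric(t(system$coords)),
    terms = lapply(system$terms, function(tm) {
      list(kind = tm$kind, idx = tm$idx, params = tm$params)
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname system_io
#' @export
read_system_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  terms <- lapply(obj$terms, function(tm) {
    p <- tm$params
    idx <- as.integer(unlist(tm$idx))
    switch(tm$kind,
      harmonic_bond = harmonic_bond(idx[1], idx[2], p$k, p$r0),
      harmonic_tether = harmonic_tether(idx[1], p$k, unlist(p$center), p$r0),
      lennard_jones_pair = lennard_jones_pair(idx[1], idx[2], p$eps, p$sigma),
      coulomb_pair = coulomb_pair(idx[1], idx[2], p$qi, p$qj, p$eps_r),
      torsion_cosine = torsion_cosine(idx[1], idx[2], idx[3], idx[4],
                                      p$amplitude, p$periodicity, p$phase),
      double_well_tether = double_well_tether(idx[1], p$k_site, p$k_bulk,
                                              unlist(p$site_center),
                                              unlist(p$bulk_center), p$kT),
      abort_parse(sprintf("unknown term kind '%s' in %s", tm$kind, path)))
  })
  toy_system(matrix(as.numeric(unlist(obj$coordinates)), ncol = 3, byrow = TRUE),
             terms,
             ligand_a = as.integer(unlist(obj$ligand_a)),
             ligand_b = as.integer(unlist(obj$ligand_b)),
             site_center = as.numeric(unlist(obj$site_center)),
             bulk_center = as.numeric(unlist(obj$bulk_center)),
             temperature = obj$temperature,
             masses = as.numeric(unlist(obj$masses)),
             analytic_ddg = obj$analytic_ddg %||% NA_real_)
}

#' Per-window sample files
#'
#' One CSV per lambda window with columns `step, lambda, u, u_sc, W`
#' (kcal/mol), plus a `states.yaml` describing the alchemical states, so a
#' directory of sample files can be read back into a
#' [perturbation_samples] object.
#'
#' @param samples a [perturbation_samples] object. @param dir directory.
#' @name samples_io
NULL

#' @rdname samples_io
#' @export
write_samples_dir <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(samples$u_by_state)
  for (k in seq_len(K)) {
    st <- samples$states[[k]]
    u <- samples$u_by_state[[k]]
    usc <- softcore(u, st$softcore)
    df <- tibble(step = seq_along(u), lambda = st$lam, u = u, u_sc = usc,
                 W = alchemical_bias(usc, st))
    f <- file.path(dir, sprintf("window_%02d.csv", k))
    con <- file(f, "w", encoding = "UTF-8")
    writeLines("# units: kcal/mol", con)
    utils::write.table(format_num_df(df), con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  yaml::write_yaml(list(
    kT = samples$kT, leg = samples$leg, replicate = samples$replicate,
    states = lapply(samples$states, function(s) {
      list(lam = s$lam, leg = s$leg, lam1 = s$lam1, lam2 = s$lam2,
           alpha = s$alpha, u0 = s$u0, w0 = s$w0,
           softcore = unclass(s$softcore))
    })), file.path(dir, "states.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname samples_io
#' @export
read_samples_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "states.yaml"))
  states <- lapply(meta$states, function(s) {
    alchemical_state(s$lam, leg = s$leg, lam1 = s$lam1, lam2 = s$lam2,
                     alpha = s$alpha, u0 = s$u0, w0 = s$w0,
                     softcore = softcore_params(s$softcore$umax, s$softcore$uc,
                                                s$softcore$a))
  })
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.csv$", full.names = TRUE))
  if (length(files) != length(states)) {
    abort_parse("window file count does not match states.yaml")
  }
  u_by_state <- lapply(files, function(f) {
    readr::read_csv(f, comment = "#", show_col_types = FALSE, progress = FALSE)$u
  })
  perturbation_samples(u_by_state, states, meta$kT, leg = meta$leg,
                       replicate = meta$replicate)
}

#' Write a replayable run manifest
#'
#' Records the full configuration, seeds, and package version needed to
#' replay a run bit-identically; content is deterministic (no timestamps).
#'
#' @param path file path. @param config named list.
#' @export
write_manifest <- function(path, config) {
  config$atmkit_version <- as.character(utils::packageVersion("atmkit"))
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
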