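#' Export a network or summary network as a PyMOL script
#'
#' Writes a `.pml` script drawing one pseudoatom per node and one
#' distance object per edge. For a summary network the pseudoatoms carry
#' the conservation value in their b property and each distinct
#' conservation level gets its own colour (blue-to-red ramp).
#'
#' @param x A `wn_network` or `wn_summary`.
#' @param path Output `.pml` file.
#' @return `path`, invisibly.
#' @export
write_pml <- function(x, path) {
  UseMethod("write_pml")
}

#' @export
write_pml.wn_network <- function(x, path) {
  if (nrow(x$nodes) == 0) {
    abort("network is empty; nothing to export",
          class = "hydronet_precondition_error")
  }
  nd <- x$nodes
  lines <- c("# hydronet water network export",
             sprintf("# structure %s", x$structure_id))
  obj <- function(serial) sprintf("hn_node_%d", serial)
  lines <- c(lines, vapply(seq_len(nrow(nd)), function(i) {
    sprintf("pseudoatom %s, pos=[%.3f, %.3f, %.3f], b=%.2f",
            obj(nd$serial[i]), nd$x[i], nd$y[i], nd$z[i],
            as.numeric(nd$is_water[i]))
  }, character(1)))
  if (nrow(x$edges) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(x$edges)), function(k) {
      sprintf("distance hn_edge_%d, %s, %s", k,
              obj(x$edges$serial_a[k]), obj(x$edges$serial_b[k]))
    }, character(1)))
  }
  lines <- c(lines,
             "hide labels, hn_edge_*",
             "show spheres, hn_node_*",
             "set sphere_scale, 0.3, hn_node_*")
  writeLines(lines, path)
  invisible(path)
}

#' @export
write_pml.wn_summary <- function(x, path) {
  if (x$n_summary == 0) {
    abort("summary network is empty; nothing to export",
          class = "hydronet_precondition_error")
  }
  cent <- x$centroids
  lines <- c("# hydronet summary water network export")
  cols <- unique(round(cent$conservation, 2))
  for (cv in cols) {
    lines <- c(lines, sprintf("set_color hn_cons_%03d, [%.3f, 0.2, %.3f]",
                              round(cv * 100), cv, 1 - cv))
  }
  for (i in seq_len(nrow(cent))) {
    lines <- c(lines,
               sprintf("pseudoatom hn_site_%d, pos=[%.3f, %.3f, %.3f], b=%.3f",
                       cent$cluster[i], cent$x[i], cent$y[i], cent$z[i],
                       cent$conservation[i]),
               sprintf("color hn_cons_%03d, hn_site_%d",
                       round(round(cent$conservation[i], 2) * 100),
                       cent$cluster[i]))
  }
  if (nrow(x$edges) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(x$edges)), function(k) {
      sprintf("distance hn_sedge_%d, hn_site_%d, hn_site_%d", k,
              x$edges$cluster_a[k], x$edges$cluster_b[k])
    }, character(1)))
  }
  lines <- c(lines, "show spheres, hn_site_*",
             "set sphere_scale, 0.4, hn_site_*")
  writeLines(lines, path)
  invisible(path)
}

#' Write a summary network as a PDB of pseudo-waters
#'
#' Centroids become HOH oxygen HETATM records with the conservation
#' value in the B-factor column, so any molecular viewer can colour the
#' consensus sites by conservation.
#'
#' @param summary A `wn_summary`.
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
write_summary_pdb <- function(summary, path) {
  cent <- summary$centroids
  if (nrow(cent) == 0) {
    abort("summary network is empty; nothing to export",
          class = "hydronet_precondition_error")
  }
  xyz <- as.vector(t(as.matrix(cent[, c("x", "y", "z")])))
  n <- nrow(cent)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("HETATM", n),
                   resno = cent$cluster, resid = rep("HOH", n),
                   eleno = cent$cluster, elety = rep("O", n),
                   chain = rep("W", n), o = rep(1, n),
                   b = round(cent$conservation, 2), elesy = rep("O", n))
  invisible(path)
}

#' @rdname write_summary_pdb
#' @export
write_summary_csv <- function(summary, path) {
  write.csv(summary$centroids, path, row.names = FALSE)
  invisible(path)
}

#' Write a density grid in OpenDX volumetric format
#'
#' @param grid A `wn_density_grid`.
#' @param path Output `.dx` file.
#' @param normalise Divide counts by the number of networks (occupancy)?
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, normalise = FALSE) {
  dims <- dim(grid$counts)
  vals <- as.numeric(grid$counts)
  if (normalise) vals <- vals / grid$n_networks
  # OpenDX expects the last (z) index fastest
  ord <- array(seq_along(vals), dim = dims)
  ord <- as.vector(aperm(ord, c(3, 2, 1)))
  vals <- vals[order(ord)]
  n <- length(vals)
  pad <- c(vals, rep(NA_real_, (3 - n %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r) {
    paste(formatC(r[!is.na(r)], format = "g", digits = 6), collapse = " ")
  })
  lines <- c(
    "# hydronet water occupancy grid",
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.4f %.4f %.4f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n),
    data_lines,
    'attribute "dep" string "positions"',
    'object "density" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3')
  writeLines(lines, path)
  invisible(path)
}

#' Write angle and interaction-score tables as CSV
#'
#' @param records Tibble from [water_protein_angles()] or
#'   [interaction_scores()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Plot the two-angle projection of water-protein contacts
#'
#' @param records Tibble from [water_protein_angles()].
#' @return A ggplot object: angle1 vs angle2, coloured by residue.
#' @export
plot_angles <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$angle1, y = .data$angle2,
                               colour = factor(.data$resno),
                               shape = .data$protein_site)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::lims(x = c(0, 180), y = c(0, 180)) +
    ggplot2::labs(x = "angle to reference 1 (deg)",
                  y = "angle to reference 2 (deg)",
                  colour = "residue", shape = "site")
}
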