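#' Conservation-analysis parameters
#'
#' @param match_distance A summary water counts as matched in a structure
#'   when the structure has a water within this distance (default 1 A).
#' @param local_sphere Radius of the local crowding sphere used to
#'   normalise the conservation score (default 6 A).
#' @param pair_distance Centroid pairs closer than this are tracked for
#'   the pairwise conservation score (default 2 A).
#' @return A `conservation_params` object.
#' @export
conservation_params <- function(match_distance = 1.0, local_sphere = 6.0,
                                pair_distance = 2.0) {
  stopifnot(match_distance > 0, local_sphere > 0, pair_distance > 0)
  structure(list(match_distance = match_distance,
                 local_sphere = local_sphere,
                 pair_distance = pair_distance),
            class = "conservation_params")
}

#' Pool water positions across networks
#'
#' Collects every water-oxygen coordinate of a set of (superposed)
#' networks into one labelled point set; duplicates are kept as-is.
#'
#' @param networks A `wn_network` or list of them.
#' @return Tibble: `structure_id`, `frame`, `serial`, `x`, `y`, `z`.
#' @export
pool_positions <- function(networks) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  pts <- bind_rows(lapply(networks, function(net) {
    w <- filter(net$nodes, .data$is_water, .data$element == "O")
    tibble(structure_id = net$structure_id,
           frame = net$frame_index,
           serial = w$serial, x = w$x, y = w$y, z = w$z)
  }))
  # structures without any water still count as sources downstream
  attr(pts, "sources") <- unique(vapply(networks, function(net) {
    paste(net$structure_id, net$frame_index, sep = "\r")
  }, character(1)))
  pts
}

#' Cluster pooled water positions into a summary network
#'
#' Density-based clustering of pooled water oxygens yields conserved
#' hydration sites; each cluster is summarised by the arithmetic mean of
#' its member coordinates. Per-cluster conservation is the fraction of
#' source structures (or frames) holding a water within `match_distance`
#' of the centroid; the pairwise conservation of two nearby centroids is
#' the fraction of sources with waters within `match_distance` of both.
#' Centroids within the H-bond distance cutoff are connected as summary
#' edges.
#'
#' @param points Pooled positions from [pool_positions()].
#' @param params A [cluster_params()].
#' @param conservation A [conservation_params()].
#' @param criteria An [hbond_criteria()] supplying the summary-edge
#'   distance cutoff.
#' @return A `wn_summary`: list with `centroids` (tibble: `cluster`,
#'   `x`, `y`, `z`, `size`, `conservation`), `pairs`, `edges`,
#'   `n_summary`, `n_sources`.
#' @export
cluster_waters <- function(points, params = cluster_params(),
                           conservation = conservation_params(),
                           criteria = hbond_criteria()) {
  pts <- as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(pts))) {
    abort("points must have x, y, z columns",
          class = "hydronet_precondition_error")
  }
  if (!"structure_id" %in% names(pts)) pts$structure_id <- "structure"
  if (!"frame" %in% names(pts)) pts$frame <- NA_integer_
  pts$source <- paste(pts$structure_id, pts$frame, sep = "\r")
  sources <- attr(points, "sources") %||% unique(pts$source)
  sources <- union(sources, unique(pts$source))
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  labels <- cluster_points(xyz, params)
  if (all(labels == 0L)) {
    warn("all pooled water positions were classified as noise")
    return(empty_summary(length(sources), params, conservation, criteria))
  }
  cent <- tibble(cluster = labels, x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3]) |>
    filter(.data$cluster > 0) |>
    group_by(.data$cluster) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              size = n(), .groups = "drop") |>
    arrange(.data$cluster)
  cxyz <- as.matrix(cent[, c("x", "y", "z")])
  # which sources have a water within match_distance of each centroid
  match_mat <- vapply(seq_len(nrow(cent)), function(i) {
    d <- row_dist(xyz, cxyz[i, ])
    sources %in% pts$source[d <= conservation$match_distance]
  }, logical(length(sources)))
  match_mat <- matrix(match_mat, nrow = length(sources))
  cent$conservation <- colMeans(match_mat)
  pairs <- centroid_pairs(cxyz, conservation$pair_distance)
  if (nrow(pairs) > 0) {
    pairs$conservation <- vapply(seq_len(nrow(pairs)), function(k) {
      mean(match_mat[, pairs$cluster_a[k]] & match_mat[, pairs$cluster_b[k]])
    }, numeric(1))
  } else {
    pairs$conservation <- numeric(0)
  }
  edges <- centroid_pairs(cxyz, criteria$distance_cutoff)
  structure(list(centroids = cent, pairs = pairs, edges = edges,
                 n_summary = nrow(cent), n_sources = length(sources),
                 cluster_params = params, conservation_params = conservation,
                 criteria = criteria),
            class = "wn_summary")
}

centroid_pairs <- function(cxyz, cutoff) {
  n <- nrow(cxyz)
  if (n < 2) {
    return(tibble(cluster_a = integer(0), cluster_b = integer(0),
                  distance = numeric(0)))
  }
  d <- as.matrix(dist(cxyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  tibble(cluster_a = idx[, 1], cluster_b = idx[, 2],
         distance = d[idx]) |>
    arrange(.data$cluster_a, .data$cluster_b)
}

empty_summary <- function(n_sources, params, conservation, criteria) {
  structure(list(
    centroids = tibble(cluster = integer(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), size = integer(0),
                       conservation = numeric(0)),
    pairs = tibble(cluster_a = integer(0), cluster_b = integer(0),
                   distance = numeric(0), conservation = numeric(0)),
    edges = tibble(cluster_a = integer(0), cluster_b = integer(0),
                   distance = numeric(0)),
    n_summary = 0L, n_sources = n_sources,
    cluster_params = params, conservation_params = conservation,
    criteria = criteria),
    class = "wn_summary")
}

#' @export
print.wn_summary <- function(x, ...) {
  cat(sprintf(
    "# Summary water network: %d sites from %d sources, %d edges\n",
    x$n_summary, x$n_sources, nrow(x$edges)))
  if (x$n_summary > 0) print(x$centroids)
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.wn_summary <- function(x, ...) x$centroids

#' @exportS3Method generics::glance
#' @export
glance.wn_summary <- function(x, ...) {
  tibble(n_summary = x$n_summary, n_sources = x$n_sources,
         n_edges = nrow(x$edges),
         mean_conservation = if (x$n_summary > 0)
           mean(x$centroids$conservation) else NA_real_)
}

#' Plot a summary network coloured by conservation
#'
#' @param object A `wn_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.wn_summary <- function(object, ...) {
  cent <- object$centroids
  ed <- object$edges
  seg <- tibble(x = cent$x[ed$cluster_a], y = cent$y[ed$cluster_a],
                xend = cent$x[ed$cluster_b], yend = cent$y[ed$cluster_b])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = cent,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$conservation,
                                     size = .data$size)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1),
                                    name = "conservation") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "Summary water network")
}

#' Conservation score of one structure against the summary network
#'
#' For each summary water i, let `a_i = 1` if the structure has a water
#' within `match_distance` of it (else 0), and let `w_i` be the number of
#' additional structure waters inside the `local_sphere` around it (the
#' matched water itself is excluded). The score is
#' `(1/N_s) * sum_i a_i / (1 + w_i)`: 1 when every summary water is
#' matched exactly with no local crowding, and insensitive, by the
#' normalisation, to the overall water density of the structure.
#'
#' @param summary A `wn_summary`.
#' @param waters A `wn_structure`, a `wn_network`, or a data frame with
#'   `x`, `y`, `z` columns holding the structure's water-oxygen
#'   positions.
#' @param params A [conservation_params()].
#' @return A single number in `[0, 1]`.
#' @export
conservation_score <- function(summary, waters,
                               params = conservation_params()) {
  if (summary$n_summary == 0) {
    abort("summary network is empty; conservation score is undefined",
          class = "hydronet_precondition_error")
  }
  xyz <- water_xyz(waters)
  cxyz <- as.matrix(summary$centroids[, c("x", "y", "z")])
  if (nrow(xyz) == 0) return(0)
  terms <- vapply(seq_len(nrow(cxyz)), function(i) {
    d <- row_dist(xyz, cxyz[i, ])
    if (!any(d <= params$match_distance)) return(0)
    w <- sum(d <= params$local_sphere) - 1  # exclude the matched water
    1 / (1 + w)
  }, numeric(1))
  sum(terms) / summary$n_summary
}

water_xyz <- function(waters) {
  if (inherits(waters, "wn_network")) {
    w <- filter(waters$nodes, .data$is_water, .data$element == "O")
    return(as.matrix(w[, c("x", "y", "z")]))
  }
  if (inherits(waters, "wn_structure")) {
    w <- waters[water_oxygen_indices(waters), , drop = FALSE]
    return(as.matrix(w[, c("x", "y", "z")]))
  }
  as.matrix(as_tibble(waters)[, c("x", "y", "z")])
}

#' Conservation scores for a whole set of networks
#'
#' @param summary A `wn_summary`.
#' @param networks List of `wn_network` objects.
#' @param params A [conservation_params()].
#' @return Tibble: `structure_id`, `frame`, `score`.
#' @export
conservation_scores <- function(summary, networks,
                                params = conservation_params()) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  bind_rows(lapply(networks, function(net) {
    tibble(structure_id = net$structure_id, frame = net$frame_index,
           score = conservation_score(summary, net, params))
  }))
}

#' Default reference points of the two-angle classification
#' @export
ANGLE_REFERENCES <- list(ref1 = c(0, 10, 0), ref2 = c(10, 0, 10))

#' Two-reference-angle descriptor of a water-protein contact
#'
#' The angle at the water oxygen between the vector to the interacting
#' protein atom and the vector to each of two fixed reference points
#' places every water-protein contact in a 2-D coordinate that is
#' comparable across structures once they share an alignment frame.
#' Defaults are the points (0, 10, 0) and (10, 0, 10) in the common
#' frame; any fixed coordinate (e.g. a conserved C-alpha) can be used.
#'
#' @param water,protein Length-3 coordinates (Angstrom).
#' @param ref1,ref2 Reference coordinates.
#' @return Named numeric vector `c(angle1, angle2)` in degrees.
#' @export
two_angle_classify <- function(water, protein,
                               ref1 = ANGLE_REFERENCES$ref1,
                               ref2 = ANGLE_REFERENCES$ref2) {
  c(angle1 = vec_angle(protein - water, ref1 - water),
    angle2 = vec_angle(protein - water, ref2 - water))
}

#' Two-angle records for all water-protein contacts of a network set
#'
#' @param networks A `wn_network` or list of them.
#' @param alignment Optional mapped `wn_alignment`; when given, each
#'   record carries the common alignment column of its residue.
#' @param ref1,ref2 Reference coordinates (see [two_angle_classify()]).
#' @return Tibble: `structure_id`, `frame`, `chain`, `resno`, `icode`,
#'   `resname`, `common_column`, `protein_site`, `angle1`, `angle2`.
#' @export
water_protein_angles <- function(networks, alignment = NULL,
                                 ref1 = ANGLE_REFERENCES$ref1,
                                 ref2 = ANGLE_REFERENCES$ref2) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  recs <- bind_rows(lapply(networks, function(net) {
    ed <- filter(net$edges, .data$kind == "water-protein")
    if (nrow(ed) == 0) return(NULL)
    nd <- net$nodes
    purrr::pmap_dfr(ed, function(serial_a, serial_b, protein_site, ...) {
      ia <- match(serial_a, nd$serial); ib <- match(serial_b, nd$serial)
      wi <- if (nd$is_water[ia]) ia else ib
      pi <- if (nd$is_water[ia]) ib else ia
      ang <- two_angle_classify(
        c(nd$x[wi], nd$y[wi], nd$z[wi]),
        c(nd$x[pi], nd$y[pi], nd$z[pi]), ref1, ref2)
      tibble(structure_id = net$structure_id, frame = net$frame_index,
             chain = nd$chain[pi], resno = nd$resno[pi],
             icode = nd$icode[pi], resname = nd$resname[pi],
             protein_site = protein_site,
             angle1 = ang[["angle1"]], angle2 = ang[["angle2"]])
    })
  }))
  if (nrow(recs) == 0) {
    return(tibble(structure_id = character(0), frame = integer(0),
                  chain = character(0), resno = integer(0),
                  icode = character(0), resname = character(0),
                  common_column = integer(0), protein_site = character(0),
                  angle1 = numeric(0), angle2 = numeric(0)))
  }
  add_common_column(recs, alignment) |>
    select("structure_id", "frame", "chain", "resno", "icode", "resname",
           "common_column", "protein_site", "angle1", "angle2")
}

add_common_column <- function(recs, alignment) {
  if (is.null(alignment) || is.null(alignment$mapping)) {
    recs$common_column <- NA_integer_
    return(recs)
  }
  left_join(recs,
            select(alignment$mapping, "structure_id", "chain", "resno",
                   "icode", common_column = "column"),
            by = c("structure_id", "chain", "resno", "icode"))
}

#' Per-residue water interaction scores
#'
#' A residue's interaction score is its total number of water-protein
#' interactions across all networks divided by the number of networks:
#' a residue bound to one water in every frame, or to two waters in half
#' of the frames, both score 1. `mean_simultaneous` — the mean number of
#' simultaneously bound waters over the frames where the residue binds
#' at all — separates those two situations (1.0 vs 2.0). Backbone and
#' side-chain contributions are reported separately and sum to the
#' total.
#'
#' @param networks A `wn_network` or list of them.
#' @param alignment Optional mapped `wn_alignment` for common residue
#'   indexing; without it residues are keyed by chain/number/icode.
#' @return Tibble: `common_column`, `chain`, `resno`, `icode`,
#'   `resname`, `raw_count`, `score`, `mean_simultaneous`,
#'   `score_backbone`, `score_sidechain`.
#' @export
interaction_scores <- function(networks, alignment = NULL) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  n_units <- length(networks)
  per_net <- bind_rows(lapply(seq_along(networks), function(k) {
    net <- networks[[k]]
    ed <- filter(net$edges, .data$kind == "water-protein")
    if (nrow(ed) == 0) return(NULL)
    nd <- net$nodes
    prot_serial <- ifelse(nd$is_water[match(ed$serial_a, nd$serial)],
                          ed$serial_b, ed$serial_a)
    ip <- match(prot_serial, nd$serial)
    tibble(unit = k, structure_id = net$structure_id,
           chain = nd$chain[ip], resno = nd$resno[ip],
           icode = nd$icode[ip], resname = nd$resname[ip],
           protein_site = ed$protein_site)
  }))
  if (nrow(per_net) == 0) {
    return(tibble(common_column = integer(0), chain = character(0),
                  resno = integer(0), icode = character(0),
                  resname = character(0), raw_count = integer(0),
                  score = numeric(0), mean_simultaneous = numeric(0),
                  score_backbone = numeric(0), score_sidechain = numeric(0)))
  }
  per_net <- add_common_column(per_net, alignment)
  key <- c("common_column", "chain", "resno", "icode", "resname")
  counts <- per_net |>
    group_by(across(all_of(c(key, "unit")))) |>
    summarise(count = n(),
              n_backbone = sum(.data$protein_site == "backbone"),
              n_sidechain = sum(.data$protein_site == "side-chain"),
              .groups = "drop")
  counts |>
    group_by(across(all_of(key))) |>
    summarise(raw_count = sum(.data$count),
              score = sum(.data$count) / n_units,
              mean_simultaneous = mean(.data$count),
              score_backbone = sum(.data$n_backbone) / n_units,
              score_sidechain = sum(.data$n_sidechain) / n_units,
              .groups = "drop") |>
    arrange(.data$chain, .data$resno, .data$icode)
}

#' Water-occupancy density grid
#'
#' Bins the water-oxygen positions of superposed networks on a regular
#' axis-aligned grid, exposing high-occupancy (hotspot) regions.
#'
#' @param networks A `wn_network` or list of them.
#' @param spacing Grid spacing, Angstrom (default 0.5).
#' @param padding Extra margin around the bounding box of the positions.
#' @return A `wn_density_grid`: list with `origin`, `spacing`, `counts`
#'   (3-D array), `n_samples` (positions offered), `n_networks`.
#' @export
density_hotspots <- function(networks, spacing = 0.5, padding = 0) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  if (length(networks) == 0) {
    abort("no networks supplied", class = "hydronet_precondition_error")
  }
  stopifnot(spacing > 0)
  pts <- pool_positions(networks)
  if (nrow(pts) == 0) {
    abort("networks contain no water positions",
          class = "hydronet_precondition_error")
  }
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  origin <- floor((apply(xyz, 2, min) - padding) / spacing) * spacing
  upper <- apply(xyz, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((upper - origin) / spacing + 1e-9)))
  idx <- floor(sweep(xyz, 2L, origin) / spacing) + 1L
  idx <- pmin(idx, matrix(dims, nrow(idx), 3, byrow = TRUE))
  counts <- array(0L, dim = dims)
  for (r in seq_len(nrow(idx))) {
    counts[idx[r, 1], idx[r, 2], idx[r, 3]] <-
      counts[idx[r, 1], idx[r, 2], idx[r, 3]] + 1L
  }
  structure(list(origin = origin, spacing = spacing, counts = counts,
                 n_samples = nrow(xyz), n_networks = length(networks)),
            class = "wn_density_grid")
}

#' @export
print.wn_density_grid <- function(x, ...) {
  cat(sprintf(
    "# Density grid: %s voxels at %.2f A, %d samples from %d networks\n",
    paste(dim(x$counts), collapse = "x"), x$spacing, x$n_samples,
    x$n_networks))
  invisible(x)
}

#' Tidy a density grid into voxel records
#'
#' @param x A `wn_density_grid`.
#' @param ... Unused.
#' @return Tibble of occupied voxels: `x`, `y`, `z` (voxel centres),
#'   `count`, `occupancy` (count / number of networks).
#' @exportS3Method generics::tidy
#' @export
tidy.wn_density_grid <- function(x, ...) {
  occ <- which(x$counts > 0, arr.ind = TRUE)
  origin <- x$origin
  spacing <- x$spacing
  counts <- x$counts[occ]
  n_networks <- x$n_networks
  tibble(
    x = origin[1] + (occ[, 1] - 0.5) * spacing,
    y = origin[2] + (occ[, 2] - 0.5) * spacing,
    z = origin[3] + (occ[, 3] - 0.5) * spacing,
    count = counts,
    occupancy = counts / n_networks) |>
    arrange(dplyr::desc(.data$count))
}
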