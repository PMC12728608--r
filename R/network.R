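#' Hydrogen-bond criteria
#'
#' A hydrogen bond is declared between a donor and an acceptor heavy atom
#' when their distance is at most `distance_cutoff` (default 3.8 A) and —
#' when hydrogen positions are available — at least one
#' donor–hydrogen...acceptor angle is at least `angle_cutoff`
#' (default 150 degrees). Candidate partners are searched among the
#' `neighbor_k` nearest members (default 10) of each water oxygen.
#'
#' @param distance_cutoff Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cutoff D-H...A angle cutoff, degrees.
#' @param use_angle `TRUE`/`FALSE`, or `NULL` to enable the angle test
#'   automatically when water hydrogens are present.
#' @param neighbor_k Number of nearest candidate partners per water
#'   oxygen.
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(distance_cutoff = 3.8, angle_cutoff = 150,
                           use_angle = NULL, neighbor_k = 10L) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180,
            neighbor_k >= 1)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 use_angle = use_angle,
                 neighbor_k = as.integer(neighbor_k)),
            class = "hbond_criteria")
}

BACKBONE_NAMES <- c("N", "O", "OXT")

# Indices of atoms eligible as H-bond partners: water oxygens and
# protein N/O heavy atoms (plus S of Cys/Met); carbon never participates.
partner_indices <- function(structure) {
  with(structure,
       which((is_water & element == "O") |
               (!is_water & !is_hydrogen &
                  (element %in% c("N", "O") |
                     (element == "S" & resname %in% c("CYS", "MET"))))))
}

water_oxygen_indices <- function(structure) {
  which(structure$is_water & structure$element == "O")
}

#' Candidate partner pairs from a nearest-neighbour search
#'
#' For every water oxygen, its `neighbor_k` nearest candidate partners
#' (water oxygens and protein donor/acceptor heavy atoms) are found with
#' a kd-tree; deduplicated pairs are returned with their distances.
#' Distance and angle filtering happen later, in [detect_hbonds()].
#'
#' @param structure A `wn_structure`.
#' @param criteria An [hbond_criteria()].
#' @return Tibble with `idx_a`, `idx_b` (row indices, `idx_a < idx_b`),
#'   `serial_a`, `serial_b`, `distance`.
#' @export
find_candidate_pairs <- function(structure, criteria = hbond_criteria()) {
  wat <- water_oxygen_indices(structure)
  pool <- partner_indices(structure)
  if (length(wat) == 0 || length(pool) < 2) {
    return(tibble(idx_a = integer(0), idx_b = integer(0),
                  serial_a = integer(0), serial_b = integer(0),
                  distance = numeric(0)))
  }
  xyz <- coords(structure)
  k <- min(criteria$neighbor_k + 1L, length(pool))
  nn <- RANN::nn2(xyz[pool, , drop = FALSE], xyz[wat, , drop = FALSE], k = k)
  pairs <- tibble(
    a = rep(wat, each = k),
    b = pool[as.vector(t(nn$nn.idx))],
    distance = as.vector(t(nn$nn.dists)))
  pairs <- filter(pairs, .data$a != .data$b)
  # at most neighbor_k partners per water after removing self
  pairs <- pairs |>
    group_by(.data$a) |>
    filter(row_number() <= criteria$neighbor_k) |>
    ungroup()
  pairs <- pairs |>
    mutate(idx_a = pmin(.data$a, .data$b), idx_b = pmax(.data$a, .data$b)) |>
    distinct(.data$idx_a, .data$idx_b, .keep_all = TRUE) |>
    arrange(.data$idx_a, .data$idx_b)
  tibble(idx_a = pairs$idx_a, idx_b = pairs$idx_b,
         serial_a = structure$serial[pairs$idx_a],
         serial_b = structure$serial[pairs$idx_b],
         distance = pairs$distance)
}

# Hydrogens covalently riding on heavy atom i: same residue, within 1.2 A.
attached_hydrogens <- function(structure, xyz, i) {
  h <- which(structure$is_hydrogen &
               structure$resno == structure$resno[i] &
               structure$chain == structure$chain[i] &
               structure$icode == structure$icode[i])
  if (length(h) == 0) return(integer(0))
  d <- row_dist(xyz[h, , drop = FALSE], xyz[i, ])
  h[d <= 1.2]
}

#' Detect hydrogen bonds in a structure
#'
#' Applies the distance test to candidate pairs and, when hydrogens are
#' in play, the D-H...A angle test: the bond is accepted if any hydrogen
#' on either partner gives an angle at the hydrogen of at least
#' `angle_cutoff`, and the edge is oriented from the passing donor (ties
#' go to the lower atom serial). If neither partner carries a resolvable
#' hydrogen the pair is judged on distance alone.
#'
#' @inheritParams find_candidate_pairs
#' @param mode `"full"`, `"water-water"`, or `"water-protein"`.
#' @return Tibble of interactions: `serial_a`, `serial_b` (donor first
#'   when directed), `kind`, `distance`, `dha_angle`, `donor_serial`,
#'   `protein_site` (`"backbone"`/`"side-chain"` for water-protein).
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria(),
                          mode = c("full", "water-water", "water-protein")) {
  mode <- match.arg(mode)
  use_angle <- criteria$use_angle
  if (is.null(use_angle)) use_angle <- has_hydrogens(structure)
  if (isTRUE(use_angle) && !has_hydrogens(structure)) {
    abort("angle criterion requested but the structure has no water hydrogens",
          class = "hydronet_configuration_error")
  }
  pairs <- find_candidate_pairs(structure, criteria)
  pairs <- filter(pairs, .data$distance <= criteria$distance_cutoff)
  if (nrow(pairs) == 0) return(empty_interactions())
  wat_a <- structure$is_water[pairs$idx_a]
  wat_b <- structure$is_water[pairs$idx_b]
  pairs$kind <- ifelse(wat_a & wat_b, "water-water", "water-protein")
  if (mode == "water-water") pairs <- filter(pairs, .data$kind == "water-water")
  if (mode == "water-protein") {
    pairs <- filter(pairs, .data$kind == "water-protein")
  }
  if (nrow(pairs) == 0) return(empty_interactions())
  xyz <- coords(structure)
  out <- purrr::pmap(
    list(pairs$idx_a, pairs$idx_b, pairs$distance, pairs$kind),
    function(ia, ib, dist, kind) {
      donor <- NA_integer_
      angle <- NA_real_
      if (use_angle) {
        res <- best_dha(structure, xyz, ia, ib, criteria$angle_cutoff)
        if (res$testable && !res$pass) return(NULL)
        donor <- res$donor
        angle <- res$angle
      }
      site <- NA_character_
      if (kind == "water-protein") {
        prot <- if (structure$is_water[ia]) ib else ia
        site <- if (structure$name[prot] %in% BACKBONE_NAMES) "backbone"
        else "side-chain"
      }
      sa <- structure$serial[ia]; sb <- structure$serial[ib]
      if (!is.na(donor) && donor == sb) { tmp <- sa; sa <- sb; sb <- tmp }
      tibble(serial_a = sa, serial_b = sb, kind = kind, distance = dist,
             dha_angle = angle, donor_serial = donor, protein_site = site)
    })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty_interactions())
  arrange(out, .data$serial_a, .data$serial_b)
}

empty_interactions <- function() {
  tibble(serial_a = integer(0), serial_b = integer(0),
         kind = character(0), distance = numeric(0),
         dha_angle = numeric(0), donor_serial = integer(0),
         protein_site = character(0))
}

# Best passing D-H...A geometry over both donor directions.
best_dha <- function(structure, xyz, ia, ib, angle_cutoff) {
  best <- list(pass = FALSE, testable = FALSE, donor = NA_integer_,
               angle = NA_real_)
  for (don in c(ia, ib)) {
    acc <- if (don == ia) ib else ia
    hs <- attached_hydrogens(structure, xyz, don)
    if (length(hs) == 0) next
    best$testable <- TRUE
    for (h in hs) {
      ang <- vec_angle(xyz[don, ] - xyz[h, ], xyz[acc, ] - xyz[h, ])
      if (ang >= angle_cutoff) {
        take <- !best$pass ||
          structure$serial[don] < best$donor ||
          (structure$serial[don] == best$donor && ang > best$angle)
        if (take) {
          best$pass <- TRUE
          best$donor <- structure$serial[don]
          best$angle <- ang
        }
      }
    }
  }
  best
}

#' Build a water network graph
#'
#' Assembles the hydrogen bonds of a structure into a graph whose nodes
#' are water oxygens (all of them, bonded or not) and any protein heavy
#' atoms that take part in an edge. With an active region, waters inside
#' the sphere seed the network and out-of-region partners within the
#' H-bond distance of an in-region water are retained (halo convention);
#' every edge touches an in-region water.
#'
#' @inheritParams detect_hbonds
#' @param region Optional [active_region()].
#' @return A `wn_network`: list with `nodes` (atom tibble plus
#'   `in_region`), `edges` (interaction tibble), `mode`, `directed`,
#'   `structure_id`, `frame_index`, `criteria`.
#' @export
build_network <- function(structure, criteria = hbond_criteria(),
                          mode = c("full", "water-water", "water-protein"),
                          region = NULL) {
  mode <- match.arg(mode)
  use_angle <- criteria$use_angle
  if (is.null(use_angle)) use_angle <- has_hydrogens(structure)
  edges <- detect_hbonds(structure, criteria, mode)
  atoms <- as_tibble(structure)
  if (!is.null(region)) {
    in_region <- region_membership(structure, region)
    wat_serials <- structure$serial[water_oxygen_indices(structure)]
    in_reg_wat <- intersect(structure$serial[in_region], wat_serials)
    edges <- filter(edges, .data$serial_a %in% in_reg_wat |
                      .data$serial_b %in% in_reg_wat)
    water_nodes <- in_reg_wat
  } else {
    in_region <- rep(TRUE, nrow(atoms))
    water_nodes <- structure$serial[water_oxygen_indices(structure)]
  }
  node_serials <- sort(unique(c(water_nodes, edges$serial_a, edges$serial_b)))
  nodes <- atoms[match(node_serials, atoms$serial), , drop = FALSE]
  nodes$in_region <- in_region[match(node_serials, atoms$serial)]
  structure(list(nodes = nodes, edges = edges, mode = mode,
                 directed = isTRUE(use_angle),
                 structure_id = structure_id(structure),
                 frame_index = attr(structure, "frame_index"),
                 criteria = criteria),
            class = "wn_network")
}

#' @export
print.wn_network <- function(x, ...) {
  cat(sprintf(
    "# Water network '%s'%s: %d nodes (%d waters), %d edges (%s, %s)\n",
    x$structure_id,
    if (!is.na(x$frame_index)) paste0(" frame ", x$frame_index) else "",
    nrow(x$nodes), sum(x$nodes$is_water), nrow(x$edges), x$mode,
    if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Convert a water network to an igraph graph
#'
#' Vertex names are atom serials (as character); edges keep distance,
#' kind and angle attributes.
#'
#' @param net A `wn_network`.
#' @param directed Build a directed graph (defaults to the network's
#'   mode; metrics other than density use the undirected projection).
#' @return An `igraph` object.
#' @export
as_igraph <- function(net, directed = net$directed) {
  verts <- data.frame(name = as.character(net$nodes$serial),
                      is_water = net$nodes$is_water)
  ed <- net$edges
  el <- data.frame(from = as.character(ed$serial_a),
                   to = as.character(ed$serial_b),
                   kind = ed$kind, distance = ed$distance)
  igraph::graph_from_data_frame(el, directed = directed, vertices = verts)
}

#' Tidy a water network into its edge list
#'
#' @param x A `wn_network`.
#' @param ... Unused.
#' @return Edge tibble with structure id and frame index attached.
#' @exportS3Method generics::tidy
#' @export
tidy.wn_network <- function(x, ...) {
  mutate(x$edges, structure_id = x$structure_id,
         frame = x$frame_index, .before = 1)
}

#' Write networks as an edge-list CSV
#'
#' @param networks A `wn_network` or list of them.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(networks, path) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  tab <- bind_rows(lapply(networks, tidy))
  tab$directed <- vapply(networks, function(n) n$directed, logical(1))[
    rep(seq_along(networks), vapply(networks, function(n) nrow(n$edges),
                                    integer(1)))]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Plot a water network in projection
#'
#' Draws nodes at their (x, y) coordinates, edges as segments; waters and
#' protein atoms are distinguished by colour.
#'
#' @param object A `wn_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.wn_network <- function(object, ...) {
  nd <- object$nodes
  ed <- object$edges
  seg <- tibble(
    x = nd$x[match(ed$serial_a, nd$serial)],
    y = nd$y[match(ed$serial_a, nd$serial)],
    xend = nd$x[match(ed$serial_b, nd$serial)],
    yend = nd$y[match(ed$serial_b, nd$serial)],
    kind = ed$kind)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$kind),
      colour = "grey40") +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$is_water),
      size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "firebrick"),
      labels = c(`TRUE` = "water", `FALSE` = "protein"),
      name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = sprintf("Water network: %s", object$structure_id))
}
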