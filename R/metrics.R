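#' Graph metrics for water networks
#'
#' Seven quantities summarise a water network: graph density, degree
#' entropy, characteristic path length averaged over connected
#' components, characteristic path length of the largest component,
#' number of connected components, per-node clustering coefficients, and
#' the counts of water-water / water-protein interactions. Apart from
#' density (which uses the directed formula on directed networks), all
#' metrics are computed on the undirected projection of the graph.
#'
#' @param net A `wn_network`.
#' @return `network_metrics()`: one-row tibble with all scalar metrics.
#' @export
network_metrics <- function(net) {
  cpl <- characteristic_path_length(net)
  tibble(
    structure_id = net$structure_id,
    frame = net$frame_index,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_ww_interactions = sum(net$edges$kind == "water-water"),
    n_wp_interactions = sum(net$edges$kind == "water-protein"),
    density = graph_density(net),
    entropy = graph_entropy(net),
    cpl_mean = cpl$cpl_mean,
    cpl_largest = cpl$cpl_largest,
    n_components = n_components(net))
}

#' @rdname network_metrics
#' @exportS3Method generics::glance
#' @export
glance.wn_network <- function(x, ...) network_metrics(x)

undirected_graph <- function(net) {
  igraph::simplify(as_igraph(net, directed = FALSE))
}

#' @rdname network_metrics
#' @details `graph_density()` is the ratio of edges to possible edges:
#'   `2E / (N(N-1))` undirected, `E / (N(N-1))` directed; defined as 0
#'   for fewer than two nodes.
#' @export
graph_density <- function(net) {
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  if (n < 2) return(0)
  if (net$directed) e / (n * (n - 1)) else 2 * e / (n * (n - 1))
}

#' @rdname network_metrics
#' @details `graph_entropy()` is the Shannon entropy (nats) of the
#'   empirical node-degree distribution; a regular graph — every node
#'   with the same degree — has entropy 0, and more heterogeneous
#'   degree mixes score higher.
#' @export
graph_entropy <- function(net) {
  if (nrow(net$nodes) == 0) return(0)
  g <- undirected_graph(net)
  deg <- igraph::degree(g)
  p <- as.numeric(table(deg)) / length(deg)
  -sum(p * log(p))
}

#' @rdname network_metrics
#' @details `characteristic_path_length()` averages the shortest-path
#'   edge count over all distinct vertex pairs within each connected
#'   component; `cpl_mean` is the unweighted mean over components with
#'   at least two nodes, `cpl_largest` the value for the component with
#'   most nodes (ties broken by edge count, then first). Both are `NA`
#'   when no component has two nodes.
#' @export
characteristic_path_length <- function(net) {
  g <- undirected_graph(net)
  if (igraph::vcount(g) == 0) {
    return(list(cpl_mean = NA_real_, cpl_largest = NA_real_))
  }
  comp <- igraph::components(g)
  per_comp <- purrr::map(seq_len(comp$no), function(ci) {
    vs <- which(comp$membership == ci)
    if (length(vs) < 2) return(NULL)
    sub <- igraph::induced_subgraph(g, vs)
    dmat <- igraph::distances(sub)
    list(cpl = mean(dmat[upper.tri(dmat)]),
         n = length(vs), e = igraph::ecount(sub))
  })
  per_comp <- purrr::compact(per_comp)
  if (length(per_comp) == 0) {
    return(list(cpl_mean = NA_real_, cpl_largest = NA_real_))
  }
  cpls <- vapply(per_comp, `[[`, numeric(1), "cpl")
  ns <- vapply(per_comp, `[[`, numeric(1), "n")
  es <- vapply(per_comp, `[[`, numeric(1), "e")
  best <- order(-ns, -es)[1]
  list(cpl_mean = mean(cpls), cpl_largest = cpls[best])
}

#' @rdname network_metrics
#' @export
n_components <- function(net) {
  g <- undirected_graph(net)
  if (igraph::vcount(g) == 0) return(0L)
  igraph::components(g)$no
}

#' @rdname network_metrics
#' @details `clustering_coefficients()` returns the triangle-based local
#'   clustering coefficient of every node (0 for nodes of degree < 2).
#' @export
clustering_coefficients <- function(net) {
  g <- undirected_graph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble(serial = net$nodes$serial,
         is_water = net$nodes$is_water,
         clustering = unname(cc[match(as.character(net$nodes$serial),
                                      igraph::V(g)$name)]))
}

#' Shortest path between two atoms of a network
#'
#' @param net A `wn_network`.
#' @param from,to Atom serials.
#' @return Integer vector of serials along one minimum-hop path, or
#'   `NULL` when the two atoms are disconnected.
#' @export
shortest_path_between <- function(net, from, to) {
  g <- undirected_graph(net)
  nm <- igraph::V(g)$name
  if (!as.character(from) %in% nm || !as.character(to) %in% nm) {
    abort("atom serial not present in the network",
          class = "hydronet_lookup_error")
  }
  p <- suppressWarnings(
    igraph::shortest_paths(g, as.character(from), as.character(to)))
  verts <- p$vpath[[1]]
  if (length(verts) == 0) return(NULL)
  as.integer(names(verts))
}

#' Write scalar metrics (one row per structure/frame) to CSV
#'
#' @param networks A `wn_network` or list of them.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(networks, path) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  write.csv(bind_rows(lapply(networks, network_metrics)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_clustering_csv <- function(networks, path) {
  if (inherits(networks, "wn_network")) networks <- list(networks)
  tab <- bind_rows(lapply(networks, function(n) {
    mutate(clustering_coefficients(n), structure_id = n$structure_id,
           frame = n$frame_index, .before = 1)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
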