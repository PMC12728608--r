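#' Density-based clustering parameters
#'
#' Pooled water-oxygen positions are grouped into spatial clusters with a
#' density-based algorithm. DBSCAN (the default) uses a fixed
#' neighbourhood radius `eps`; OPTICS orders points by reachability and
#' extracts the DBSCAN-equivalent clustering at `eps`; HDBSCAN builds the
#' mutual-reachability minimum spanning tree and selects clusters of at
#' least `min_cluster_size` points by stability. A point's neighbourhood
#' count includes the point itself.
#'
#' @param algorithm `"dbscan"`, `"optics"`, or `"hdbscan"`.
#' @param eps Neighbourhood radius, Angstrom (dbscan/optics).
#' @param min_samples Minimum neighbourhood size for a core point.
#' @param min_cluster_size Minimum cluster size (hdbscan).
#' @return A `cluster_params` object.
#' @export
cluster_params <- function(algorithm = c("dbscan", "optics", "hdbscan"),
                           eps = 1.0, min_samples = 5L,
                           min_cluster_size = 5L) {
  algorithm <- match.arg(algorithm)
  stopifnot(eps > 0, min_samples >= 1, min_cluster_size >= 2)
  structure(list(algorithm = algorithm, eps = eps,
                 min_samples = as.integer(min_samples),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Cluster a point cloud
#'
#' Low-level interface used by [cluster_waters()]. Labels are integers:
#' 0 marks noise, clusters are numbered 1, 2, ... by the index of their
#' first member point, so labelling is deterministic.
#'
#' @param xyz Numeric matrix of points (rows) in 3-space.
#' @param params A [cluster_params()].
#' @return Integer vector of labels, one per row of `xyz`.
#' @export
cluster_points <- function(xyz, params = cluster_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  labels <- switch(params$algorithm,
                   dbscan = dbscan_labels(xyz, params$eps, params$min_samples),
                   optics = optics_labels(xyz, params$eps, params$min_samples),
                   hdbscan = hdbscan_labels(xyz, params$min_samples,
                                            params$min_cluster_size))
  relabel_by_first(labels)
}

relabel_by_first <- function(labels) {
  ids <- unique(labels[labels > 0])
  firsts <- vapply(ids, function(i) min(which(labels == i)), integer(1))
  new_ids <- setNames(order(order(firsts)), ids)
  out <- labels
  out[labels > 0] <- new_ids[as.character(labels[labels > 0])]
  out
}

eps_neighbours <- function(xyz, eps) {
  n <- nrow(xyz)
  k <- min(n, 1024L)
  nn <- RANN::nn2(xyz, xyz, k = k, searchtype = "radius", radius = eps)
  lapply(seq_len(n), function(i) {
    idx <- nn$nn.idx[i, ]
    idx[idx > 0]
  })
}

dbscan_labels <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  nbrs <- eps_neighbours(xyz, eps)
  core <- lengths(nbrs) >= min_samples
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (!visited[q] && core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Core distance: distance to the min_samples-th nearest point (self
# included), as in the OPTICS/HDBSCAN literature.
core_distances <- function(xyz, min_samples) {
  n <- nrow(xyz)
  k <- min(min_samples, n)
  nn <- RANN::nn2(xyz, xyz, k = k)
  nn$nn.dists[, k]
}

# OPTICS reachability ordering with DBSCAN-equivalent extraction at eps.
optics_labels <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  cd <- core_distances(xyz, min_samples)
  nbrs <- eps_neighbours(xyz, eps)
  dmat_row <- function(i) row_dist(xyz, xyz[i, ])
  order_out <- integer(0)
  reach <- rep(Inf, n)
  processed <- logical(n)
  seeds <- numeric(0)  # named vector: names = point index, value = reach
  for (start in seq_len(n)) {
    if (processed[start]) next
    queue <- start
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (processed[p]) next
      processed[p] <- TRUE
      order_out <- c(order_out, p)
      if (cd[p] <= eps) {
        d <- dmat_row(p)
        for (q in nbrs[[p]]) {
          if (processed[q]) next
          newreach <- max(cd[p], d[q])
          if (newreach < reach[q]) reach[q] <- newreach
        }
        todo <- which(!processed & is.finite(reach))
        if (length(todo) > 0) {
          queue <- todo[order(reach[todo], todo)]
        }
      }
    }
  }
  labels <- integer(n)
  cl <- 0L
  current <- 0L
  for (p in order_out) {
    if (reach[p] > eps) {
      if (cd[p] <= eps) {
        cl <- cl + 1L
        current <- cl
        labels[p] <- current
      } else {
        labels[p] <- 0L
        current <- 0L
      }
    } else {
      labels[p] <- current
    }
  }
  labels
}

hdbscan_labels <- function(xyz, min_samples, min_cluster_size,
                           allow_single_cluster = TRUE) {
  n <- nrow(xyz)
  if (n < min_cluster_size) return(integer(n))
  cd <- core_distances(xyz, min_samples)
  d <- as.matrix(dist(xyz))
  dmr <- pmax(d, outer(cd, cd, pmax))
  diag(dmr) <- 0
  hc <- hclust(as.dist(dmr), method = "single")
  condensed <- condense_tree(hc, n, min_cluster_size)
  chosen <- select_clusters(condensed, allow_single_cluster)
  labels <- integer(n)
  for (k in seq_along(chosen)) labels[chosen[[k]]$points] <- k
  labels
}

# Build the condensed cluster tree from a single-linkage dendrogram.
# Returns the root condensed cluster: list(points, stability, children).
condense_tree <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  nm <- nrow(merge)
  members <- vector("list", nm)
  for (k in seq_len(nm)) {
    get_m <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- c(get_m(merge[k, 1]), get_m(merge[k, 2]))
  }
  lambda_of <- function(h) if (h <= 0) 1e12 else 1 / h
  # node reference: k > 0 internal (merge row), k < 0 leaf (-point)
  node_size <- function(v) if (v < 0) 1L else length(members[[v]])
  condense <- function(node, lambda_birth) {
    pts <- if (node < 0) -node else members[[node]]
    res <- list(points = pts, stability = 0, children = list())
    walk <- function(v) {
      if (v < 0) return()  # single point handled by its parent
      lam <- lambda_of(height[v])
      l <- merge[v, 1]; r <- merge[v, 2]
      sl <- node_size(l); sr <- node_size(r)
      if (sl >= mcs && sr >= mcs) {
        res$stability <<- res$stability +
          (sl + sr) * (lam - lambda_birth)
        res$children <<- c(res$children,
                           list(condense(l, lam), condense(r, lam)))
      } else {
        for (ch in list(l, r)) {
          if (node_size(ch) < mcs) {
            res$stability <<- res$stability +
              node_size(ch) * (lam - lambda_birth)
          } else {
            walk(ch)
          }
        }
      }
    }
    if (node > 0) walk(node) else {
      res$stability <- 0
    }
    res
  }
  condense(nm, 0)
}

# Excess-of-mass cluster selection: keep a cluster unless its selected
# descendants are jointly more stable. The root is only returned when it
# has no competing children and single-cluster output is allowed.
select_clusters <- function(root, allow_single_cluster) {
  pick <- function(cl, is_root) {
    if (length(cl$children) == 0) {
      if (is_root && !allow_single_cluster) return(list())
      return(list(cl))
    }
    below <- unlist(lapply(cl$children, pick, is_root = FALSE),
                    recursive = FALSE)
    below_stab <- sum(vapply(below, `[[`, numeric(1), "stability"))
    if (is_root || below_stab > cl$stability) below else list(cl)
  }
  pick(root, TRUE)
}
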