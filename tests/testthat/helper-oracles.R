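# Independent brute-force references used across the suite. These are
# deliberately written with plain loops and base R, not via the package
# internals they check.

o_dist <- function(p, q) sqrt(sum((p - q)^2))

o_angle <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# All-pairs H-bond test over the same partner-atom definition as the
# package documents: water oxygens, protein N/O heavy atoms, S of
# Cys/Met; every bond involves at least one water.
oracle_partner_rows <- function(s) {
  which((s$is_water & s$element == "O") |
          (!s$is_water & !s$is_hydrogen &
             (s$element %in% c("N", "O") |
                (s$element == "S" & s$resname %in% c("CYS", "MET")))))
}

oracle_hydrogens_of <- function(s, xyz, i) {
  out <- integer(0)
  for (h in which(s$is_hydrogen)) {
    if (s$resno[h] == s$resno[i] && s$chain[h] == s$chain[i] &&
        o_dist(xyz[h, ], xyz[i, ]) <= 1.2) {
      out <- c(out, h)
    }
  }
  out
}

oracle_hbonds <- function(s, distance_cutoff = 3.8, angle_cutoff = 150,
                          use_angle = FALSE,
                          mode = c("full", "water-water", "water-protein")) {
  mode <- match.arg(mode)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rows <- oracle_partner_rows(s)
  edges <- NULL
  for (ii in seq_along(rows)) {
    for (jj in seq_along(rows)) {
      if (jj <= ii) next
      a <- rows[ii]; b <- rows[jj]
      if (!s$is_water[a] && !s$is_water[b]) next
      kind <- if (s$is_water[a] && s$is_water[b]) "water-water"
      else "water-protein"
      if (mode == "water-water" && kind != "water-water") next
      if (mode == "water-protein" && kind != "water-protein") next
      d <- o_dist(xyz[a, ], xyz[b, ])
      if (d > distance_cutoff) next
      if (use_angle) {
        testable <- FALSE
        pass <- FALSE
        for (don in c(a, b)) {
          acc <- if (don == a) b else a
          for (h in oracle_hydrogens_of(s, xyz, don)) {
            testable <- TRUE
            ang <- o_angle(xyz[don, ] - xyz[h, ], xyz[acc, ] - xyz[h, ])
            if (ang >= angle_cutoff) pass <- TRUE
          }
        }
        if (testable && !pass) next
      }
      edges <- rbind(edges, data.frame(serial_a = min(s$serial[a],
                                                      s$serial[b]),
                                       serial_b = max(s$serial[a],
                                                      s$serial[b])))
    }
  }
  if (is.null(edges)) {
    return(data.frame(serial_a = integer(0), serial_b = integer(0)))
  }
  edges[order(edges$serial_a, edges$serial_b), , drop = FALSE]
}

# Canonical unordered edge-set string for comparison.
edge_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(pmin(df$serial_a, df$serial_b),
             pmax(df$serial_a, df$serial_b), sep = "-"))
}

# --- graph references on an adjacency list ------------------------------

# edges: data.frame(a, b) over nodes 1..n
oracle_adj <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$a[k]; b <- edges$b[k]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

oracle_bfs_dist <- function(adj, src) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

oracle_components <- function(adj) {
  n <- length(adj)
  comp <- rep(0L, n)
  c0 <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      c0 <- c0 + 1L
      reach <- which(is.finite(oracle_bfs_dist(adj, v)))
      comp[reach] <- c0
    }
  }
  comp
}

oracle_cpl <- function(adj) {
  comp <- oracle_components(adj)
  cpls <- c(); sizes <- c(); nedges <- c()
  for (ci in unique(comp)) {
    vs <- which(comp == ci)
    if (length(vs) < 2) next
    tot <- 0; np <- 0
    for (v in vs) {
      d <- oracle_bfs_dist(adj, v)
      for (w in vs) {
        if (w != v) { tot <- tot + d[w]; np <- np + 1 }
      }
    }
    cpls <- c(cpls, tot / np)
    sizes <- c(sizes, length(vs))
    nedges <- c(nedges, sum(lengths(adj[vs])) / 2)
  }
  if (length(cpls) == 0) return(list(mean = NA_real_, largest = NA_real_))
  best <- order(-sizes, -nedges)[1]
  list(mean = mean(cpls), largest = cpls[best])
}

oracle_density <- function(n, n_edges, directed = FALSE) {
  if (n < 2) return(0)
  if (directed) n_edges / (n * (n - 1)) else 2 * n_edges / (n * (n - 1))
}

oracle_entropy <- function(adj) {
  deg <- lengths(adj)
  if (length(deg) == 0) return(0)
  p <- as.numeric(table(deg)) / length(deg)
  -sum(p * log(p))
}

oracle_clustering <- function(adj) {
  vapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (j > i && nb[j] %in% adj[[nb[i]]]) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# --- constructors for arbitrary test graphs -----------------------------

# Wrap an abstract graph (nodes 1..n, edge list) as a wn_network so the
# package metrics can run on it.
net_from_edges <- function(n, edges, directed = FALSE) {
  nodes <- tibble::tibble(
    serial = seq_len(n), name = "O", element = "O", resname = "HOH",
    resno = seq_len(n), chain = "W", icode = "",
    x = stats::runif(n, 0, 50), y = stats::runif(n, 0, 50),
    z = stats::runif(n, 0, 50),
    occupancy = 1, is_water = TRUE, is_hydrogen = FALSE, in_region = TRUE)
  ed <- if (nrow(edges) == 0) {
    tibble::tibble(serial_a = integer(0), serial_b = integer(0),
                   kind = character(0), distance = numeric(0),
                   dha_angle = numeric(0), donor_serial = integer(0),
                   protein_site = character(0))
  } else {
    tibble::tibble(serial_a = as.integer(edges$a),
                   serial_b = as.integer(edges$b),
                   kind = "water-water", distance = 3.0,
                   dha_angle = NA_real_, donor_serial = NA_integer_,
                   protein_site = NA_character_)
  }
  structure(list(nodes = nodes, edges = ed, mode = "water-water",
                 directed = directed, structure_id = "testgraph",
                 frame_index = NA_integer_,
                 criteria = hydronet::hbond_criteria()),
            class = "wn_network")
}

random_graph_edges <- function(n, p) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(a = pairs[keep, 1], b = pairs[keep, 2])
}

# Random structure with waters (optionally protons) and a few protein
# polar atoms, for oracle-equivalence testing of network construction.
random_fixture_structure <- function(n_waters = 8, n_protein = 4,
                                     box = 8, hydrogens = FALSE) {
  atoms <- NULL
  serial <- 0L
  for (i in seq_len(n_protein)) {
    serial <- serial + 1L
    atoms <- rbind(atoms, data.frame(
      serial = serial, name = sample(c("N", "O", "OG", "ND1"), 1),
      element = sample(c("N", "O"), 1), resname = "SER", resno = i,
      chain = "A", icode = "",
      x = stats::runif(1, 0, box), y = stats::runif(1, 0, box),
      z = stats::runif(1, 0, box), occupancy = 1,
      is_water = FALSE, is_hydrogen = FALSE))
  }
  for (w in seq_len(n_waters)) {
    o <- stats::runif(3, 0, box)
    serial <- serial + 1L
    atoms <- rbind(atoms, data.frame(
      serial = serial, name = "O", element = "O", resname = "HOH",
      resno = n_protein + w, chain = "W", icode = "",
      x = o[1], y = o[2], z = o[3], occupancy = 1,
      is_water = TRUE, is_hydrogen = FALSE))
    if (hydrogens) {
      for (hn in c("H1", "H2")) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        h <- o + 0.96 * u
        serial <- serial + 1L
        atoms <- rbind(atoms, data.frame(
          serial = serial, name = hn, element = "H", resname = "HOH",
          resno = n_protein + w, chain = "W", icode = "",
          x = h[1], y = h[2], z = h[3], occupancy = 1,
          is_water = TRUE, is_hydrogen = TRUE))
      }
    }
  }
  hydronet::new_structure(atoms, id = "random", source = "static")
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- exhaustive global-alignment oracle ---------------------------------

# Enumerates every global alignment of two short sequences and scores it
# with BLOSUM62 + affine gap penalties (open 10, extend 0.5, charged as
# 10.5 for the first gap character). Returns the best score and one
# optimal alignment (ties: first found).
oracle_nw <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  sub <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, a = NULL, b = NULL)
  rec <- function(i, j, sa, sb, score, last) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score) best <<- list(score = score, a = sa, b = sb)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, c(sa, a[i]), c(sb, b[j]),
          score + sub[a[i], b[j]], "m")
    }
    if (i <= length(a)) {
      pen <- if (last == "x") gap_extend else gap_open + gap_extend
      rec(i + 1, j, c(sa, a[i]), c(sb, "-"), score - pen, "x")
    }
    if (j <= length(b)) {
      pen <- if (last == "y") gap_extend else gap_open + gap_extend
      rec(i, j + 1, c(sa, "-"), c(sb, b[j]), score - pen, "y")
    }
  }
  rec(1, 1, character(0), character(0), 0, "m")
  best
}

# --- deliberately sparse protein for interaction-score tests ------------

# Three serine-like residues 12 A apart: waters planted near one OG are
# out of H-bond range of every other residue.
protein_for_scores <- function() {
  one <- function(i) {
    ox <- 12 * (i - 1)
    data.frame(
      serial = (i - 1) * 6 + 1:6,
      name = c("N", "CA", "C", "O", "CB", "OG"),
      element = c("N", "C", "C", "O", "C", "O"),
      resname = "SER", resno = i, chain = "A", icode = "",
      x = ox + c(0, 0.9, 2.1, 2.4, 0.9, 0.8),
      y = c(0, 1.1, 0.9, 0.0, 2.3, 3.1),
      z = c(0, 0.3, 0.8, 1.5, 0.8, 2.0),
      occupancy = 1, is_water = FALSE, is_hydrogen = FALSE)
  }
  do.call(rbind, lapply(1:3, one))
}

water_rows <- function(xyz, serial_offset) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(
    serial = serial_offset + seq_len(nrow(xyz)),
    name = "O", element = "O", resname = "HOH",
    resno = 100 + seq_len(nrow(xyz)), chain = "W", icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, is_water = TRUE, is_hydrogen = FALSE)
}
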