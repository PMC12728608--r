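#' Synthetic structure and trajectory fixtures with planted geometry
#'
#' Generates minimal protein structures decorated with waters at known
#' ("planted") sites so that every stage of the pipeline can be
#' validated against construction: presence probabilities set cluster
#' conservation, positional jitter sets cluster spread, and planted
#' donor-hydrogen-acceptor angles and distances probe the hydrogen-bond
#' thresholds. The protein template is a short chain of serine-like
#' pseudo-residues (backbone N, CA, C, O plus side-chain CB, OG) laid
#' out on a gentle helix, enough for backbone/side-chain classification
#' and C-alpha superposition without any force field.
#'
#' All randomness flows from `seed` through a counter-based scheme: the
#' draw for structure (or frame) `i` depends only on `seed` and `i`, so
#' sub-generators are order-independent and a fixed seed reproduces the
#' fixture exactly.
#'
#' @param n_structures Number of static structures.
#' @param n_frames Number of trajectory frames.
#' @param n_residues Residues in the protein template.
#' @param water_sites Matrix (sites x 3) of planted water-oxygen
#'   positions; default places one site 2.8 A off each of the first
#'   three side-chain oxygens.
#' @param presence Per-site probability that a structure realises the
#'   site (recycled; default 1).
#' @param jitter Positional jitter sigma, Angstrom (default 0.2).
#' @param rigid_sigma When > 0, each structure is displaced by a random
#'   small rigid rotation (radians scale) and translation (Angstrom) to
#'   exercise superposition.
#' @param hydrogens Add water hydrogens (0.96 A bond length)?
#' @param dha_angle Planted donor-hydrogen-acceptor angle towards the
#'   nearest H-bond partner, degrees (default 165).
#' @param schedule Optional trajectory schedule: list of
#'   `list(position = c(x, y, z), frames = integer frame numbers
#'   (1-based))` entries, each planting one water in the given frames.
#'   When `NULL`, all `water_sites` are present in every frame.
#' @param seed Integer seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_structures = 5L, n_frames = 10L, n_residues = 4L,
                         water_sites = NULL, presence = 1, jitter = 0.2,
                         rigid_sigma = 0, hydrogens = FALSE,
                         dha_angle = 165, schedule = NULL, seed = 1L) {
  stopifnot(jitter >= 0, all(presence >= 0 & presence <= 1),
            n_residues >= 3)
  template <- protein_template(n_residues)
  if (is.null(water_sites)) {
    og <- as.matrix(filter(template, .data$name == "OG")[, c("x", "y", "z")])
    k <- min(3L, nrow(og))
    water_sites <- og[seq_len(k), , drop = FALSE] +
      matrix(rep(c(0.0, 1.4, 2.4), each = k), ncol = 3)
  }
  water_sites <- as.matrix(water_sites)
  structure(list(n_structures = as.integer(n_structures),
                 n_frames = as.integer(n_frames),
                 n_residues = as.integer(n_residues),
                 template = template,
                 water_sites = water_sites,
                 presence = rep_len(presence, nrow(water_sites)),
                 jitter = jitter, rigid_sigma = rigid_sigma,
                 hydrogens = hydrogens, dha_angle = dha_angle,
                 schedule = schedule, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Serine-like pseudo-residues on a gentle helix; coordinates in Angstrom.
protein_template <- function(n_residues) {
  res_atoms <- tibble(
    name = c("N", "CA", "C", "O", "CB", "OG"),
    element = c("N", "C", "C", "O", "C", "O"),
    dx = c(0.0, 0.9, 2.1, 2.4, 0.9, 0.8),
    dy = c(0.0, 1.1, 0.9, 0.0, 2.3, 3.1),
    dz = c(0.0, 0.3, 0.8, 1.5, 0.8, 2.0))
  rows <- purrr::map_dfr(seq_len(n_residues), function(i) {
    off <- c(3.8 * (i - 1), 1.2 * sin(0.9 * i), 1.2 * cos(0.9 * i))
    mutate(res_atoms,
           resno = i, resname = "SER", chain = "A",
           x = .data$dx + off[1], y = .data$dy + off[2],
           z = .data$dz + off[3])
  })
  rows |>
    mutate(serial = row_number(), icode = "", occupancy = 1,
           is_water = FALSE, is_hydrogen = FALSE) |>
    select("serial", "name", "element", "resname", "resno", "chain",
           "icode", "x", "y", "z", "occupancy", "is_water", "is_hydrogen")
}

# Counter-based sub-seed: draws for unit i depend only on (seed, i).
mix_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1299721 + 1) %%
               2147483629)
}

#' Generate the fixture's static structures in memory
#'
#' @param spec A [fixture_spec()].
#' @return Named list of `wn_structure` objects (`fix001`, `fix002`, ...).
#' @export
make_structures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- lapply(seq_len(spec$n_structures), function(i) {
    withr::with_seed(mix_seed(spec$seed, i), {
      realised <- runif(nrow(spec$water_sites)) <= spec$presence
      atoms <- assemble_fixture(spec,
                                spec$water_sites[realised, , drop = FALSE])
      if (spec$rigid_sigma > 0) {
        rot <- small_rotation(spec$rigid_sigma)
        shift <- rnorm(3, sd = spec$rigid_sigma * 5)
        xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
        xyz <- sweep(xyz, 2L, shift, "+")
        atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
      }
      new_structure(atoms, id = sprintf("fix%03d", i), source = "static")
    })
  })
  setNames(out, vapply(out, structure_id, character(1)))
}

small_rotation <- function(sigma) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- rnorm(1, sd = sigma)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Protein template + jittered waters (+ optional hydrogens).
assemble_fixture <- function(spec, sites) {
  atoms <- spec$template
  if (nrow(sites) > 0) {
    jit <- matrix(rnorm(length(sites), sd = spec$jitter), ncol = 3)
    wpos <- sites + jit
    atoms <- bind_rows(atoms, water_atoms(spec, atoms, wpos))
  }
  atoms$serial <- seq_len(nrow(atoms))
  atoms
}

water_atoms <- function(spec, protein, wpos) {
  next_serial <- max(protein$serial)
  next_resno <- max(protein$resno)
  rows <- purrr::map_dfr(seq_len(nrow(wpos)), function(w) {
    o <- wpos[w, ]
    at <- tibble(name = "O", element = "O", resname = "HOH", resno = 0L,
                 chain = "W", icode = "", x = o[1], y = o[2], z = o[3],
                 occupancy = 1, is_water = TRUE, is_hydrogen = FALSE)
    if (spec$hydrogens) {
      partner <- nearest_partner(protein, wpos, w)
      h1 <- place_hydrogen(o, partner, theta_deg = spec$dha_angle)
      h2 <- second_hydrogen(o, h1)
      at <- bind_rows(
        at,
        tibble(name = c("H1", "H2"), element = "H", resname = "HOH",
               resno = 0L, chain = "W", icode = "",
               x = c(h1[1], h2[1]), y = c(h1[2], h2[2]),
               z = c(h1[3], h2[3]),
               occupancy = 1, is_water = TRUE, is_hydrogen = TRUE))
    }
    at
  })
  n_waters <- nrow(wpos)
  resnos <- rep(seq_len(n_waters), times = nrow(rows) / n_waters)
  rows$resno <- next_resno + sort(rep(seq_len(n_waters),
                                      length.out = nrow(rows)))
  rows$serial <- next_serial + seq_len(nrow(rows))
  rows
}

# Nearest N/O/OG heavy atom or other planted water oxygen.
nearest_partner <- function(protein, wpos, w) {
  cand <- filter(protein, .data$element %in% c("N", "O"))
  pool <- rbind(as.matrix(cand[, c("x", "y", "z")]),
                wpos[-w, , drop = FALSE])
  d <- row_dist(pool, wpos[w, ])
  pool[which.min(d), ]
}

# Place a hydrogen at bond length r from donor D so that the
# D-H...A angle equals theta_deg.
place_hydrogen <- function(D, A, r = 0.96, theta_deg = 165) {
  v <- A - D
  L <- sqrt(sum(v^2))
  e1 <- v / L
  e2 <- perpendicular_unit(e1)
  angle_at_h <- function(phi) {
    H <- D + r * (cos(phi) * e1 + sin(phi) * e2)
    vec_angle(D - H, A - H)
  }
  if (theta_deg >= angle_at_h(0)) {
    phi <- 0
  } else {
    phi <- uniroot(function(p) angle_at_h(p) - theta_deg,
                   lower = 0, upper = pi * 0.98, tol = 1e-10)$root
  }
  D + r * (cos(phi) * e1 + sin(phi) * e2)
}

perpendicular_unit <- function(e1) {
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 / sqrt(sum(e2^2))
}

# Second hydrogen ~104.5 degrees from the first, out of plane.
second_hydrogen <- function(O, H1, r = 0.96) {
  u <- (H1 - O) / sqrt(sum((H1 - O)^2))
  e2 <- perpendicular_unit(u)
  e3 <- c(u[2] * e2[3] - u[3] * e2[2],
          u[3] * e2[1] - u[1] * e2[3],
          u[1] * e2[2] - u[2] * e2[1])
  ang <- 104.5 * pi / 180
  O + r * (cos(ang) * u + sin(ang) * (0.5 * e2 + 0.866 * e3) /
             sqrt(sum((0.5 * e2 + 0.866 * e3)^2)))
}

#' Write the fixture's static structures as PDB files
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
make_static_set <- function(spec, dir) {
  structures <- make_structures(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(structures, function(s) {
    p <- file.path(dir, paste0(structure_id(s), ".pdb"))
    write_structure(s, p)
    p
  }, character(1))
  invisible(paths)
}

#' Generate the fixture's trajectory frames in memory
#'
#' Waters follow `spec$schedule` (or occupy every site in every frame);
#' each occurrence is jittered independently.
#'
#' @param spec A [fixture_spec()].
#' @return List of `wn_structure` frames with 0-based `frame_index`.
#' @export
make_frames <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  schedule <- spec$schedule
  if (is.null(schedule)) {
    schedule <- lapply(seq_len(nrow(spec$water_sites)), function(s) {
      list(position = spec$water_sites[s, ], frames = seq_len(spec$n_frames))
    })
  }
  lapply(seq_len(spec$n_frames), function(f) {
    withr::with_seed(mix_seed(spec$seed, 100000L + f), {
      pos <- purrr::map(schedule, function(entry) {
        if (f %in% entry$frames) entry$position else NULL
      })
      pos <- do.call(rbind, purrr::compact(pos))
      if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
      atoms <- assemble_fixture(spec, pos)
      new_structure(atoms, id = sprintf("traj_frame%04d", f - 1L),
                    source = "frame", frame_index = f - 1L)
    })
  })
}

#' Write the fixture's trajectory as a multi-model PDB
#'
#' Frame 0 doubles as the topology; every frame must therefore contain
#' the same atoms, so `make_trajectory` requires a schedule in which the
#' set of planted waters is constant across frames (waters that "leave"
#' should instead be scheduled at a distant parking position).
#'
#' @param spec A [fixture_spec()].
#' @param path Output multi-model PDB file.
#' @return `path`, invisibly.
#' @export
make_trajectory <- function(spec, path) {
  frames <- make_frames(spec)
  n_atoms <- unique(vapply(frames, nrow, integer(1)))
  if (length(n_atoms) != 1) {
    abort(paste("multi-model output needs a constant atom count;",
                "schedule waters in every frame (use a parking position)"),
          class = "hydronet_precondition_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    tmp <- tempfile(fileext = ".pdb")
    write_structure(frames[[k]], tmp)
    lines <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    lines <- lines[!grepl("^END\\s*$|^END$", lines)]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
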