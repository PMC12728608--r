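#' Atom tables for structures and trajectory frames
#'
#' A structure is a tibble of atoms (one row per atom) carrying a few
#' attributes: an `id` (file stem or frame label), a `source` flag
#' (`"static"` for an experimental structure, `"frame"` for a trajectory
#' snapshot), an optional `frame_index`, and the set of residue names that
#' were treated as water. Columns:
#' `serial`, `name`, `element`, `resname`, `resno`, `chain`, `icode`,
#' `x`, `y`, `z` (Angstrom), `occupancy`, `is_water`, `is_hydrogen`.
#'
#' @param atoms A data frame with the columns listed above (missing
#'   `icode`/`occupancy` are filled with `""` / `1`).
#' @param id Structure identifier.
#' @param source `"static"` or `"frame"`.
#' @param frame_index Integer frame number (0-based) or `NA` for static
#'   structures.
#' @param water_residue_names Residue names flagged as water.
#' @return A `wn_structure` tibble.
#' @export
new_structure <- function(atoms, id,
                          source = c("static", "frame"),
                          frame_index = NA_integer_,
                          water_residue_names = WATER_RESIDUE_NAMES) {
  source <- match.arg(source)
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    abort(sprintf("structure '%s' contains no atoms", id),
          class = "hydronet_empty_structure_error")
  }
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$element <- toupper(atoms$element)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_water <- atoms$resname %in% water_residue_names
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort(sprintf("structure '%s' has non-finite coordinates", id),
          class = "hydronet_format_error")
  }
  if (anyDuplicated(atoms$serial)) {
    atoms$serial <- seq_len(nrow(atoms))
  }
  cols <- c("serial", "name", "element", "resname", "resno", "chain",
            "icode", "x", "y", "z", "occupancy", "is_water", "is_hydrogen")
  atoms <- atoms[, cols]
  structure(atoms,
            class = c("wn_structure", class(tibble()))) |>
    set_structure_attrs(id = id, source = source,
                        frame_index = as.integer(frame_index),
                        water_residue_names = water_residue_names)
}

set_structure_attrs <- function(x, id, source, frame_index,
                                water_residue_names) {
  attr(x, "id") <- id
  attr(x, "source") <- source
  attr(x, "frame_index") <- frame_index
  attr(x, "water_residue_names") <- water_residue_names
  attr(x, "has_hydrogens") <- any(x$is_water & x$is_hydrogen)
  x
}

# Rebuild a wn_structure from a plain atom tibble, inheriting attributes.
rewrap_structure <- function(atoms, template) {
  new_structure(atoms,
                id = structure_id(template),
                source = attr(template, "source"),
                frame_index = attr(template, "frame_index"),
                water_residue_names = attr(template, "water_residue_names"))
}

#' @export
print.wn_structure <- function(x, ...) {
  cat(sprintf("# Structure '%s' (%s%s): %d atoms, %d waters%s\n",
              structure_id(x), attr(x, "source"),
              if (!is.na(attr(x, "frame_index")))
                paste0(" ", attr(x, "frame_index")) else "",
              nrow(x), sum(x$is_water & !x$is_hydrogen),
              if (isTRUE(attr(x, "has_hydrogens"))) ", with water hydrogens"
              else ""))
  NextMethod()
}

#' @rdname new_structure
#' @param x A `wn_structure`.
#' @export
structure_id <- function(x) attr(x, "id")

#' @rdname new_structure
#' @export
has_hydrogens <- function(x) isTRUE(attr(x, "has_hydrogens"))

coords <- function(x) as.matrix(x[, c("x", "y", "z")])

#' Read a PDB structure into an atom table
#'
#' Reads ATOM/HETATM records (first MODEL only), flags waters by residue
#' name, and resolves alternate locations by keeping the highest-occupancy
#' conformer of each atom (ties go to the first encountered).
#'
#' @param path Path to a PDB file.
#' @param water_residue_names Residue names treated as water (default
#'   HOH, WAT, TIP3, SPC, T3P, SOL).
#' @return A [new_structure()] tibble with `id` set to the file stem.
#' @export
read_structure <- function(path, water_residue_names = WATER_RESIDUE_NAMES) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "hydronet_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      abort(sprintf("cannot parse '%s' as PDB: %s", path, conditionMessage(e)),
            class = "hydronet_format_error")
    })
  atoms <- pdb_to_atoms(pdb)
  if (nrow(atoms) == 0) {
    abort(sprintf("'%s' contains no atoms", path),
          class = "hydronet_empty_structure_error")
  }
  id <- sub("\\.[^.]*$", "", basename(path))
  new_structure(atoms, id = id, source = "static",
                water_residue_names = water_residue_names)
}

pdb_to_atoms <- function(pdb) {
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) return(tibble())
  element <- a$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- suppressWarnings(
      bio3d::atom2ele(a$elety[missing_el], rescue = TRUE))
  }
  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = a$elety,
    element = toupper(trimws(element)),
    resname = trimws(a$resid),
    resno = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt))
  resolve_altlocs(atoms)
}

# Keep the highest-occupancy altloc per atom site; first wins ties.
resolve_altlocs <- function(atoms) {
  if (all(atoms$alt == "")) return(select(atoms, -"alt"))
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    group_by(.data$chain, .data$resno, .data$icode, .data$name) |>
    filter(row_number() == which.max(.data$occupancy)) |>
    ungroup() |>
    arrange(.data$.ord)
  select(atoms, -"alt", -".ord")
}

#' Write an atom table to a PDB file
#'
#' Waters are written as HETATM records, protein atoms as ATOM records;
#' occupancy is preserved. Coordinates follow PDB precision (0.001 A).
#'
#' @param structure A `wn_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  xyz <- as.vector(t(coords(structure)))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(structure$is_water, "HETATM", "ATOM"),
    resno = structure$resno,
    resid = structure$resname,
    eleno = structure$serial,
    elety = structure$name,
    chain = structure$chain,
    insert = ifelse(structure$icode == "", NA, structure$icode),
    o = structure$occupancy,
    b = rep(0, nrow(structure)),
    elesy = structure$element)
  invisible(path)
}

#' Read trajectory frames as a list of structures
#'
#' Accepts a multi-model PDB (topology only) or a topology PDB plus a DCD
#' trajectory. Frames are assumed already unwrapped and aligned; each
#' selected frame becomes an independent structure (coordinates copied)
#' with a 0-based `frame_index`.
#'
#' @param topology Path to a PDB file (multi-model allowed).
#' @param trajectory Optional path to a DCD trajectory.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @inheritParams read_structure
#' @return A list of `wn_structure` objects in frame order.
#' @export
read_frames <- function(topology, trajectory = NULL, stride = 1L,
                        water_residue_names = WATER_RESIDUE_NAMES) {
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1) {
    abort("stride must be a positive integer",
          class = "hydronet_precondition_error")
  }
  stride <- as.integer(stride)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(topology, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      abort(sprintf("cannot parse '%s' as PDB: %s", topology,
                    conditionMessage(e)),
            class = "hydronet_format_error")
    })
  atoms <- pdb_to_atoms(pdb)
  n_atoms <- nrow(atoms)
  if (n_atoms == 0) {
    abort(sprintf("'%s' contains no atoms", topology),
          class = "hydronet_empty_structure_error")
  }
  if (is.null(trajectory)) {
    xyz <- pdb$xyz
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(trajectory, verbose = FALSE))
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms) {
    abort(sprintf(
      "topology has %d atoms but trajectory frames have %d coordinates",
      n_atoms, ncol(xyz)), class = "hydronet_consistency_error")
  }
  keep <- seq(1L, nrow(xyz), by = stride)
  stem <- sub("\\.[^.]*$", "", basename(topology))
  lapply(keep, function(i) {
    fr <- atoms
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    fr$x <- m[, 1]; fr$y <- m[, 2]; fr$z <- m[, 3]
    new_structure(fr, id = sprintf("%s_frame%04d", stem, i - 1L),
                  source = "frame", frame_index = i - 1L,
                  water_residue_names = water_residue_names)
  })
}

#' Define a spherical active region
#'
#' Restricts network construction to a sphere around atoms of interest.
#' `selection` is an R logical expression over the atom-table columns
#' (e.g. `"name == 'CA' & chain == 'A'"` or `"resno %in% 5:10"`).
#' With `center_mode = "com"` the sphere is centred on the mean
#' coordinate of the selected atoms; with `"atom"` an atom is kept if it
#' lies within `radius` of any selected atom.
#'
#' @param selection Selection expression (string).
#' @param radius Sphere radius in Angstrom (default 9).
#' @param center_mode `"com"` or `"atom"`.
#' @return An `active_region` object.
#' @export
active_region <- function(selection, radius = 9, center_mode = c("com", "atom")) {
  center_mode <- match.arg(center_mode)
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(selection = selection, radius = radius,
                 center_mode = center_mode),
            class = "active_region")
}

select_atoms <- function(structure, selection) {
  expr <- rlang::parse_expr(selection)
  keep <- rlang::eval_tidy(expr, data = structure)
  if (!is.logical(keep)) {
    abort("selection must evaluate to a logical vector",
          class = "hydronet_selection_error")
  }
  which(keep & !is.na(keep))
}

#' Restrict a structure to an active region
#'
#' Returns the sub-structure of atoms inside the region (closed ball:
#' distance <= radius). Hydrogens riding on a retained heavy atom of the
#' same residue are kept with it so that angle criteria stay evaluable.
#'
#' @param structure A `wn_structure`.
#' @param region An [active_region()].
#' @return A `wn_structure` containing the in-region atoms.
#' @export
select_region <- function(structure, region) {
  stopifnot(inherits(region, "active_region"))
  idx <- select_atoms(structure, region$selection)
  if (length(idx) == 0) {
    abort("active-region selection matched no atoms",
          class = "hydronet_selection_error")
  }
  keep <- region_membership(structure, region, idx)
  rewrap_structure(structure[keep, , drop = FALSE], structure)
}

region_membership <- function(structure, region, idx = NULL) {
  if (is.null(idx)) idx <- select_atoms(structure, region$selection)
  xyz <- coords(structure)
  sel <- xyz[idx, , drop = FALSE]
  if (region$center_mode == "com") {
    d <- row_dist(xyz, colMeans(sel))
  } else {
    nn <- RANN::nn2(sel, xyz, k = 1L)
    d <- nn$nn.dists[, 1]
  }
  keep <- d <= region$radius
  # keep hydrogens riding on retained heavy atoms
  h <- which(structure$is_hydrogen & !keep)
  if (length(h) > 0) {
    heavy <- which(!structure$is_hydrogen & keep)
    if (length(heavy) > 0) {
      nn <- RANN::nn2(xyz[heavy, , drop = FALSE], xyz[h, , drop = FALSE],
                      k = 1L)
      same_res <- structure$resno[h] ==
        structure$resno[heavy[nn$nn.idx[, 1]]] &
        structure$chain[h] == structure$chain[heavy[nn$nn.idx[, 1]]]
      keep[h[nn$nn.dists[, 1] <= 1.2 & same_res]] <- TRUE
    }
  }
  keep
}

#' One-letter sequence of a structure's protein residues
#'
#' Walks non-water residues in file order (grouped by chain, residue
#' number, insertion code) and maps three-letter codes to one-letter
#' codes; nonstandard residues become `X`.
#'
#' @param structure A `wn_structure`.
#' @return A tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resname`, `aa`.
#' @export
structure_sequence <- function(structure) {
  prot <- filter(as_tibble(structure), !.data$is_water, !.data$is_hydrogen)
  res <- prot |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$resno, .data$icode) |>
    summarise(resname = first(.data$resname), .ord = min(.data$.ord),
              .groups = "drop") |>
    arrange(.data$.ord) |>
    select(-".ord")
  aa <- suppressWarnings(bio3d::aa321(res$resname))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  res$aa <- aa
  res
}
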