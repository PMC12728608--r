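#' Multiple sequence alignment and common residue indexing
#'
#' Related structures are compared through a common column indexing:
#' every residue of every structure is assigned to a column of a multiple
#' sequence alignment, so that "the same" residue can be recognised
#' across homologues that differ in numbering or in sequence. The
#' alignment is computed by progressive global alignment: all pairwise
#' Needleman-Wunsch alignments (BLOSUM62, affine gap penalties) give a
#' percent-identity matrix, a UPGMA guide tree is built from it, and
#' profiles are merged along the tree. Gap runs longer than `max_gap`
#' are disallowed inside the dynamic programme.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (one-letter codes; nonstandard letters are mapped to `X`).
#' @param max_gap Maximum allowed gap run length (default 20).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10, 0.5).
#' @return A `wn_alignment` object: list with `msa` (named character
#'   vector of aligned sequences), `columns`, `pim` (percent-identity
#'   matrix over both-aligned positions) and, once mapped to structures,
#'   a `mapping` tibble (`structure_id`, `chain`, `resno`, `icode`,
#'   `column` with columns numbered 1..`columns`).
#' @export
align_sequences <- function(sequences, max_gap = 20L,
                            gap_open = 10, gap_extend = 0.5) {
  check_sequences(sequences)
  seqs <- lapply(sequences, clean_aa)
  n <- length(seqs)
  labs <- names(seqs)
  sub <- blosum62()

  if (n == 2) {
    prof <- nw_profile(matrix(seqs[[1]], nrow = 1),
                       matrix(seqs[[2]], nrow = 1),
                       sub, gap_open, gap_extend, max_gap)
    msa_mat <- prof
    rownames(msa_mat) <- labs
  } else {
    # guide tree from pairwise identities
    pid <- matrix(100, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ali <- nw_profile(matrix(seqs[[i]], nrow = 1),
                          matrix(seqs[[j]], nrow = 1),
                          sub, gap_open, gap_extend, max_gap)
        pid[i, j] <- pid[j, i] <- percent_identity(ali[1, ], ali[2, ])
      }
    }
    tree <- hclust(as.dist(100 - pid), method = "average")
    profiles <- lapply(seq_len(n), function(i) {
      m <- matrix(seqs[[i]], nrow = 1)
      rownames(m) <- labs[i]
      m
    })
    merged <- vector("list", nrow(tree$merge))
    for (k in seq_len(nrow(tree$merge))) {
      pick <- function(v) if (v < 0) profiles[[-v]] else merged[[v]]
      merged[[k]] <- nw_profile(pick(tree$merge[k, 1]),
                                pick(tree$merge[k, 2]),
                                sub, gap_open, gap_extend, max_gap)
    }
    msa_mat <- merged[[length(merged)]]
    msa_mat <- msa_mat[labs, , drop = FALSE]
  }

  msa <- apply(msa_mat, 1, paste, collapse = "")
  pim <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        pim[i, j] <- percent_identity(msa_mat[i, ], msa_mat[j, ])
      }
    }
  }
  structure(list(msa = msa, columns = ncol(msa_mat), pim = pim,
                 mapping = NULL),
            class = "wn_alignment")
}

check_sequences <- function(sequences) {
  if (length(sequences) < 2) {
    abort("need at least two sequences to align",
          class = "hydronet_precondition_error")
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("sequences must be named", class = "hydronet_precondition_error")
  }
  if (any(!nzchar(sequences))) {
    abort("empty sequence supplied", class = "hydronet_input_error")
  }
}

clean_aa <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  ch[!ch %in% strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]] <- "X"
  ch
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

percent_identity <- function(a, b) {
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

# Profile-profile Needleman-Wunsch with affine gaps and a cap on gap run
# length. Profiles are character matrices (rows = sequences, cols =
# alignment columns, "-" for gaps). Column-pair score is the sum-of-pairs
# BLOSUM62 mean over all row pairs; gap characters contribute 0.
nw_profile <- function(pa, pb, sub, gap_open, gap_extend, max_gap) {
  la <- ncol(pa); lb <- ncol(pb)
  score_cols <- profile_col_scores(pa, pb, sub)
  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # gap in B (consume A column)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in A (consume B column)
  LX <- matrix(0L, la + 1, lb + 1)
  LY <- matrix(0L, la + 1, lb + 1)
  tb_M <- matrix(0L, la + 1, lb + 1)
  tb_X <- matrix(0L, la + 1, lb + 1)
  tb_Y <- matrix(0L, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in seq_len(la)) {
    prev <- if (i == 1) M[i, 1] else X[i, 1]
    can_ext <- i > 1 && LX[i, 1] < max_gap
    open_s <- M[i, 1] - gap_open - gap_extend
    ext_s <- if (can_ext) X[i, 1] - gap_extend else NEG
    if (open_s >= ext_s) {
      X[i + 1, 1] <- open_s; LX[i + 1, 1] <- 1L; tb_X[i + 1, 1] <- 1L
    } else {
      X[i + 1, 1] <- ext_s; LX[i + 1, 1] <- LX[i, 1] + 1L; tb_X[i + 1, 1] <- 2L
    }
  }
  for (j in seq_len(lb)) {
    can_ext <- j > 1 && LY[1, j] < max_gap
    open_s <- M[1, j] - gap_open - gap_extend
    ext_s <- if (can_ext) Y[1, j] - gap_extend else NEG
    if (open_s >= ext_s) {
      Y[1, j + 1] <- open_s; LY[1, j + 1] <- 1L; tb_Y[1, j + 1] <- 1L
    } else {
      Y[1, j + 1] <- ext_s; LY[1, j + 1] <- LY[1, j] + 1L; tb_Y[1, j + 1] <- 2L
    }
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- score_cols[i, j]
      cand <- c(M[i, j], X[i, j], Y[i, j])
      w <- which.max(cand)
      M[i + 1, j + 1] <- cand[w] + s
      tb_M[i + 1, j + 1] <- w

      open_s <- M[i, j + 1] - gap_open - gap_extend
      ext_s <- if (LX[i, j + 1] < max_gap) X[i, j + 1] - gap_extend else NEG
      if (open_s >= ext_s) {
        X[i + 1, j + 1] <- open_s; LX[i + 1, j + 1] <- 1L
        tb_X[i + 1, j + 1] <- 1L
      } else {
        X[i + 1, j + 1] <- ext_s; LX[i + 1, j + 1] <- LX[i, j + 1] + 1L
        tb_X[i + 1, j + 1] <- 2L
      }

      open_s <- M[i + 1, j] - gap_open - gap_extend
      ext_s <- if (LY[i + 1, j] < max_gap) Y[i + 1, j] - gap_extend else NEG
      if (open_s >= ext_s) {
        Y[i + 1, j + 1] <- open_s; LY[i + 1, j + 1] <- 1L
        tb_Y[i + 1, j + 1] <- 1L
      } else {
        Y[i + 1, j + 1] <- ext_s; LY[i + 1, j + 1] <- LY[i + 1, j] + 1L
        tb_Y[i + 1, j + 1] <- 2L
      }
    }
  }
  # traceback
  i <- la; j <- lb
  state <- which.max(c(M[la + 1, lb + 1], X[la + 1, lb + 1],
                       Y[la + 1, lb + 1]))
  cols_a <- integer(0); cols_b <- integer(0)  # 0 marks a gap column
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- tb_M[i + 1, j + 1]
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b)
      i <- i - 1; j <- j - 1
      state <- prev
    } else if (state == 2L) {
      prev <- if (tb_X[i + 1, j + 1] == 1L) 1L else 2L
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b)
      i <- i - 1
      state <- prev
    } else {
      prev <- if (tb_Y[i + 1, j + 1] == 1L) 1L else 3L
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b)
      j <- j - 1
      state <- prev
    }
  }
  out <- matrix("-", nrow(pa) + nrow(pb), length(cols_a))
  nzA <- cols_a > 0; nzB <- cols_b > 0
  out[seq_len(nrow(pa)), nzA] <- pa[, cols_a[nzA], drop = FALSE]
  out[nrow(pa) + seq_len(nrow(pb)), nzB] <- pb[, cols_b[nzB], drop = FALSE]
  rownames(out) <- c(rownames(pa), rownames(pb))
  out
}

profile_col_scores <- function(pa, pb, sub) {
  aa <- rownames(sub)
  score_one <- function(ca, cb) {
    ca <- ca[ca != "-"]; cb <- cb[cb != "-"]
    if (length(ca) == 0 || length(cb) == 0) return(0)
    ca[!ca %in% aa] <- "X"; cb[!cb %in% aa] <- "X"
    mean(sub[ca, cb, drop = FALSE])
  }
  out <- matrix(0, ncol(pa), ncol(pb))
  for (i in seq_len(ncol(pa))) {
    for (j in seq_len(ncol(pb))) {
      out[i, j] <- score_one(pa[, i], pb[, j])
    }
  }
  out
}

#' @export
print.wn_alignment <- function(x, ...) {
  cat(sprintf("# Alignment: %d sequences, %d columns%s\n",
              length(x$msa), x$columns,
              if (is.null(x$mapping)) "" else ", mapped to structures"))
  for (nm in names(x$msa)) cat(sprintf("  %-12s %s\n", nm, x$msa[[nm]]))
  invisible(x)
}

#' Align a set of structures and build the common residue indexing
#'
#' Extracts each structure's protein sequence, aligns all of them (or
#' walks an imported alignment), and records which alignment column every
#' residue occupies.
#'
#' @param structures Named list of `wn_structure` objects (names default
#'   to their ids).
#' @inheritParams align_sequences
#' @return A `wn_alignment` with its `mapping` tibble filled in.
#' @export
align_structures <- function(structures, max_gap = 20L,
                             gap_open = 10, gap_extend = 0.5) {
  structures <- name_structures(structures)
  seqs <- vapply(structures,
                 function(s) paste(structure_sequence(s)$aa, collapse = ""),
                 character(1))
  ali <- align_sequences(seqs, max_gap = max_gap, gap_open = gap_open,
                         gap_extend = gap_extend)
  map_residues(ali, structures)
}

name_structures <- function(structures) {
  if (inherits(structures, "wn_structure")) structures <- list(structures)
  if (is.null(names(structures))) {
    names(structures) <- vapply(structures, structure_id, character(1))
  }
  structures
}

#' @rdname align_structures
#' @param alignment A `wn_alignment`.
#' @export
map_residues <- function(alignment, structures) {
  structures <- name_structures(structures)
  maps <- purrr::imap(structures, function(s, label) {
    if (!label %in% names(alignment$msa)) {
      abort(sprintf("structure '%s' is not in the alignment", label),
            class = "hydronet_reconciliation_error")
    }
    res <- structure_sequence(s)
    ach <- strsplit(alignment$msa[[label]], "")[[1]]
    cols <- which(ach != "-")
    if (length(cols) != nrow(res)) {
      abort(sprintf(
        "alignment sequence for '%s' has %d residues but the structure has %d",
        label, length(cols), nrow(res)),
        class = "hydronet_reconciliation_error")
    }
    mismatch <- which(ach[cols] != res$aa & ach[cols] != "X" & res$aa != "X")
    if (length(mismatch) > 0) {
      k <- mismatch[1]
      abort(sprintf(
        "sequence mismatch for '%s' at residue %s%d%s: alignment '%s' vs structure '%s'",
        label, res$chain[k], res$resno[k], res$icode[k], ach[cols][k],
        res$aa[k]),
        class = "hydronet_reconciliation_error")
    }
    tibble(structure_id = label, chain = res$chain, resno = res$resno,
           icode = res$icode, resname = res$resname, column = cols)
  })
  alignment$mapping <- bind_rows(maps)
  alignment
}

#' Import an existing alignment in PIR or aligned-FASTA format
#'
#' @param path Alignment file. PIR entries start with `>P1;label`;
#'   FASTA entries with `>label`. Detected from the first record.
#' @param structures Optional named list of structures; when given, the
#'   residue-to-column mapping is built and sequences are reconciled
#'   against the structures.
#' @return A `wn_alignment`.
#' @export
import_alignment <- function(path, structures = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("'%s' is empty", path), class = "hydronet_format_error")
  }
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) {
    abort(sprintf("'%s' has no sequence records", path),
          class = "hydronet_format_error")
  }
  pir <- grepl("^>P1;", lines[hdr[1]])
  ends <- c(hdr[-1] - 1L, length(lines))
  msa <- character(0)
  for (k in seq_along(hdr)) {
    head_line <- lines[hdr[k]]
    label <- if (pir) sub("^>P1;\\s*", "", head_line) else
      sub("^>\\s*", "", strsplit(head_line, "\\s+")[[1]][1])
    label <- trimws(label)
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    if (pir && length(body) > 0) body <- body[-1]  # PIR description line
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    if (pir) seq <- sub("\\*$", "", seq)
    seq <- gsub("[.]", "-", seq)
    msa[label] <- toupper(seq)
  }
  if (length(unique(nchar(msa))) != 1) {
    abort("aligned sequences differ in length",
          class = "hydronet_format_error")
  }
  cols <- nchar(msa[[1]])
  mm <- do.call(rbind, strsplit(msa, ""))
  labs <- names(msa)
  pim <- matrix(100, length(msa), length(msa), dimnames = list(labs, labs))
  for (i in seq_along(msa)) {
    for (j in seq_along(msa)) {
      if (i != j) pim[i, j] <- percent_identity(mm[i, ], mm[j, ])
    }
  }
  ali <- structure(list(msa = msa, columns = cols, pim = pim,
                        mapping = NULL),
                   class = "wn_alignment")
  if (!is.null(structures)) ali <- map_residues(ali, structures)
  ali
}

#' Write an alignment as aligned FASTA, and its identity matrix as CSV
#'
#' @param alignment A `wn_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(alignment$msa)) {
    writeLines(c(paste0(">", nm), alignment$msa[[nm]]), con)
  }
  invisible(path)
}

#' @rdname write_alignment
#' @export
write_pim <- function(alignment, path) {
  write.csv(as.data.frame(alignment$pim), path, row.names = TRUE)
  invisible(path)
}

#' Rigid-body superposition onto a reference structure
#'
#' Least-squares (Kabsch) superposition on the C-alpha atoms of residues
#' that share an alignment column in the two structures. The whole mobile
#' structure — waters included — is moved by the fitted rotation and
#' translation, so that pooled water positions live in the reference
#' coordinate frame.
#'
#' @param mobile,reference `wn_structure` objects present in `alignment`'s
#'   mapping.
#' @param alignment A mapped `wn_alignment` (see [align_structures()]).
#' @return List with `structure` (transformed copy of `mobile`) and
#'   `result`: `rotation` (3x3, det +1), `translation` (length-3),
#'   `rmsd` (Angstrom over matched C-alpha pairs) and `n_pairs`.
#' @export
superpose <- function(mobile, reference, alignment) {
  if (is.null(alignment$mapping)) {
    abort("alignment has no structure mapping; call map_residues() first",
          class = "hydronet_precondition_error")
  }
  pa <- ca_by_column(mobile, alignment)
  pb <- ca_by_column(reference, alignment)
  shared <- intersect(pa$column, pb$column)
  if (length(shared) < 3) {
    abort(sprintf(
      "only %d shared aligned C-alpha pairs; need at least 3",
      length(shared)), class = "hydronet_underdetermined_error")
  }
  P <- as.matrix(pa[match(shared, pa$column), c("x", "y", "z")])
  Q <- as.matrix(pb[match(shared, pb$column), c("x", "y", "z")])
  fit <- kabsch(P, Q)
  moved <- transform_structure(mobile, fit$rotation, fit$translation)
  Pt <- sweep(P %*% t(fit$rotation), 2L, fit$translation, "+")
  fit$rmsd <- sqrt(mean(rowSums((Pt - Q)^2)))
  fit$n_pairs <- length(shared)
  list(structure = moved, result = fit)
}

ca_by_column <- function(structure, alignment) {
  id <- structure_id(structure)
  map <- filter(alignment$mapping, .data$structure_id == id)
  if (nrow(map) == 0) {
    abort(sprintf("structure '%s' is not in the alignment mapping", id),
          class = "hydronet_precondition_error")
  }
  ca <- filter(as_tibble(structure), .data$name == "CA")
  dplyr::inner_join(map, ca, by = c("chain", "resno", "icode")) |>
    select("column", "x", "y", "z")
}

# Optimal proper rotation + translation mapping P onto Q (rows = points).
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2L, pc)) %*% sweep(Q, 2L, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(qc - R %*% pc))
}

#' Apply a rigid transform to a structure
#'
#' @param structure A `wn_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `wn_structure`.
#' @export
transform_structure <- function(structure, rotation,
                                translation = c(0, 0, 0)) {
  xyz <- coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  out <- as_tibble(structure)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  rewrap_structure(out, structure)
}
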