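test_that("identical sequences align to the identity with 100% identity", {
  ali <- align_sequences(c(s1 = "ACDEFG", s2 = "ACDEFG"))
  expect_equal(ali$columns, 6)
  expect_equal(unname(ali$msa["s1"]), "ACDEFG")
  expect_equal(unname(ali$msa["s2"]), "ACDEFG")
  expect_equal(unname(ali$pim["s1", "s2"]), 100)
})

test_that("pairwise alignment matches the exhaustive affine-gap oracle", {
  cases <- list(c("ACDE", "ACE"), c("WKDE", "WDE"), c("MKVL", "MKAVL"),
                c("ACDEF", "ADF"))
  for (cs in cases) {
    ali <- align_sequences(setNames(cs, c("a", "b")))
    best <- oracle_nw(cs[1], cs[2])
    expect_equal(ali$columns, length(best$a),
                 info = paste(cs, collapse = " vs "))
    # the package alignment must reach the oracle's optimal score
    sub <- local({
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    })
    score_of <- function(sa, sb) {
      sc <- 0; last <- "m"
      for (k in seq_along(sa)) {
        if (sa[k] != "-" && sb[k] != "-") {
          sc <- sc + sub[sa[k], sb[k]]; last <- "m"
        } else if (sa[k] == "-") {
          sc <- sc - (if (last == "y") 0.5 else 10.5); last <- "y"
        } else {
          sc <- sc - (if (last == "x") 0.5 else 10.5); last <- "x"
        }
      }
      sc
    }
    got <- score_of(strsplit(ali$msa[["a"]], "")[[1]],
                    strsplit(ali$msa[["b"]], "")[[1]])
    expect_equal(got, best$score, info = paste(cs, collapse = " vs "))
  }
  # the canonical worked case: the D column is gapped in the short one
  ali <- align_sequences(c(a = "ACDE", b = "ACE"))
  expect_equal(ali$columns, 4)
  expect_equal(unname(ali$msa[["a"]]), "ACDE")
  expect_equal(substr(ali$msa[["b"]], 3, 3), "-")
})

test_that("degenerate sequence inputs are rejected", {
  expect_error(align_sequences(c(a = "ACDE")),
               class = "hydronet_precondition_error")
  expect_error(align_sequences(c(a = "ACDE", b = "")),
               class = "hydronet_input_error")
})

test_that("percent-identity matrix is symmetric with a 100% diagonal", {
  ali <- align_sequences(c(a = "ACDEFGHIK", b = "ACDEFGHIR",
                           c = "ACDFGHIK", d = "MCDEFGHIK"))
  expect_equal(ali$pim, t(ali$pim))
  expect_equal(unname(diag(ali$pim)), rep(100, 4))
  expect_true(all(ali$pim >= 0 & ali$pim <= 100))
})

test_that("PIR import builds the residue mapping and flags mismatches", {
  spec <- fixture_spec(n_structures = 2, n_residues = 4, jitter = 0,
                       seed = 5)
  ss <- make_structures(spec)
  pir <- tempfile(fileext = ".pir")
  writeLines(c(">P1;fix001", "structure", "SSSS*",
               ">P1;fix002", "structure", "SSSS*"), pir)
  ali <- import_alignment(pir, ss)
  expect_equal(ali$columns, 4)
  m1 <- ali$mapping[ali$mapping$structure_id == "fix001", ]
  expect_equal(m1$column, 1:4)
  expect_equal(m1$resno, 1:4)

  # a gap column leaves no mapping entry for that structure
  pir2 <- tempfile(fileext = ".pir")
  writeLines(c(">P1;fix001", "d", "SSSS*", ">P1;short", "d", "SS-S*"), pir2)
  ali2 <- import_alignment(pir2)
  expect_equal(ali2$columns, 4)
  expect_equal(unname(ali2$msa[["short"]]), "SS-S")

  # alignment shorter than the structure sequence is a reconciliation error
  pir3 <- tempfile(fileext = ".pir")
  writeLines(c(">P1;fix001", "d", "SSS*", ">P1;fix002", "d", "SSS*"), pir3)
  expect_error(import_alignment(pir3, ss),
               class = "hydronet_reconciliation_error")
})

test_that("superposing a structure onto itself gives the identity", {
  spec <- fixture_spec(n_structures = 2, n_residues = 5, jitter = 0,
                       seed = 2)
  ss <- make_structures(spec)
  ali <- align_structures(ss)
  fit <- superpose(ss[[1]], ss[[1]], ali)
  expect_equal(fit$result$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$result$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$result$n_pairs, 5)
})

test_that("a known rigid transform is recovered by superposition", {
  spec <- fixture_spec(n_structures = 2, n_residues = 5, jitter = 0,
                       seed = 2)
  ss <- make_structures(spec)
  ali <- align_structures(ss)
  R90 <- rotation_z(90)
  moved <- transform_structure(ss[[1]], R90, c(5, 0, 0))
  fit <- superpose(moved, ss[[1]], ali)
  expect_lt(fit$result$rmsd, 1e-6)
  expect_equal(det(fit$result$rotation), 1, tolerance = 1e-9)
  # recovered rotation undoes the applied one
  expect_equal(fit$result$rotation %*% R90, diag(3), tolerance = 1e-6)
  expect_equal(as.matrix(fit$structure[, c("x", "y", "z")]),
               as.matrix(ss[[1]][, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("superposition never increases C-alpha RMSD and is self-inverse", {
  set.seed(31)
  spec <- fixture_spec(n_structures = 4, n_residues = 6, jitter = 0.1,
                       rigid_sigma = 0.2, seed = 31)
  ss <- make_structures(spec)
  ali <- align_structures(ss)
  ref <- ss[[1]]
  for (k in 2:4) {
    ca_before <- as.matrix(dplyr::filter(tibble::as_tibble(ss[[k]]),
                                         name == "CA")[, c("x", "y", "z")])
    ca_ref <- as.matrix(dplyr::filter(tibble::as_tibble(ref),
                                      name == "CA")[, c("x", "y", "z")])
    rmsd_before <- sqrt(mean(rowSums((ca_before - ca_ref)^2)))
    fit <- superpose(ss[[k]], ref, ali)
    expect_lte(fit$result$rmsd, rmsd_before + 1e-12)
    # transforming again onto itself is the identity
    fit2 <- superpose(fit$structure, fit$structure, ali)
    expect_equal(fit2$result$rotation, diag(3), tolerance = 1e-8)
    expect_equal(fit2$result$translation, c(0, 0, 0), tolerance = 1e-8)
  }
})

test_that("too few shared aligned residues is an underdetermined error", {
  spec <- fixture_spec(n_structures = 2, n_residues = 3, jitter = 0, seed = 4)
  ss <- make_structures(spec)
  ali <- align_structures(ss)
  # drop one CA from the mobile copy so only 2 pairs remain
  mobile <- ss[[2]]
  keep <- !(mobile$name == "CA" & mobile$resno == 1)
  mobile2 <- new_structure(tibble::as_tibble(mobile)[keep, ],
                           id = structure_id(mobile))
  expect_error(superpose(mobile2, ss[[1]], ali),
               class = "hydronet_underdetermined_error")
})
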