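# summary network with centroids exactly at the given sites
summary_at <- function(sites, n_sources = 1L) {
  pts <- tibble::tibble(
    structure_id = rep("seed", nrow(sites) * 5), frame = NA_integer_,
    serial = seq_len(nrow(sites) * 5),
    x = rep(sites[, 1], each = 5), y = rep(sites[, 2], each = 5),
    z = rep(sites[, 3], each = 5))
  cluster_waters(pts, cluster_params(eps = 0.5, min_samples = 3))
}

waters_at <- function(xyz) {
  tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("pooling collects labelled water positions without dedup", {
  spec <- fixture_spec(n_structures = 3, jitter = 0.1, seed = 21)
  nets <- lapply(make_structures(spec), build_network)
  pts <- pool_positions(nets)
  expect_equal(nrow(pts), 9)  # 3 structures x 3 default sites
  expect_setequal(unique(pts$structure_id), c("fix001", "fix002", "fix003"))
  # duplicated networks duplicate points
  pts2 <- pool_positions(c(nets, nets[1]))
  expect_equal(nrow(pts2), 12)
})

test_that("the conservation score reproduces the worked limiting cases", {
  sites <- rbind(c(0, 0, 0), c(10, 0, 0))
  sm <- summary_at(sites)
  expect_equal(sm$n_summary, 2L)
  # perfect case: one water exactly at each summary site, nothing nearby
  expect_equal(conservation_score(sm, waters_at(sites)), 1.0)
  # no waters at all: score 0
  expect_equal(conservation_score(sm, waters_at(sites[0, , drop = FALSE])),
               0.0)
  # N_s = 2: site 1 matched with one extra local water, site 2 unmatched
  w <- rbind(c(0.2, 0, 0),    # matches site 1
             c(3.0, 0, 0))    # extra water inside the 6 A sphere of site 1
  expect_equal(conservation_score(sm, waters_at(w)), 0.25)
  # empty summary is undefined
  empty <- suppressWarnings(cluster_waters(
    tibble::tibble(structure_id = "s", frame = NA, serial = 1:2,
                   x = c(0, 50), y = 0, z = 0),
    cluster_params(eps = 0.5, min_samples = 3)))
  expect_error(conservation_score(empty, waters_at(sites)),
               class = "hydronet_precondition_error")
})

test_that("waters outside every local sphere never change the score", {
  sites <- rbind(c(0, 0, 0), c(12, 0, 0))
  sm <- summary_at(sites)
  w <- rbind(c(0.3, 0, 0), c(12.2, 0, 0))
  base <- conservation_score(sm, waters_at(w))
  far <- rbind(w, c(40, 40, 40), c(-30, 5, 60), c(6.05, 8, 0) * 10)
  expect_equal(conservation_score(sm, waters_at(far)), base)
})

test_that("per-cluster and pairwise conservation equal exhaustive checks", {
  set.seed(22)
  # 5 structures; site A in all, site B in 3 of 5; A and B 1.6 A apart
  siteA <- c(0, 0, 0); siteB <- c(1.6, 0, 0)
  pts <- purrr::map_dfr(1:5, function(s) {
    rows <- tibble::tibble(structure_id = sprintf("s%d", s),
                           frame = NA_integer_, serial = 1L,
                           x = siteA[1] + rnorm(1, 0, 0.05),
                           y = siteA[2] + rnorm(1, 0, 0.05),
                           z = siteA[3] + rnorm(1, 0, 0.05))
    if (s <= 3) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        structure_id = sprintf("s%d", s), frame = NA_integer_, serial = 2L,
        x = siteB[1] + rnorm(1, 0, 0.05), y = siteB[2] + rnorm(1, 0, 0.05),
        z = siteB[3] + rnorm(1, 0, 0.05)))
    }
    rows
  })
  sm <- cluster_waters(pts, cluster_params(eps = 0.5, min_samples = 3),
                       conservation_params(match_distance = 0.5))
  expect_equal(sm$n_summary, 2L)
  # exhaustive per-structure distance check
  cxyz <- as.matrix(sm$centroids[, c("x", "y", "z")])
  expected_cons <- vapply(1:2, function(i) {
    mean(vapply(sprintf("s%d", 1:5), function(sid) {
      sw <- as.matrix(pts[pts$structure_id == sid, c("x", "y", "z")])
      any(sqrt(rowSums(sweep(sw, 2, cxyz[i, ])^2)) <= 0.5)
    }, logical(1)))
  }, numeric(1))
  expect_equal(sm$centroids$conservation, expected_cons)
  # the two centroids are within the 2 A pair cutoff; pairwise value is
  # the fraction of structures matching both
  expect_equal(nrow(sm$pairs), 1)
  expect_equal(sm$pairs$conservation, 3 / 5)
})

test_that("two-angle geometry matches hand-computed references", {
  w <- c(0, 0, 0)
  expect_equal(two_angle_classify(w, c(1, 0, 0), ref1 = c(-1, 0, 0),
                                  ref2 = c(0, 1, 0))[["angle1"]], 180)
  expect_equal(two_angle_classify(w, c(1, 0, 0), ref1 = c(0, 1, 0),
                                  ref2 = c(0, 0, 1))[["angle1"]], 90)
  expect_equal(two_angle_classify(w, c(1, 1, 0), ref1 = c(1, 0, 0),
                                  ref2 = c(0, 0, 1))[["angle1"]], 45,
               tolerance = 1e-9)
  expect_error(two_angle_classify(w, w), class = "hydronet_geometry_error")
})

test_that("angle records carry residue identity and the common column", {
  spec <- fixture_spec(n_structures = 2, n_residues = 4, jitter = 0,
                       seed = 23)
  ss <- make_structures(spec)
  ali <- align_structures(ss)
  nets <- lapply(ss, build_network)
  recs <- water_protein_angles(nets, ali)
  expect_gt(nrow(recs), 0)
  expect_true(all(recs$angle1 >= 0 & recs$angle1 <= 180))
  expect_true(all(recs$angle2 >= 0 & recs$angle2 <= 180))
  expect_false(any(is.na(recs$common_column)))
  expect_true(all(recs$protein_site %in% c("backbone", "side-chain")))
  # identical structures give identical angle sets
  r1 <- recs[recs$structure_id == "fix001", c("angle1", "angle2")]
  r2 <- recs[recs$structure_id == "fix002", c("angle1", "angle2")]
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-9)
})

test_that("interaction scores reproduce the one-vs-two-waters example", {
  # residue A: one bound water in all 10 frames
  # residue B: two bound waters in frames 1-5, none later
  prot <- protein_for_scores()
  nets <- lapply(1:10, function(f) {
    waters <- rbind(c(0.8, 4.6, 4.4))            # near residue 1 OG
    if (f <= 5) {
      waters <- rbind(waters,
                      c(24.8, 4.6, 4.4),         # near residue 3 OG
                      c(26.6, 4.1, 4.0))         # second water, same OG
    }
    atoms <- dplyr::bind_rows(prot, water_rows(waters, nrow(prot)))
    s <- new_structure(atoms, id = sprintf("f%02d", f),
                       source = "frame", frame_index = f - 1L)
    build_network(s, hbond_criteria(neighbor_k = 20))
  })
  sc <- interaction_scores(nets)
  a <- sc[sc$resno == 1, ]
  b <- sc[sc$resno == 3, ]
  expect_equal(a$score, 1.0)
  expect_equal(a$mean_simultaneous, 1.0)
  expect_equal(a$raw_count, 10L)
  expect_equal(b$score, 1.0)
  expect_equal(b$mean_simultaneous, 2.0)
  expect_equal(b$raw_count, 10L)
  # never-bound residues are absent (score undefined / zero by omission)
  expect_false(2 %in% sc$resno)
  # backbone + side-chain sub-scores recover the total
  expect_equal(sc$score_backbone + sc$score_sidechain, sc$score)
  expect_true(all(b$score_sidechain == 1.0))
})

test_that("interaction score equals per-frame counts over frames exactly", {
  set.seed(24)
  spec <- fixture_spec(n_structures = 6, jitter = 0.15, seed = 24)
  nets <- lapply(make_structures(spec), build_network)
  ali <- align_structures(make_structures(spec))
  sc <- interaction_scores(nets, ali)
  # recompute from the raw edge lists
  for (k in seq_len(nrow(sc))) {
    total <- 0
    nz <- c()
    for (net in nets) {
      ed <- net$edges[net$edges$kind == "water-protein", ]
      nd <- net$nodes
      prot <- ifelse(nd$is_water[match(ed$serial_a, nd$serial)],
                     ed$serial_b, ed$serial_a)
      cnt <- sum(nd$resno[match(prot, nd$serial)] == sc$resno[k])
      total <- total + cnt
      if (cnt > 0) nz <- c(nz, cnt)
    }
    expect_equal(sc$score[k], total / length(nets))
    expect_equal(sc$raw_count[k], total)
    expect_equal(sc$mean_simultaneous[k], mean(nz))
  }
})

test_that("density grids conserve counts and resolve alternating sites", {
  # one immobile water across 50 frames -> a single voxel with count 50
  prot <- protein_for_scores()
  nets <- lapply(1:50, function(f) {
    sites <- rbind(c(2, 8, 2))
    atoms <- dplyr::bind_rows(prot, water_rows(sites, nrow(prot)))
    build_network(new_structure(atoms, id = sprintf("f%02d", f),
                                source = "frame", frame_index = f - 1L))
  })
  grid <- density_hotspots(nets, spacing = 0.5)
  expect_equal(sum(grid$counts), 50)
  expect_equal(max(grid$counts), 50)
  # two waters alternating between two sites -> two equal maxima
  nets2 <- lapply(1:40, function(f) {
    pos <- if (f %% 2 == 0) rbind(c(2, 8, 2), c(6, 8, 2)) else
      rbind(c(6, 8, 2), c(2, 8, 2))
    atoms <- dplyr::bind_rows(prot, water_rows(pos, nrow(prot)))
    build_network(new_structure(atoms, id = sprintf("g%02d", f),
                                source = "frame", frame_index = f - 1L))
  })
  grid2 <- density_hotspots(nets2, spacing = 0.5)
  expect_equal(sum(grid2$counts), 80)
  tt <- tidy(grid2)
  expect_equal(tt$count[1:2], c(40L, 40L))
  expect_equal(nrow(tt), 2)
})

test_that("rigid motion leaves scores, angles and clusters unchanged", {
  set.seed(25)
  spec <- fixture_spec(n_structures = 5, jitter = 0.15, seed = 25)
  ss <- make_structures(spec)
  R <- random_rotation()
  tr <- c(13.5, -7.2, 4.4)
  ss_rot <- lapply(ss, transform_structure, rotation = R, translation = tr)
  build_all <- function(strs) lapply(strs, build_network)
  nets <- build_all(ss)
  nets_rot <- build_all(ss_rot)
  # graph structure identical
  for (k in seq_along(nets)) {
    expect_equal(edge_key(nets[[k]]$edges), edge_key(nets_rot[[k]]$edges))
  }
  # clustering memberships and conservation identical
  cp <- cluster_params(eps = 1.0, min_samples = 3)
  sm <- cluster_waters(pool_positions(nets), cp)
  sm_rot <- cluster_waters(pool_positions(nets_rot), cp)
  expect_equal(sm$centroids$size, sm_rot$centroids$size)
  expect_equal(sm$centroids$conservation, sm_rot$centroids$conservation,
               tolerance = 1e-6)
  sc <- conservation_scores(sm, nets)
  sc_rot <- conservation_scores(sm_rot, nets_rot)
  expect_equal(sc$score, sc_rot$score, tolerance = 1e-6)
  # two-angle records with co-rotated (C-alpha style) references
  ref1 <- c(0, 10, 0); ref2 <- c(10, 0, 10)
  ref1_rot <- as.numeric(R %*% ref1 + tr)
  ref2_rot <- as.numeric(R %*% ref2 + tr)
  ang <- water_protein_angles(nets, ref1 = ref1, ref2 = ref2)
  ang_rot <- water_protein_angles(nets_rot, ref1 = ref1_rot, ref2 = ref2_rot)
  expect_equal(ang$angle1, ang_rot$angle1, tolerance = 1e-6)
  expect_equal(ang$angle2, ang_rot$angle2, tolerance = 1e-6)
  # interaction scores identical
  is1 <- interaction_scores(nets)
  is2 <- interaction_scores(nets_rot)
  expect_equal(is1$score, is2$score)
})
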