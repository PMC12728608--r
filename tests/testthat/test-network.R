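two_waters <- function(d, h_pos = NULL) {
  atoms <- data.frame(
    serial = 1:2, name = "O", element = "O", resname = "HOH",
    resno = 1:2, chain = "W", icode = "", x = c(0, d), y = 0, z = 0,
    occupancy = 1, is_water = TRUE, is_hydrogen = FALSE)
  if (!is.null(h_pos)) {
    atoms <- rbind(atoms, data.frame(
      serial = 3, name = "H1", element = "H", resname = "HOH",
      resno = 1, chain = "W", icode = "",
      x = h_pos[1], y = h_pos[2], z = h_pos[3],
      occupancy = 1, is_water = TRUE, is_hydrogen = TRUE))
  }
  new_structure(atoms, id = "pair")
}

test_that("distance cutoff separates bonded from unbonded water pairs", {
  expect_equal(nrow(detect_hbonds(two_waters(3.0))), 1)
  expect_equal(detect_hbonds(two_waters(3.0))$kind, "water-water")
  expect_equal(nrow(detect_hbonds(two_waters(4.5))), 0)
  # boundary: exactly at the cutoff is accepted
  expect_equal(nrow(detect_hbonds(two_waters(3.8))), 1)
})

test_that("the D-H...A angle criterion gates and orients bonds", {
  # compute the true planted angle independently, then bracket the cutoff
  h_off <- c(0.45, 0.85, 0) / sqrt(sum(c(0.45, 0.85, 0)^2)) * 0.96
  s <- two_waters(2.9, h_pos = h_off)
  true_angle <- o_angle(c(0, 0, 0) - h_off, c(2.9, 0, 0) - h_off)
  expect_lt(true_angle, 150)  # this geometry is sub-cutoff by construction
  expect_equal(nrow(detect_hbonds(s)), 0)
  # loosening the cutoff just below the true angle re-admits the bond
  hb <- detect_hbonds(s, hbond_criteria(angle_cutoff = true_angle - 1))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_serial, 1L)
  expect_equal(hb$serial_a, 1L)
  expect_equal(hb$dha_angle, true_angle, tolerance = 1e-9)
  # near-collinear hydrogen passes the default cutoff
  s_good <- two_waters(2.9, h_pos = c(0.96, 0.02, 0))
  hb2 <- detect_hbonds(s_good)
  expect_equal(nrow(hb2), 1)
  expect_gt(hb2$dha_angle, 150)
  # angle requested without hydrogens is a configuration error
  expect_error(detect_hbonds(two_waters(3.0),
                             hbond_criteria(use_angle = TRUE)),
               class = "hydronet_configuration_error")
})

test_that("a 3-water line yields a path graph and isolated waters stay nodes", {
  atoms <- data.frame(
    serial = 1:3, name = "O", element = "O", resname = "HOH",
    resno = 1:3, chain = "W", icode = "", x = c(0, 3, 6), y = 0, z = 0,
    occupancy = 1, is_water = TRUE, is_hydrogen = FALSE)
  s <- new_structure(atoms, id = "line")
  net <- build_network(s)
  expect_equal(nrow(net$edges), 2)
  expect_equal(n_components(net), 1)
  # water bonded only to protein still appears as a node in ww mode
  spec <- fixture_spec(n_structures = 1, water_sites = rbind(c(0.8, 5.4, 5.2)),
                       jitter = 0, seed = 1)
  s2 <- make_structures(spec)[[1]]
  net2 <- build_network(s2, mode = "water-water")
  expect_equal(sum(net2$nodes$is_water), 1)
  expect_equal(nrow(net2$edges), 0)
})

test_that("candidate search equals brute force when partner counts fit in k", {
  # 12 equidistant protein partners around one water, neighbor_k = 10:
  # only the water queries, so exactly 10 candidates come back
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(3 * cos(th), 3 * sin(th), 0)
  atoms <- data.frame(
    serial = 1:13, name = c("O", rep("OG", 12)), element = "O",
    resname = c("HOH", rep("SER", 12)), resno = 1:13,
    chain = c("W", rep("A", 12)), icode = "",
    x = c(0, ring[, 1]), y = c(0, ring[, 2]), z = 0,
    occupancy = 1, is_water = c(TRUE, rep(FALSE, 12)),
    is_hydrogen = FALSE)
  s <- new_structure(atoms, id = "ring")
  pairs <- find_candidate_pairs(s, hbond_criteria(neighbor_k = 10))
  centre_pairs <- pairs[pairs$serial_a == 1 | pairs$serial_b == 1, ]
  expect_equal(nrow(centre_pairs), 10)
})

test_that("network edges equal exhaustive pairwise testing on random fixtures", {
  set.seed(101)
  for (rep in 1:60) {
    hydrogens <- rep %% 2 == 0
    s <- random_fixture_structure(n_waters = sample(3:8, 1),
                                  n_protein = sample(2:5, 1),
                                  box = 7, hydrogens = hydrogens)
    crit <- hbond_criteria(neighbor_k = 50)  # partner count always <= k
    net <- build_network(s, crit)
    oracle <- oracle_hbonds(s, use_angle = hydrogens)
    expect_equal(edge_key(net$edges), edge_key(oracle),
                 info = sprintf("replicate %d", rep))
  }
})

test_that("edge sets respond monotonically to the cutoffs", {
  set.seed(202)
  for (rep in 1:20) {
    s <- random_fixture_structure(n_waters = 6, n_protein = 3, box = 7,
                                  hydrogens = TRUE)
    base <- edge_key(build_network(s, hbond_criteria(neighbor_k = 50))$edges)
    wider <- edge_key(build_network(
      s, hbond_criteria(distance_cutoff = 5.0, neighbor_k = 50))$edges)
    looser <- edge_key(build_network(
      s, hbond_criteria(angle_cutoff = 120, neighbor_k = 50))$edges)
    expect_true(all(base %in% wider))
    expect_true(all(base %in% looser))
  }
})

test_that("water-water and water-protein modes partition the full mode", {
  set.seed(303)
  for (rep in 1:20) {
    s <- random_fixture_structure(n_waters = 6, n_protein = 4, box = 7)
    crit <- hbond_criteria(neighbor_k = 50)
    full <- edge_key(build_network(s, crit, mode = "full")$edges)
    ww <- edge_key(build_network(s, crit, mode = "water-water")$edges)
    wp <- edge_key(build_network(s, crit, mode = "water-protein")$edges)
    expect_setequal(full, c(ww, wp))
    expect_length(intersect(ww, wp), 0)
  }
})

test_that("identical inputs give identical graphs", {
  set.seed(404)
  s <- random_fixture_structure(n_waters = 8, n_protein = 4, box = 7)
  n1 <- build_network(s)
  n2 <- build_network(s)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("active regions keep halo partners of in-region waters", {
  # water inside the sphere bonded to a water just outside it
  atoms <- data.frame(
    serial = 1:3, name = c("CA", "O", "O"), element = c("C", "O", "O"),
    resname = c("SER", "HOH", "HOH"), resno = 1:3,
    chain = c("A", "W", "W"), icode = "",
    x = c(0, 8, 11), y = 0, z = 0,
    occupancy = 1, is_water = c(FALSE, TRUE, TRUE), is_hydrogen = FALSE)
  s <- new_structure(atoms, id = "halo")
  region <- active_region("name == 'CA'", radius = 9)
  net <- build_network(s, region = region)
  # water at x=11 is outside the 9 A sphere but within 3 A of the
  # in-region water at x=8: the boundary bond is kept
  expect_setequal(net$nodes$serial, c(2, 3))
  expect_equal(nrow(net$edges), 1)
  expect_false(net$nodes$in_region[net$nodes$serial == 3])
  # with a smaller radius the in-region water disappears and so does the edge
  net2 <- build_network(s, region = active_region("name == 'CA'", radius = 5))
  expect_equal(nrow(net2$edges), 0)
  expect_equal(nrow(net2$nodes), 0)
})
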