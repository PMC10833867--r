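# Helix construction, rigid-body placement, the orientation scanner, and
# the insertion/mutation ddG protocols.

test_that("ideal helices have the canonical rise, axis alignment, and sequence patterns", {
  s <- build_ideal_helix(strrep("A", 20))
  ca <- as.matrix(s$atoms[s$atoms$name == "CA", c("x", "y", "z")])
  rise <- (ca[20, 3] - ca[1, 3]) / 19
  expect_lt(abs(rise - 1.5), 0.1)
  expect_equal(tilt_angle(s), 0, tolerance = 1e-6)
  expect_equal(fixture_sequence("walp", 8),
               paste0("GWW", strrep("LA", 8), "LWWA"))
  expect_equal(nchar(fixture_sequence("walp", 8)), 23)
  expect_equal(fixture_sequence("polyleu", 5), "GLLLLLRLLLLLG")
  expect_equal(fixture_sequence("gwl"), "GWLLLLLLRLLLLLLLG")
  expect_error(build_ideal_helix("A"), "at least 3")
  expect_error(build_ideal_helix("AAXA"), "unknown residue")
})

test_that("orientation moves are exactly rigid and (0,0,0) is the centered identity", {
  s <- build_ideal_helix(fixture_sequence("walp", 4))
  d0 <- stats::dist(s$xyz0)
  for (tr in list(c(0, 0, 0), c(12, 35, 70), c(-30, 120, 200))) {
    s2 <- apply_orientation(s, tr[1], tr[2], tr[3])
    d2 <- stats::dist(as.matrix(s2$atoms[, c("x", "y", "z")]))
    expect_lt(max(abs(d0 - d2)), 1e-9)
  }
  s0 <- apply_orientation(s, 0, 0, 0)
  expect_equal(as.matrix(s0$atoms[, c("x", "y", "z")]),
               unname(s$xyz0), tolerance = 1e-12, ignore_attr = TRUE)
  # mirrored placement: depth -d with tilt theta + 180 gives z -> -z
  sa <- apply_orientation(s, 8, 30, 0)
  sb <- apply_orientation(s, -8, 30 + 180, 0)
  expect_equal(sa$atoms$z, -sb$atoms$z, tolerance = 1e-9)
})

test_that("tilt angles are measured against the membrane normal and folded into [0, 90]", {
  s <- build_ideal_helix(strrep("L", 12))
  expect_equal(tilt_angle(apply_orientation(s, 0, 0, 0)), 0,
               tolerance = 1e-6)
  expect_equal(tilt_angle(apply_orientation(s, 0, 90, 0)), 90,
               tolerance = 1e-6)
  expect_equal(tilt_angle(apply_orientation(s, 0, 120, 0)), 60,
               tolerance = 1e-6)
  expect_equal(tilt_angle(apply_orientation(s, 0, -45, 30)), 45,
               tolerance = 1e-6)
})

test_that("the scanner finds analytic minima, breaks ties deterministically, and matches a shuffled exhaustive oracle", {
  s <- build_ideal_helix("LALALALA")
  grid <- orientation_grid(c(-12, 12), 1, c(0, 10), 10, c(0, 45), 45)
  land <- scan_orientations(s, grid, toy_scorer_depth_well(7))
  expect_equal(land$argmin$d, 7)
  # constant scorer: the tie-break returns the origin
  landc <- scan_orientations(s, grid, function(st) 1)
  expect_equal(unlist(landc$argmin[c("d", "theta", "phi")],
                      use.names = FALSE), c(0, 0, 0))
  # oracle: independent exhaustive re-scan in shuffled order
  prof <- synthetic_profile_params()
  sc <- membrane_scorer(prof)
  g2 <- orientation_grid(c(-20, 20), 4, c(0, 60), 20, c(0, 90), 45)
  land2 <- scan_orientations(s, g2, sc)
  set.seed(4)
  combos <- land2$grid[sample(nrow(land2$grid)), c("d", "theta", "phi")]
  E <- vapply(seq_len(nrow(combos)), function(i)
    sc(apply_orientation(s, combos$d[i], combos$theta[i], combos$phi[i])),
    numeric(1))
  expect_equal(min(E), land2$argmin$E, tolerance = 1e-10)
  best <- combos[which.min(E), ]
  expect_equal(sc(apply_orientation(s, land2$argmin$d, land2$argmin$theta,
                                    land2$argmin$phi)),
               sc(apply_orientation(s, best$d, best$theta, best$phi)),
               tolerance = 1e-10)
  expect_error(scan_orientations(s, grid, "not a scorer"), "scorer")
})

test_that("an apolar charge-free helix has a phi-periodic landscape", {
  s <- build_ideal_helix(strrep("L", 10), charged_termini = FALSE)
  s$atoms$charge <- 0
  sc <- membrane_scorer(synthetic_profile_params())
  g <- orientation_grid(c(0, 0), 1, c(30, 30), 5, c(0, 360), 90)
  land <- scan_orientations(s, g, sc)
  # phi and phi + 360 coincide: the grid excludes the duplicate endpoint
  expect_equal(length(unique(land$grid$phi)), 4)
})

test_that("insertion ddG is the membrane-minus-aqueous minimum difference and shifts cancel", {
  s <- build_ideal_helix(fixture_sequence("polyala", 10))
  nres <- 10
  burial_scorer <- function(st) {
    if (abs(mean(st$atoms$z)) < 15) -nres else 0
  }
  grid <- orientation_grid(c(-60, 60), 10, c(0, 0), 5, c(0, 0), 15)
  v <- ddg_insertion(s, burial_scorer, grid)
  expect_equal(as.numeric(v), -nres)
  expect_equal(attr(v, "G_ref"), 0)
  # additive constants cancel
  v2 <- ddg_insertion(s, function(st) burial_scorer(st) + 123.4, grid)
  expect_equal(as.numeric(v2), as.numeric(v))
  # zero scorer gives zero
  expect_equal(as.numeric(ddg_insertion(s, function(st) 0, grid)), 0)
  shallow <- orientation_grid(c(-10, 10), 5, c(0, 0), 5, c(0, 0), 15)
  expect_error(ddg_insertion(s, burial_scorer, shallow), "aqueous")
})

test_that("mutation ddG is zero for self-mutations, reduces to bilayer differences for membrane-only scorers, and matches a transfer-term oracle", {
  prof <- synthetic_profile_params()
  sc <- membrane_scorer(prof)
  s <- apply_orientation(build_ideal_helix(strrep("A", 9)), 0, 0, 0)
  expect_equal(ddg_mutation(s, 5, "A", sc), 0)
  expect_error(ddg_mutation(s, 5, "Z", sc), "unknown residue")
  expect_error(ddg_mutation(s, 99, "W", sc), "out of range")

  # membrane-only scorer: aqueous energies are numerically negligible, so
  # ddG reduces to the bilayer-state difference
  v <- ddg_mutation(s, 5, "W", sc)
  nat <- memscore:::swap_sidechain(s, 5, "A")
  mut <- memscore:::swap_sidechain(s, 5, "W")
  direct <- sc(apply_orientation(mut, 0, 0, 0)) -
    sc(apply_orientation(nat, 0, 0, 0))
  expect_equal(v, direct, tolerance = 1e-3)

  # transfer-term oracle: with zero charges and a transfer-only weight set,
  # ddG equals the hydration-weighted atom-scale difference of the two
  # side chains
  s0 <- build_ideal_helix(strrep("A", 9), charged_termini = FALSE)
  s0$atoms$charge <- 0
  sc_tr <- membrane_scorer(prof, weights = weight_set(1, 0, 0))
  v2 <- ddg_mutation(apply_orientation(s0, 0, 0, 0), 5, "L", sc_tr)
  natl <- apply_orientation(memscore:::swap_sidechain(s0, 5, "A"), 0, 0, 0)
  mutl <- apply_orientation(memscore:::swap_sidechain(s0, 5, "L"), 0, 0, 0)
  scale <- default_atom_scale()
  oracle <- transfer_energy(mutl, scale)$total -
    transfer_energy(natl, scale)$total
  expect_equal(v2, oracle, tolerance = 1e-3)
})
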