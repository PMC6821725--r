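# Kabsch superposition, protomer RMSD, pore axis, HOLE-style profile,
# ring geometry and distances.

test_that("superposition recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  # identity
  s0 <- superpose(P, P)
  expect_lt(s0$rmsd, 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation plus translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% R90, 2, c(4, -2, 7), "+")
  expect_lt(superpose(P, Q)$rmsd, 1e-9)
  expect_equal(det(superpose(P, Q)$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(P, P[1:5, ]), "paired")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition RMSD matches an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (rep in 1:5) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    ours <- superpose(P, Q)$rmsd
    ref <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
    # bio3d::rmsd rounds its return value to 3 decimals
    expect_lt(abs(ours - ref), 5.1e-4)
    # a coarse rotation-grid search can never beat the closed form
    grid <- expand.grid(a = seq(0, 2 * pi, length.out = 7),
                        b = seq(0, pi, length.out = 5),
                        c = seq(0, 2 * pi, length.out = 7))
    P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
    best_grid <- min(apply(grid, 1, function(g) {
      Rm <- rigid_motion(P0, unlist(g), c(0, 0, 0))
      sqrt(mean(rowSums((Rm - Q0)^2)))
    }))
    expect_lte(ours, best_grid + 1e-9)
  }
})

test_that("pairwise protomer RMSD is symmetric, zero for copies, and metric", {
  pent <- gen_ideal_pentamer()
  M <- pairwise_protomer_rmsd(pent, LETTERS[1:5])
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_lt(max(M), 1e-9)
  # uniform shift of a chain is removed by superposition
  shifted <- pent
  a_rows <- shifted$chain_id == "A"
  shifted$x[a_rows] <- shifted$x[a_rows] + 1
  expect_lt(pairwise_protomer_rmsd(shifted, c("A", "B"))[1, 2], 1e-9)
  # jittered protomers: triangle inequality across all chain triples
  pj <- gen_ideal_pentamer(jitter_sd = 0.1, seed = 5)
  Mj <- pairwise_protomer_rmsd(pj, LETTERS[1:5])
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(Mj[i, j], Mj[i, k] + Mj[k, j] + 1e-9)
})

test_that("pore axis is the symmetry axis and is rigid-motion covariant", {
  pent <- gen_ideal_pentamer()
  ax <- pore_axis(pent, LETTERS[1:5])
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(0.5 * pi / 180))
  # after an arbitrary rigid motion the axis follows the structure
  moved <- apply_rigid_motion(pent)
  ax2 <- pore_axis(moved, LETTERS[1:5])
  expected_dir <- rigid_motion(matrix(ax$direction, 1), shift = c(0, 0, 0))
  cosang <- abs(sum(ax2$direction * expected_dir))
  expect_gt(cosang, cos(0.5 * pi / 180))
  expect_error(pore_axis(pent, c("A", "B")), "3 chains")
})

test_that("pore radius is exact for an analytic ring and C5-consistent", {
  ring <- structure_model(data.frame(
    element = "C", atom_name = "C", residue_name = "RNG",
    residue_number = 1:12, chain_id = rep(LETTERS[1:4], 3),
    x = 5 * cos(2 * pi * (1:12) / 12), y = 5 * sin(2 * pi * (1:12) / 12),
    z = 0, occupancy = 1, altloc = "", b_factor = 0))
  axz <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  pp <- pore_radius_profile(ring, axz, c(-0.2, 0.2), step = 0.2)
  # ring radius 5 minus Bondi carbon radius 1.7
  expect_equal(pp$radius[2], 3.3, tolerance = 1e-6)
  # ideal pentamer: profile unchanged by a 72-degree rotation
  pent <- gen_ideal_pentamer()
  ax <- pore_axis(pent, LETTERS[1:5])
  prof <- pore_radius_profile(pent, ax, c(-10, 10), step = 2)
  th <- 72 * pi / 180
  rot <- pent
  xy <- cbind(pent$x, pent$y) %*%
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot$x <- xy[, 1]; rot$y <- xy[, 2]
  prof_rot <- pore_radius_profile(rot, ax, c(-10, 10), step = 2)
  expect_lt(max(abs(prof$radius - prof_rot$radius)), 0.05)
  # local probe search never underperforms a coarse in-plane grid oracle
  local <- pentarho:::to_axis_frame(
    as.matrix(pent[pent$element != "H", c("x", "y", "z")]), ax)
  vdw <- pentarho:::bondi_radius(pent$element[pent$element != "H"])
  for (zi in seq_len(nrow(prof))) {
    g <- expand.grid(x = seq(-3, 3, by = 0.2), y = seq(-3, 3, by = 0.2))
    clear <- apply(g, 1, function(p) {
      min(sqrt((local[, 1] - p[1])^2 + (local[, 2] - p[2])^2 +
               (local[, 3] - prof$z[zi])^2) - vdw)
    })
    expect_gte(prof$radius[zi], min(max(clear), 15) - 0.05)
  }
  # empty slab: radius capped and flagged
  far <- pore_radius_profile(ring, axz, c(100, 100.4), step = 0.4)
  expect_true(all(far$capped))
  expect_equal(far$radius, rep(15, nrow(far)))
})

test_that("ring geometry orders members by azimuth and measures chords", {
  axz <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  # regular pentagon with circumradius 2.212: chord 2 r sin(36 deg)
  ang <- 2 * pi * (0:4) / 5
  pent_xyz <- cbind(2.212 * cos(ang), 2.212 * sin(ang), 0)
  rg <- ring_geometry(NULL, pent_xyz[c(3, 1, 5, 2, 4), ], axz)
  expect_equal(rg$mean, 2 * 2.212 * sin(36 * pi / 180), tolerance = 1e-9)
  expect_equal(rg$sd, 0, tolerance = 1e-12)
  # unit square: all adjacent distances 1
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0) - 0.5
  rg_sq <- ring_geometry(NULL, sq[c(2, 4, 1, 3), ] + 0.5,
                         list(point = c(0.5, 0.5, 0), direction = c(0, 0, 1)))
  expect_equal(rg_sq$adjacent_distances, rep(1, 4))
  expect_error(ring_geometry(NULL, pent_xyz[1:2, ], axz), "3 atoms")
})

test_that("minimum interatomic distance scans the selection cross product", {
  atoms <- structure_model(data.frame(
    element = c("O", "N", "H"), atom_name = c("O", "N", "H"),
    residue_name = c("HOH", "ARG", "ARG"), residue_number = c(1, 2, 2),
    chain_id = "A", x = c(0, 3, 0.1), y = c(0, 4, 0), z = 0,
    occupancy = 1, altloc = "", b_factor = 0))
  a <- atom_select(atoms, resno = 1)
  b <- atom_select(atoms, resno = 2)
  res <- min_atom_distance(a, b)
  # hydrogen at 0.1 A ignored: the heavy-atom minimum is the 3-4-5 triangle
  expect_equal(res$distance, 5)
  expect_identical(res$atom_b$atom_name, "N")
  expect_equal(min_atom_distance(a, b, heavy_only = FALSE)$distance, 0.1)
  # symmetry of the minimum
  expect_equal(min_atom_distance(b, a)$distance,
               min_atom_distance(a, b)$distance)
  expect_error(min_atom_distance(atom_select(atoms, resno = 99), b), "empty")
})

test_that("geometric outputs are invariant under global rigid motion", {
  pent <- gen_ideal_pentamer(jitter_sd = 0.08, seed = 3)
  moved <- apply_rigid_motion(pent)
  M1 <- pairwise_protomer_rmsd(pent, LETTERS[1:5])
  M2 <- pairwise_protomer_rmsd(moved, LETTERS[1:5])
  expect_equal(M1, M2, tolerance = 1e-6)
  ax1 <- pore_axis(pent, LETTERS[1:5])
  ax2 <- pore_axis(moved, LETTERS[1:5])
  rg1 <- ring_geometry(pent, atom_select(pent, chain = "W"), ax1)
  rg2 <- ring_geometry(moved, atom_select(moved, chain = "W"), ax2)
  expect_equal(rg1$adjacent_distances, rg2$adjacent_distances,
               tolerance = 1e-6)
  d1 <- min_atom_distance(atom_select(pent, chain = "A"),
                          atom_select(pent, chain = "W"))$distance
  d2 <- min_atom_distance(atom_select(moved, chain = "A"),
                          atom_select(moved, chain = "W"))$distance
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("PDB writing and reading round-trips structures at file precision", {
  pent <- gen_ideal_pentamer(atoms_per_chain = 40)
  tf <- tempfile(fileext = ".pdb")
  write_structure(pent, tf)
  back <- read_structure(tf)
  expect_equal(nrow(back), nrow(pent))
  expect_setequal(unique(back$chain_id), unique(pent$chain_id))
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                    as.matrix(pent[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  # waters keep their HETATM identity
  expect_true(all(back$residue_name[back$chain_id == "W"] == "HOH"))
  # a 2-atom handcrafted PDB reads back exactly
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2      -1.500   0.250   9.000  0.50  1.00           N",
    "END"), tf2)
  two <- read_structure(tf2)
  expect_equal(two$x, c(1, -1.5))
  expect_equal(two$occupancy, c(1, 0.5))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       0.000   1.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       0.000   9.000   0.000  0.50  0.00           C",
    "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[1], 5)      # occupancy 0.6 conformer wins
  expect_equal(s$y[2], 1)      # tie broken in favour of altloc A
})
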