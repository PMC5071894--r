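test_that("STL, OBJ and PLY readers handle the standard dialects", {
  cube <- write_cube_stl(tempfile(fileext = ".stl"))
  m <- read_mesh(cube, unit_scale = 1)
  expect_s3_class(m, "surface_mesh")
  expect_equal(nrow(m$faces), 12L)
  expect_equal(nrow(m$vertices), 8L)
  expect_true(is_watertight(m))

  quad <- write_quad_obj(tempfile(fileext = ".obj"))
  mq <- read_mesh(quad, unit_scale = 1)
  expect_equal(nrow(mq$faces), 2L)  # fan split of the quad

  tet <- write_tetra_ply(tempfile(fileext = ".ply"))
  mt <- read_mesh(tet, unit_scale = 1)
  expect_equal(nrow(mt$faces), 4L)
  expect_true(is_watertight(mt))

  bad <- write_cube_stl(tempfile(fileext = ".stl"), truncate = TRUE)
  expect_error(read_mesh(bad, unit_scale = 1), "format error")
})

test_that("write/read round trip preserves coordinates to 6 significant figures", {
  spec <- ellipsoid_spec(0.0137, 0.0082, 0.0051)
  mesh <- aeroscatter:::ellipsoid_mesh(spec, 8, 16)
  path <- tempfile(fileext = ".stl")
  write_stl(mesh, path, unit_scale = 1)
  back <- read_mesh(path, unit_scale = 1)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  # vertex sets match to 6 significant figures (soup order differs)
  key <- function(v) sort(apply(signif(v, 6), 1, paste, collapse = "_"))
  expect_equal(key(back$vertices), key(mesh$vertices))
})

test_that("ellipsoid lattices converge to the analytic volume", {
  # sphere a = 5 mm, d = 1 mm: exact brute-force grid enumeration
  sph <- make_ellipsoid_lattice(ellipsoid_spec(0.005, 0.005, 0.005), 0.001)
  g <- as.matrix(expand.grid(x = -10:9, y = -10:9, z = -10:9)) + 0.5
  oracle_count <- sum(rowSums(g^2) <= 25)   # 552 on this registration
  expect_equal(nrow(sph$positions), oracle_count)
  # and within ~6% of the continuum count 4/3 pi a^3 / d^3 = 523.6
  expect_equal(nrow(sph$positions), (4 / 3) * pi * 125, tolerance = 0.06)
  # equivalent-ellipsoid body of the small bat at 1 mm pitch
  ell <- make_ellipsoid_lattice(paper_ellipsoid(), 0.001)
  expect_equal(nrow(ell$positions), (4 / 3) * pi * 25 * 11.56 * 7.9,
               tolerance = 0.05)
  expect_error(make_ellipsoid_lattice(paper_ellipsoid(), 0.03),
               "discretization error")
  # volume convergence: error shrinks with d and is <= 2% at d = a/10
  sph10 <- make_ellipsoid_lattice(ellipsoid_spec(0.005, 0.005, 0.005), 0.0005)
  vol <- function(l) nrow(l$positions) * l$spacing^3
  v_true <- (4 / 3) * pi * 0.005^3
  expect_lt(abs(vol(sph10) / v_true - 1), 0.02)
  expect_lt(abs(vol(sph10) / v_true - 1), abs(vol(sph) / v_true - 1))
})

test_that("voxelization counts match brute-force point-in-solid oracles", {
  cube <- read_mesh(write_cube_stl(tempfile(fileext = ".stl")), unit_scale = 1)
  lat <- voxelize_mesh(cube, 0.25, material = material(4))
  expect_equal(nrow(lat$positions), 64L)  # 4^3 interior centers
  # brute force: every center must satisfy the analytic inside test
  inside <- apply(lat$positions, 1, function(p) all(p > 0 & p < 1))
  expect_true(all(inside))

  sph_mesh <- aeroscatter:::ellipsoid_mesh(
    ellipsoid_spec(0.005, 0.005, 0.005), 24, 48)
  lat2 <- voxelize_mesh(sph_mesh, 5e-4, material = material(4))
  v_true <- (4 / 3) * pi * 0.005^3
  expect_equal(nrow(lat2$positions) * (5e-4)^3, v_true, tolerance = 0.02)

  open_cube <- cube
  open_cube$faces <- open_cube$faces[-1, ]
  expect_error(voxelize_mesh(open_cube, 0.25), "geometry error")
})

test_that("winding number separates inside from outside on a closed mesh", {
  cube <- read_mesh(write_cube_stl(tempfile(fileext = ".stl")), unit_scale = 1)
  set.seed(7)
  pts <- matrix(runif(300, -0.5, 1.5), ncol = 3)
  w <- winding_number(pts, cube)
  truth <- apply(pts, 1, function(p) all(p > 0 & p < 1))
  expect_equal(abs(w) > 0.5, truth)
  expect_equal(w[truth], rep(1, sum(truth)), tolerance = 1e-9)
  expect_equal(w[!truth], rep(0, sum(!truth)), tolerance = 1e-9)
})

test_that("mirror_lattice doubles a strict half and is idempotent", {
  ell <- make_ellipsoid_lattice(paper_ellipsoid(), 0.002)
  half_sel <- ell$positions[, 2] > 0
  half <- dipole_lattice(ell$positions[half_sel, , drop = FALSE], 0.002,
                         ell$material_ids[half_sel], ell$materials)
  full <- mirror_lattice(half, "sagittal")
  # no sites on the plane (grid is offset by d/2): count exactly doubles
  expect_equal(nrow(full$positions), 2L * nrow(half$positions))
  # brute-force reflection + dedup oracle
  refl <- half$positions
  refl[, 2] <- -refl[, 2]
  oracle <- unique(rbind(half$positions, refl))
  expect_equal(nrow(full$positions), nrow(oracle))
  # idempotence on the symmetric result
  again <- mirror_lattice(full, "sagittal")
  expect_equal(sort(apply(again$positions, 1, paste, collapse = ",")),
               sort(apply(full$positions, 1, paste, collapse = ",")))
  expect_error(mirror_lattice(half, "sagittal", coordinate = 0.002 / 3),
               "geometry error")
})

test_that("toy organism mesh is watertight and sagittally symmetric", {
  toy <- make_toy_organism(toy_organism_spec(wing_span = 0.28,
                                             wing_chord = 0.06,
                                             wing_thickness = 0.001))
  expect_true(is_watertight(toy, by_region = TRUE))
  expect_setequal(unique(toy$region), c("torso", "wing"))
  # vertex set maps onto itself under y -> -y
  key <- function(v) sort(apply(round(v, 10), 1, paste, collapse = "_"))
  mirrored <- toy$vertices
  mirrored[, 2] <- -mirrored[, 2]
  expect_equal(key(mirrored), key(toy$vertices))
  expect_error(toy_organism_spec(wing_span = 0), "validation error")
})

test_that("voxelized toy organism keeps its thin wing membrane", {
  spec <- toy_organism_spec(wing_span = 0.12, wing_chord = 0.03,
                            wing_thickness = 0.001)
  toy <- make_toy_organism(spec, n_theta = 12, n_phi = 24)
  lat <- voxelize_mesh(toy, 5e-4,
                       material_map = list(torso = "bat_effective",
                                           wing = "bat_effective"))
  # brute-force thin-sheet expectation: wing plate area / d^2 sites per
  # layer, two layers at d = t/2
  span_out <- (0.12 - 2 * 0.9 * 0.01156) / 2
  expected_per_wing <- (span_out * 0.03 * 0.001) / (5e-4)^3
  wing_sites <- sum(abs(lat$positions[, 2]) > 0.012)
  expect_gt(wing_sites, 0.7 * 2 * expected_per_wing)
  expect_lt(wing_sites, 1.5 * 2 * expected_per_wing)
  # partial-volume mode keeps the membrane on a grid coarser than it
  lat2 <- voxelize_mesh(toy, 2e-3, partial = TRUE,
                        material_map = list(torso = "bat_effective",
                                            wing = "bat_effective"))
  wing_ids <- grepl("@", lat2$material_ids)
  expect_gt(sum(wing_ids), 0)
  # diluted permittivity sits between vacuum and the full tissue value
  eps <- vapply(lat2$materials, function(m) Re(m$epsilon_r), numeric(1))
  expect_true(all(eps >= 1 - 1e-9 & eps <= 29.29 + 1e-9))
})
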