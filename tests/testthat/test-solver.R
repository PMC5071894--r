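test_that("a single dipole reproduces the point-scatterer closed forms", {
  lam <- 0.03
  k <- 2 * pi / lam
  d <- lam / 100
  lat <- dipole_lattice(matrix(0, 1, 3), d, "eps4",
                        list(eps4 = material(4)))
  w <- plane_wave(lam, c(-1, 0, 0))
  al <- polarizability(material(4), d, lam, model = "cm")$alpha
  # moment = alpha * E_inc exactly (no coupling)
  P <- solve_internal(lat, w, "h", model = "cm")
  expect_equal(drop(P), al * w$hhat, tolerance = 1e-12, ignore_attr = TRUE)
  # backscatter sigma = 4 pi k^4 |alpha|^2, equal co-pol, zero cross-pol
  s <- rcs(backscatter_matrix(lat, w, model = "cm"))
  expect_equal(unname(s["hh"]), 4 * pi * k^4 * Mod(al)^2, tolerance = 1e-10)
  expect_equal(unname(s["vv"]), unname(s["hh"]), tolerance = 1e-12)
  expect_equal(unname(s["hv"]), 0)
  expect_equal(unname(s["vh"]), 0)
})

test_that("two coupled dipoles match an independent closed-form solve", {
  lam <- 0.05
  k <- 2 * pi / lam
  d <- 0.002
  pos <- rbind(c(0, 0, 0), c(0, d, 0))  # separated along the H axis
  lat <- dipole_lattice(pos, d, "m", list(m = material(12 - 3i)))
  w <- plane_wave(lam, c(-1, 0, 0))
  al <- polarizability(material(12 - 3i), d, lam, model = "cm_rr")$alpha
  oracle <- oracle_dipole_moments(pos, rep(al, 2), k, w$khat, w$hhat + 0i)
  P <- solve_internal(lat, w, "h", model = "cm_rr")
  expect_equal(P, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("solver paths agree: parity, plain dense, FFT-Krylov, half-body", {
  lam <- 0.03
  m <- tissue_default("bat_effective")
  sp <- make_ellipsoid_lattice(ellipsoid_spec(0.003, 0.003, 0.003), 0.0005, m)
  w <- plane_wave(lam, c(-1, 0, 0))
  s_plain <- backscatter_matrix(sp, w, use_symmetry = FALSE)
  s_par <- backscatter_matrix(sp, w)
  s_fft <- backscatter_matrix(sp, w, method = "fft", use_symmetry = FALSE)
  ref <- max(Mod(s_plain$S))
  expect_lt(max(Mod(s_par$S - s_plain$S)) / ref, 1e-10)
  expect_lt(max(Mod(s_fft$S - s_plain$S)) / ref, 1e-4)
  # half-body + mirror deduction equals the full solve
  sel <- sp$positions[, 2] > 0
  half <- dipole_lattice(sp$positions[sel, , drop = FALSE], 0.0005,
                         sp$material_ids[sel], sp$materials)
  s_sym <- symmetric_solve(half, "sagittal", w)
  expect_lt(max(Mod(s_sym$S - s_plain$S)) / ref, 0.01)
  # passing an already-mirrored (two-sided) lattice is a geometry error
  expect_error(symmetric_solve(sp, "sagittal", w), "geometry error")
})

test_that("mirror-plane excitation produces no cross-polar backscatter", {
  # k in the sagittal plane + ellipsoid symmetric about it: the
  # mirror-odd mode is unexcited, so S_HV vanishes
  lam <- 0.03
  m <- tissue_default("bat_effective")
  ell <- make_ellipsoid_lattice(ellipsoid_spec(0.004, 0.0025, 0.0015),
                                0.0005, m)
  w <- plane_wave(lam, c(-1, 0, 0))  # head-on: in every mirror plane
  s <- backscatter_matrix(ell, w)
  expect_lt(Mod(s$S["h", "v"]) / max(Mod(s$S)), 1e-10)
})

test_that("sphere lattice matches the Mie backscatter oracle", {
  # x = 1 sits off the material's internal resonances, where the
  # point-dipole formulation converges cleanly (the resonant size
  # parameters are exercised, and documented, by the acceptance gate)
  lam <- 0.03
  m <- tissue_default("bat_effective")
  a <- lam / (2 * pi)  # x = 1
  mie <- mie_solve(a, lam, m)
  sig <- sapply(c(8.4e-4, 4.2e-4), function(d) {
    lat <- make_ellipsoid_lattice(ellipsoid_spec(a, a, a), d, m)
    unname(suppressWarnings(
      rcs(backscatter_matrix(lat, plane_wave(lam, c(-1, 0, 0))))["hh"]))
  })
  err <- abs(sig / mie$sigma_b - 1)
  expect_lt(err[2], 0.10)      # within the oracle gate at |m|kd <= 0.5
  expect_lt(err[2], err[1])    # and converging as d decreases
})

test_that("reciprocity holds on every converged solve", {
  lam <- 0.03
  m <- tissue_default("bat_effective")
  ell <- make_ellipsoid_lattice(ellipsoid_spec(0.004, 0.0025, 0.0015),
                                0.0005, m)
  for (az in c(17, 63, 155)) {  # generic oblique looks, tilted plane
    w <- plane_wave(lam, look_direction(az, 35))
    s <- backscatter_matrix(ell, w)
    expect_lt(Mod(s$S["h", "v"] - s$S["v", "h"]) / max(Mod(s$S)), 0.01)
  }
})

test_that("rotating lattice and look geometry together leaves RCS unchanged", {
  lam <- 0.03
  m <- tissue_default("bat_effective")
  ell <- make_ellipsoid_lattice(ellipsoid_spec(0.004, 0.0025, 0.0015),
                                0.0005, m)
  w <- plane_wave(lam, look_direction(40, 0))
  s0 <- rcs(backscatter_matrix(ell, w, use_symmetry = FALSE))
  # rotate both by 90 deg about z (grid-preserving)
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  rot <- dipole_lattice(ell$positions %*% t(R), ell$spacing,
                        ell$material_ids, ell$materials)
  wr <- plane_wave(lam, drop(R %*% w$khat))
  s1 <- rcs(backscatter_matrix(rot, wr, use_symmetry = FALSE))
  expect_equal(s1, s0, tolerance = 1e-8)
})

test_that("energy balance: extinction >= scattering, equality when lossless", {
  lam <- 0.03
  sp_lossy <- make_ellipsoid_lattice(ellipsoid_spec(0.003, 0.003, 0.003),
                                     4e-4, tissue_default("bat_effective"))
  w <- plane_wave(lam, c(-1, 0, 0))
  cs <- cross_sections(sp_lossy, w, "h")
  expect_gt(cs$c_ext, cs$c_sca)
  expect_gt(cs$c_abs, 0)
  sp_real <- make_ellipsoid_lattice(ellipsoid_spec(0.003, 0.003, 0.003),
                                    4e-4, material(4))
  cs4 <- cross_sections(sp_real, w, "h", model = "cm_rr")
  expect_lt(abs(cs4$c_abs) / cs4$c_ext, 0.01)
})

test_that("azimuth sweeps respect symmetry and validate their grid", {
  lam <- 0.03
  m <- tissue_default("bat_effective")
  sp <- make_ellipsoid_lattice(ellipsoid_spec(0.0025, 0.0025, 0.0025),
                               4e-4, m)
  flat <- azimuth_sweep(sp, lam, step = 30)
  expect_lt(max(flat$sigma_vv_m2) / min(flat$sigma_vv_m2), 1.02)
  ell <- make_ellipsoid_lattice(ellipsoid_spec(0.004, 0.0025, 0.0015),
                                5e-4, m)
  pat <- azimuth_sweep(ell, lam, step = 30)
  sig <- pat$sigma_vv_m2
  naz <- nrow(pat)
  # sigma(phi) = sigma(-phi) and sigma(phi) = sigma(180 - phi)
  neg <- c(1, rev(seq_len(naz)[-1]))
  opp <- (naz / 2 - (seq_len(naz) - 1)) %% naz + 1
  expect_equal(sig[neg], sig, tolerance = 1e-6)
  expect_equal(sig[opp], sig, tolerance = 1e-6)
  expect_error(azimuth_sweep(ell, lam, step = 7), "validation error")
})

test_that("frequency sweep respaces the lattice and finds the Rayleigh slope", {
  m <- tissue_default("bat_effective")
  sph <- ellipsoid_spec(0.002, 0.002, 0.002)
  freqs <- c(0.25e9, 0.5e9, 1e9)
  pats <- frequency_sweep(sph, freqs, material = m, step = 90,
                          spacing_rule = function(lam, mat) 5e-4)
  sig <- vapply(pats, function(p) p$sigma_hh_m2[1], numeric(1))
  slope <- coef(lm(log(sig) ~ log(freqs)))[2]
  expect_equal(unname(slope), 4, tolerance = 0.1)
  # Mie cross-check in the Rayleigh limit at the highest frequency
  mie <- mie_solve(0.002, c_mps / 1e9, m)
  expect_equal(sig[3], mie$sigma_b, tolerance = 0.15)
  # single frequency equals a plain azimuth sweep
  one <- frequency_sweep(sph, 1e9, material = m, step = 90,
                         spacing_rule = function(lam, mat) 5e-4)
  direct <- azimuth_sweep(make_ellipsoid_lattice(sph, 5e-4, m),
                          c_mps / 1e9, step = 90)
  expect_equal(one[[1]]$sigma_hh_m2, direct$sigma_hh_m2, tolerance = 1e-10)
  expect_error(frequency_sweep(sph, numeric(0)), "validation error")
})

test_that("discretization guard rejects |m|kd > 1 and warns above 0.5", {
  m <- tissue_default("bat_effective")
  lam <- 0.03
  coarse <- make_ellipsoid_lattice(ellipsoid_spec(0.005, 0.005, 0.005),
                                   0.0015, m)
  expect_error(backscatter_matrix(coarse, plane_wave(lam, c(-1, 0, 0))),
               "too coarse")
  mid <- make_ellipsoid_lattice(ellipsoid_spec(0.003, 0.003, 0.003),
                                7e-4, m)
  expect_warning(backscatter_matrix(mid, plane_wave(lam, c(-1, 0, 0))),
                 "inaccurate")
})
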