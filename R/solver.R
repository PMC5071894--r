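# User-facing solver operations: internal moments, backscatter matrices,
# azimuth and frequency sweeps, and the mirror-symmetry (half-body) solve.

#' Solve the coupled-dipole system for the internal dipole moments
#'
#' @param lattice A `dipole_lattice`.
#' @param wave A `plane_wave`.
#' @param polarization `"h"`, `"v"`, or a (possibly complex) 3-vector
#'   incident amplitude perpendicular to the propagation direction.
#' @param tolerance Relative residual for the iterative path (the dense
#'   direct path solves to machine level).
#' @param method `"auto"` (dense when it fits, FFT-Krylov otherwise),
#'   `"direct"`, or `"fft"`.
#' @param model Polarizability model (see [polarizability()]).
#' @return n x 3 complex matrix of dipole moments (engineering `exp(+jwt)`
#'   convention), with attributes `residual` and `method`.
#' @export
solve_internal <- function(lattice, wave, polarization = "h",
                           tolerance = 1e-5,
                           method = c("auto", "direct", "fft"),
                           model = "ldr") {
  stopifnot(inherits(lattice, "dipole_lattice"), inherits(wave, "plane_wave"))
  method <- match.arg(method)
  check_discretization(lattice, wave$k)
  e0 <- polarization_vector(polarization, wave)
  sys <- dda_solve_system(lattice, wave$k,
                          list(list(khat = wave$khat, e0 = Conj(e0))),
                          tolerance = tolerance, method = method,
                          planes = NULL, model = model,
                          check_residual = (method != "fft" &&
                                            nrow(lattice$positions) <= 3000))
  P <- moments_from_system(sys, 1L)
  structure(Conj(P), residual = sys$residual, method = sys$method)
}

polarization_vector <- function(polarization, wave) {
  if (is.character(polarization)) {
    switch(match.arg(polarization, c("h", "v")),
           h = wave$hhat + 0i, v = wave$vhat + 0i)
  } else {
    e0 <- as.complex(polarization)
    if (length(e0) != 3L) stop("polarization vector must have length 3")
    if (abs(sum(e0 * wave$khat)) > 1e-8 * sqrt(sum(Mod(e0)^2))) {
      stop("polarization must be perpendicular to the propagation direction")
    }
    e0
  }
}

#' Monostatic (backscatter) polarimetric scattering matrix
#'
#' Solves the lattice for horizontal and vertical incident polarizations
#' and assembles the complex backscatter amplitudes S_pq in the
#' backscatter-alignment basis, normalized so that `sigma_pq = 4 pi
#' |S_pq|^2` (m^2).
#'
#' @inheritParams solve_internal
#' @param use_symmetry Exploit grid mirror symmetries of the lattice to
#'   block-diagonalize the dense solve (results are identical up to
#'   solver tolerance).
#' @return Object of class `scattering_matrix`.
#' @export
backscatter_matrix <- function(lattice, wave, tolerance = 1e-5,
                               method = c("auto", "direct", "fft"),
                               model = "ldr", use_symmetry = TRUE) {
  stopifnot(inherits(lattice, "dipole_lattice"), inherits(wave, "plane_wave"))
  method <- match.arg(method)
  check_discretization(lattice, wave$k)
  planes <- if (use_symmetry) usable_symmetry_planes(lattice) else NULL
  exc <- list(list(khat = wave$khat, e0 = wave$hhat + 0i),
              list(khat = wave$khat, e0 = wave$vhat + 0i))
  sys <- dda_solve_system(lattice, wave$k, exc, tolerance = tolerance,
                          method = method, planes = planes, model = model)
  smatrix_at(sys, wave, c(1L, 2L))
}

usable_symmetry_planes <- function(lattice) {
  planes <- lattice_symmetry_planes(lattice)
  planes <- Filter(function(p) !p$onplane, planes)
  if (length(planes) == 0L) NULL else
    lapply(planes, function(p) p[c("axis", "coordinate")])
}

# assemble a scattering_matrix from a solved system; eh, ev are the
# excitation column indices for H and V transmit
smatrix_at <- function(sys, wave, cols) {
  nhat <- -wave$khat
  Fh <- farfield_from_system(sys, cols[1L], nhat)
  Fv <- farfield_from_system(sys, cols[2L], nhat)
  S <- matrix(c(sum(wave$hhat * Fh), sum(wave$vhat * Fh),
                sum(wave$hhat * Fv), sum(wave$vhat * Fv)),
              2L, 2L, dimnames = list(rx = c("h", "v"), tx = c("h", "v")))
  structure(
    list(S = Conj(S), wavelength = wave$wavelength, khat = wave$khat,
         hhat = wave$hhat, vhat = wave$vhat,
         residual = sys$residual, method = sys$method),
    class = "scattering_matrix"
  )
}

#' Polarimetric radar cross sections from a scattering matrix
#'
#' @param s A `scattering_matrix`.
#' @return Named numeric vector `c(hh, hv, vh, vv)` in m^2
#'   (`sigma_pq = 4 pi |S_pq|^2`; p = receive, q = transmit).
#' @export
rcs <- function(s) {
  stopifnot(inherits(s, "scattering_matrix"))
  4 * pi * c(hh = Mod(s$S["h", "h"])^2, hv = Mod(s$S["h", "v"])^2,
             vh = Mod(s$S["v", "h"])^2, vv = Mod(s$S["v", "v"])^2)
}

#' @export
print.scattering_matrix <- function(x, ...) {
  sig <- rcs(x)
  cat(sprintf("<scattering_matrix> lambda = %g m, look k_hat = (%.3f, %.3f, %.3f) [%s]\n",
              x$wavelength, x$khat[1], x$khat[2], x$khat[3], x$method))
  cat(sprintf("  sigma [m^2]: HH %.4g | VV %.4g | HV %.4g | VH %.4g\n",
              sig["hh"], sig["vv"], sig["hv"], sig["vh"]))
  invisible(x)
}

#' Monostatic azimuth sweep over a (possibly tilted) scan plane
#'
#' For each azimuth the look direction lies in the scan plane obtained by
#' rotating the horizontal plane about the anteroposterior (x) axis by
#' `plane_tilt` degrees; azimuth 0 is head-on and increases clockwise
#' viewed from above. On the dense path one factorization per parity
#' sector serves all azimuths and both polarizations.
#'
#' @inheritParams backscatter_matrix
#' @param wavelength Wavelength in meters.
#' @param plane_tilt Scan-plane tilt in degrees.
#' @param step Azimuth step in degrees; must divide 360.
#' @return A `polar_pattern` (data frame of sigma_hh/vv/hv/vh vs azimuth
#'   with the complex scattering matrices as attribute `smatrix`).
#' @export
azimuth_sweep <- function(lattice, wavelength, plane_tilt = 0, step = 10,
                          tolerance = 1e-5,
                          method = c("auto", "direct", "fft"),
                          model = "ldr", use_symmetry = TRUE) {
  stopifnot(inherits(lattice, "dipole_lattice"))
  method <- match.arg(method)
  if (!is.numeric(step) || step <= 0 || abs(360 / step - round(360 / step)) > 1e-9) {
    stop("validation error: `step` must be a positive divisor of 360")
  }
  k <- 2 * pi / wavelength
  check_discretization(lattice, k)
  azimuths <- seq(0, 360 - step, by = step)
  waves <- lapply(azimuths, function(az) {
    plane_wave(wavelength, look_direction(az, plane_tilt))
  })
  exc <- vector("list", 2L * length(waves))
  for (i in seq_along(waves)) {
    exc[[2L * i - 1L]] <- list(khat = waves[[i]]$khat, e0 = waves[[i]]$hhat + 0i)
    exc[[2L * i]] <- list(khat = waves[[i]]$khat, e0 = waves[[i]]$vhat + 0i)
  }
  planes <- if (use_symmetry) usable_symmetry_planes(lattice) else NULL
  sys <- dda_solve_system(lattice, k, exc, tolerance = tolerance,
                          method = method, planes = planes, model = model)
  sm <- matrix(0 + 0i, length(azimuths), 4L,
               dimnames = list(NULL, c("hh", "hv", "vh", "vv")))
  for (i in seq_along(waves)) {
    s <- smatrix_at(sys, waves[[i]], c(2L * i - 1L, 2L * i))
    sm[i, ] <- c(s$S["h", "h"], s$S["h", "v"], s$S["v", "h"], s$S["v", "v"])
  }
  polar_pattern(azimuths,
                sigma_hh = 4 * pi * Mod(sm[, "hh"])^2,
                sigma_vv = 4 * pi * Mod(sm[, "vv"])^2,
                sigma_hv = 4 * pi * Mod(sm[, "hv"])^2,
                sigma_vh = 4 * pi * Mod(sm[, "vh"])^2,
                wavelength = wavelength, tilt = plane_tilt,
                spacing = lattice$spacing, residual = sys$residual,
                smatrix = sm)
}

#' Frequency sweep at fixed geometry
#'
#' Re-discretizes the geometry at each frequency (holding the physical
#' shape fixed) and runs an azimuth sweep per frequency.
#'
#' @param geometry An `ellipsoid_spec`, a `surface_mesh`, a
#'   `toy_organism_spec`, or a function `function(spacing) -> dipole_lattice`.
#' @param frequencies Frequencies in Hz (all > 0).
#' @param material Material for spec/mesh geometries.
#' @param plane_tilt,step,tolerance,method,model Passed to [azimuth_sweep()].
#' @param spacing_rule `function(wavelength, material) -> spacing` in
#'   meters; the default is `lambda / (10 |m|)` capped at `max_spacing`.
#' @param max_spacing Upper bound on the spacing (e.g. a thin-feature
#'   thickness), meters.
#' @param partial Passed to [voxelize_mesh()] for mesh geometries.
#' @return List of `polar_pattern`s with attribute `frequencies`.
#' @export
frequency_sweep <- function(geometry, frequencies, material = "bat_effective",
                            plane_tilt = 0, step = 10, tolerance = 1e-5,
                            method = "auto", model = "ldr",
                            spacing_rule = NULL, max_spacing = Inf,
                            partial = FALSE) {
  if (length(frequencies) == 0L) stop("validation error: empty frequency list")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("validation error: frequencies must be positive")
  }
  if (inherits(geometry, "toy_organism_spec")) {
    geometry <- make_toy_organism(geometry)
  }
  mat <- as_material(material)
  mk_lattice <- if (is.function(geometry)) {
    geometry
  } else if (inherits(geometry, "ellipsoid_spec")) {
    function(d) make_ellipsoid_lattice(geometry, d, mat)
  } else if (inherits(geometry, "surface_mesh")) {
    function(d) voxelize_mesh(geometry, d, material = mat, partial = partial)
  } else {
    stop("unsupported geometry of class ", paste(class(geometry), collapse = "/"))
  }
  if (is.null(spacing_rule)) {
    spacing_rule <- function(wavelength, material) {
      min(wavelength / (10 * Mod(refractive_index(material))), max_spacing)
    }
  }
  patterns <- lapply(frequencies, function(f) {
    lambda <- .c_mps / f
    d <- spacing_rule(lambda, mat)
    azimuth_sweep(mk_lattice(d), lambda, plane_tilt = plane_tilt, step = step,
                  tolerance = tolerance, method = method, model = model)
  })
  attr(patterns, "frequencies") <- frequencies
  patterns
}

#' Full-body backscatter from a half-body lattice by mirror symmetry
#'
#' Solves the two parity sub-problems (symmetric and antisymmetric
#' combinations of the original and mirrored excitations) on the half
#' lattice and combines them; equals [backscatter_matrix()] on
#' `mirror_lattice(half_lattice, plane)` up to solver tolerance at half
#' the unknown count.
#'
#' @param half_lattice Lattice strictly on one side of the plane.
#' @param plane Mirror plane (as in [mirror_lattice()]).
#' @param wave A `plane_wave`.
#' @param coordinate Plane coordinate (default 0).
#' @inheritParams backscatter_matrix
#' @return A `scattering_matrix` for the mirrored (full) body.
#' @export
symmetric_solve <- function(half_lattice, plane, wave, coordinate = 0,
                            tolerance = 1e-5, model = "ldr") {
  stopifnot(inherits(half_lattice, "dipole_lattice"),
            inherits(wave, "plane_wave"))
  ax <- plane_axis(plane)
  side <- half_lattice$positions[, ax] - coordinate
  if (any(side > 1e-12) && any(side < -1e-12)) {
    stop("geometry error: lattice has sites on both sides of the mirror ",
         "plane; pass a strict half-body")
  }
  if (any(abs(side) <= 1e-12)) {
    stop("geometry error: lattice has sites on the mirror plane")
  }
  check_discretization(half_lattice, wave$k)
  # orient the domain to the positive side expected by the parity solver
  lat <- half_lattice
  if (all(side < 0)) {
    lat$positions[, ax] <- 2 * coordinate - lat$positions[, ax]
  }
  planes <- list(list(axis = ax, coordinate = coordinate))
  # full lattice = domain + image; dda_solve_system checks 2 * nd == n on
  # the mirrored lattice, so hand it the mirrored one with parity planes
  full <- mirror_lattice(lat, plane, coordinate)
  exc <- list(list(khat = wave$khat, e0 = wave$hhat + 0i),
              list(khat = wave$khat, e0 = wave$vhat + 0i))
  sys <- dda_solve_system(full, wave$k, exc, tolerance = tolerance,
                          method = "direct", planes = planes, model = model)
  smatrix_at(sys, wave, c(1L, 2L))
}

#' Extinction, scattering and absorption cross sections
#'
#' Optical-theorem and moment-sum cross sections of a solved lattice:
#' `C_ext` from the forward-scattering (optical) theorem applied to the
#' moment sums, `C_abs` from the per-dipole dissipation, and
#' `C_sca = C_ext - C_abs`. For passive materials `C_ext >= C_sca`.
#'
#' @inheritParams solve_internal
#' @return Named list `c_ext`, `c_sca`, `c_abs` (m^2).
#' @export
cross_sections <- function(lattice, wave, polarization = "h",
                           tolerance = 1e-5, method = "auto",
                           model = "ldr") {
  e0 <- polarization_vector(polarization, wave)
  P_eng <- solve_internal(lattice, wave, polarization, tolerance, method,
                          model = model)
  P <- Conj(P_eng)  # physics convention
  k <- wave$k
  Einc <- incident_field(lattice$positions, k, wave$khat, Conj(e0))
  alpha_inv <- lattice_alpha_inv(lattice, k, model)
  c_ext <- 4 * pi * k * sum(Im(rowSums(P * Conj(Einc))))
  c_abs <- 4 * pi * k * sum(Im(rowSums(P * Conj(P * alpha_inv))) -
                              (2 / 3) * k^3 * rowSums(Mod(P)^2))
  list(c_ext = c_ext, c_sca = c_ext - c_abs, c_abs = c_abs)
}
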