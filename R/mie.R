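# Mie series for homogeneous dielectric and perfectly conducting spheres.
# This is the calibration standard of the measurement emulation and the
# primary analytic oracle for the volume solver.
#
# Internally the series uses the physics time convention exp(-iwt)
# (absorbing index Im(m) >= 0); all derived quantities (cross sections,
# efficiencies) are real and convention-free.

#' Mie solution for a homogeneous or perfectly conducting sphere
#'
#' Computes the partial-wave coefficients `a_n`, `b_n` and the derived
#' monostatic (backscatter) radar cross section and efficiencies for a
#' sphere of given radius at a given wavelength.
#'
#' Dielectric coefficients use the logarithmic-derivative formulation with
#' downward recurrence for stability; the perfectly conducting (PEC) case
#' uses the conducting limit `a_n = psi_n(x)/xi_n(x)`,
#' `b_n = psi_n'(x)/xi_n'(x)` rather than a large-permittivity dielectric.
#' The backscatter RCS is
#' `sigma_b = (pi/k^2) |sum (2n+1)(-1)^n (a_n - b_n)|^2`,
#' which matches the solver normalization `sigma = 4*pi*|S|^2`.
#'
#' @param radius Sphere radius in meters.
#' @param wavelength Wavelength in meters.
#' @param material An `em_material` (or coercible), or the string
#'   `"conducting"` for a perfect electric conductor.
#' @param n_terms Series truncation; defaults to the standard rule
#'   `ceiling(x + 4 x^(1/3) + 2)`.
#' @return Object of class `mie_solution` with fields `x` (size parameter),
#'   `m` (complex index, engineering convention; NA for conducting), `a`,
#'   `b` (coefficient vectors), `sigma_b` (backscatter RCS, m^2), `q_ext`,
#'   `q_sca`, `q_back`, `radius`, `wavelength`.
#' @examples
#' # calibration sphere at X band
#' mie_solve(0.01582 / 2, 0.03, "conducting")
#' @export
mie_solve <- function(radius, wavelength, material = "conducting",
                      n_terms = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.numeric(wavelength) || wavelength <= 0) stop("`wavelength` must be > 0")
  k <- 2 * pi / wavelength
  x <- k * radius
  if (x > 5e3) {
    stop("size parameter x = ", signif(x, 4),
         " too large for the series (overflow); use a shorter radius/",
         "longer wavelength or a geometric-optics approximation")
  }
  conducting <- identical(material, "conducting")
  if (!conducting) material <- as_material(material)

  nmax <- if (is.null(n_terms)) ceiling(x + 4 * x^(1 / 3) + 2) else as.integer(n_terms)
  nmax <- max(nmax, 3L)

  rb <- ricatti_bessel(x, nmax)
  psi <- rb$psi
  chi <- rb$chi
  xi <- psi - 1i * chi
  psi_nm1 <- c(rb$psi0, psi[-nmax])  # psi_{n-1}
  xi_nm1 <- psi_nm1 - 1i * c(rb$chi0, chi[-nmax])
  n <- seq_len(nmax)

  if (conducting) {
    # PEC limit; derivatives via psi'_n = psi_{n-1} - n psi_n / x
    dpsi <- psi_nm1 - n * psi / x
    dxi <- xi_nm1 - n * xi / x
    a <- psi / xi
    b <- dpsi / dxi
    m_out <- NA_complex_
  } else {
    m <- sqrt(Conj(material$epsilon_r))       # physics convention, Im >= 0
    if (Re(m) < 0) m <- -m
    if (abs(m - 1) < 1e-14) {
      a <- b <- rep(0 + 0i, nmax)
    } else {
      D <- mie_log_derivative(m * x, nmax)
      ta <- D / m + n / x
      tb <- D * m + n / x
      a <- (ta * psi - psi_nm1) / (ta * xi - xi_nm1)
      b <- (tb * psi - psi_nm1) / (tb * xi - xi_nm1)
    }
    m_out <- Conj(m)
  }

  two_n1 <- 2 * n + 1
  q_ext <- (2 / x^2) * sum(two_n1 * Re(a + b))
  q_sca <- (2 / x^2) * sum(two_n1 * (Mod(a)^2 + Mod(b)^2))
  s_back <- sum(two_n1 * (-1)^n * (a - b))  # S(180 deg)
  sigma_b <- (pi / k^2) * Mod(s_back)^2
  q_back <- sigma_b / (pi * radius^2)

  structure(
    list(x = x, m = m_out, a = a, b = b, n_terms = nmax,
         sigma_b = sigma_b, q_ext = q_ext, q_sca = q_sca, q_back = q_back,
         radius = radius, wavelength = wavelength,
         conducting = conducting),
    class = "mie_solution"
  )
}

# Riccati-Bessel psi_n = x j_n(x), chi_n = -x y_n(x), upward recurrence.
# Returns psi, chi for n = 1..nmax plus the order-0 values.
ricatti_bessel <- function(x, nmax) {
  psi <- numeric(nmax)
  chi <- numeric(nmax)
  psi_m1 <- cos(x)   # psi_{-1}
  psi_0 <- sin(x)
  chi_m1 <- -sin(x)  # chi_{-1}
  chi_0 <- cos(x)
  pa <- psi_m1; pb <- psi_0
  ca <- chi_m1; cb <- chi_0
  for (n in seq_len(nmax)) {
    pn <- (2 * n - 1) / x * pb - pa
    cn <- (2 * n - 1) / x * cb - ca
    psi[n] <- pn
    chi[n] <- cn
    pa <- pb; pb <- pn
    ca <- cb; cb <- cn
    if (!is.finite(cn)) {
      stop("Riccati-Bessel overflow at order ", n, " (x = ", signif(x, 4), ")")
    }
  }
  list(psi = psi, chi = chi, psi0 = psi_0, chi0 = chi_0)
}

# Logarithmic derivative D_n(z) = psi_n'(z)/psi_n(z) by downward recurrence.
mie_log_derivative <- function(z, nmax) {
  nstart <- max(nmax, ceiling(Mod(z))) + 16L
  D <- complex(nstart + 1L)  # D[n+1] = D_n, D_nstart = 0
  for (n in seq(nstart, 1L)) {
    D[n] <- n / z - 1 / (D[n + 1L] + n / z)
  }
  D[seq_len(nmax) + 1L]
}

#' @export
print.mie_solution <- function(x, ...) {
  cat(sprintf(
    "<mie_solution> %s sphere: a = %.4g m, lambda = %.4g m (x = %.4g)\n",
    if (x$conducting) "conducting" else "dielectric", x$radius, x$wavelength, x$x
  ))
  if (!x$conducting) cat(sprintf("  m = %.4g %+.4gi\n", Re(x$m), Im(x$m)))
  cat(sprintf(
    "  sigma_b = %.6g m^2 (%.2f dBsm), Q_ext = %.6g, Q_sca = %.6g, Q_back = %.6g\n",
    x$sigma_b, 10 * log10(x$sigma_b), x$q_ext, x$q_sca, x$q_back
  ))
  invisible(x)
}

#' Backscatter RCS of the conducting calibration sphere
#'
#' The substitution-calibration reference: monostatic Mie RCS of a
#' perfectly conducting sphere of the given diameter at the radar
#' frequency.
#'
#' @param diameter Sphere diameter in meters.
#' @param frequency Radar frequency in Hz.
#' @return Backscatter RCS in m^2.
#' @examples
#' calibration_sphere_rcs(0.01582, 10e9)
#' @export
calibration_sphere_rcs <- function(diameter, frequency) {
  if (!is.numeric(diameter) || diameter <= 0) stop("`diameter` must be > 0")
  if (!is.numeric(frequency) || frequency <= 0) stop("`frequency` must be > 0")
  lambda <- .c_mps / frequency
  mie_solve(diameter / 2, lambda, "conducting")$sigma_b
}

# speed of light, m/s
.c_mps <- 299792458
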