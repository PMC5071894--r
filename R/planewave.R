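# Incident plane waves and look geometry.
#
# Backscatter-alignment (BSA) basis: for look direction k_hat (propagation
# toward the target), h_hat = normalize(k_hat x z_hat) is horizontal at
# zero tilt and v_hat = k_hat x h_hat completes the right-handed triad
# (h, v, k). The same basis is used on transmit and receive, which makes
# the backscatter matrix symmetric (S_HV = S_VH) for reciprocal media.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-14) stop("cannot normalize near-zero vector")
  v / n
}

#' Incident plane wave
#'
#' @param wavelength Wavelength in meters (give this or `frequency`).
#' @param direction Propagation direction (3-vector, toward the target);
#'   normalized internally.
#' @param frequency Frequency in Hz (alternative to `wavelength`,
#'   c = 299792458 m/s).
#' @return Object of class `plane_wave` with fields `wavelength`, `k`
#'   (angular wavenumber), `khat`, `hhat`, `vhat`.
#' @export
plane_wave <- function(wavelength = NULL, direction = c(-1, 0, 0),
                       frequency = NULL) {
  if (is.null(wavelength)) {
    if (is.null(frequency)) stop("give `wavelength` or `frequency`")
    wavelength <- .c_mps / frequency
  }
  if (!is.numeric(wavelength) || wavelength <= 0) stop("`wavelength` must be > 0")
  khat <- normalize(as.numeric(direction))
  hv <- bsa_basis(khat)
  structure(list(wavelength = wavelength, k = 2 * pi / wavelength,
                 khat = khat, hhat = hv$h, vhat = hv$v),
            class = "plane_wave")
}

#' @export
print.plane_wave <- function(x, ...) {
  cat(sprintf(
    "<plane_wave> lambda = %g m, k_hat = (%.3f, %.3f, %.3f)\n",
    x$wavelength, x$khat[1], x$khat[2], x$khat[3]))
  invisible(x)
}

bsa_basis <- function(khat) {
  hz <- cross3(khat, c(0, 0, 1))
  if (sqrt(sum(hz^2)) < 1e-10) {
    # vertical look: pick lateral axis as "horizontal"
    h <- c(0, 1, 0)
    h <- normalize(h - sum(h * khat) * khat)
  } else {
    h <- normalize(hz)
  }
  list(h = h, v = cross3(khat, h))
}

#' Look direction for an azimuth on a (possibly tilted) scan plane
#'
#' The scan plane is the horizontal plane rotated by `tilt_deg` about the
#' anteroposterior (x) axis; azimuth 0 is head-on (radar on the +x side)
#' and azimuth increases clockwise viewed from above.
#'
#' @param azimuth_deg Azimuth in degrees.
#' @param tilt_deg Scan-plane tilt in degrees.
#' @return Unit propagation direction k_hat (radar toward target).
#' @export
look_direction <- function(azimuth_deg, tilt_deg = 0) {
  phi <- azimuth_deg * pi / 180
  tau <- tilt_deg * pi / 180
  u <- c(cos(phi), -cos(tau) * sin(phi), -sin(tau) * sin(phi))
  -u
}
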