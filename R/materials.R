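# Complex permittivity, effective-medium averaging and per-dipole polarizability.
#
# Sign convention: time factor exp(+j*omega*t), so a lossy material has
# eps = eps' - j*eps'' with eps'' >= 0, and Im(m) <= 0 for the refractive
# index.  The solver works internally in the opposite (physics) convention
# and conjugates at its boundary; user-facing quantities always follow the
# engineering convention above.

#' Create a material from its complex relative permittivity
#'
#' @param epsilon_r Complex relative permittivity under the `exp(+jwt)`
#'   convention, i.e. `eps' - 1i*eps''` with `eps'' >= 0` for a lossy
#'   material. A real number is promoted to a lossless permittivity.
#' @param name Optional label.
#' @return An object of class `em_material`.
#' @examples
#' bat <- material(29.29 - 12.89i, "bat_effective")
#' refractive_index(bat)
#' @export
material <- function(epsilon_r, name = "material") {
  epsilon_r <- as.complex(epsilon_r)
  if (length(epsilon_r) != 1L || is.na(epsilon_r)) {
    stop("`epsilon_r` must be a single complex value")
  }
  if (Im(epsilon_r) > 1e-12) {
    stop(
      "Im(epsilon_r) > 0: under the exp(+jwt) convention a lossy material ",
      "has eps = eps' - j*eps'' (negative imaginary part)"
    )
  }
  structure(
    list(epsilon_r = epsilon_r, name = as.character(name)[1L]),
    class = "em_material"
  )
}

#' @export
print.em_material <- function(x, ...) {
  cat(sprintf(
    "<em_material> %s: eps_r = %.4g %s j%.4g\n",
    x$name, Re(x$epsilon_r),
    if (Im(x$epsilon_r) <= 0) "-" else "+", abs(Im(x$epsilon_r))
  ))
  invisible(x)
}

is_material <- function(x) inherits(x, "em_material")

as_material <- function(x) {
  if (is_material(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(tissue_default(x))
  if (is.numeric(x) || is.complex(x)) return(material(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a material")
}

#' Volume-weighted effective permittivity
#'
#' Collapses a heterogeneous body into a single body-averaged complex
#' permittivity: the arithmetic mean of the component permittivities
#' weighted by volume fraction. This is the simplest homogenization rule;
#' it is exact in the Rayleigh limit for field components parallel to thin
#' laminae and adequate for the body-averaged use made of it here.
#'
#' @param materials List of `em_material` objects (or things coercible to
#'   them, e.g. names in the tissue table).
#' @param weights Non-negative volume weights, at least one positive.
#'   Normalized internally to sum to one.
#' @param name Label for the resulting material.
#' @return An `em_material` with the averaged permittivity.
#' @examples
#' effective_permittivity(list(10 - 2i, 20 - 4i), c(1, 1)) # 15 - 3i
#' @export
effective_permittivity <- function(materials, weights, name = "effective") {
  if (is_material(materials)) materials <- list(materials)
  materials <- lapply(materials, as_material)
  weights <- as.numeric(weights)
  if (length(materials) != length(weights)) {
    stop("`materials` and `weights` must have the same length")
  }
  if (length(weights) == 0L || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with at least one positive entry")
  }
  w <- weights / sum(weights)
  eps <- sum(vapply(materials, function(m) m$epsilon_r, complex(1)) * w)
  material(eps, name)
}

#' Complex refractive index of a material
#'
#' Principal square root of the relative permittivity with `Re(m) > 0` and
#' `Im(m) <= 0` (engineering convention).
#'
#' @param material An `em_material` (or something coercible to one).
#' @return Complex refractive index `m` with `m^2 = epsilon_r`.
#' @examples
#' refractive_index(material(4))              # 2
#' refractive_index(material(29.29 - 12.89i)) # ~ 5.54 - 1.16i
#' @export
refractive_index <- function(material) {
  material <- as_material(material)
  # principal root in the physics convention (Im >= 0), then conjugate back
  m_phys <- sqrt(Conj(material$epsilon_r))
  if (Re(m_phys) < 0) m_phys <- -m_phys
  Conj(m_phys)
}

# Lattice-dispersion-relation coefficients (cubic lattice, pulse basis).
.ldr_b1 <- -1.891531
.ldr_b2 <- 0.1648469
.ldr_b3 <- -1.7700004

# Polarizability in the internal physics convention (exp(-iwt), Im eps >= 0).
# eps_phys: physics-convention permittivity; d: lattice pitch (m); k = 2*pi/lambda.
# model: "cm" plain Clausius-Mossotti, "cm_rr" CM + radiative reaction,
# "ldr" CM + lattice dispersion relation + radiative reaction (default).
# ldr_s is the orientation factor S; 0.2 is the orientation average, used so
# that the polarizability (and hence one factorization) serves every look
# direction of a sweep.
alpha_phys <- function(eps_phys, d, k, model = c("ldr", "cm_rr", "cm"),
                       ldr_s = 0.2) {
  model <- match.arg(model)
  if (abs(eps_phys + 2) < 1e-12) {
    stop("epsilon_r = -2 is the Clausius-Mossotti pole; polarizability undefined")
  }
  a_cm <- (3 * d^3 / (4 * pi)) * (eps_phys - 1) / (eps_phys + 2)
  if (a_cm == 0) return(a_cm)
  kd <- k * d
  corr <- switch(model,
    cm = 0 + 0i,
    cm_rr = -(2 / 3) * 1i * kd^3,
    ldr = {
      m2 <- eps_phys
      (.ldr_b1 + m2 * .ldr_b2 + m2 * .ldr_b3 * ldr_s) * kd^2 -
        (2 / 3) * 1i * kd^3
    }
  )
  a_cm / (1 + (a_cm / d^3) * corr)
}

#' Per-dipole polarizability for the coupled-dipole solver
#'
#' Scalar polarizability of a cubic lattice cell of pitch `spacing` filled
#' with `material`, at wavelength `wavelength`. The base value is the
#' Clausius-Mossotti polarizability `d^3 * (3/(4*pi)) * (eps-1)/(eps+2)`;
#' the default model adds the lattice-dispersion-relation correction and the
#' radiative-reaction term, the standard accuracy fix for the coupled-dipole
#' method at finite spacing.
#'
#' @param material An `em_material` (or coercible).
#' @param spacing Lattice pitch d in meters.
#' @param wavelength Wavelength in meters.
#' @param model One of `"ldr"` (default), `"cm_rr"`, `"cm"`.
#' @param ldr_s Orientation factor S of the LDR correction; the default 0.2
#'   is the orientation average so that the value is look-angle independent.
#' @return An object of class `polarizability` with fields `alpha` (complex,
#'   m^3, engineering sign convention: `Im(alpha) <= 0` for passive
#'   materials), `spacing`, `wavelength` and `model`.
#' @export
polarizability <- function(material, spacing, wavelength,
                           model = c("ldr", "cm_rr", "cm"), ldr_s = 0.2) {
  material <- as_material(material)
  model <- match.arg(model)
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (!is.numeric(wavelength) || wavelength <= 0) stop("`wavelength` must be > 0")
  a <- alpha_phys(Conj(material$epsilon_r), spacing, 2 * pi / wavelength,
                  model, ldr_s)
  if (!is.finite(Re(a)) || !is.finite(Im(a))) {
    stop("polarizability is not finite for this material/spacing/wavelength")
  }
  structure(
    list(alpha = Conj(a), spacing = spacing, wavelength = wavelength,
         model = model, material = material$name),
    class = "polarizability"
  )
}

#' @export
print.polarizability <- function(x, ...) {
  cat(sprintf(
    "<polarizability> %s model, material %s: alpha = %.4g %+.4gi m^3 (d = %g m, lambda = %g m)\n",
    x$model, x$material, Re(x$alpha), Im(x$alpha), x$spacing, x$wavelength
  ))
  invisible(x)
}

# package-local cache (materials table etc.)
.aeroscatter_env <- new.env(parent = emptyenv())

#' Read a materials table
#'
#' The table is a JSON array of records with fields `name`, `eps_real`,
#' `eps_imag` (the loss magnitude eps'', stored positive) and optionally
#' `frequency_hz` (frequency of validity) and `note`.
#'
#' @param path Path to a JSON materials file.
#' @return Named list of `em_material` objects.
#' @export
read_materials <- function(path) {
  if (!file.exists(path)) stop("materials file not found: ", path)
  tab <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  mats <- lapply(seq_len(nrow(tab)), function(i) {
    material(complex(real = tab$eps_real[i], imaginary = -abs(tab$eps_imag[i])),
             tab$name[i])
  })
  names(mats) <- tab$name
  mats
}

default_materials <- function() {
  if (is.null(.aeroscatter_env$materials)) {
    path <- system.file("extdata", "materials.json", package = "aeroscatter")
    .aeroscatter_env$materials <- read_materials(path)
  }
  .aeroscatter_env$materials
}

#' Look up a shipped tissue/material default
#'
#' The shipped table contains `"bat_effective"` (the homogenized
#' body-averaged permittivity 29.29 - j12.89 used throughout for organism
#' bodies), `"vacuum"`, and wet/dry skin values at 10 GHz from the standard
#' tissue dielectric parameterization. Perfectly conducting targets (the
#' calibration sphere) are requested from the Mie module with the string
#' `"conducting"`, not through this table.
#'
#' @param name Material name in the shipped table.
#' @return An `em_material`.
#' @examples
#' tissue_default("bat_effective")
#' @export
tissue_default <- function(name) {
  mats <- default_materials()
  if (!name %in% names(mats)) {
    stop("unknown material \"", name, "\"; shipped table has: ",
         paste(names(mats), collapse = ", "))
  }
  mats[[name]]
}
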