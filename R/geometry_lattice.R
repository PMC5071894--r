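# Dipole lattices: the volumetric discretization consumed by the
# coupled-dipole solver. Sites live on a single cubic grid of pitch d;
# each site carries a material reference.

#' Construct a dipole lattice
#'
#' @param positions n x 3 matrix of site centers (meters) on a cubic grid.
#' @param spacing Grid pitch d in meters.
#' @param material_ids Character vector (length n) of material ids, or a
#'   single id recycled.
#' @param materials Named list of `em_material` objects covering all ids.
#' @return Object of class `dipole_lattice`.
#' @export
dipole_lattice <- function(positions, spacing, material_ids = "bat_effective",
                           materials = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  if (nrow(positions) == 0L) stop("lattice must be nonempty")
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (length(material_ids) == 1L) {
    material_ids <- rep(material_ids, nrow(positions))
  }
  if (length(material_ids) != nrow(positions)) {
    stop("`material_ids` must have one entry per site")
  }
  ids <- unique(material_ids)
  if (is.null(materials)) {
    materials <- lapply(ids, as_material)
    names(materials) <- ids
  }
  if (!all(ids %in% names(materials))) {
    stop("materials table missing ids: ",
         paste(setdiff(ids, names(materials)), collapse = ", "))
  }
  # verify single cubic grid
  ref <- positions[1, ]
  offs <- sweep(positions, 2, ref) / spacing
  if (max(abs(offs - round(offs))) > 1e-6) {
    stop("positions do not lie on a single cubic grid of pitch ", spacing)
  }
  structure(
    list(positions = positions, spacing = spacing,
         material_ids = as.character(material_ids),
         materials = materials[ids]),
    class = "dipole_lattice"
  )
}

#' @export
print.dipole_lattice <- function(x, ...) {
  bb <- apply(x$positions, 2, range)
  cat(sprintf(
    "<dipole_lattice> %d sites, d = %g m | materials: %s\n  extent [m]: x %.4g..%.4g, y %.4g..%.4g, z %.4g..%.4g\n",
    nrow(x$positions), x$spacing, paste(names(x$materials), collapse = ", "),
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

# integer grid indices relative to the site-wise minimum corner
lattice_grid_index <- function(lattice) {
  ref <- apply(lattice$positions, 2, min)
  idx <- sweep(lattice$positions, 2, ref) / lattice$spacing
  storage.mode(idx) <- "double"
  round(idx)
}

#' Parametric ellipsoid specification
#'
#' Semi-axes follow the body-axis convention: x anteroposterior,
#' y lateral, z dorsoventral.
#'
#' @param semi_ap,semi_lat,semi_dv Semi-axes in meters (> 0).
#' @param center Center, meters.
#' @param orientation 3 x 3 rotation matrix taking body axes to world axes.
#' @return Object of class `ellipsoid_spec`.
#' @examples
#' # equivalent ellipsoid of a small bat: full axes 50 x 23.12 x 15.8 mm
#' ellipsoid_spec(0.025, 0.01156, 0.0079)
#' @export
ellipsoid_spec <- function(semi_ap, semi_lat, semi_dv, center = c(0, 0, 0),
                           orientation = diag(3)) {
  semi <- c(semi_ap, semi_lat, semi_dv)
  if (!is.numeric(semi) || any(semi <= 0)) stop("all semi-axes must be > 0")
  orientation <- as.matrix(orientation)
  if (!isTRUE(all.equal(crossprod(orientation), diag(3), tolerance = 1e-8)) ||
      det(orientation) < 0) {
    stop("`orientation` must be a proper rotation matrix")
  }
  structure(list(semi = semi, center = as.numeric(center),
                 orientation = orientation),
            class = "ellipsoid_spec")
}

#' @export
print.ellipsoid_spec <- function(x, ...) {
  cat(sprintf("<ellipsoid_spec> semi-axes (AP, lat, DV) = (%g, %g, %g) m\n",
              x$semi[1], x$semi[2], x$semi[3]))
  invisible(x)
}

#' Dipole lattice filling a parametric ellipsoid
#'
#' Grid sites whose centers satisfy the ellipsoid inequality, on the
#' package's symmetric grid registration. The site count approaches
#' (4/3) pi a b c / d^3 as the pitch d decreases.
#'
#' @param spec An `ellipsoid_spec`.
#' @param spacing Pitch d in meters; must be smaller than the smallest
#'   semi-axis.
#' @param material Material or shipped-table name.
#' @return A `dipole_lattice`.
#' @export
make_ellipsoid_lattice <- function(spec, spacing, material = "bat_effective") {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (spacing >= min(spec$semi)) {
    stop("discretization error: spacing ", spacing,
         " m is not smaller than the smallest semi-axis (", min(spec$semi), " m)")
  }
  R <- spec$orientation
  # axis-aligned half-extents of the rotated ellipsoid
  half <- sqrt((R^2) %*% (spec$semi^2))
  centers <- lapply(1:3, function(ax) {
    grid_axis(spec$center[ax] - half[ax], spec$center[ax] + half[ax], spacing)
  })
  pts <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  body <- sweep(pts, 2, spec$center) %*% R  # back to body frame
  q <- (body[, 1] / spec$semi[1])^2 + (body[, 2] / spec$semi[2])^2 +
    (body[, 3] / spec$semi[3])^2
  keep <- q <= 1
  if (!any(keep)) {
    stop("discretization error: spacing too coarse, no sites inside ellipsoid")
  }
  mat <- as_material(material)
  dipole_lattice(pts[keep, , drop = FALSE], spacing, mat$name,
                 stats::setNames(list(mat), mat$name))
}

plane_axis <- function(plane) {
  if (is.numeric(plane)) {
    ax <- as.integer(plane)
    if (!ax %in% 1:3) stop("plane axis must be 1, 2 or 3")
    return(ax)
  }
  switch(match.arg(plane, c("transverse", "sagittal", "coronal")),
         transverse = 1L, sagittal = 2L, coronal = 3L)
}

#' Mirror a lattice across a grid-aligned mid-plane
#'
#' The output is the union of the input and its mirror image (duplicates
#' on the plane are kept once), so the operation is idempotent on
#' already-symmetric lattices.
#'
#' @param lattice A `dipole_lattice`.
#' @param plane `"sagittal"` (normal y), `"transverse"` (normal x),
#'   `"coronal"` (normal z), or an axis index 1..3.
#' @param coordinate Plane position along the axis (meters, default 0 =
#'   the body mid-plane). Must coincide with a lattice grid plane (a site
#'   plane or a mid-plane between sites).
#' @return A `dipole_lattice`.
#' @export
mirror_lattice <- function(lattice, plane = "sagittal", coordinate = 0) {
  stopifnot(inherits(lattice, "dipole_lattice"))
  ax <- plane_axis(plane)
  d <- lattice$spacing
  # reflection must map the grid onto itself
  twice <- 2 * (coordinate - lattice$positions[1, ax]) / d
  if (abs(twice - round(twice)) > 1e-6) {
    stop("geometry error: mirror plane is not aligned with the lattice grid")
  }
  refl <- lattice$positions
  refl[, ax] <- 2 * coordinate - refl[, ax]
  all_pos <- rbind(lattice$positions, refl)
  all_ids <- c(lattice$material_ids, lattice$material_ids)
  key <- apply(round(sweep(all_pos, 2, all_pos[1, ]) / d), 1, paste,
               collapse = ",")
  keep <- !duplicated(key)
  dipole_lattice(all_pos[keep, , drop = FALSE], d, all_ids[keep],
                 lattice$materials)
}

# Detect grid-aligned mirror symmetries through the lattice mid-planes.
# Returns a list of list(axis=, coordinate=) for use by the parity solver.
lattice_symmetry_planes <- function(lattice) {
  d <- lattice$spacing
  idx <- lattice_grid_index(lattice)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], lattice$material_ids, sep = ",")
  planes <- list()
  for (ax in 1:3) {
    rng <- range(lattice$positions[, ax])
    coord <- mean(rng)
    m <- round(2 * (coord - min(lattice$positions[, ax])) / d)
    ridx <- idx
    ridx[, ax] <- m - idx[, ax]
    if (any(ridx[, ax] < 0)) next
    rkey <- paste(ridx[, 1], ridx[, 2], ridx[, 3], lattice$material_ids,
                  sep = ",")
    if (all(rkey %in% key)) {
      # exclude planes with sites on them (parity reduction assumes none)
      onplane <- abs(lattice$positions[, ax] - coord) < d * 1e-6
      planes[[length(planes) + 1L]] <-
        list(axis = ax, coordinate = coord, onplane = any(onplane))
    }
  }
  planes
}

#' Toy organism specification
#'
#' A parametric stand-in for an anatomical small-bat mesh: an ellipsoidal
#' head+torso with two thin prismatic wing plates attached at the flanks,
#' coplanar with the anteroposterior-lateral plane and mirror-symmetric
#' across the sagittal plane.
#'
#' @param body An `ellipsoid_spec` (default: 50 x 23.12 x 15.8 mm full
#'   axes, the equivalent-ellipsoid body used throughout).
#' @param wing_span Tip-to-tip span in meters (default 0.24 m).
#' @param wing_chord Chord (anteroposterior width) in meters (default 0.06).
#' @param wing_thickness Membrane thickness in meters (default 1 mm).
#' @param wing_sweep_deg Backward sweep angle in degrees (default 0).
#' @return Object of class `toy_organism_spec`.
#' @export
toy_organism_spec <- function(body = ellipsoid_spec(0.025, 0.01156, 0.0079),
                              wing_span = 0.24, wing_chord = 0.06,
                              wing_thickness = 0.001, wing_sweep_deg = 0) {
  stopifnot(inherits(body, "ellipsoid_spec"))
  if (!all(c(wing_span, wing_chord, wing_thickness) > 0)) {
    stop("validation error: wing dimensions must be > 0")
  }
  if (wing_span <= 2 * body$semi[2]) {
    stop("validation error: wing_span must exceed the body width")
  }
  structure(list(body = body, wing_span = wing_span, wing_chord = wing_chord,
                 wing_thickness = wing_thickness,
                 wing_sweep_deg = wing_sweep_deg),
            class = "toy_organism_spec")
}

#' Equivalent ellipsoid of a body specification
#'
#' The size-ratio simplification replaces a detailed body by an ellipsoid
#' built from the body's approximate overall dimensions along the three
#' anatomical axes. For a winged organism the lateral extent includes the
#' wings: thin high-permittivity membranes dominate the lateral
#' polarizability at long wavelengths, so an ellipsoid matching only the
#' torso produces patterns that are anti-correlated with the winged body
#' rather than equivalent to it.
#'
#' @param spec A `toy_organism_spec` (or an `ellipsoid_spec`, returned
#'   unchanged).
#' @return An `ellipsoid_spec` with semi-axes (max(body AP, chord/2),
#'   span/2, body DV).
#' @export
equivalent_ellipsoid <- function(spec) {
  if (inherits(spec, "ellipsoid_spec")) return(spec)
  stopifnot(inherits(spec, "toy_organism_spec"))
  ellipsoid_spec(max(spec$body$semi[1], spec$wing_chord / 2),
                 spec$wing_span / 2,
                 spec$body$semi[3],
                 center = spec$body$center,
                 orientation = spec$body$orientation)
}

#' Build the toy-organism surface mesh
#'
#' Returns a watertight multi-component mesh (regions `"torso"` and
#' `"wing"`); the wing plates overlap slightly into the body flank so the
#' union of the closed components is a connected solid.
#'
#' @param spec A `toy_organism_spec`.
#' @param n_theta,n_phi Ellipsoid tessellation resolution.
#' @return A `surface_mesh` with region labels.
#' @export
make_toy_organism <- function(spec, n_theta = 16L, n_phi = 32L) {
  stopifnot(inherits(spec, "toy_organism_spec"))
  body <- ellipsoid_mesh(spec$body, n_theta, n_phi)
  b <- spec$body$semi
  root <- 0.9 * b[2]           # wing root tucked into the flank
  tip <- spec$wing_span / 2
  t2 <- spec$wing_thickness / 2
  c2 <- spec$wing_chord / 2
  shear <- tan(spec$wing_sweep_deg * pi / 180)
  right <- prism_mesh(root, tip, c2, t2, shear)
  left <- right
  left$vertices[, 2] <- -left$vertices[, 2]
  left$faces <- left$faces[, c(1, 3, 2)]  # restore outward orientation
  vs <- rbind(body$vertices, right$vertices, left$vertices)
  fo <- nrow(body$vertices)
  fs <- rbind(body$faces,
              right$faces + fo,
              left$faces + fo + nrow(right$vertices))
  region <- c(rep("torso", nrow(body$faces)),
              rep("wing", nrow(right$faces) + nrow(left$faces)))
  surface_mesh(vs, fs, region)
}

# UV-tessellated ellipsoid, watertight, mirror-symmetric across all three
# body mid-planes when n_theta is even and n_phi divisible by 4.
ellipsoid_mesh <- function(spec, n_theta, n_phi) {
  n_theta <- max(4L, as.integer(n_theta))
  n_phi <- max(8L, as.integer(n_phi))
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  ring <- as.matrix(expand.grid(phi = phi, theta = theta))
  unit <- cbind(cos(ring[, "theta"]),
                sin(ring[, "theta"]) * cos(ring[, "phi"]),
                sin(ring[, "theta"]) * sin(ring[, "phi"]))
  verts <- rbind(c(1, 0, 0), unit, c(-1, 0, 0))
  npole <- 1L
  spole <- nrow(verts)
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(npole, vid(1L, j), vid(1L, j + 1L))
  }
  nb <- n_theta - 2L
  for (i in seq_len(nb)) {
    for (j in seq_len(n_phi)) {
      a <- vid(i, j); b2 <- vid(i, j + 1L)
      c3 <- vid(i + 1L, j); d4 <- vid(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c3, b2)
      faces[[length(faces) + 1L]] <- c(b2, c3, d4)
    }
  }
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(spole, vid(nb + 1L, j + 1L), vid(nb + 1L, j))
  }
  verts <- sweep(verts %*% diag(spec$semi) %*% t(spec$orientation), 2,
                 -spec$center)
  surface_mesh(verts, do.call(rbind, faces))
}

# sheared rectangular prism for one (right, +y) wing
prism_mesh <- function(y0, y1, c2, t2, shear) {
  corners <- as.matrix(expand.grid(x = c(-c2, c2), y = c(y0, y1),
                                   z = c(-t2, t2)))
  corners[, 1] <- corners[, 1] - shear * (corners[, 2] - y0)
  # unit-cube triangulation (outward-facing) on the expand.grid ordering
  idx <- function(x, y, z) 1L + x + 2L * y + 4L * z
  quads <- rbind(
    c(idx(0,0,0), idx(0,1,0), idx(1,1,0), idx(1,0,0)),  # z = -t2 (bottom)
    c(idx(0,0,1), idx(1,0,1), idx(1,1,1), idx(0,1,1)),  # z = +t2 (top)
    c(idx(0,0,0), idx(1,0,0), idx(1,0,1), idx(0,0,1)),  # y = y0
    c(idx(0,1,0), idx(0,1,1), idx(1,1,1), idx(1,1,0)),  # y = y1
    c(idx(0,0,0), idx(0,0,1), idx(0,1,1), idx(0,1,0)),  # x min
    c(idx(1,0,0), idx(1,1,0), idx(1,1,1), idx(1,0,1))   # x max
  )
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  surface_mesh(corners, faces)
}
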