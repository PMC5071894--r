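# Triangulated surface meshes: readers (STL/OBJ/PLY), STL writer,
# watertightness via directed-edge pairing, winding-number inside test,
# and voxelization onto a cubic dipole lattice.
#
# Axis convention used throughout the package:
#   x = anteroposterior (nose -> +x), y = lateral (left -> +y),
#   z = dorsoventral (up -> +z).
# Azimuth 0 deg is head-on (look direction -x).

#' Construct a surface mesh
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates in meters.
#' @param faces Integer m x 3 matrix of 1-based vertex indices
#'   (counter-clockwise when viewed from outside).
#' @param region Optional character vector of per-face region labels
#'   (e.g. "torso", "wing").
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, region = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix of vertex triples")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("geometry error: face indices out of range")
  }
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != nrow(faces)) {
      stop("`region` must have one label per face")
    }
  }
  structure(list(vertices = vertices, faces = faces, region = region),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$region)) {
    cat(" | regions:", paste(unique(x$region), collapse = ", "))
  }
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("\n  bbox [m]: x %.4g..%.4g, y %.4g..%.4g, z %.4g..%.4g\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Read a triangulated mesh from STL, OBJ or PLY
#'
#' STL is read in both ASCII and binary dialects; OBJ and PLY are read in
#' their ASCII forms. Polygonal faces (quads and larger) are triangulated
#' with a deterministic fan split. STL soup vertices are merged exactly so
#' that edge-based watertightness checks are meaningful.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"stl"`, `"obj"`, `"ply"`.
#' @param unit_scale Multiplicative conversion of file coordinates to
#'   meters. Organism meshes are conventionally authored in millimeters,
#'   hence the default `1e-3`.
#' @return A `surface_mesh` with coordinates in meters.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj", "ply"),
                      unit_scale = 1e-3) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "obj", "ply")) {
      stop("format error: cannot infer mesh format from extension \".",
           format, "\"")
    }
  }
  mesh <- switch(format,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path)
  )
  mesh$vertices <- mesh$vertices * unit_scale
  mesh
}

read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(ntri) == 1L && !is.na(ntri) && size == 84 + 50 * as.numeric(ntri) &&
      ntri > 0L) {
    # binary STL
    raw <- readBin(con, "raw", 50L * ntri)
    if (length(raw) < 50L * ntri) stop("format error: truncated binary STL")
    m <- matrix(raw, nrow = 50L)
    tri <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                   n = 12L * ntri, size = 4L, endian = "little")
    tri <- matrix(tri, ncol = 12L, byrow = TRUE)  # normal + 3 vertices
    # per-face vertex order v1,v2,v3
    verts <- matrix(t(cbind(tri[, 4:6], tri[, 7:9], tri[, 10:12])),
                    ncol = 3L, byrow = TRUE)
    soup_to_mesh(verts)
  } else {
    # ASCII STL
    txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) {
      stop("format error: unreadable STL file: ", conditionMessage(e))
    })
    if (length(txt) == 0L || !grepl("^\\s*solid", txt[1])) {
      stop("format error: file is neither valid binary nor ASCII STL")
    }
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("format error: truncated or malformed ASCII STL (",
           length(vl), " vertex lines)")
    }
    if (!any(grepl("^\\s*endsolid", txt))) {
      stop("format error: truncated ASCII STL (missing endsolid)")
    }
    nums <- strsplit(trimws(vl), "\\s+")
    verts <- t(vapply(nums, function(v) as.numeric(v[2:4]), numeric(3)))
    if (anyNA(verts)) stop("format error: non-numeric vertex in ASCII STL")
    soup_to_mesh(verts)
  }
}

# triangle soup (3m x 3 vertex rows, consecutive triples) -> indexed mesh
soup_to_mesh <- function(verts) {
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "_")
  uid <- !duplicated(key)
  vmap <- match(key, key[uid])
  faces <- matrix(vmap, ncol = 3L, byrow = TRUE)
  surface_mesh(verts[uid, , drop = FALSE], faces)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L) {
    stop("format error: OBJ file has no vertices or no faces")
  }
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(v) as.numeric(v[2:4]), numeric(3)))
  if (anyNA(verts)) stop("format error: non-numeric OBJ vertex")
  faces <- list()
  for (fl in strsplit(trimws(flines), "\\s+")) {
    idx <- vapply(fl[-1], function(tok) {
      as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1])
    }, integer(1))
    if (anyNA(idx) || length(idx) < 3L) {
      stop("geometry error: OBJ face with fewer than 3 vertices")
    }
    idx <- ifelse(idx < 0L, nrow(verts) + 1L + idx, idx)  # negative refs
    # deterministic fan triangulation
    for (k in seq_len(length(idx) - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
  }
  surface_mesh(verts, do.call(rbind, faces))
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || txt[1] != "ply") stop("format error: not a PLY file")
  hdr_end <- which(txt == "end_header")[1]
  if (is.na(hdr_end)) stop("format error: PLY header not terminated")
  hdr <- txt[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) {
    stop("format error: only ASCII PLY is supported")
  }
  elems <- grep("^element ", hdr)
  get_count <- function(what) {
    ln <- grep(paste0("^element ", what, " "), hdr, value = TRUE)
    if (length(ln) == 0L) stop("format error: PLY missing element ", what)
    as.integer(strsplit(ln[1], "\\s+")[[1]][3])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  body <- txt[(hdr_end + 1L):length(txt)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("format error: truncated PLY body")
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(v) as.numeric(v[1:3]), numeric(3)))
  faces <- list()
  for (ln in strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")) {
    cnt <- as.integer(ln[1])
    idx <- as.integer(ln[1L + seq_len(cnt)]) + 1L  # PLY is 0-based
    if (anyNA(idx) || cnt < 3L) stop("geometry error: malformed PLY face")
    for (k in seq_len(cnt - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
  }
  surface_mesh(verts, do.call(rbind, faces))
}

#' Write a mesh as ASCII STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param unit_scale Divisor applied to meter coordinates before writing
#'   (1e-3 writes millimeters; default writes meters).
#' @export
write_stl <- function(mesh, path, unit_scale = 1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices / unit_scale
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aeroscatter", con)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  out <- character(7L * nrow(f))
  for (i in seq_len(nrow(f))) {
    j <- 7L * (i - 1L)
    out[j + 1L] <- sprintf("  facet normal %.9e %.9e %.9e",
                           nrm[i, 1], nrm[i, 2], nrm[i, 3])
    out[j + 2L] <- "    outer loop"
    for (k in 1:3) {
      out[j + 2L + k] <- sprintf("      vertex %.9e %.9e %.9e",
                                 v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3])
    }
    out[j + 6L] <- "    endloop"
    out[j + 7L] <- "  endfacet"
  }
  writeLines(out, con)
  writeLines("endsolid aeroscatter", con)
  invisible(path)
}

# Directed-edge pairing: a closed orientable mesh has every directed edge
# appearing exactly once with its reverse also appearing exactly once.
#' Test whether a mesh (or each labeled region of it) is watertight
#'
#' @param mesh A `surface_mesh`.
#' @param by_region If `TRUE` and the mesh has region labels, each region
#'   must be independently closed (the package's multi-component organism
#'   fixtures are unions of closed solids).
#' @return Logical.
#' @export
is_watertight <- function(mesh, by_region = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (by_region && !is.null(mesh$region)) {
    return(all(vapply(unique(mesh$region), function(r) {
      sel <- mesh$region == r
      is_watertight(surface_mesh(mesh$vertices, mesh$faces[sel, , drop = FALSE]))
    }, logical(1))))
  }
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(from, to)
  rkey <- paste(to, from)
  !anyDuplicated(key) && all(rkey %in% key)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Generalized winding number of points with respect to a mesh
#'
#' Sum of signed solid angles over all faces, divided by 4*pi. For a
#' watertight mesh this is 1 for interior points and 0 for exterior points
#' (up to floating error), which makes the even-odd inside test well
#' defined.
#'
#' @param points n x 3 matrix of query points (meters).
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of winding numbers.
#' @export
winding_number <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  points <- matrix(as.numeric(points), ncol = 3L)
  cpp_winding_number(points, mesh$vertices, mesh$faces)
}

#' Voxelize a watertight mesh into a dipole lattice
#'
#' Grid registration: the cell-center grid is centered on the mesh bounding
#' box with pitch `spacing`; when the box span is an integer multiple of
#' the pitch this coincides with "bounding-box minimum + spacing/2". The
#' centered form keeps the lattice exactly mirror-symmetric for symmetric
#' bodies, which the solver exploits.
#'
#' Inclusion rule: a cell belongs to the body iff its center is inside the
#' surface (winding-number test). With `partial = TRUE`, cells cut by the
#' surface are instead assigned a volume-fraction-diluted permittivity
#' (arithmetic mixing with vacuum, fraction estimated on a
#' `subsamples^3` sub-grid); this keeps sub-cell features such as 1-mm wing
#' membranes on lattices coarser than the membrane.
#'
#' @param mesh Watertight `surface_mesh` (each labeled region must be
#'   independently closed).
#' @param spacing Lattice pitch in meters.
#' @param material Material (or name) for unlabeled meshes.
#' @param material_map Named list/character mapping region label ->
#'   material for labeled meshes; earlier entries take precedence where
#'   regions overlap.
#' @param partial Use partial-volume dilution for surface-cut cells.
#' @param subsamples Sub-grid resolution per axis for fraction estimates.
#' @return A `dipole_lattice`.
#' @export
voxelize_mesh <- function(mesh, spacing, material = "bat_effective",
                          material_map = NULL, partial = FALSE,
                          subsamples = 3L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (any(face_areas(mesh) <= 0)) {
    stop("geometry error: mesh has degenerate (zero-area) faces")
  }
  has_regions <- !is.null(mesh$region)
  if (has_regions) {
    if (!is_watertight(mesh, by_region = TRUE)) {
      stop("geometry error: mesh regions are not individually watertight")
    }
  } else if (!is_watertight(mesh)) {
    stop("geometry error: mesh is not watertight")
  }

  bb <- apply(mesh$vertices, 2, range)
  centers <- lapply(1:3, function(ax) {
    grid_axis(bb[1, ax], bb[2, ax], spacing)
  })
  nx <- length(centers[[1]]); ny <- length(centers[[2]]); nz <- length(centers[[3]])
  pts <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]],
                               z = centers[[3]], KEEP.OUT.ATTRS = FALSE))

  if (has_regions) {
    regions <- if (!is.null(material_map)) names(material_map) else unique(mesh$region)
    if (!all(unique(mesh$region) %in% regions)) {
      stop("material_map is missing regions: ",
           paste(setdiff(unique(mesh$region), regions), collapse = ", "))
    }
    submeshes <- lapply(regions, function(r) {
      sel <- mesh$region == r
      surface_mesh(mesh$vertices, mesh$faces[sel, , drop = FALSE])
    })
    names(submeshes) <- regions
  } else {
    regions <- "body"
    submeshes <- list(body = mesh)
    material_map <- stats::setNames(list(material), "body")
  }
  if (is.null(material_map)) {
    material_map <- stats::setNames(rep(list(material), length(regions)), regions)
  }

  assigned <- character(nrow(pts))  # "" = empty
  frac <- numeric(nrow(pts))
  materials <- list()
  for (r in regions) {
    mat_r <- as_material(material_map[[r]])
    sub <- submeshes[[r]]
    inside <- abs(winding_number(pts, sub)) > 0.5
    if (partial) {
      cand <- candidate_cells(pts, spacing, sub) & assigned == ""
      f_r <- numeric(nrow(pts))
      f_r[inside] <- 1
      if (any(cand)) {
        f_r[cand] <- cell_fill_fraction(pts[cand, , drop = FALSE], spacing,
                                        sub, subsamples)
      }
      # quantize so that geometric symmetry survives float jitter
      f_q <- round(f_r * 32) / 32
      take <- assigned == "" & f_q > 0
      full <- take & f_q >= 1
      part <- take & f_q < 1
      assigned[full] <- mat_r$name
      materials[[mat_r$name]] <- mat_r
      for (fv in unique(f_q[part])) {
        id <- sprintf("%s@%.5f", mat_r$name, fv)
        dil <- effective_permittivity(list(mat_r, material(1 + 0i, "vacuum")),
                                      c(fv, 1 - fv), id)
        materials[[id]] <- dil
        assigned[part & f_q == fv] <- id
      }
    } else {
      take <- inside & assigned == ""
      assigned[take] <- mat_r$name
      materials[[mat_r$name]] <- mat_r
    }
  }

  keep <- assigned != ""
  if (!any(keep)) {
    stop("discretization error: spacing ", spacing,
         " m yields no lattice sites inside the mesh")
  }
  dipole_lattice(pts[keep, , drop = FALSE], spacing,
                 material_ids = assigned[keep],
                 materials = materials)
}

# Symmetric grid registration (see voxelize_mesh docs). The cell count
# per axis is rounded up to an even number so that the body mid-planes
# fall exactly between lattice sites: mirror symmetries of the body then
# survive discretization with no site on a mirror plane, which is what
# the parity-reduced solver requires.
grid_axis <- function(lo, hi, d) {
  span <- hi - lo
  n <- max(2L, as.integer(ceiling(span / d - 1e-9)))
  if (n %% 2L == 1L) n <- n + 1L
  mid <- (lo + hi) / 2
  mid + (seq_len(n) - (n + 1) / 2) * d
}

# cells whose cube could be cut by any face of `mesh` (conservative:
# face-bbox vs cell-bbox overlap)
candidate_cells <- function(pts, d, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- logical(nrow(pts))
  half <- d / 2 + 1e-12
  fx <- cbind(pmin(v[f[, 1], 1], v[f[, 2], 1], v[f[, 3], 1]),
              pmax(v[f[, 1], 1], v[f[, 2], 1], v[f[, 3], 1]))
  fy <- cbind(pmin(v[f[, 1], 2], v[f[, 2], 2], v[f[, 3], 2]),
              pmax(v[f[, 1], 2], v[f[, 2], 2], v[f[, 3], 2]))
  fz <- cbind(pmin(v[f[, 1], 3], v[f[, 2], 3], v[f[, 3], 3]),
              pmax(v[f[, 1], 3], v[f[, 2], 3], v[f[, 3], 3]))
  mesh_bb <- rbind(c(min(fx[, 1]), min(fy[, 1]), min(fz[, 1])),
                   c(max(fx[, 2]), max(fy[, 2]), max(fz[, 2])))
  near <- pts[, 1] > mesh_bb[1, 1] - half & pts[, 1] < mesh_bb[2, 1] + half &
          pts[, 2] > mesh_bb[1, 2] - half & pts[, 2] < mesh_bb[2, 2] + half &
          pts[, 3] > mesh_bb[1, 3] - half & pts[, 3] < mesh_bb[2, 3] + half
  idx <- which(near)
  if (length(idx) == 0L) return(out)
  p <- pts[idx, , drop = FALSE]
  hit <- logical(length(idx))
  for (i in seq_len(nrow(f))) {
    hit <- hit | (p[, 1] + half >= fx[i, 1] & p[, 1] - half <= fx[i, 2] &
                  p[, 2] + half >= fy[i, 1] & p[, 2] - half <= fy[i, 2] &
                  p[, 3] + half >= fz[i, 1] & p[, 3] - half <= fz[i, 2])
  }
  out[idx[hit]] <- TRUE
  out
}

cell_fill_fraction <- function(centers, d, mesh, s) {
  s <- max(2L, as.integer(s))
  off <- (seq_len(s) - (s + 1) / 2) / s * d
  sub <- as.matrix(expand.grid(off, off, off))
  nin <- numeric(nrow(centers))
  # evaluate winding on all subpoints of all candidate cells at once
  allpts <- centers[rep(seq_len(nrow(centers)), each = nrow(sub)), , drop = FALSE] +
    sub[rep(seq_len(nrow(sub)), times = nrow(centers)), , drop = FALSE]
  w <- abs(winding_number(allpts, mesh)) > 0.5
  colSums(matrix(w, nrow = nrow(sub))) / nrow(sub)
}
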