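# Shared fixtures and independent oracles used across the suite.

# ---- tiny mesh files, written programmatically -------------------------

# ASCII STL of the unit cube [0,1]^3 (12 facets), optionally truncated.
write_cube_stl <- function(path, truncate = FALSE) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  idx <- function(x, y, z) which(v[, 1] == x & v[, 2] == y & v[, 3] == z)
  quads <- rbind(
    c(idx(0,0,0), idx(0,1,0), idx(1,1,0), idx(1,0,0)),  # z = 0
    c(idx(0,0,1), idx(1,0,1), idx(1,1,1), idx(0,1,1)),  # z = 1
    c(idx(0,0,0), idx(1,0,0), idx(1,0,1), idx(0,0,1)),  # y = 0
    c(idx(0,1,0), idx(0,1,1), idx(1,1,1), idx(1,1,0)),  # y = 1
    c(idx(0,0,0), idx(0,0,1), idx(0,1,1), idx(0,1,0)),  # x = 0
    c(idx(1,0,0), idx(1,1,0), idx(1,1,1), idx(1,0,1))   # x = 1
  )
  lines <- c("solid cube")
  for (q in seq_len(nrow(quads))) {
    for (tri in list(quads[q, c(1, 2, 3)], quads[q, c(1, 3, 4)])) {
      lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %g %g %g",
                         v[tri, 1], v[tri, 2], v[tri, 3]),
                 "    endloop", "  endfacet")
    }
  }
  lines <- c(lines, "endsolid cube")
  if (truncate) lines <- lines[seq_len(floor(length(lines) / 2))]
  writeLines(lines, path)
  path
}

# OBJ with a single quad face (unit square extruded is overkill; a quad
# tests fan triangulation)
write_quad_obj <- function(path) {
  writeLines(c(
    "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "f 1 2 3 4"
  ), path)
  path
}

write_tetra_ply <- function(path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 4",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"
  ), path)
  path
}

# ---- independent electromagnetic oracles -------------------------------

# Closed-form coupled system for a small set of dipoles, written directly
# from the field of an oscillating dipole in the engineering exp(+jwt)
# convention (independent of the package's internal physics-convention
# path). Returns the 3n moments for a unit plane wave.
oracle_dipole_moments <- function(positions, alpha_eng, k, khat, e0) {
  n <- nrow(positions)
  G <- function(rvec) {
    r <- sqrt(sum(rvec^2))
    rh <- rvec / r
    rr <- outer(rh, rh)
    exp(-1i * k * r) * ((k^2 / r) * (diag(3) - rr) +
                          (1 / r^3 + 1i * k / r^2) * (3 * rr - diag(3)))
  }
  A <- matrix(0 + 0i, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      blk <- if (i == j) diag(3) / alpha_eng[i] else
        -G(positions[i, ] - positions[j, ])
      A[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    }
  }
  Einc <- t(vapply(seq_len(n), function(i) {
    e0 * exp(-1i * k * sum(khat * positions[i, ]))
  }, complex(3)))
  matrix(solve(A, as.vector(t(Einc))), ncol = 3, byrow = TRUE)
}

# Mie logarithmic derivative by Lentz continued fraction (independent of
# the package's downward recurrence)
lentz_log_derivative <- function(z, nmax) {
  D <- complex(nmax)
  for (n in seq_len(nmax)) {
    # continued fraction for D_n (Lentz 1976)
    ak <- function(k) {
      s <- if (k %% 2 == 1) 1 else -1
      s * 2 * (n + k - 0.5) / z  # a_k = (-1)^(k+1) 2 (n + k - 1/2) / z
    }
    f <- ak(1); C <- f; Dm <- 0
    for (k in 2:200) {
      a <- ak(k)
      Dm <- a + 1 / Dm
      if (Dm == 0) Dm <- 1e-30
      C <- a + 1 / C
      if (C == 0) C <- 1e-30
      Dm <- 1 / Dm
      delta <- C * Dm
      f <- f * delta
      if (abs(Mod(delta) - 1) < 1e-15) break
    }
    D[n] <- -n / z + f
  }
  D
}

# shared cache for expensive solves reused across acceptance tests
acceptance_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, compute) {
    if (is.null(env[[key]])) env[[key]] <- compute()
    env[[key]]
  }
})

paper_ellipsoid <- function() ellipsoid_spec(0.025, 0.01156, 0.0079)

expect_close <- function(actual, expected, rel = NULL, abs = NULL) {
  if (!is.null(rel)) {
    testthat::expect_lt(max(abs(actual / expected - 1)), rel)
  }
  if (!is.null(abs)) {
    testthat::expect_lt(max(base::abs(actual - expected)), abs)
  }
}

c_mps <- 299792458
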