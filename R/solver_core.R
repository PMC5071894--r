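# Core of the volume-integral method-of-moments (coupled-dipole) solver.
#
# The discretized electric-field volume integral equation reads
#   alpha_i^{-1} p_i - sum_{j != i} G(r_i - r_j) p_j = E_inc(r_i)
# where p_i are dipole moments, alpha_i the cell polarizabilities and G
# the free-space dyadic Green function. Internally the physics time
# convention exp(-iwt) is used; conversions to the package's user-facing
# exp(+jwt) convention happen in the calling layer.
#
# Two solution paths:
#  * "direct": dense assembly + LAPACK zgesv. For lattices symmetric
#    across grid mid-planes the system is block-diagonalized into 2^m
#    parity sectors on a 1/2^m fundamental domain (method of images);
#    one factorization per sector then serves every excitation of a
#    sweep.
#  * "fft": matrix-free Krylov iteration (BiCGSTAB) with the lattice
#    embedded in its bounding grid and the Green convolution applied by
#    3-D FFTs. Used when the dense sector systems would not fit.

# per-site inverse polarizability (physics convention)
lattice_alpha_inv <- function(lattice, k, model = "ldr", ldr_s = 0.2) {
  d <- lattice$spacing
  a_by_id <- vapply(lattice$materials, function(m) {
    a <- alpha_phys(Conj(m$epsilon_r), d, k, model, ldr_s)
    if (a == 0) complex(real = Inf) else 1 / a
  }, complex(1))
  unname(a_by_id[lattice$material_ids])
}

max_mkd <- function(lattice, k) {
  mmax <- max(vapply(lattice$materials,
                     function(m) Mod(refractive_index(m)), numeric(1)))
  mmax * k * lattice$spacing
}

check_discretization <- function(lattice, k) {
  mkd <- max_mkd(lattice, k)
  if (mkd > 1) {
    stop("discretization too coarse: |m| k d = ", signif(mkd, 3),
         " > 1; reduce the lattice spacing")
  }
  if (mkd > 0.5) {
    warning("|m| k d = ", signif(mkd, 3),
            " > 0.5; cross sections may be inaccurate", call. = FALSE)
  }
  mkd
}

# image descriptor for a composition of mirror reflections
# planes: list of list(axis, coordinate); subset: logical selector
compose_image <- function(planes, subset, signs) {
  refl <- c(1, 1, 1)
  off <- c(0, 0, 0)
  sgn <- 1
  for (t in seq_along(planes)) {
    if (!subset[t]) next
    ax <- planes[[t]]$axis
    # reflection about axis=coord composed with current transform
    refl[ax] <- -refl[ax]
    off[ax] <- 2 * planes[[t]]$coordinate - off[ax]
    sgn <- sgn * signs[t]
  }
  list(sign = sgn, refl = refl, offset = off,
       identity = !any(subset))
}

all_subsets <- function(m) {
  if (m == 0L) return(list(logical(0)))
  g <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
}

sign_combos <- function(m) {
  if (m == 0L) return(list(numeric(0)))
  g <- expand.grid(rep(list(c(1, -1)), m))
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}

# incident field of a plane wave at given positions (physics convention)
# e0 may be complex; returns n x 3 complex
incident_field <- function(positions, k, khat, e0) {
  ph <- exp(1i * k * drop(positions %*% khat))
  cbind(e0[1] * ph, e0[2] * ph, e0[3] * ph)
}

# parity-projected incident field on the fundamental domain for sector s:
#   E_s(r) = (1/2^m) sum_T (prod_t s_t) R_T E(M_T r)
projected_incident <- function(positions, k, khat, e0, planes, signs) {
  m <- length(planes)
  subsets <- all_subsets(m)
  acc <- matrix(0 + 0i, nrow(positions), 3L)
  for (sub in subsets) {
    img <- compose_image(planes, sub, signs)
    tpos <- sweep(positions %*% diag(img$refl), 2, -img$offset)
    E <- incident_field(tpos, k, khat, e0)
    acc <- acc + img$sign * sweep(E, 2, img$refl, `*`)
  }
  acc / 2^m
}

# Solve the coupled-dipole system for a set of plane-wave excitations.
#
# lattice    : dipole_lattice
# k          : angular wavenumber (2 pi / lambda)
# excitations: list of list(khat =, e0 =) (e0 complex 3-vector, phys conv)
# planes     : NULL or list of list(axis, coordinate) mirror symmetries of
#              the lattice (no sites on the planes)
# Returns list with:
#   sectors   : for each parity sector, list(signs, domain_idx, x (3nd x ne),
#               images)
#   planes, method, residual (relative, conservative estimate)
dda_solve_system <- function(lattice, k, excitations,
                             tolerance = 1e-5,
                             method = c("auto", "direct", "fft"),
                             planes = NULL,
                             model = "ldr", ldr_s = 0.2,
                             direct_limit = 12000L,
                             max_iter = 2000L,
                             check_residual = FALSE) {
  method <- match.arg(method)
  n <- nrow(lattice$positions)
  alpha_inv <- lattice_alpha_inv(lattice, k, model, ldr_s)

  m <- length(planes)
  if (m > 0L) {
    dom <- rep(TRUE, n)
    for (pl in planes) {
      dom <- dom & lattice$positions[, pl$axis] > pl$coordinate
    }
    if (sum(dom) * 2^m != n) {
      stop("lattice is not an exact union of the fundamental domain and its ",
           "mirror images; cannot use parity reduction")
    }
  } else {
    dom <- rep(TRUE, n)
  }
  nd <- sum(dom)

  if (method == "auto") {
    method <- if (3 * nd <= direct_limit) "direct" else "fft"
    if (method == "fft" && m > 0L) {
      # parity reduction only exists on the dense path
      method <- if (3 * n <= direct_limit) "direct" else "fft"
      if (method == "fft") { m <- 0L; planes <- NULL; dom <- rep(TRUE, n); nd <- n }
    }
  }
  if (method == "fft" && m > 0L) {
    m <- 0L; planes <- NULL; dom <- rep(TRUE, n); nd <- n
  }

  dpos <- lattice$positions[dom, , drop = FALSE]
  dalpha <- alpha_inv[dom]
  ne <- length(excitations)
  sectors <- list()

  if (method == "direct") {
    for (signs in sign_combos(m)) {
      images <- lapply(all_subsets(m), compose_image, planes = planes,
                       signs = signs)
      B <- matrix(0 + 0i, 3L * nd, ne)
      for (e in seq_len(ne)) {
        E <- projected_incident(dpos, k, excitations[[e]]$khat,
                                excitations[[e]]$e0, planes, signs)
        B[, e] <- as.vector(t(E))
      }
      if (max(Mod(B)) < 1e-13) {
        # sector not excited (e.g. axis-aligned incidence): solution is zero
        sectors[[length(sectors) + 1L]] <-
          list(signs = signs, x = B, images = images, residual = 0)
        next
      }
      X <- cpp_dda_solve(dpos, dalpha, k, images, B)
      res <- NA_real_
      if (check_residual) {
        y <- cpp_dda_matvec(dpos, dalpha, k, images, X[, 1L])
        res <- sqrt(sum(Mod(y - B[, 1L])^2) / max(sum(Mod(B[, 1L])^2), 1e-300))
      }
      sectors[[length(sectors) + 1L]] <-
        list(signs = signs, x = X, images = images, residual = res)
    }
  } else {
    op <- fft_dda_operator(lattice, alpha_inv, k)
    X <- matrix(0 + 0i, 3L * n, ne)
    res <- numeric(ne)
    for (e in seq_len(ne)) {
      E <- incident_field(lattice$positions, k, excitations[[e]]$khat,
                          excitations[[e]]$e0)
      b <- as.vector(t(E))
      sol <- bicgstab(op, b, tol = tolerance, max_iter = max_iter,
                      x0 = as.vector(t(E / alpha_inv)))
      if (!sol$converged) {
        stop("convergence error: iterative solver stalled at relative ",
             "residual ", signif(sol$residual, 3), " after ", sol$iterations,
             " iterations (tolerance ", tolerance, ")")
      }
      X[, e] <- sol$x
      res[e] <- sol$residual
    }
    sectors[[1L]] <- list(signs = numeric(0), x = X,
                          images = list(compose_image(list(), logical(0),
                                                      numeric(0))),
                          residual = max(res))
  }

  list(sectors = sectors, planes = planes, method = method,
       domain = which(dom), lattice = lattice, k = k,
       residual = suppressWarnings(max(unlist(lapply(sectors,
                                                     `[[`, "residual")),
                                       na.rm = TRUE)))
}

# Far-field scattering amplitude F(nhat) for excitation column e:
#   F = k^2 (I - nn) sum_images sign R_T sum_j p_j e^{-ik n.(M_T r_j)}
# sigma(nhat) = 4 pi |F|^2 for unit incident amplitude.
farfield_from_system <- function(sys, e, nhat) {
  k <- sys$k
  dpos <- sys$lattice$positions[sys$domain, , drop = FALSE]
  Fv <- c(0 + 0i, 0, 0)
  for (sec in sys$sectors) {
    X <- matrix(sec$x[, e], ncol = 3L, byrow = TRUE)  # nd x 3
    for (img in sec$images) {
      tpos <- sweep(dpos %*% diag(img$refl), 2, -img$offset)
      ph <- exp(-1i * k * drop(tpos %*% nhat))
      s <- colSums(X * ph)              # sum_j p_j phase (then reflect)
      Fv <- Fv + img$sign * (img$refl * s)
    }
  }
  Fv <- k^2 * Fv
  Fv - nhat * sum(nhat * Fv)
}

# Reconstruct full-lattice moments (nd -> n) for excitation column e.
moments_from_system <- function(sys, e) {
  lat <- sys$lattice
  n <- nrow(lat$positions)
  dpos <- lat$positions[sys$domain, , drop = FALSE]
  d <- lat$spacing
  ref <- apply(lat$positions, 2, min)
  key_all <- apply(round(sweep(lat$positions, 2, ref) / d), 1, paste,
                   collapse = ",")
  P <- matrix(0 + 0i, n, 3L)
  imgs <- sys$sectors[[1L]]$images
  for (ii in seq_along(imgs)) {
    img0 <- imgs[[ii]]
    tpos <- sweep(dpos %*% diag(img0$refl), 2, -img0$offset)
    key_t <- apply(round(sweep(tpos, 2, ref) / d), 1, paste, collapse = ",")
    rows <- match(key_t, key_all)
    if (anyNA(rows)) stop("internal error: image sites not found in lattice")
    acc <- matrix(0 + 0i, nrow(dpos), 3L)
    for (sec in sys$sectors) {
      Xs <- matrix(sec$x[, e], ncol = 3L, byrow = TRUE)
      # parity weight of this image within sector `sec`
      img <- compose_image(sys$planes, attr_subset(imgs, ii), sec$signs)
      acc <- acc + img$sign * sweep(Xs, 2, img$refl, `*`)
    }
    P[rows, ] <- acc
  }
  P
}

# subset selector corresponding to the ii-th image in the all_subsets order
attr_subset <- function(imgs, ii) {
  m <- length(imgs)
  nplanes <- as.integer(round(log2(m)))
  if (nplanes == 0L) return(logical(0))
  all_subsets(nplanes)[[ii]]
}
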