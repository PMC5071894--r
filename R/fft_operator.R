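# Matrix-free application of the coupled-dipole system matrix by 3-D FFT
# convolution, plus a BiCGSTAB Krylov driver. Used for lattices whose
# dense (sector) systems would be too large to factorize.

# Build the FFT operator for a lattice. Returns a function(x) -> A x where
# x is the 3n interleaved moment vector (site-major: x1,y1,z1,x2,...).
fft_dda_operator <- function(lattice, alpha_inv, k) {
  d <- lattice$spacing
  idx <- lattice_grid_index(lattice)
  dims <- apply(idx, 2, max) + 1L
  pad <- vapply(dims, function(n) stats::nextn(2L * n, c(2, 3, 5)), integer(1))
  # linear indices of occupied cells in the padded grid
  lin <- 1L + idx[, 1] + pad[1] * (idx[, 2] + pad[2] * idx[, 3])

  # lag coordinates along each padded axis (wrapped to negative beyond n)
  lag1 <- ifelse(seq_len(pad[1]) - 1L > pad[1] / 2,
                 seq_len(pad[1]) - 1L - pad[1], seq_len(pad[1]) - 1L) * d
  lag2 <- ifelse(seq_len(pad[2]) - 1L > pad[2] / 2,
                 seq_len(pad[2]) - 1L - pad[2], seq_len(pad[2]) - 1L) * d
  lag3 <- ifelse(seq_len(pad[3]) - 1L > pad[3] / 2,
                 seq_len(pad[3]) - 1L - pad[3], seq_len(pad[3]) - 1L) * d
  LX <- array(lag1, dim = pad)
  LY <- array(rep(lag2, each = pad[1]), dim = pad)
  LZ <- array(rep(lag3, each = pad[1] * pad[2]), dim = pad)
  R2 <- LX^2 + LY^2 + LZ^2
  R <- sqrt(R2)
  R[1] <- 1  # lag 0 placeholder; zeroed below
  eikr <- exp(1i * k * R)
  A1 <- eikr * k^2 / R
  A2 <- eikr * (1 / R^3 - 1i * k / R2)
  comp <- function(La, Lb, same) {
    rr <- (La / R) * (Lb / R)
    G <- A1 * ((if (same) 1 else 0) - rr) + A2 * (3 * rr - (if (same) 1 else 0))
    G[1] <- 0  # no self term
    fft(G)
  }
  Gx <- list(xx = comp(LX, LX, TRUE), xy = comp(LX, LY, FALSE),
             xz = comp(LX, LZ, FALSE), yy = comp(LY, LY, TRUE),
             yz = comp(LY, LZ, FALSE), zz = comp(LZ, LZ, TRUE))
  rm(LX, LY, LZ, R2, R, eikr, A1, A2)

  npad <- prod(pad)
  function(x) {
    P <- matrix(x, ncol = 3L, byrow = TRUE)
    Fx <- array(0 + 0i, dim = pad); Fx[lin] <- P[, 1]; Fx <- fft(Fx)
    Fy <- array(0 + 0i, dim = pad); Fy[lin] <- P[, 2]; Fy <- fft(Fy)
    Fz <- array(0 + 0i, dim = pad); Fz[lin] <- P[, 3]; Fz <- fft(Fz)
    Ex <- fft(Gx$xx * Fx + Gx$xy * Fy + Gx$xz * Fz, inverse = TRUE)[lin] / npad
    Ey <- fft(Gx$xy * Fx + Gx$yy * Fy + Gx$yz * Fz, inverse = TRUE)[lin] / npad
    Ez <- fft(Gx$xz * Fx + Gx$yz * Fy + Gx$zz * Fz, inverse = TRUE)[lin] / npad
    out <- P * alpha_inv - cbind(Ex, Ey, Ez)
    as.vector(t(out))
  }
}

# BiCGSTAB for a general complex operator, relative-residual stopping rule.
bicgstab <- function(op, b, tol = 1e-5, max_iter = 2000L, x0 = NULL) {
  cdot <- function(u, v) sum(Conj(u) * v)
  nb <- sqrt(Re(cdot(b, b)))
  if (nb == 0) return(list(x = b * 0, converged = TRUE, iterations = 0L,
                           residual = 0))
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - op(x)
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- r * 0
  best <- list(x = x, res = sqrt(Re(cdot(r, r))) / nb)
  for (it in seq_len(max_iter)) {
    rho1 <- cdot(rhat, r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- op(p)
    alpha <- rho / cdot(rhat, v)
    s <- r - alpha * v
    t <- op(s)
    tt <- Re(cdot(t, t))
    omega <- if (tt > 0) cdot(t, s) / tt else 0 + 0i
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    res <- sqrt(Re(cdot(r, r))) / nb
    if (res < best$res) best <- list(x = x, res = res)
    if (res < tol) {
      return(list(x = x, converged = TRUE, iterations = it, residual = res))
    }
  }
  list(x = best$x, converged = best$res < tol, iterations = max_iter,
       residual = best$res)
}
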