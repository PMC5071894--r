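// Numerical kernels: coupled-dipole interaction matrix assembly (with
// mirror-image terms for the parity-reduced solver), an in-place dense
// solve via LAPACK zgesv, an on-the-fly matrix-vector product for
// residual checks, and the generalized winding number for voxelization.
//
// Convention inside these kernels: physics time factor exp(-i w t),
// Green factor exp(+i k r).  The R layer conjugates at the user boundary.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Field at displacement rvec of a unit dipole:  G(r) p  with
// G = e^{ikr} [ (k^2/r)(I - rr) + (1/r^3 - ik/r^2)(3 rr - I) ].
// Writes the 3x3 matrix into G[9] (column-major).
static inline void green_tensor(const double rvec[3], double k, cplx G[9]) {
  double r2 = rvec[0] * rvec[0] + rvec[1] * rvec[1] + rvec[2] * rvec[2];
  double r = std::sqrt(r2);
  double rh[3] = {rvec[0] / r, rvec[1] / r, rvec[2] / r};
  cplx eikr = std::polar(1.0, k * r);
  cplx A1 = eikr * (k * k / r);
  cplx A2 = eikr * (cplx(1.0, 0.0) / (r2 * r) - cplx(0.0, k) / r2);
  for (int b = 0; b < 3; ++b) {
    for (int a = 0; a < 3; ++a) {
      double rr = rh[a] * rh[b];
      double del = (a == b) ? 1.0 : 0.0;
      G[a + 3 * b] = A1 * (del - rr) + A2 * (3.0 * rr - del);
    }
  }
}

// Build the (possibly parity-reduced) coupled-dipole system matrix
//   A[3i+a, 3j+b] = delta_ij delta_ab / alpha_i
//                   - sum_images sign * G_ab(r_i - T r_j) * refl_b
// and solve A X = B in place (B is overwritten with the solution).
// images: list of list(sign, refl (len 3, +-1), offset (len 3),
//                      identity (bool; skip the i == j self term)).
// [[Rcpp::export]]
ComplexMatrix cpp_dda_solve(NumericMatrix pos, ComplexVector alpha_inv,
                            double k, List images, ComplexMatrix B) {
  const int n = pos.nrow();
  const int N = 3 * n;
  if (B.nrow() != N) stop("RHS has wrong row count");
  const double self_tol = 1e-12;

  std::vector<cplx> A((size_t)N * N, cplx(0.0, 0.0));
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
  }

  for (int im = 0; im < images.size(); ++im) {
    List img = images[im];
    double sign = as<double>(img["sign"]);
    NumericVector refl = img["refl"];
    NumericVector off = img["offset"];
    bool identity = as<bool>(img["identity"]);
    for (int j = 0; j < n; ++j) {
      double tj[3] = {refl[0] * px[j] + off[0],
                      refl[1] * py[j] + off[1],
                      refl[2] * pz[j] + off[2]};
      size_t col0 = (size_t)(3 * j) * N;
      for (int i = 0; i < n; ++i) {
        double rvec[3] = {px[i] - tj[0], py[i] - tj[1], pz[i] - tj[2]};
        double r2 = rvec[0] * rvec[0] + rvec[1] * rvec[1] + rvec[2] * rvec[2];
        if (identity && i == j) continue;
        if (r2 < self_tol) continue;  // image coincides with source site
        cplx G[9];
        green_tensor(rvec, k, G);
        for (int b = 0; b < 3; ++b) {
          cplx s = sign * refl[b];
          size_t col = col0 + (size_t)b * N + 3 * i;
          A[col + 0] -= s * G[0 + 3 * b];
          A[col + 1] -= s * G[1 + 3 * b];
          A[col + 2] -= s * G[2 + 3 * b];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  const cplx *ai = reinterpret_cast<const cplx *>(COMPLEX(alpha_inv));
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) {
      size_t d = (size_t)(3 * i + a);
      A[d * N + d] += ai[i];
    }
  }

  // in-place zgesv on a copy-free view of B's memory
  ComplexMatrix X(clone(B));
  int nrhs = X.ncol(), info = 0;
  std::vector<int> ipiv(N);
  F77_CALL(zgesv)(&N, &nrhs, reinterpret_cast<Rcomplex *>(A.data()), &N,
                  ipiv.data(), reinterpret_cast<Rcomplex *>(COMPLEX(X)), &N,
                  &info);
  if (info != 0) stop("zgesv failed with info = %d", info);
  return X;
}

// On-the-fly product y = A x of the same system matrix (for residual and
// energy checks without storing A).
// [[Rcpp::export]]
ComplexVector cpp_dda_matvec(NumericMatrix pos, ComplexVector alpha_inv,
                             double k, List images, ComplexVector x) {
  const int n = pos.nrow();
  const int N = 3 * n;
  if (x.size() != N) stop("x has wrong length");
  const double self_tol = 1e-12;
  const cplx *xv = reinterpret_cast<const cplx *>(COMPLEX(x));
  const cplx *ai = reinterpret_cast<const cplx *>(COMPLEX(alpha_inv));
  ComplexVector yout(N);
  cplx *y = reinterpret_cast<cplx *>(COMPLEX(yout));
  for (int i = 0; i < N; ++i) y[i] = 0.0;

  for (int im = 0; im < images.size(); ++im) {
    List img = images[im];
    double sign = as<double>(img["sign"]);
    NumericVector refl = img["refl"];
    NumericVector off = img["offset"];
    bool identity = as<bool>(img["identity"]);
    for (int j = 0; j < n; ++j) {
      double tj[3] = {refl[0] * pos(j, 0) + off[0],
                      refl[1] * pos(j, 1) + off[1],
                      refl[2] * pos(j, 2) + off[2]};
      cplx pj[3] = {sign * refl[0] * xv[3 * j],
                    sign * refl[1] * xv[3 * j + 1],
                    sign * refl[2] * xv[3 * j + 2]};
      for (int i = 0; i < n; ++i) {
        if (identity && i == j) continue;
        double rvec[3] = {pos(i, 0) - tj[0], pos(i, 1) - tj[1],
                          pos(i, 2) - tj[2]};
        double r2 = rvec[0] * rvec[0] + rvec[1] * rvec[1] + rvec[2] * rvec[2];
        if (r2 < self_tol) continue;
        cplx G[9];
        green_tensor(rvec, k, G);
        for (int a = 0; a < 3; ++a) {
          y[3 * i + a] -= G[a + 0] * pj[0] + G[a + 3] * pj[1] + G[a + 6] * pj[2];
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) y[3 * i + a] += ai[i] * xv[3 * i + a];
  }
  return yout;
}

// Generalized winding number (sum of signed solid angles / 4 pi),
// van Oosterom-Strackee formula per triangle.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points, NumericMatrix vertices,
                                 IntegerMatrix faces) {
  const int np = points.nrow();
  const int nf = faces.nrow();
  NumericVector w(np);
  for (int f = 0; f < nf; ++f) {
    int i1 = faces(f, 0) - 1, i2 = faces(f, 1) - 1, i3 = faces(f, 2) - 1;
    double A[3] = {vertices(i1, 0), vertices(i1, 1), vertices(i1, 2)};
    double Bv[3] = {vertices(i2, 0), vertices(i2, 1), vertices(i2, 2)};
    double C[3] = {vertices(i3, 0), vertices(i3, 1), vertices(i3, 2)};
    for (int p = 0; p < np; ++p) {
      double a[3] = {A[0] - points(p, 0), A[1] - points(p, 1), A[2] - points(p, 2)};
      double b[3] = {Bv[0] - points(p, 0), Bv[1] - points(p, 1), Bv[2] - points(p, 2)};
      double c[3] = {C[0] - points(p, 0), C[1] - points(p, 1), C[2] - points(p, 2)};
      double la = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
      double lb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
      double lc = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
      double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                   a[1] * (b[0] * c[2] - b[2] * c[0]) +
                   a[2] * (b[0] * c[1] - b[1] * c[0]);
      double ab = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
      double bc = b[0] * c[0] + b[1] * c[1] + b[2] * c[2];
      double ca = c[0] * a[0] + c[1] * a[1] + c[2] * a[2];
      double denom = la * lb * lc + ab * lc + bc * la + ca * lb;
      w[p] += 2.0 * std::atan2(det, denom);
    }
  }
  for (int p = 0; p < np; ++p) w[p] /= (4.0 * M_PI);
  return w;
}
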