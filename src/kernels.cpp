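// Hot kernels of the ADMM solver: forward-difference operators with
// replicate (Neumann) boundaries, their exact adjoints, and the fused
// regularizer-split update. Arrays are R 3D arrays dim = (nz, ny, nx),
// column-major: index = iz + nz * (iy + ny * ix).
//
// For axis a with element stride s (1, nz or nz*ny) the axis coordinate of
// flat index i is (i mod L) / s with L = s * alen, so the boundary cases
// are contiguous runs within blocks of length L and the loops below stay
// flat and sequential.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void axis_geom(const IntegerVector& dims, const int axis,
                             R_xlen_t& s, R_xlen_t& L) {
  const R_xlen_t nz = dims[0], ny = dims[1];
  s = (axis == 0) ? 1 : (axis == 1 ? nz : nz * ny);
  const R_xlen_t alen = (axis == 0) ? nz : (axis == 1 ? ny : dims[2]);
  L = s * alen;
}

// forward difference along axis (0 = z, 1 = y, 2 = x); last plane is 0
// [[Rcpp::export]]
NumericVector cpp_fdiff(const NumericVector& x, const IntegerVector& dims,
                        const int axis) {
  const R_xlen_t n = x.size();
  NumericVector out(no_init(n));
  R_xlen_t s, L;
  axis_geom(dims, axis, s, L);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (R_xlen_t b = 0; b < n; b += L) {
    const R_xlen_t m = L - s;
    for (R_xlen_t j = 0; j < m; ++j) po[b + j] = px[b + j + s] - px[b + j];
    for (R_xlen_t j = m; j < L; ++j) po[b + j] = 0.0;
  }
  return out;
}

// exact transpose of cpp_fdiff:
// pos = 0: -y ; 0 < pos < alen-1: y[i-s] - y[i] ; pos = alen-1: y[i-s]
// [[Rcpp::export]]
NumericVector cpp_fdiff_adj(const NumericVector& y, const IntegerVector& dims,
                            const int axis) {
  const R_xlen_t n = y.size();
  NumericVector out(no_init(n));
  R_xlen_t s, L;
  axis_geom(dims, axis, s, L);
  const double* py = REAL(y);
  double* po = REAL(out);
  for (R_xlen_t b = 0; b < n; b += L) {
    if (L == s) {  // singleton axis: operator is identically zero
      for (R_xlen_t j = 0; j < L; ++j) po[b + j] = 0.0;
      continue;
    }
    for (R_xlen_t j = 0; j < s; ++j) po[b + j] = -py[b + j];
    for (R_xlen_t j = s; j < L - s; ++j)
      po[b + j] = py[b + j - s] - py[b + j];
    for (R_xlen_t j = L - s; j < L; ++j) po[b + j] = py[b + j - s];
  }
  return out;
}

// fused z2/u2 update of the proximal regularizer split: given the operator
// field Hx, dual U2 and previous Z2, computes the group soft-threshold
// Z2new = shrink(Hx + U2, tau), U2new = U2 + Hx - Z2new, and the scalars
//   dz2 = sum (Z2new - Z2old)^2, pri2 = sum (Hx - Z2new)^2,
//   pen = sum_j ||Hx_j|| (the regularizer value at x, unweighted).
// [[Rcpp::export]]
List cpp_reg_update(const List& Hx, const List& U2, const List& Z2old,
                    const double tau) {
  const int K = Hx.size();
  std::vector<const double*> h(K), u(K), zo(K);
  std::vector<double*> z(K), un(K);
  R_xlen_t n = 0;
  List Z2(K), U2n(K);
  for (int k = 0; k < K; ++k) {
    NumericVector hk = Hx[k];
    n = hk.size();
    NumericVector zk(no_init(n)), uk(no_init(n));
    zk.attr("dim") = hk.attr("dim");
    uk.attr("dim") = hk.attr("dim");
    Z2[k] = zk; U2n[k] = uk;
  }
  for (int k = 0; k < K; ++k) {
    h[k] = REAL((SEXP)Hx[k]); u[k] = REAL((SEXP)U2[k]);
    zo[k] = REAL((SEXP)Z2old[k]);
    z[k] = REAL((SEXP)Z2[k]); un[k] = REAL((SEXP)U2n[k]);
  }
  std::vector<double> nrm2(n, 0.0), hn2(n, 0.0), sc(n);
  for (int k = 0; k < K; ++k) {
    const double* hk = h[k];
    const double* uk = u[k];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = hk[i] + uk[i];
      nrm2[i] += v * v;
      hn2[i] += hk[i] * hk[i];
    }
  }
  double pen = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    pen += std::sqrt(hn2[i]);
    const double nrm = std::sqrt(nrm2[i]);
    sc[i] = (nrm > tau) ? (1.0 - tau / nrm) : 0.0;
  }
  double dz2 = 0.0, pri2 = 0.0;
  for (int k = 0; k < K; ++k) {
    const double* hk = h[k];
    const double* uk = u[k];
    const double* zok = zo[k];
    double* zk = z[k];
    double* unk = un[k];
    double a1 = 0.0, a2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = hk[i] + uk[i];
      const double zv = sc[i] * v;
      zk[i] = zv;
      unk[i] = v - zv;  // = u + h - z
      const double dz = zv - zok[i];
      a1 += dz * dz;
      const double pr = hk[i] - zv;
      a2 += pr * pr;
    }
    dz2 += a1; pri2 += a2;
  }
  Z2.attr("names") = Hx.attr("names");
  U2n.attr("names") = Hx.attr("names");
  return List::create(_["Z2"] = Z2, _["U2"] = U2n, _["dz2"] = dz2,
                      _["pri2"] = pri2, _["pen"] = pen);
}

// elementwise A - B over matching lists (difference field for the adjoint)
// [[Rcpp::export]]
List cpp_list_diff(const List& A, const List& B) {
  const int K = A.size();
  List out(K);
  for (int k = 0; k < K; ++k) {
    NumericVector a = A[k], b = B[k];
    const R_xlen_t n = a.size();
    NumericVector d(no_init(n));
    const double* pa = REAL(a);
    const double* pb = REAL(b);
    double* pd = REAL(d);
    for (R_xlen_t i = 0; i < n; ++i) pd[i] = pa[i] - pb[i];
    d.attr("dim") = a.attr("dim");
    out[k] = d;
  }
  out.attr("names") = A.attr("names");
  return out;
}
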