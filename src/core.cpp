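// Low-level numerical primitives: separable convolution with mirror
// boundary, per-voxel symmetric 3x3 eigendecomposition, and exact
// Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope, applied per axis).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect index into [0, n) with half-sample symmetry: -1 -> 0, n -> n-1
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Convolve a 3-D array (R dim = c(n1, n2, n3), column-major) with a 1-D
// kernel along `axis` (1-based). Kernel is applied in correlation
// orientation with an odd length 2r+1 centered at r.
// [[Rcpp::export(name = ".conv3_axis")]]
NumericVector conv3_axis(NumericVector vol, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  if (vol.size() != ntot) stop("volume length does not match dim");
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = (klen - 1) / 2;
  NumericVector out(ntot);

  int nline, stride, nouter1, nouter2;
  // strides for column-major layout
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  R_xlen_t line_stride, o1_stride, o2_stride;
  if (axis == 1) {
    nline = n1; line_stride = s1; nouter1 = n2; o1_stride = s2;
    nouter2 = n3; o2_stride = s3;
  } else if (axis == 2) {
    nline = n2; line_stride = s2; nouter1 = n1; o1_stride = s1;
    nouter2 = n3; o2_stride = s3;
  } else if (axis == 3) {
    nline = n3; line_stride = s3; nouter1 = n1; o1_stride = s1;
    nouter2 = n2; o2_stride = s2;
  } else {
    stop("axis must be 1, 2 or 3");
  }

  const double *v = vol.begin();
  const double *k = kernel.begin();
  double *o = out.begin();
  std::vector<double> line(nline);

  for (int b = 0; b < nouter2; ++b) {
    for (int a = 0; a < nouter1; ++a) {
      const R_xlen_t base = a * o1_stride + b * o2_stride;
      for (int i = 0; i < nline; ++i)
        line[i] = v[base + i * line_stride];
      for (int i = 0; i < nline; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += k[j + r] * line[reflect_index(i + j, nline)];
        o[base + i * line_stride] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Eigendecomposition of per-voxel symmetric 3x3 tensors given as 6
// component vectors (11, 12, 13, 22, 23, 33). Returns eigenvalues
// sorted descending (l1 >= l2 >= l3) and the eigenvector of the
// smallest eigenvalue, sign-canonicalized so its largest-magnitude
// component is positive. Voxels with any non-finite component yield NaN.
// [[Rcpp::export(name = ".eig3_smallest")]]
List eig3_smallest(NumericVector t11, NumericVector t12, NumericVector t13,
                   NumericVector t22, NumericVector t23, NumericVector t33) {
  const R_xlen_t n = t11.size();
  NumericVector l1(n), l2(n), l3(n), v1(n), v2(n), v3(n);
  arma::mat33 T;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a11 = t11[i], a12 = t12[i], a13 = t13[i];
    const double a22 = t22[i], a23 = t23[i], a33 = t33[i];
    if (!std::isfinite(a11) || !std::isfinite(a12) || !std::isfinite(a13) ||
        !std::isfinite(a22) || !std::isfinite(a23) || !std::isfinite(a33)) {
      l1[i] = l2[i] = l3[i] = v1[i] = v2[i] = v3[i] = NA_REAL;
      continue;
    }
    T(0,0) = a11; T(0,1) = a12; T(0,2) = a13;
    T(1,0) = a12; T(1,1) = a22; T(1,2) = a23;
    T(2,0) = a13; T(2,1) = a23; T(2,2) = a33;
    arma::eig_sym(eval, evec, T);  // ascending
    l1[i] = eval(2); l2[i] = eval(1); l3[i] = eval(0);
    double x = evec(0,0), y = evec(1,0), z = evec(2,0);
    const double ax = std::fabs(x), ay = std::fabs(y), az = std::fabs(z);
    double lead = x;
    if (ay > ax && ay >= az) lead = y;
    else if (az > ax && az > ay) lead = z;
    if (lead < 0) { x = -x; y = -y; z = -z; }
    v1[i] = x; v2[i] = y; v3[i] = z;
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["e3_1"] = v1, _["e3_2"] = v2, _["e3_3"] = v3);
}

// 1-D squared distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = (double)(q - p) * (q - p) + f[p];
  }
}

// Exact Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `feature` (R dim = c(n1, n2, n3)). Infinite when the
// feature set is empty.
// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(LogicalVector feature, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  if (feature.size() != ntot) stop("feature length does not match dim");
  // large finite sentinel instead of Inf so the lower-envelope
  // intersection formula stays well defined on feature-free lines
  const double INF = 1e15;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = feature[i] ? 0.0 : INF;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  // axis 1
  for (int c = 0; c < n3; ++c)
    for (int b = 0; b < n2; ++b) {
      const R_xlen_t base = b * s2 + c * s3;
      for (int i = 0; i < n1; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) g[base + i] = d[i];
    }
  // axis 2
  for (int c = 0; c < n3; ++c)
    for (int a = 0; a < n1; ++a) {
      const R_xlen_t base = a + c * s3;
      for (int i = 0; i < n2; ++i) f[i] = g[base + i * s2];
      dt1d(f, d, v, z, n2);
      for (int i = 0; i < n2; ++i) g[base + i * s2] = d[i];
    }
  // axis 3
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      const R_xlen_t base = a + b * s2;
      for (int i = 0; i < n3; ++i) f[i] = g[base + i * s3];
      dt1d(f, d, v, z, n3);
      for (int i = 0; i < n3; ++i) g[base + i * s3] = d[i];
    }

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = (g[i] >= 1e12)
      ? std::numeric_limits<double>::infinity() : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
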