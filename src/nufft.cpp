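// Gridding kernels for the nonuniform Fourier transform.
//
// Spreading (type-1 / adjoint) and interpolation (type-2 / forward) of
// complex samples between arbitrary k-space positions and an oversampled
// Cartesian grid, using a Kaiser-Bessel window. The FFT itself and the
// deapodization are done in R; only the O(n * W^3) scatter/gather loops
// live here.

#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>

using namespace Rcpp;

// modified Bessel function I0 by its power series; converges to double
// precision for the argument range used by gridding kernels (beta < 40)
static double bessel_i0(double x) {
  double t = x * x / 4.0;
  double term = 1.0, sum = 1.0;
  for (int k = 1; k < 1000; ++k) {
    term *= t / (double(k) * double(k));
    sum += term;
    if (term < sum * 1e-18) break;
  }
  return sum;
}

// Kaiser-Bessel kernel on [-W/2, W/2], normalised to psi(0) = 1
static inline double kb_kernel(double d, double half_w, double beta,
                               double i0_beta) {
  double r = 1.0 - (d / half_w) * (d / half_w);
  if (r < 0.0) return 0.0;
  return bessel_i0(beta * std::sqrt(r)) / i0_beta;
}

static inline int wrap_index(int i, int n) {
  int m = i % n;
  return (m < 0) ? m + n : m;
}

// Per-point axis weights: the W consecutive integer grid lines covering
// [u - W/2, u + W/2] and their kernel values.
struct AxisSupport {
  int first;                 // first (unwrapped) integer index
  std::vector<double> w;     // kernel weights, length W
};

static void axis_support(double u, int W, double beta, double i0_beta,
                         AxisSupport &out) {
  double half_w = W / 2.0;
  int first = (int)std::ceil(u - half_w);
  // ceil can land exactly on u - W/2 when u is half-integral; the kernel is
  // zero there, which is harmless
  out.first = first;
  out.w.resize(W);
  for (int j = 0; j < W; ++j)
    out.w[j] = kb_kernel((double)(first + j) - u, half_w, beta, i0_beta);
}

// [[Rcpp::export(name = ".nufft_spread3")]]
ComplexVector nufft_spread3(NumericMatrix u, ComplexVector values,
                            IntegerVector nos, int W, double beta) {
  int n = u.nrow();
  int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  double i0b = bessel_i0(beta);
  std::vector<std::complex<double> > grid((size_t)n1 * n2 * n3,
                                          std::complex<double>(0.0, 0.0));
  AxisSupport sx, sy, sz;
  for (int p = 0; p < n; ++p) {
    axis_support(u(p, 0), W, beta, i0b, sx);
    axis_support(u(p, 1), W, beta, i0b, sy);
    axis_support(u(p, 2), W, beta, i0b, sz);
    std::complex<double> v(values[p].r, values[p].i);
    for (int c = 0; c < W; ++c) {
      double wz = sz.w[c];
      if (wz == 0.0) continue;
      size_t off3 = (size_t)wrap_index(sz.first + c, n3) * n1 * n2;
      for (int b = 0; b < W; ++b) {
        double wyz = sy.w[b] * wz;
        if (wyz == 0.0) continue;
        size_t off2 = off3 + (size_t)wrap_index(sy.first + b, n2) * n1;
        for (int a = 0; a < W; ++a) {
          double w = sx.w[a] * wyz;
          if (w == 0.0) continue;
          grid[off2 + wrap_index(sx.first + a, n1)] += v * w;
        }
      }
    }
  }
  ComplexVector out((size_t)n1 * n2 * n3);
  for (size_t i = 0; i < grid.size(); ++i) {
    out[i].r = grid[i].real();
    out[i].i = grid[i].imag();
  }
  out.attr("dim") = nos;
  return out;
}

// [[Rcpp::export(name = ".nufft_interp3")]]
ComplexVector nufft_interp3(ComplexVector grid, IntegerVector nos,
                            NumericMatrix u, int W, double beta) {
  int n = u.nrow();
  int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  double i0b = bessel_i0(beta);
  ComplexVector out(n);
  AxisSupport sx, sy, sz;
  for (int p = 0; p < n; ++p) {
    axis_support(u(p, 0), W, beta, i0b, sx);
    axis_support(u(p, 1), W, beta, i0b, sy);
    axis_support(u(p, 2), W, beta, i0b, sz);
    std::complex<double> acc(0.0, 0.0);
    for (int c = 0; c < W; ++c) {
      double wz = sz.w[c];
      if (wz == 0.0) continue;
      size_t off3 = (size_t)wrap_index(sz.first + c, n3) * n1 * n2;
      for (int b = 0; b < W; ++b) {
        double wyz = sy.w[b] * wz;
        if (wyz == 0.0) continue;
        size_t off2 = off3 + (size_t)wrap_index(sy.first + b, n2) * n1;
        for (int a = 0; a < W; ++a) {
          double w = sx.w[a] * wyz;
          if (w == 0.0) continue;
          size_t idx = off2 + wrap_index(sx.first + a, n1);
          acc += std::complex<double>(grid[idx].r, grid[idx].i) * w;
        }
      }
    }
    out[p].r = acc.real();
    out[p].i = acc.imag();
  }
  return out;
}
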