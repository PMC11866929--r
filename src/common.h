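#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// branch-based variant for coordinates already wrapped into [0, L)
// (|d| < L guaranteed); much cheaper than nearbyint in hot loops
inline double min_image_wrapped(double d, double L, double halfL) {
  if (d > halfL) return d - L;
  if (d < -halfL) return d + L;
  return d;
}

// Rectangular kernel of width delta centred at r, integrated over the two
// bins it overlaps.  b1 is the bin containing r, b2 the neighbour the
// kernel spills into (-1 if it falls off the grid; that mass is dropped).
// s is the sign of (r - bin centre): the kernel crosses a bin boundary at
// r + s*delta/2, so d f_b1/dr = -s/delta and d f_b2/dr = +s/delta.
struct KernelSplit {
  int b1, b2;
  double f1, f2;
  double s;
};

struct LJPair {
  double e, dedr;
};

inline LJPair lj_pair(double r, double eps, double sig) {
  const double sr = sig / r;
  const double sr6 = sr * sr * sr * sr * sr * sr;
  const double sr12 = sr6 * sr6;
  LJPair out;
  out.e = 4.0 * eps * (sr12 - sr6);
  out.dedr = -4.0 * eps * (12.0 * sr12 - 6.0 * sr6) / r;
  return out;
}

// The kernel is accepted while any part of it overlaps the grid,
// i.e. r in [r_lo - delta/2, r_lo + B*delta + delta/2); fractions falling
// outside the grid are dropped (b1/b2 set to -1) but the in-grid part
// still counts, so every interior *and* edge bin keeps an ideal-gas
// expectation of 1.
inline bool kernel_split_c(double r, double r_lo, double delta, int B,
                           KernelSplit &ks) {
  const double x = (r - r_lo) / delta;
  if (x < -0.5 || x >= B + 0.5) return false;
  int b = (int)std::floor(x);  // may be -1 or B at the grid ends
  const double u = x - b - 0.5;  // in [-0.5, 0.5)
  const double au = std::fabs(u);
  ks.f1 = 1.0 - au;
  ks.f2 = au;
  ks.s = (u >= 0.0) ? 1.0 : -1.0;
  ks.b1 = (b < 0 || b >= B) ? -1 : b;
  ks.b2 = (u >= 0.0) ? b + 1 : b - 1;
  if (ks.b2 < 0 || ks.b2 >= B) ks.b2 = -1;
  return ks.b1 >= 0 || ks.b2 >= 0;
}
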