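#include "common.h"
using namespace Rcpp;

// 12-6 Lennard-Jones with optional truncation shift.
// shift_mode: 0 plain truncation, 1 energy shift (E(rc) -> 0),
// 2 shifted-force (energy and force both continuous at rc).
void lj_accumulate(const double *x, int n, const double *box, const int *spec,
                   const double *eps, const double *sig, const double *rcut,
                   int S, int shift_mode,
                   double *forces, double &energy, double &virial) {
  energy = 0.0;
  virial = 0.0;
  for (int k = 0; k < 3 * n; ++k) forces[k] = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const int si = spec[i];
    for (int j = i + 1; j < n; ++j) {
      const int sj = spec[j];
      const double rc = rcut[si + S * sj];
      const double dx = min_image(x[3 * i] - x[3 * j], box[0]);
      const double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box[1]);
      const double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) continue;
      const double r = std::sqrt(r2);
      const double e = eps[si + S * sj], s = sig[si + S * sj];
      LJPair p = lj_pair(r, e, s);
      if (shift_mode >= 1) {
        LJPair pc = lj_pair(rc, e, s);
        p.e -= pc.e;
        if (shift_mode == 2) {
          p.e -= (r - rc) * pc.dedr;
          p.dedr -= pc.dedr;
        }
      }
      energy += p.e;
      virial += -(1.0 / 3.0) * r * p.dedr;
      const double fscal = -p.dedr / r;
      forces[3 * i] += fscal * dx;
      forces[3 * i + 1] += fscal * dy;
      forces[3 * i + 2] += fscal * dz;
      forces[3 * j] -= fscal * dx;
      forces[3 * j + 1] -= fscal * dy;
      forces[3 * j + 2] -= fscal * dz;
    }
  }
}

// [[Rcpp::export]]
List cpp_lj_eval(NumericMatrix pos, NumericVector box, IntegerVector spec,
                 NumericMatrix eps, NumericMatrix sig, NumericMatrix rcut,
                 int shift_mode) {
  const int n = pos.nrow();
  const int S = eps.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  double energy, virial;
  lj_accumulate(x.data(), n, &box[0], &spec[0], &eps[0], &sig[0], &rcut[0], S,
                shift_mode, f.data(), energy, virial);
  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) forces(i, d) = f[3 * i + d];
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["virial"] = virial);
}
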