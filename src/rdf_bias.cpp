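#include "common.h"
using namespace Rcpp;

// Instantaneous kernel RDF.
//
// pref is an S x S matrix of species-pair prefactors that already contains
// the pair weight, the volume and the pair-count normalisation:
//   pref[a,b] = w^{ab} * V * (a == b ? 2/(N_a (N_a - 1)) : 1/(N_a N_b))
// so each unordered pair (i, j) adds pref[s_i, s_j] * fraction / V_bin to
// the bins its kernel overlaps.
// [[Rcpp::export]]
List cpp_rdf_kernel(NumericMatrix pos, NumericVector box, IntegerVector spec,
                    double r_lo, double delta, int B,
                    NumericMatrix pref, NumericVector binvol) {
  const int n = pos.nrow();
  std::vector<double> g(B, 0.0);
  double dropped = 0.0;
  KernelSplit ks;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
      const double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
      const double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!kernel_split_c(r, r_lo, delta, B, ks)) continue;
      const double p = pref(spec[i], spec[j]);
      if (ks.b1 >= 0) g[ks.b1] += p * ks.f1 / binvol[ks.b1];
      else dropped += p * ks.f1;
      if (ks.b2 >= 0) g[ks.b2] += p * ks.f2 / binvol[ks.b2];
      else dropped += p * ks.f2;
    }
  }
  return List::create(_["values"] = NumericVector(g.begin(), g.end()),
                      _["dropped"] = dropped);
}

// Linear bias E = sum_b lambda[b] * g_b with exact pairwise forces and the
// per-bin force virial T_ME^b = -(1/3) sum over pair terms of r * dE_b/dr.
// pref carries the bias reference volume (no explicit dependence on the
// frame box), so the force virial equals -(1/3) dE/d ln s under isotropic
// scaling of positions and box.
// [[Rcpp::export]]
List cpp_bias_eval(NumericMatrix pos, NumericVector box, IntegerVector spec,
                   NumericVector lambda, double r_lo, double delta, int B,
                   NumericMatrix pref, NumericVector binvol) {
  const int n = pos.nrow();
  NumericMatrix forces(n, 3);
  std::vector<double> vpb(B, 0.0);
  double energy = 0.0, dropped = 0.0;
  const double rmin_guard = 1e-6 * delta;
  KernelSplit ks;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
      const double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
      const double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rmin_guard) continue;
      if (!kernel_split_c(r, r_lo, delta, B, ks)) continue;
      const double p = pref(spec[i], spec[j]);
      // dE/dr split by the bin whose lambda generates it; out-of-grid
      // fractions carry no energy and no boundary force term
      double de1 = 0.0, de2 = 0.0;
      if (ks.b1 >= 0) {
        energy += p * lambda[ks.b1] * ks.f1 / binvol[ks.b1];
        de1 = p * lambda[ks.b1] * (-ks.s / delta) / binvol[ks.b1];
      } else {
        dropped += p * ks.f1;
      }
      if (ks.b2 >= 0) {
        energy += p * lambda[ks.b2] * ks.f2 / binvol[ks.b2];
        de2 = p * lambda[ks.b2] * (ks.s / delta) / binvol[ks.b2];
      } else {
        dropped += p * ks.f2;
      }
      const double dEdr = de1 + de2;
      const double fscal = -dEdr / r;  // F_i = fscal * r_ij
      forces(i, 0) += fscal * dx;
      forces(i, 1) += fscal * dy;
      forces(i, 2) += fscal * dz;
      forces(j, 0) -= fscal * dx;
      forces(j, 1) -= fscal * dy;
      forces(j, 2) -= fscal * dz;
      if (ks.b1 >= 0) vpb[ks.b1] += -(1.0 / 3.0) * r * de1;
      if (ks.b2 >= 0) vpb[ks.b2] += -(1.0 / 3.0) * r * de2;
    }
  }
  double total = 0.0;
  for (int b = 0; b < B; ++b) total += vpb[b];
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["virial_total"] = total,
                      _["virial_per_bin"] = NumericVector(vpb.begin(), vpb.end()),
                      _["dropped"] = dropped);
}
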