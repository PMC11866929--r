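#include "common.h"
using namespace Rcpp;

// Velocity-Verlet MD with optional Langevin thermostat, isotropic Berendsen
// barostat and the maximum-entropy RDF bias as a second force provider.
//
// Reduced LJ units, k_B = 1.  All pair interactions use the minimum image
// convention in an orthorhombic periodic box.
//
// bias_pref: S x S prefactor matrix for the bias (contains the bias
//   reference volume).  meas_pref_unit: S x S prefactor matrix for RDF
//   *measurement* per unit volume (multiplied by the instantaneous V).
// sample_every > 0 accumulates the kernel RDF and the per-bin bias virial
// into running sums (the controller's averaging window).
//
// Random numbers are drawn from R's RNG, so a single set.seed() call on the
// R side makes whole runs bit-reproducible.
// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector box0,
                IntegerVector spec, NumericVector mass_s,
                NumericMatrix eps, NumericMatrix sig, NumericMatrix rcut,
                int shift_mode, double dt, int nsteps,
                double temp, double damp,
                double press, double ptau, bool use_baro,
                NumericVector lambda, double r_lo, double delta, int B,
                NumericMatrix bias_pref, NumericMatrix meas_pref_unit,
                NumericVector binvol,
                int sample_every, int traj_every, int trace_every) {
  RNGScope rngscope;
  const int n = pos0.nrow();
  const int S = eps.nrow();
  const bool bias_on = lambda.size() > 0;
  const bool thermo_on = damp > 0.0;
  const double rmin_guard = 1e-6 * (delta > 0 ? delta : 1.0);

  std::vector<double> x(3 * n), xu(3 * n), v(3 * n), f(3 * n), m(n);
  double box[3] = {box0[0], box0[1], box0[2]};
  for (int i = 0; i < n; ++i) {
    m[i] = mass_s[spec[i]];
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos0(i, d);
      xu[3 * i + d] = pos0(i, d);
      v[3 * i + d] = vel0(i, d);
    }
  }

  // kernels are accepted while any part overlaps the grid
  const double grid_max = r_lo + B * delta + 0.5 * delta;
  std::vector<double> g_sum(B, 0.0), vpb_sum(B, 0.0), g_inst(B, 0.0),
      vpb_inst(B, 0.0);
  long n_samples = 0;
  double dropped = 0.0;

  double e_lj = 0.0, e_bias = 0.0, t0_vir = 0.0, tme_vir = 0.0;

  // one pass over all pairs: LJ + bias forces (+ RDF sampling if asked)
  auto compute_forces = [&](bool sample_now) {
    e_lj = 0.0;
    e_bias = 0.0;
    t0_vir = 0.0;
    tme_vir = 0.0;
    std::fill(f.begin(), f.end(), 0.0);
    if (sample_now) std::fill(g_inst.begin(), g_inst.end(), 0.0);
    if (bias_on) std::fill(vpb_inst.begin(), vpb_inst.end(), 0.0);
    const double V = box[0] * box[1] * box[2];
    const double hx = 0.5 * box[0], hy = 0.5 * box[1], hz = 0.5 * box[2];
    KernelSplit ks;
    for (int i = 0; i < n - 1; ++i) {
      const int si = spec[i];
      const double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      for (int j = i + 1; j < n; ++j) {
        const int sj = spec[j];
        const double dx = min_image_wrapped(xi - x[3 * j], box[0], hx);
        const double dy = min_image_wrapped(yi - x[3 * j + 1], box[1], hy);
        const double dz = min_image_wrapped(zi - x[3 * j + 2], box[2], hz);
        const double r2 = dx * dx + dy * dy + dz * dz;
        double dEdr = 0.0;
        const double rc = rcut[si + S * sj];
        bool in_lj = r2 < rc * rc;
        bool in_grid = (bias_on || sample_now) && r2 < grid_max * grid_max;
        if (!in_lj && !in_grid) continue;
        const double r = std::sqrt(r2);
        if (in_lj) {
          LJPair p = lj_pair(r, eps[si + S * sj], sig[si + S * sj]);
          if (shift_mode >= 1) {
            LJPair pc = lj_pair(rc, eps[si + S * sj], sig[si + S * sj]);
            p.e -= pc.e;
            if (shift_mode == 2) {
              p.e -= (r - rc) * pc.dedr;
              p.dedr -= pc.dedr;
            }
          }
          e_lj += p.e;
          t0_vir += -(1.0 / 3.0) * r * p.dedr;
          dEdr += p.dedr;
        }
        if (in_grid && r >= rmin_guard &&
            kernel_split_c(r, r_lo, delta, B, ks)) {
          if (sample_now) {
            const double pm = meas_pref_unit(si, sj) * V;
            if (ks.b1 >= 0) g_inst[ks.b1] += pm * ks.f1 / binvol[ks.b1];
            if (ks.b2 >= 0) g_inst[ks.b2] += pm * ks.f2 / binvol[ks.b2];
          }
          if (bias_on) {
            const double p = bias_pref(si, sj);
            double de1 = 0.0, de2 = 0.0;
            if (ks.b1 >= 0) {
              e_bias += p * lambda[ks.b1] * ks.f1 / binvol[ks.b1];
              de1 = p * lambda[ks.b1] * (-ks.s / delta) / binvol[ks.b1];
              vpb_inst[ks.b1] += -(1.0 / 3.0) * r * de1;
            } else {
              dropped += p * ks.f1;
            }
            if (ks.b2 >= 0) {
              e_bias += p * lambda[ks.b2] * ks.f2 / binvol[ks.b2];
              de2 = p * lambda[ks.b2] * (ks.s / delta) / binvol[ks.b2];
              vpb_inst[ks.b2] += -(1.0 / 3.0) * r * de2;
            } else {
              dropped += p * ks.f2;
            }
            dEdr += de1 + de2;
          }
        }
        if (dEdr != 0.0) {
          const double fs = -dEdr / r;
          f[3 * i] += fs * dx;
          f[3 * i + 1] += fs * dy;
          f[3 * i + 2] += fs * dz;
          f[3 * j] -= fs * dx;
          f[3 * j + 1] -= fs * dy;
          f[3 * j + 2] -= fs * dz;
        }
      }
    }
    if (bias_on)
      for (int b = 0; b < B; ++b) tme_vir += vpb_inst[b];
    // Langevin thermostat: friction + white noise on every component
    if (thermo_on) {
      const double pref_noise_c = std::sqrt(2.0 * temp / (dt * damp));
      for (int i = 0; i < n; ++i) {
        const double gi = m[i] / damp;
        const double ni = std::sqrt(m[i]) * pref_noise_c;
        for (int d = 0; d < 3; ++d)
          f[3 * i + d] += -gi * v[3 * i + d] + ni * norm_rand();
      }
    }
  };

  auto kinetic = [&]() {
    double k = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) k += 0.5 * m[i] * v[3 * i + d] * v[3 * i + d];
    return k;
  };

  std::vector<double> tr_step, tr_tkin, tr_elj, tr_ebias, tr_t0, tr_tme, tr_vol;
  List traj = List::create();
  std::vector<Rcpp::NumericMatrix> traj_pos;
  std::vector<double> traj_step;
  std::vector<Rcpp::NumericVector> traj_box;

  compute_forces(false);
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt * f[3 * i + d] / m[i];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        const double dd = dt * v[3 * i + d];
        x[3 * i + d] += dd;
        xu[3 * i + d] += dd;
        double &xx = x[3 * i + d];
        xx -= box[d] * std::floor(xx / box[d]);
      }
    const bool sample_now = sample_every > 0 && step % sample_every == 0;
    compute_forces(sample_now);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt * f[3 * i + d] / m[i];

    if (!std::isfinite(e_lj) || !std::isfinite(x[0]))
      stop("non-finite coordinates or energy at step %d", step);

    if (use_baro) {
      const double V = box[0] * box[1] * box[2];
      const double P = ((2.0 / 3.0) * kinetic() + t0_vir + tme_vir) / V;
      double mu = std::cbrt(1.0 - dt / ptau * (press - P));
      if (mu < 0.95) mu = 0.95;
      if (mu > 1.05) mu = 1.05;
      for (int d = 0; d < 3; ++d) box[d] *= mu;
      for (int k = 0; k < 3 * n; ++k) {
        x[k] *= mu;
        xu[k] *= mu;
      }
    }

    if (sample_now) {
      ++n_samples;
      for (int b = 0; b < B; ++b) {
        g_sum[b] += g_inst[b];
        vpb_sum[b] += vpb_inst[b];
      }
    }
    if (trace_every > 0 && step % trace_every == 0) {
      tr_step.push_back(step);
      tr_tkin.push_back(2.0 * kinetic() / (3.0 * n));
      tr_elj.push_back(e_lj);
      tr_ebias.push_back(e_bias);
      tr_t0.push_back(t0_vir);
      tr_tme.push_back(tme_vir);
      tr_vol.push_back(box[0] * box[1] * box[2]);
    }
    if (traj_every > 0 && step % traj_every == 0) {
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) snap(i, d) = xu[3 * i + d];
      traj_pos.push_back(snap);
      traj_step.push_back(step);
      traj_box.push_back(NumericVector::create(box[0], box[1], box[2]));
    }
  }

  NumericMatrix pos_out(n, 3), posu_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = x[3 * i + d];
      posu_out(i, d) = xu[3 * i + d];
      vel_out(i, d) = v[3 * i + d];
    }
  NumericVector g_avg(B), vpb_avg(B);
  if (n_samples > 0)
    for (int b = 0; b < B; ++b) {
      g_avg[b] = g_sum[b] / n_samples;
      vpb_avg[b] = vpb_sum[b] / n_samples;
    }

  List trace = List::create(
      _["step"] = NumericVector(tr_step.begin(), tr_step.end()),
      _["temperature"] = NumericVector(tr_tkin.begin(), tr_tkin.end()),
      _["e_pair"] = NumericVector(tr_elj.begin(), tr_elj.end()),
      _["e_bias"] = NumericVector(tr_ebias.begin(), tr_ebias.end()),
      _["virial_pair"] = NumericVector(tr_t0.begin(), tr_t0.end()),
      _["virial_bias"] = NumericVector(tr_tme.begin(), tr_tme.end()),
      _["volume"] = NumericVector(tr_vol.begin(), tr_vol.end()));

  List traj_out(traj_pos.size());
  for (size_t k = 0; k < traj_pos.size(); ++k)
    traj_out[k] = List::create(_["step"] = traj_step[k],
                               _["positions"] = traj_pos[k],
                               _["box"] = traj_box[k]);

  return List::create(
      _["positions"] = pos_out, _["positions_unwrapped"] = posu_out,
      _["velocities"] = vel_out,
      _["box"] = NumericVector::create(box[0], box[1], box[2]),
      _["e_pair"] = e_lj, _["e_bias"] = e_bias, _["virial_pair"] = t0_vir,
      _["virial_bias"] = tme_vir, _["avg_g"] = g_avg,
      _["avg_virial_per_bin"] = vpb_avg, _["n_samples"] = (double)n_samples,
      _["dropped_kernel_mass"] = dropped, _["trace"] = trace,
      _["trajectory"] = traj_out);
}
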