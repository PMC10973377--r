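// Langevin dynamics core: analytic toy potentials + BAOAB integrator.
// Positions are flat coordinate vectors (particle-major); masses are given
// per coordinate.  All randomness comes from R's RNG so that R-level
// set.seed() gives bit-identical replay.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Potential ids (kept in sync with .potential_registry in R/toy-systems.R):
//   0 harmonic            params: k            V = k/2 * |x|^2
//   1 double_well_1d      params: b, a, tilt   V = b((x/a)^2-1)^2 + tilt*x
//   2 tilted_double_well_2d  params: b, a, tilt, ky, cxy
//                           V = b((x/a)^2-1)^2 + tilt*x + ky/2*y^2 + cxy*x*y
//   3 linear_combo_nd     params: b, a, kperp, w[0..d-1] (|w| = 1)
//                           s = w.x; V = b((s/a)^2-1)^2 + kperp/2*|x - s w|^2

static double pot_energy(int pid, const NumericVector& p,
                         const double* x, int d) {
  switch (pid) {
  case 0: {
    double s = 0.0;
    for (int i = 0; i < d; ++i) s += x[i] * x[i];
    return 0.5 * p[0] * s;
  }
  case 1: {
    double u = x[0] / p[1];
    double q = u * u - 1.0;
    return p[0] * q * q + p[2] * x[0];
  }
  case 2: {
    double u = x[0] / p[1];
    double q = u * u - 1.0;
    return p[0] * q * q + p[2] * x[0] + 0.5 * p[3] * x[1] * x[1] +
           p[4] * x[0] * x[1];
  }
  case 3: {
    double s = 0.0;
    for (int i = 0; i < d; ++i) s += p[3 + i] * x[i];
    double u = s / p[1];
    double q = u * u - 1.0;
    double perp = 0.0;
    for (int i = 0; i < d; ++i) {
      double r = x[i] - s * p[3 + i];
      perp += r * r;
    }
    return p[0] * q * q + 0.5 * p[2] * perp;
  }
  default: stop("unknown potential id");
  }
  return NA_REAL; // unreachable
}

static void pot_grad(int pid, const NumericVector& p,
                     const double* x, int d, double* g) {
  switch (pid) {
  case 0:
    for (int i = 0; i < d; ++i) g[i] = p[0] * x[i];
    return;
  case 1: {
    double a2 = p[1] * p[1];
    double u2 = x[0] * x[0] / a2;
    g[0] = 4.0 * p[0] * x[0] * (u2 - 1.0) / a2 + p[2];
    return;
  }
  case 2: {
    double a2 = p[1] * p[1];
    double u2 = x[0] * x[0] / a2;
    g[0] = 4.0 * p[0] * x[0] * (u2 - 1.0) / a2 + p[2] + p[4] * x[1];
    g[1] = p[3] * x[1] + p[4] * x[0];
    return;
  }
  case 3: {
    double s = 0.0;
    for (int i = 0; i < d; ++i) s += p[3 + i] * x[i];
    double a2 = p[1] * p[1];
    double dVds = 4.0 * p[0] * s * (s * s / a2 - 1.0) / a2;
    for (int i = 0; i < d; ++i)
      g[i] = dVds * p[3 + i] + p[2] * (x[i] - s * p[3 + i]);
    return;
  }
  default: stop("unknown potential id");
  }
}

// Harmonic biases, one per matrix row.  Row layout (width >= max(5+d, 6)):
//   type 1 (linear):   type, k, center, b0, w[0..d-1];   q = b0 + w.x
//   type 2 (distance): type, k, center, i0, j0, dim;     q = |r_i0 - r_j0|
//   type 3 (wall):     type, k, lo, hi, b0, w[0..d-1];   half-harmonic walls
//                      outside [lo, hi] on the linear q = b0 + w.x
// Adds the restraint force to f; returns q of the first bias row.
static double apply_biases(const NumericMatrix& B, const double* x, int d,
                           double* f) {
  double q_first = NA_REAL;
  for (int r = 0; r < B.nrow(); ++r) {
    int type = (int)B(r, 0);
    double k = B(r, 1), center = B(r, 2), q = NA_REAL;
    if (type == 1) {
      q = B(r, 3);
      for (int i = 0; i < d; ++i) q += B(r, 4 + i) * x[i];
      double c = -k * (q - center);
      for (int i = 0; i < d; ++i) f[i] += c * B(r, 4 + i);
    } else if (type == 2) {
      int i0 = (int)B(r, 3), j0 = (int)B(r, 4), dim = (int)B(r, 5);
      q = 0.0;
      for (int m = 0; m < dim; ++m) {
        double dd = x[i0 * dim + m] - x[j0 * dim + m];
        q += dd * dd;
      }
      q = std::sqrt(q);
      if (q > 1e-12) {
        double c = -k * (q - center) / q;
        for (int m = 0; m < dim; ++m) {
          double dd = x[i0 * dim + m] - x[j0 * dim + m];
          f[i0 * dim + m] += c * dd;
          f[j0 * dim + m] -= c * dd;
        }
      }
    } else if (type == 3) {
      double lo = B(r, 2), hi = B(r, 3);
      q = B(r, 4);
      for (int i = 0; i < d; ++i) q += B(r, 5 + i) * x[i];
      double c = 0.0;
      if (q < lo) c = -k * (q - lo);
      else if (q > hi) c = -k * (q - hi);
      if (c != 0.0)
        for (int i = 0; i < d; ++i) f[i] += c * B(r, 5 + i);
    } else {
      stop("unknown bias type");
    }
    if (r == 0) q_first = q;
  }
  return q_first;
}

// [[Rcpp::export]]
double pot_energy_cpp(int pid, NumericVector params, NumericVector x) {
  return pot_energy(pid, params, x.begin(), x.size());
}

// [[Rcpp::export]]
NumericVector pot_grad_cpp(int pid, NumericVector params, NumericVector x) {
  NumericVector g(x.size());
  pot_grad(pid, params, x.begin(), x.size(), g.begin());
  return g;
}

// BAOAB Langevin propagation (reduces to velocity Verlet when gamma = 0).
// Saves every save_stride-th step plus the initial frame.  `biases` may have
// zero rows (unbiased dynamics).
// [[Rcpp::export]]
List propagate_cpp(int pid, NumericVector params, NumericVector masses,
                   NumericVector x0, NumericVector v0, int n_steps,
                   double dt, double gamma, double kT, int save_stride,
                   NumericMatrix biases) {
  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(d);

  const double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(d), invm(d);
  for (int i = 0; i < d; ++i) {
    invm[i] = 1.0 / masses[i];
    c2[i] = std::sqrt(kT * (1.0 - c1 * c1) * invm[i]);
  }

  const int n_save = n_steps / save_stride;
  NumericMatrix pos(n_save + 1, d), vel(n_save + 1, d);
  NumericVector times(n_save + 1), qbias(n_save + 1);

  auto forces = [&](double* fr) {
    pot_grad(pid, params, x.data(), d, fr);
    for (int i = 0; i < d; ++i) fr[i] = -fr[i];
    return apply_biases(biases, x.data(), d, fr);
  };

  double q = forces(f.data());
  for (int i = 0; i < d; ++i) { pos(0, i) = x[i]; vel(0, i) = v[i]; }
  times[0] = 0.0; qbias[0] = q;

  int fail_step = -1;
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < d; ++i) {        // B
      v[i] += 0.5 * dt * f[i] * invm[i];
      x[i] += 0.5 * dt * v[i];           // A
    }
    if (gamma > 0.0)                     // O
      for (int i = 0; i < d; ++i) v[i] = c1 * v[i] + c2[i] * R::norm_rand();
    for (int i = 0; i < d; ++i) x[i] += 0.5 * dt * v[i]; // A
    q = forces(f.data());
    for (int i = 0; i < d; ++i) v[i] += 0.5 * dt * f[i] * invm[i]; // B

    bool ok = true;
    for (int i = 0; i < d; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(v[i])) ok = false;
    if (!ok) { fail_step = step; break; }

    if (step % save_stride == 0) {
      for (int i = 0; i < d; ++i) { pos(row, i) = x[i]; vel(row, i) = v[i]; }
      times[row] = step * dt; qbias[row] = q;
      ++row;
    }
  }

  if (fail_step >= 0) {
    pos = pos(Range(0, row - 1), _);
    vel = vel(Range(0, row - 1), _);
    times = times[Range(0, row - 1)];
    qbias = qbias[Range(0, row - 1)];
  }
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["times"] = times, _["bias_q"] = qbias,
                      _["fail_step"] = fail_step);
}
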