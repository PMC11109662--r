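#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ mol-1 K-1

// ---------------------------------------------------------------------------
// Funnel restraint: cone (half-aperture alpha from the axis) merging into a
// cylinder of radius rcyl at axial coordinate zcc.  One-sided harmonic wall.
// ---------------------------------------------------------------------------
struct Funnel {
  bool active;
  double o[3], a[3];
  double zcc, rcyl, alpha, kwall, tana;
  Funnel() : active(false) {
    o[0] = o[1] = o[2] = 0.0;
    a[0] = a[1] = 0.0; a[2] = 1.0;
    zcc = 0.5; rcyl = 0.1; alpha = 1.1; kwall = 0.0; tana = std::tan(1.1);
  }
};

static Funnel parse_funnel(const List& fl) {
  Funnel f;
  if (fl.size() == 0) return f;
  f.active = true;
  NumericVector o = fl["origin"], a = fl["axis"];
  for (int i = 0; i < 3; ++i) { f.o[i] = o[i]; f.a[i] = a[i]; }
  f.zcc = as<double>(fl["z_cc"]);
  f.rcyl = as<double>(fl["r_cyl"]);
  f.alpha = as<double>(fl["alpha"]);
  f.kwall = as<double>(fl["k_wall"]);
  f.tana = std::tan(f.alpha);
  return f;
}

static inline double funnel_radius_c(double z, const Funnel& f) {
  return (z >= f.zcc) ? f.rcyl : f.rcyl + (f.zcc - z) * f.tana;
}

// decompose pos into axial z, radial rho and unit radial vector
static inline void axial_rho(const Funnel& f, const double* x, double& z,
                             double& rho, double* rhat) {
  double d[3] = { x[0] - f.o[0], x[1] - f.o[1], x[2] - f.o[2] };
  z = d[0] * f.a[0] + d[1] * f.a[1] + d[2] * f.a[2];
  double rv[3] = { d[0] - z * f.a[0], d[1] - z * f.a[1], d[2] - z * f.a[2] };
  rho = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2]);
  if (rho > 1e-14) { rhat[0] = rv[0] / rho; rhat[1] = rv[1] / rho; rhat[2] = rv[2] / rho; }
  else { rhat[0] = rhat[1] = rhat[2] = 0.0; }
}

// wall energy; adds -grad to force f if f != nullptr
static double wall_energy_c(const Funnel& fn, const double* x, double* f) {
  if (!fn.active || fn.kwall <= 0.0) return 0.0;
  double z, rho, rhat[3];
  axial_rho(fn, x, z, rho, rhat);
  double rad = funnel_radius_c(z, fn);
  double exc = rho - rad;
  if (exc <= 0.0) return 0.0;
  double U = 0.5 * fn.kwall * exc * exc;
  if (f) {
    // dU/drho along rhat, plus dU/dz along axis (cone section only)
    double g = fn.kwall * exc;
    double dz = (z < fn.zcc) ? fn.kwall * exc * fn.tana : 0.0;
    for (int i = 0; i < 3; ++i) f[i] -= g * rhat[i] + dz * fn.a[i];
  }
  return U;
}

// ---------------------------------------------------------------------------
// Analytic toy potentials.
// preset codes: 0 harmonic, 1 double_well_1d, 2 square_well_axial,
//               3 funnel_trap_3d, 4 two_channel_exit
// ---------------------------------------------------------------------------
static double energy_only(int preset, const double* p, const double* x);

static double potential_force(int preset, const double* p, const double* x,
                              double* f) {
  switch (preset) {
  case 0: { // harmonic: p = (k)
    double k = p[0];
    double U = 0.5 * k * (x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
    for (int i = 0; i < 3; ++i) f[i] -= k * x[i];
    return U;
  }
  case 1: { // double_well_1d: p = (Vb, a, tilt, kperp)
    double Vb = p[0], a = p[1], tilt = p[2], kp = p[3];
    double u = x[0] / a, q = u * u - 1.0;
    double U = Vb * q * q + 0.5 * tilt * u
             + 0.5 * kp * (x[1] * x[1] + x[2] * x[2]);
    f[0] -= (4.0 * Vb * u * q + 0.5 * tilt) / a;
    f[1] -= kp * x[1];
    f[2] -= kp * x[2];
    return U;
  }
  case 2: { // square_well_axial (smoothed box along z): p = (D, L, w)
    double D = p[0], L = p[1], w = p[2];
    double s1 = 1.0 / (1.0 + std::exp(-x[2] / w));
    double s2 = 1.0 / (1.0 + std::exp((x[2] - L) / w));
    double U = -D * s1 * s2;
    double d = -D * (s1 * (1.0 - s1) / w * s2 - s1 * s2 * (1.0 - s2) / w);
    f[2] -= d;
    return U;
  }
  case 3: { // funnel_trap_3d: p = (D, R, w, zmin, zmax, kax)
    double D = p[0], R = p[1], w = p[2], zmin = p[3], zmax = p[4], kax = p[5];
    double r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
    double s = 1.0 / (1.0 + std::exp((r - R) / w));
    double U = -D * s;
    if (r > 1e-12) {
      double dUdr = D * s * (1.0 - s) / w;
      for (int i = 0; i < 3; ++i) f[i] -= dUdr * x[i] / r;
    }
    if (x[2] > zmax) { U += 0.5 * kax * (x[2] - zmax) * (x[2] - zmax); f[2] -= kax * (x[2] - zmax); }
    if (x[2] < zmin) { U += 0.5 * kax * (x[2] - zmin) * (x[2] - zmin); f[2] -= kax * (x[2] - zmin); }
    return U;
  }
  case 4: { // two_channel_exit: numeric gradient (smooth ring barrier with 2 gaps)
    double U = energy_only(4, p, x);
    double h = 1e-6, xp[3];
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) xp[j] = x[j];
      xp[i] = x[i] + h; double up = energy_only(4, p, xp);
      xp[i] = x[i] - h; double um = energy_only(4, p, xp);
      f[i] -= (up - um) / (2.0 * h);
    }
    return U;
  }
  default:
    stop("unknown preset code %d", preset);
  }
  return 0.0;
}

static double energy_only(int preset, const double* p, const double* x) {
  if (preset == 4) {
    // p = (B, R0, wr, kap1, kap2, kz): ring barrier of height B at radius R0
    // in the xy-plane with angular gaps at theta = 0 (concentration kap1,
    // wider) and theta = pi (kap2, narrower); harmonic z confinement.
    double B = p[0], R0 = p[1], wr = p[2], k1 = p[3], k2 = p[4], kz = p[5];
    double rho = std::sqrt(x[0] * x[0] + x[1] * x[1]);
    double ct = (rho > 1e-12) ? x[0] / rho : 1.0;
    double gap = std::exp(k1 * (ct - 1.0)) + std::exp(k2 * (-ct - 1.0));
    double ring = B * std::exp(-(rho - R0) * (rho - R0) / (2.0 * wr * wr));
    return ring * (1.0 - gap) + 0.5 * kz * x[2] * x[2];
  }
  double f[3] = {0, 0, 0};
  return potential_force(preset, p, x, f);
}

// ---------------------------------------------------------------------------
// Collective-variable maps (position -> scalar, with gradient).
// codes: 0 x, 1 y, 2 z, 3 axial, 4 radial, 5 dist, 6 compactness
// ---------------------------------------------------------------------------
static double cv_eval(int code, const double* cvp, const Funnel& fn,
                      const double* x, double* grad) {
  grad[0] = grad[1] = grad[2] = 0.0;
  switch (code) {
  case 0: grad[0] = 1; return x[0];
  case 1: grad[1] = 1; return x[1];
  case 2: grad[2] = 1; return x[2];
  case 3: { // axial projection onto funnel axis
    double z, rho, rhat[3];
    axial_rho(fn, x, z, rho, rhat);
    for (int i = 0; i < 3; ++i) grad[i] = fn.a[i];
    return z;
  }
  case 4: { // radial distance from the axis
    double z, rho, rhat[3];
    axial_rho(fn, x, z, rho, rhat);
    for (int i = 0; i < 3; ++i) grad[i] = rhat[i];
    return rho;
  }
  case 5: { // distance from funnel origin
    double d[3] = { x[0] - fn.o[0], x[1] - fn.o[1], x[2] - fn.o[2] };
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r > 1e-12) for (int i = 0; i < 3; ++i) grad[i] = d[i] / r;
    return r;
  }
  case 6: { // logistic compactness of |pos - origin|: cvp = (beta, r_half)
    double d[3] = { x[0] - fn.o[0], x[1] - fn.o[1], x[2] - fn.o[2] };
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double s = 1.0 / (1.0 + std::exp(cvp[0] * (r - cvp[1])));
    if (r > 1e-12) {
      double dsdr = -cvp[0] * s * (1.0 - s);
      for (int i = 0; i < 3; ++i) grad[i] = dsdr * d[i] / r;
    }
    return s;
  }
  default: stop("unknown cv code %d", code);
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// Bias grid cache: V and dV/dcv_d accumulated per hill, multilinear lookup.
// ---------------------------------------------------------------------------
struct BiasGrid {
  int ncv;
  int n[2];
  double lo[2], hi[2], dx[2];
  std::vector<double> V, G1, G2;
  void init(int ncv_, const NumericVector& gmin, const NumericVector& gmax,
            const IntegerVector& gn) {
    ncv = ncv_;
    size_t tot = 1;
    for (int d = 0; d < ncv; ++d) {
      n[d] = gn[d]; lo[d] = gmin[d]; hi[d] = gmax[d];
      dx[d] = (hi[d] - lo[d]) / (n[d] - 1);
      tot *= (size_t)n[d];
    }
    V.assign(tot, 0.0); G1.assign(tot, 0.0);
    if (ncv == 2) G2.assign(tot, 0.0);
  }
  void add_hill(const double* c, const double* sig, double h) {
    // truncate support at 6 sigma
    if (ncv == 1) {
      int i0 = std::max(0, (int)std::floor((c[0] - 6 * sig[0] - lo[0]) / dx[0]));
      int i1 = std::min(n[0] - 1, (int)std::ceil((c[0] + 6 * sig[0] - lo[0]) / dx[0]));
      for (int i = i0; i <= i1; ++i) {
        double u = (lo[0] + i * dx[0]) - c[0];
        double e = h * std::exp(-u * u / (2 * sig[0] * sig[0]));
        V[i] += e;
        G1[i] += -u / (sig[0] * sig[0]) * e;
      }
    } else {
      int i0 = std::max(0, (int)std::floor((c[0] - 6 * sig[0] - lo[0]) / dx[0]));
      int i1 = std::min(n[0] - 1, (int)std::ceil((c[0] + 6 * sig[0] - lo[0]) / dx[0]));
      int j0 = std::max(0, (int)std::floor((c[1] - 6 * sig[1] - lo[1]) / dx[1]));
      int j1 = std::min(n[1] - 1, (int)std::ceil((c[1] + 6 * sig[1] - lo[1]) / dx[1]));
      for (int i = i0; i <= i1; ++i) {
        double u = (lo[0] + i * dx[0]) - c[0];
        double e1 = std::exp(-u * u / (2 * sig[0] * sig[0]));
        double du = -u / (sig[0] * sig[0]);
        for (int j = j0; j <= j1; ++j) {
          double v = (lo[1] + j * dx[1]) - c[1];
          double e2 = std::exp(-v * v / (2 * sig[1] * sig[1]));
          double e = h * e1 * e2;
          size_t k = (size_t)i * n[1] + j;
          V[k] += e;
          G1[k] += du * e;
          G2[k] += -v / (sig[1] * sig[1]) * e;
        }
      }
    }
  }
  // multilinear interpolation of V (and gradients g[0..ncv-1] if g != nullptr)
  double lookup(const double* s, double* g) const {
    if (ncv == 1) {
      double t = (s[0] - lo[0]) / dx[0];
      int i = (int)std::floor(t);
      if (i < 0) i = 0; if (i > n[0] - 2) i = n[0] - 2;
      double w = t - i; if (w < 0) w = 0; if (w > 1) w = 1;
      if (g) g[0] = (1 - w) * G1[i] + w * G1[i + 1];
      return (1 - w) * V[i] + w * V[i + 1];
    }
    double t1 = (s[0] - lo[0]) / dx[0], t2 = (s[1] - lo[1]) / dx[1];
    int i = (int)std::floor(t1), j = (int)std::floor(t2);
    if (i < 0) i = 0; if (i > n[0] - 2) i = n[0] - 2;
    if (j < 0) j = 0; if (j > n[1] - 2) j = n[1] - 2;
    double w1 = t1 - i, w2 = t2 - j;
    if (w1 < 0) w1 = 0; if (w1 > 1) w1 = 1;
    if (w2 < 0) w2 = 0; if (w2 > 1) w2 = 1;
    size_t k00 = (size_t)i * n[1] + j, k01 = k00 + 1;
    size_t k10 = k00 + n[1], k11 = k10 + 1;
    double a00 = (1 - w1) * (1 - w2), a01 = (1 - w1) * w2,
           a10 = w1 * (1 - w2), a11 = w1 * w2;
    if (g) {
      g[0] = a00 * G1[k00] + a01 * G1[k01] + a10 * G1[k10] + a11 * G1[k11];
      g[1] = a00 * G2[k00] + a01 * G2[k01] + a10 * G2[k10] + a11 * G2[k11];
    }
    return a00 * V[k00] + a01 * V[k01] + a10 * V[k10] + a11 * V[k11];
  }
};

// ---------------------------------------------------------------------------
// Exported helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector toy_energy_cpp(int preset, NumericVector params, List funnel,
                             NumericMatrix pos, bool include_wall) {
  Funnel fn = parse_funnel(funnel);
  int n = pos.nrow();
  NumericVector out(n);
  std::vector<double> p(params.begin(), params.end());
  for (int i = 0; i < n; ++i) {
    double x[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    double U = energy_only(preset, p.data(), x);
    if (include_wall) U += wall_energy_c(fn, x, nullptr);
    out[i] = U;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix toy_force_cpp(int preset, NumericVector params, List funnel,
                            NumericMatrix pos, bool include_wall) {
  Funnel fn = parse_funnel(funnel);
  int n = pos.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> p(params.begin(), params.end());
  for (int i = 0; i < n; ++i) {
    double x[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    double f[3] = { 0, 0, 0 };
    potential_force(preset, p.data(), x, f);
    if (include_wall) wall_energy_c(fn, x, f);
    for (int j = 0; j < 3; ++j) out(i, j) = f[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cv_eval_cpp(IntegerVector codes, NumericMatrix cv_params,
                          List funnel, NumericMatrix pos) {
  Funnel fn = parse_funnel(funnel);
  int n = pos.nrow(), ncv = codes.size();
  NumericMatrix out(n, ncv);
  double g[3];
  for (int i = 0; i < n; ++i) {
    double x[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    for (int d = 0; d < ncv; ++d) {
      double cvp[4] = { cv_params(d, 0), cv_params(d, 1), 0, 0 };
      out(i, d) = cv_eval(codes[d], cvp, fn, x, g);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Main engine: Langevin (BAOAB) + optional well-tempered metadynamics +
// optional funnel wall + optional RAMD constant force with redirection rule.
// Randomness comes from R's RNG, so set.seed() upstream fixes the run.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_langevin_cpp(int preset, NumericVector params, List funnel,
                      NumericVector x0, double mass, double friction,
                      double temperature, double dt, int n_steps, int stride,
                      int pace, double height0, double bias_factor,
                      NumericVector sigma, IntegerVector cv_codes,
                      NumericMatrix cv_params, NumericVector grid_min,
                      NumericVector grid_max, IntegerVector grid_n,
                      double ramd_f, int ramd_check_steps,
                      double ramd_threshold, NumericVector ramd_dir0,
                      double exit_radius) {
  Funnel fn = parse_funnel(funnel);
  std::vector<double> p(params.begin(), params.end());
  bool metad = pace > 0 && height0 > 0.0;
  bool ramd = ramd_f > 0.0;
  int ncv = cv_codes.size();
  double kT = KB * temperature;

  BiasGrid grid;
  if (metad) grid.init(ncv, grid_min, grid_max, grid_n);

  double x[3] = { x0[0], x0[1], x0[2] };
  double v[3];
  // Maxwell-Boltzmann start
  double vth = std::sqrt(kT / mass);
  for (int i = 0; i < 3; ++i) v[i] = vth * norm_rand();

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1) * vth;

  double f[3] = { 0, 0, 0 };
  double U = potential_force(preset, p.data(), x, f);
  U += wall_energy_c(fn, x, f);

  double dir[3] = { ramd_dir0[0], ramd_dir0[1], ramd_dir0[2] };
  double last_com[3] = { x[0], x[1], x[2] };
  if (ramd) for (int i = 0; i < 3; ++i) f[i] += ramd_f * dir[i];

  // bias force accumulator uses cv gradients
  double cvg[2][3];
  double s[2], gb[2];
  auto add_bias_force = [&](double* ff) {
    if (!metad) return;
    for (int d = 0; d < ncv; ++d) {
      double cvp[4] = { cv_params(d, 0), cv_params(d, 1), 0, 0 };
      s[d] = cv_eval(cv_codes[d], cvp, fn, x, cvg[d]);
    }
    grid.lookup(s, gb);
    for (int d = 0; d < ncv; ++d)
      for (int i = 0; i < 3; ++i) ff[i] -= gb[d] * cvg[d][i];
  };
  add_bias_force(f);

  int n_rec = n_steps / stride + 1;
  NumericMatrix traj(n_rec, 4);
  NumericMatrix colvar(n_rec, 1 + ncv);
  int max_hills = metad ? n_steps / pace + 1 : 0;
  NumericMatrix hills(max_hills, 2 + 2 * ncv + 2);
  int nh = 0, nrec = 0, n_wall_viol = 0;

  auto record = [&](double t) {
    traj(nrec, 0) = t;
    for (int i = 0; i < 3; ++i) traj(nrec, 1 + i) = x[i];
    colvar(nrec, 0) = t;
    for (int d = 0; d < ncv; ++d) {
      double cvp[4] = { cv_params(d, 0), cv_params(d, 1), 0, 0 };
      double gtmp[3];
      colvar(nrec, 1 + d) = cv_eval(cv_codes[d], cvp, fn, x, gtmp);
    }
    if (fn.active) {
      double z, rho, rh[3];
      axial_rho(fn, x, z, rho, rh);
      if (rho > funnel_radius_c(z, fn)) ++n_wall_viol;
    }
    ++nrec;
  };
  record(0.0);

  bool egressed = false;
  int step_done = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < 3; ++i) v[i] += 0.5 * dt * f[i] / mass;
    // A
    for (int i = 0; i < 3; ++i) x[i] += 0.5 * dt * v[i];
    // O
    for (int i = 0; i < 3; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    // A
    for (int i = 0; i < 3; ++i) x[i] += 0.5 * dt * v[i];
    // force at new position
    for (int i = 0; i < 3; ++i) f[i] = 0.0;
    U = potential_force(preset, p.data(), x, f);
    U += wall_energy_c(fn, x, f);
    if (!std::isfinite(U) || !std::isfinite(x[0]) || !std::isfinite(x[1]) ||
        !std::isfinite(x[2]))
      stop("non-finite energy or position at step %d", step);
    if (ramd) for (int i = 0; i < 3; ++i) f[i] += ramd_f * dir[i];

    // metadynamics deposition
    if (metad && step % pace == 0) {
      for (int d = 0; d < ncv; ++d) {
        double cvp[4] = { cv_params(d, 0), cv_params(d, 1), 0, 0 };
        s[d] = cv_eval(cv_codes[d], cvp, fn, x, cvg[d]);
      }
      double vb = grid.lookup(s, nullptr);
      double h = height0 * std::exp(-vb / ((bias_factor - 1.0) * kT));
      double sig[2] = { sigma[0], ncv == 2 ? sigma[1] : 0.0 };
      grid.add_hill(s, sig, h);
      hills(nh, 0) = step * dt;
      for (int d = 0; d < ncv; ++d) hills(nh, 1 + d) = s[d];
      for (int d = 0; d < ncv; ++d) hills(nh, 1 + ncv + d) = sigma[d];
      hills(nh, 1 + 2 * ncv) = h;
      hills(nh, 2 + 2 * ncv) = bias_factor;
      ++nh;
    }
    add_bias_force(f);

    // B
    for (int i = 0; i < 3; ++i) v[i] += 0.5 * dt * f[i] / mass;

    // RAMD checkpoint: keep direction only if COM moved beyond threshold
    if (ramd && step % ramd_check_steps == 0) {
      double dd = 0;
      for (int i = 0; i < 3; ++i) {
        double u = x[i] - last_com[i];
        dd += u * u;
      }
      if (std::sqrt(dd) <= ramd_threshold) {
        double nrm = 0;
        for (int i = 0; i < 3; ++i) { dir[i] = norm_rand(); nrm += dir[i] * dir[i]; }
        nrm = std::sqrt(nrm);
        for (int i = 0; i < 3; ++i) dir[i] /= nrm;
      }
      for (int i = 0; i < 3; ++i) last_com[i] = x[i];
    }

    if (step % stride == 0) record(step * dt);
    step_done = step;

    if (exit_radius > 0.0) {
      double d2 = 0;
      for (int i = 0; i < 3; ++i) {
        double u = x[i] - fn.o[i];
        d2 += u * u;
      }
      if (std::sqrt(d2) > exit_radius) { egressed = true; break; }
    }
  }

  return List::create(
    _["trajectory"] = traj(Range(0, nrec - 1), Range(0, 3)),
    _["colvar"] = colvar(Range(0, nrec - 1), Range(0, ncv)),
    _["hills"] = nh > 0 ? hills(Range(0, nh - 1), Range(0, 1 + 2 * ncv + 1))
                        : NumericMatrix(0, 2 + 2 * ncv + 2),
    _["egressed"] = egressed,
    _["final_position"] = NumericVector::create(x[0], x[1], x[2]),
    _["final_direction"] = NumericVector::create(dir[0], dir[1], dir[2]),
    _["steps_done"] = step_done,
    _["wall_violation_frames"] = n_wall_viol,
    _["frames_recorded"] = nrec);
}
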