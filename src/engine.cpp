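// Langevin MD engine for a bead-spring worm-like chain in an implicit
// cylindrical/helical channel, with optional bottom wall and piston.
// Reduced units: sigma = 1 (length), eps0 = kT = 1 (energy), bead mass m = 1.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double WCA_CUT = 1.1224620483089301;   // 2^(1/6) sigma
static const double WALL_SIG = 0.5;                 // wall length scale (bead radius)
static const double WALL_CUT = WCA_CUT * WALL_SIG;  // cutoff on the wall gap

struct Channel {
  bool active;
  double Rch, RH, k, omega;
};

// Stationarity condition of |p - r0(t)|^2 along the helix mid-curve
// r0(t) = (k t, RH cos(w t), RH sin(w t)).  The RH^2 terms cancel:
// g(t) = k (x - k t) - RH w (y sin(w t) - z cos(w t)).
static inline double helix_g(const Channel& ch, double t,
                             double x, double y, double z) {
  double s = sin(ch.omega * t), c = cos(ch.omega * t);
  return ch.k * (x - ch.k * t) - ch.RH * ch.omega * (y * s - z * c);
}

static inline double helix_gprime(const Channel& ch, double t,
                                  double y, double z) {
  double s = sin(ch.omega * t), c = cos(ch.omega * t);
  // omega^2 = 1 for omega = +/-1
  return -ch.k * ch.k - ch.RH * (y * c + z * s);
}

// Nearest point on the mid-curve.  Newton from t0 (axial projection or warm
// start), |g| < tol within itmax iterations, else bisection fallback over
// +/- one pitch around the axial estimate.  Returns t*; fills d and normal.
static int helix_nearest(const Channel& ch, double x, double y, double z,
                         double t0, double& tstar, double& d, double* nrm,
                         double tol = 1e-10, int itmax = 50) {
  if (ch.RH == 0.0) {
    tstar = x / ch.k;
    d = sqrt(y * y + z * z);
    if (d > 0) { nrm[0] = 0.0; nrm[1] = y / d; nrm[2] = z / d; }
    else { nrm[0] = nrm[1] = nrm[2] = 0.0; }
    return 0;
  }
  // Note g(t) = -(1/2) d|p - r0(t)|^2/dt, so the nearest point has
  // g(t*) = 0 with g'(t*) < 0 (a maximum of g would be a distance maximum).
  double t = t0;
  bool ok = false;
  for (int it = 0; it < itmax; ++it) {
    double g = helix_g(ch, t, x, y, z);
    if (fabs(g) < tol) { ok = (helix_gprime(ch, t, y, z) < 0.0); break; }
    double gp = helix_gprime(ch, t, y, z);
    if (gp == 0.0) break;
    double step = g / gp;
    // small trust region: never hop across stationary points of other loops
    if (step > 1.0) step = 1.0;
    if (step < -1.0) step = -1.0;
    t -= step;
  }
  // any true root lies within |t - x/k| <= RH*sqrt(y^2+z^2)/k^2 of the
  // axial projection; reject Newton roots outside a one-pitch window
  if (ok && fabs(t - x / ch.k) > 6.283185307179586) ok = false;
  if (!ok) {
    // global fallback: scan |p - r0(t)|^2 over +/- one pitch around the
    // axial projection, then bisect g on the best panel
    const int M = 128;
    double tc = x / ch.k, halfw = 6.283185307179586;
    double best_t = tc, best_d2 = HUGE_VAL;
    for (int i = 0; i <= M; ++i) {
      double ti = tc - halfw + 2.0 * halfw * i / M;
      double si = sin(ch.omega * ti), ci = cos(ch.omega * ti);
      double ddx = x - ch.k * ti, ddy = y - ch.RH * ci, ddz = z - ch.RH * si;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best_d2) { best_d2 = d2; best_t = ti; }
    }
    double ta = best_t - 2.0 * halfw / M, tb = best_t + 2.0 * halfw / M;
    double ga = helix_g(ch, ta, x, y, z), gb = helix_g(ch, tb, x, y, z);
    if (ga * gb > 0) {
      // fall back to golden-section on the distance itself
      const double gr = 0.6180339887498949;
      for (int it = 0; it < 120 && (tb - ta) > 1e-13; ++it) {
        double t1 = tb - gr * (tb - ta), t2 = ta + gr * (tb - ta);
        double s1 = sin(ch.omega * t1), c1 = cos(ch.omega * t1);
        double s2 = sin(ch.omega * t2), c2 = cos(ch.omega * t2);
        double d1 = (x - ch.k * t1) * (x - ch.k * t1) + (y - ch.RH * c1) * (y - ch.RH * c1) + (z - ch.RH * s1) * (z - ch.RH * s1);
        double d2v = (x - ch.k * t2) * (x - ch.k * t2) + (y - ch.RH * c2) * (y - ch.RH * c2) + (z - ch.RH * s2) * (z - ch.RH * s2);
        if (d1 < d2v) tb = t2; else ta = t1;
      }
      t = 0.5 * (ta + tb);
      ok = true;
    } else {
      for (int it = 0; it < 200; ++it) {
        double tm = 0.5 * (ta + tb), gm = helix_g(ch, tm, x, y, z);
        if (fabs(gm) < tol || (tb - ta) < 1e-14) { t = tm; ok = true; break; }
        if (ga * gm <= 0) { tb = tm; gb = gm; } else { ta = tm; ga = gm; }
      }
      if (!ok) return 1;
    }
  }
  tstar = t;
  double s = sin(ch.omega * t), c = cos(ch.omega * t);
  double dx = x - ch.k * t, dy = y - ch.RH * c, dz = z - ch.RH * s;
  d = sqrt(dx * dx + dy * dy + dz * dz);
  if (d > 0) { nrm[0] = dx / d; nrm[1] = dy / d; nrm[2] = dz / d; }
  else { nrm[0] = nrm[1] = nrm[2] = 0.0; }
  return 0;
}

//' @title Batch nearest-point solve on the helix mid-curve (internal kernel)
//' @noRd
// [[Rcpp::export(rng = false)]]
NumericMatrix helix_nearest_cpp(NumericMatrix pts, double Rch, double RH,
                                double k, double omega) {
  Channel ch{true, Rch, RH, k, omega};
  int n = pts.nrow();
  NumericMatrix out(n, 6);  // t*, d, nx, ny, nz, status
  for (int i = 0; i < n; ++i) {
    double tst, d, nrm[3];
    int status = helix_nearest(ch, pts(i, 0), pts(i, 1), pts(i, 2),
                               pts(i, 0) / k, tst, d, nrm);
    out(i, 0) = tst; out(i, 1) = d;
    out(i, 2) = nrm[0]; out(i, 3) = nrm[1]; out(i, 4) = nrm[2];
    out(i, 5) = status;
  }
  return out;
}

// WCA on a scalar gap with length scale sig: returns energy, sets dU/dg.
static inline double wca_gap(double g, double sig, double& dUdg) {
  double cut = WCA_CUT * sig;
  if (g >= cut) { dUdg = 0.0; return 0.0; }
  double s2 = (sig * sig) / (g * g);
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  dUdg = -(24.0 / g) * (2.0 * s12 - s6);
  return 4.0 * (s12 - s6) + 1.0;
}

// Fast thermal-noise stream: xoshiro256++ feeding a Marsaglia-Tsang
// ziggurat Gaussian sampler.  Seeded from R's RNG at run start, so
// trajectories remain deterministic under set.seed().
struct NoiseRng {
  uint64_t s[4];
  uint64_t buf;        // holds a spare 32-bit word from each 64-bit draw
  bool has_buf;
  static double wn[128], fn[128];
  static uint32_t kn[128];
  static bool tables_ready;

  static void zig_init() {
    if (tables_ready) return;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = sqrt(-2.0 * log(vn / dn + exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
    tables_ready = true;
  }
  static uint64_t splitmix64(uint64_t& z) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t r = z;
    r = (r ^ (r >> 30)) * 0xbf58476d1ce4e5b9ULL;
    r = (r ^ (r >> 27)) * 0x94d049bb133111ebULL;
    return r ^ (r >> 31);
  }
  void seed_from_R() {
    zig_init();
    uint64_t z = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                 (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(z);
    has_buf = false; buf = 0;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline uint32_t next32() {
    if (has_buf) { has_buf = false; return (uint32_t)(buf >> 32); }
    buf = next();
    has_buf = true;
    return (uint32_t)buf;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    for (;;) {
      int32_t hz = (int32_t)next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      if (iz == 0) {  // tail
        const double r = 3.442619855899;
        double x, y;
        do { x = -log(unif()) / r; y = -log(unif()); } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < exp(-0.5 * x * x)) return x;
    }
  }
};
double NoiseRng::wn[128];
double NoiseRng::fn[128];
uint32_t NoiseRng::kn[128];
bool NoiseRng::tables_ready = false;

//' Draw n samples from the engine's thermal-noise Gaussian (internal)
//' @noRd
// [[Rcpp::export]]
NumericVector noise_sample_cpp(int n) {
  NoiseRng rng;
  rng.seed_from_R();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.gauss();
  return out;
}

struct SimParams {
  double ks, r0, kb;          // kb is the prefactor c in U = c (theta - pi)^2
  double gamma, dt;
  Channel ch;
  bool bottom_wall;
  bool piston_on;
  double piston_F, piston_gamma, piston_offset, piston_radius;
  double skin;
  bool mirror_noise;
  bool piston_thermostat;
};

struct Workspace {
  std::vector<double> F;             // 3N forces
  std::vector<double> warm_t;        // warm-start parameters for the helix solve
  std::vector<int> nb_i, nb_j;       // neighbour list
  std::vector<double> ref_pos;       // positions at last list build
  double piston_reaction;            // x-force of chain on piston
  long n_rebuilds;
};

static void build_neighbour_list(const std::vector<double>& x, int N,
                                 double rl, Workspace& w) {
  w.nb_i.clear(); w.nb_j.clear();
  double rl2 = rl * rl;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 2; j < N; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < rl2) { w.nb_i.push_back(i); w.nb_j.push_back(j); }
    }
  }
  w.ref_pos = x;
  w.n_rebuilds++;
}

// Total force; returns potential energy.  use_list = false does an all-pairs
// sweep (used for validation and one-shot calls).
static double compute_forces(const std::vector<double>& x, int N,
                             const SimParams& p, double piston_x,
                             Workspace& w, bool use_list) {
  double U = 0.0;
  std::fill(w.F.begin(), w.F.end(), 0.0);
  w.piston_reaction = 0.0;

  // bonds: U = ks (r - r0)^2
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double r = sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("degenerate bond (coincident beads) at bead %d", i + 1);
    double dr = r - p.r0;
    U += p.ks * dr * dr;
    double fmag = -2.0 * p.ks * dr / r;  // along the bond, on bead i+1
    w.F[3 * (i + 1)] += fmag * dx; w.F[3 * (i + 1) + 1] += fmag * dy; w.F[3 * (i + 1) + 2] += fmag * dz;
    w.F[3 * i] -= fmag * dx; w.F[3 * i + 1] -= fmag * dy; w.F[3 * i + 2] -= fmag * dz;
  }

  // angles: U = kb (theta - pi)^2 at each interior bead
  for (int j = 1; j < N - 1; ++j) {
    double ax = x[3 * (j - 1)] - x[3 * j], ay = x[3 * (j - 1) + 1] - x[3 * j + 1], az = x[3 * (j - 1) + 2] - x[3 * j + 2];
    double bx = x[3 * (j + 1)] - x[3 * j], by = x[3 * (j + 1) + 1] - x[3 * j + 1], bz = x[3 * (j + 1) + 2] - x[3 * j + 2];
    double la = sqrt(ax * ax + ay * ay + az * az), lb = sqrt(bx * bx + by * by + bz * bz);
    if (la <= 0 || lb <= 0) stop("degenerate angle triplet at bead %d", j + 1);
    double cth = (ax * bx + ay * by + az * bz) / (la * lb);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    double th = acos(cth);
    double dth = th - M_PI;
    U += p.kb * dth * dth;
    double sth = sqrt(1.0 - cth * cth);
    // w = (dU/dtheta)/sin(theta); finite limit -2 kb as theta -> pi
    double wcoef = (sth > 1e-9) ? (2.0 * p.kb * dth / sth) : (-2.0 * p.kb);
    double uax = ax / la, uay = ay / la, uaz = az / la;
    double ubx = bx / lb, uby = by / lb, ubz = bz / lb;
    double f1x = (wcoef / la) * (ubx - cth * uax);
    double f1y = (wcoef / la) * (uby - cth * uay);
    double f1z = (wcoef / la) * (ubz - cth * uaz);
    double f3x = (wcoef / lb) * (uax - cth * ubx);
    double f3y = (wcoef / lb) * (uay - cth * uby);
    double f3z = (wcoef / lb) * (uaz - cth * ubz);
    w.F[3 * (j - 1)] += f1x; w.F[3 * (j - 1) + 1] += f1y; w.F[3 * (j - 1) + 2] += f1z;
    w.F[3 * (j + 1)] += f3x; w.F[3 * (j + 1) + 1] += f3y; w.F[3 * (j + 1) + 2] += f3z;
    w.F[3 * j] -= (f1x + f3x); w.F[3 * j + 1] -= (f1y + f3y); w.F[3 * j + 2] -= (f1z + f3z);
  }

  // excluded volume (WCA), all pairs except directly bonded neighbours
  const double cut2 = WCA_CUT * WCA_CUT;
  size_t npair = use_list ? w.nb_i.size() : 0;
  if (use_list) {
    for (size_t m = 0; m < npair; ++m) {
      int i = w.nb_i[m], j = w.nb_j[m];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1], dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      if (r2 < 1e-12) stop("overlapping beads %d and %d", i + 1, j + 1);
      double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
      U += 4.0 * (s12 - s6) + 1.0;
      double fr = 24.0 * (2.0 * s12 - s6) / r2;  // (1/r) dU/dr with sign folded
      w.F[3 * i] += fr * dx; w.F[3 * i + 1] += fr * dy; w.F[3 * i + 2] += fr * dz;
      w.F[3 * j] -= fr * dx; w.F[3 * j + 1] -= fr * dy; w.F[3 * j + 2] -= fr * dz;
    }
  } else {
    for (int i = 0; i < N; ++i) {
      for (int j = i + 2; j < N; ++j) {
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1], dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cut2) continue;
        if (r2 < 1e-12) stop("overlapping beads %d and %d", i + 1, j + 1);
        double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
        U += 4.0 * (s12 - s6) + 1.0;
        double fr = 24.0 * (2.0 * s12 - s6) / r2;
        w.F[3 * i] += fr * dx; w.F[3 * i + 1] += fr * dy; w.F[3 * i + 2] += fr * dz;
        w.F[3 * j] -= fr * dx; w.F[3 * j + 1] -= fr * dy; w.F[3 * j + 2] -= fr * dz;
      }
    }
  }

  // channel wall (implicit): WCA on the surface gap R_ch - d
  if (p.ch.active) {
    // d <= rho + R_H (rho = distance from the axis), so beads with
    // rho + R_H < R_ch - cutoff cannot feel the wall: skip the solve
    double safe = p.ch.Rch - WALL_CUT - p.ch.RH;
    double safe2 = (safe > 0) ? safe * safe : -1.0;
    for (int i = 0; i < N; ++i) {
      double rho2 = x[3 * i + 1] * x[3 * i + 1] + x[3 * i + 2] * x[3 * i + 2];
      if (rho2 < safe2) {
        if (!w.warm_t.empty()) w.warm_t[i] = x[3 * i] / p.ch.k;
        continue;
      }
      double tst, d, nrm[3];
      double t0 = (w.warm_t.empty()) ? x[3 * i] / p.ch.k : w.warm_t[i];
      int status = helix_nearest(p.ch, x[3 * i], x[3 * i + 1], x[3 * i + 2], t0, tst, d, nrm);
      if (status != 0)
        stop("helix nearest-point solver failed for bead %d", i + 1);
      if (!w.warm_t.empty()) w.warm_t[i] = tst;
      double gap = p.ch.Rch - d;
      if (gap <= 0)
        stop("bead %d outside the channel wall (d = %g > R_ch = %g)", i + 1, d, p.ch.Rch);
      if (gap < WALL_CUT) {
        double dUdg;
        U += wca_gap(gap, WALL_SIG, dUdg);
        // dg/dd = -1 -> force along -normal with magnitude -dU/dg
        double fmag = dUdg;  // F_d = dU/dg (negative) along +normal
        w.F[3 * i] += fmag * nrm[0]; w.F[3 * i + 1] += fmag * nrm[1]; w.F[3 * i + 2] += fmag * nrm[2];
      }
    }
  }

  // bottom wall at x = 0: WCA on the gap x
  if (p.bottom_wall) {
    for (int i = 0; i < N; ++i) {
      double g = x[3 * i];
      if (g <= 0) stop("bead %d penetrated the bottom wall (x = %g)", i + 1, g);
      if (g < WALL_CUT) {
        double dUdg;
        U += wca_gap(g, WALL_SIG, dUdg);
        w.F[3 * i] += -dUdg;  // repulsion along +x
      }
    }
  }

  // piston: WCA on (r - offset) from the piston centre (x_p, 0, 0)
  if (p.piston_on) {
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - piston_x, dy = x[3 * i + 1], dz = x[3 * i + 2];
      double r = sqrt(dx * dx + dy * dy + dz * dz);
      double s = r - p.piston_offset;
      if (s < WCA_CUT) {
        if (s <= 0) stop("bead %d penetrated the piston surface", i + 1);
        double dUds;
        U += wca_gap(s, 1.0, dUds);
        double fmag = -dUds / r;  // repulsive, along (p - centre)
        w.F[3 * i] += fmag * dx; w.F[3 * i + 1] += fmag * dy; w.F[3 * i + 2] += fmag * dz;
        w.piston_reaction += -fmag * dx;  // reaction on the piston (x only)
      }
    }
  }

  return U;
}

//' One-shot total force/energy evaluation (internal kernel)
//' @noRd
// [[Rcpp::export(rng = false)]]
List forces_cpp(NumericMatrix pos, double ks, double r0, double kb,
                bool channel_on, double Rch, double RH, double k, double omega,
                bool bottom_wall, bool piston_on, double piston_x,
                double piston_offset) {
  int N = pos.nrow();
  SimParams p;
  p.ks = ks; p.r0 = r0; p.kb = kb;
  p.ch = Channel{channel_on, Rch, RH, k, omega};
  p.bottom_wall = bottom_wall;
  p.piston_on = piston_on;
  p.piston_offset = piston_offset;
  Workspace w;
  w.F.assign(3 * N, 0.0);
  w.n_rebuilds = 0;
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  double U = compute_forces(x, N, p, piston_x, w, false);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = w.F[3 * i + d];
  return List::create(_["forces"] = F, _["energy"] = U,
                      _["piston_reaction"] = w.piston_reaction);
}

//' BAOAB Langevin integrator (internal kernel)
//' @noRd
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos0, NumericMatrix vel0,
                double ks, double r0, double kb, double gamma, double dt,
                double n_steps_d, int sample_every,
                bool channel_on, double Rch, double RH, double k, double omega,
                bool bottom_wall,
                bool piston_on, double piston_x0, double piston_F,
                double piston_gamma, double piston_offset,
                double skin, bool mirror_noise, bool piston_thermostat,
                bool store_velocities) {
  long n_steps = (long) n_steps_d;
  int N = pos0.nrow();
  SimParams p;
  p.ks = ks; p.r0 = r0; p.kb = kb; p.gamma = gamma; p.dt = dt;
  p.ch = Channel{channel_on, Rch, RH, k, omega};
  p.bottom_wall = bottom_wall;
  p.piston_on = piston_on; p.piston_F = piston_F;
  p.piston_gamma = piston_gamma; p.piston_offset = piston_offset;
  p.skin = skin; p.mirror_noise = mirror_noise;
  p.piston_thermostat = piston_thermostat;

  std::vector<double> x(3 * N), v(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = pos0(i, d); v[3 * i + d] = vel0(i, d); }

  Workspace w;
  w.F.assign(3 * N, 0.0);
  w.n_rebuilds = 0;
  if (channel_on) {
    w.warm_t.assign(N, 0.0);
    for (int i = 0; i < N; ++i) w.warm_t[i] = x[3 * i] / k;
  }
  double rl = WCA_CUT + skin;
  build_neighbour_list(x, N, rl, w);

  double piston_x = piston_x0;
  double c1 = (gamma > 0) ? exp(-gamma * dt) : 1.0;
  double c2 = sqrt(1.0 - c1 * c1);  // kT = 1, m = 1
  double noise_sign = mirror_noise ? -1.0 : 1.0;
  double half_dt = 0.5 * dt;

  long n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector frames(n_samples > 0 ? n_samples * N * 3 : 0);
  NumericVector vframes(store_velocities && n_samples > 0 ? n_samples * N * 3 : 0);
  NumericVector piston_trace(n_samples > 0 ? n_samples : 0);
  NumericVector times(n_samples > 0 ? n_samples : 0);
  long isample = 0;

  NoiseRng rng;
  rng.seed_from_R();
  double U = compute_forces(x, N, p, piston_x, w, true);
  (void) U;
  std::vector<double> xprev(3 * N);
  bool piston_clamped = false;

  for (long step = 0; step < n_steps; ++step) {
    xprev = x;
    // B
    for (int i = 0; i < 3 * N; ++i) v[i] += half_dt * w.F[i];
    // A
    for (int i = 0; i < 3 * N; ++i) x[i] += half_dt * v[i];
    // O (skip drawing when thermostat disabled to keep NVE limit exact)
    if (gamma > 0) {
      for (int i = 0; i < N; ++i) {
        double nx = rng.gauss(), ny = rng.gauss(), nz = noise_sign * rng.gauss();
        v[3 * i] = c1 * v[3 * i] + c2 * nx;
        v[3 * i + 1] = c1 * v[3 * i + 1] + c2 * ny;
        v[3 * i + 2] = c1 * v[3 * i + 2] + c2 * nz;
      }
    }
    // A
    for (int i = 0; i < 3 * N; ++i) x[i] += half_dt * v[i];

    // stability check: displacement per step
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - xprev[3 * i], dy = x[3 * i + 1] - xprev[3 * i + 1], dz = x[3 * i + 2] - xprev[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > 0.25)
        stop("integration instability: bead %d moved more than 0.5 sigma at step %ld", i + 1, step + 1);
    }

    // neighbour list maintenance (displacement-triggered)
    double max_disp2 = 0.0, thr = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - w.ref_pos[3 * i], dy = x[3 * i + 1] - w.ref_pos[3 * i + 1], dz = x[3 * i + 2] - w.ref_pos[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max_disp2) max_disp2 = d2;
    }
    if (max_disp2 > thr) build_neighbour_list(x, N, rl, w);

    // forces at new positions; accumulates the chain's reaction on the piston
    compute_forces(x, N, p, piston_x, w, true);

    // piston: overdamped 1-D Langevin along the axis
    if (p.piston_on) {
      double drift = (-p.piston_F + w.piston_reaction) * dt / p.piston_gamma;
      double kick = p.piston_thermostat ? sqrt(2.0 * dt / p.piston_gamma) * rng.gauss() : 0.0;
      piston_x += drift + kick;
      if (piston_x < p.piston_offset) { piston_x = p.piston_offset; piston_clamped = true; }
    }

    // B
    for (int i = 0; i < 3 * N; ++i) v[i] += half_dt * w.F[i];

    if (sample_every > 0 && ((step + 1) % sample_every == 0) && isample < n_samples) {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          frames[isample + n_samples * ((long) i + (long) N * d)] = x[3 * i + d];
      if (store_velocities)
        for (int i = 0; i < N; ++i)
          for (int d = 0; d < 3; ++d)
            vframes[isample + n_samples * ((long) i + (long) N * d)] = v[3 * i + d];
      piston_trace[isample] = piston_x;
      times[isample] = (step + 1) * dt;
      isample++;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix posf(N, 3), velf(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { posf(i, d) = x[3 * i + d]; velf(i, d) = v[3 * i + d]; }
  if (n_samples > 0) frames.attr("dim") = IntegerVector::create(n_samples, N, 3);
  if (store_velocities && n_samples > 0) vframes.attr("dim") = IntegerVector::create(n_samples, N, 3);
  return List::create(
    _["frames"] = frames, _["vframes"] = vframes,
    _["times"] = times, _["piston_x"] = piston_trace,
    _["pos"] = posf, _["vel"] = velf,
    _["piston_final"] = piston_x, _["piston_clamped"] = piston_clamped,
    _["n_list_rebuilds"] = (double) w.n_rebuilds);
}
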