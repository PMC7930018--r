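// Coarse-grained bead dynamics: potential energy, analytic forces and a
// BAOAB Langevin integrator.  Energies kcal/mol, distances Angstrom, time ps,
// masses in kcal/mol ps^2/A^2 (1 unit ~ 418.4 amu).  All quadratic terms use
// the no-1/2 convention E = k * delta^2.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double RGAS = 1.9872e-3; // kcal/mol/K

// ---------------------------------------------------------------------------
// deterministic RNG: mt19937_64 + Box-Muller (fully specified, portable)
struct Rng {
  std::mt19937_64 mt;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : mt(seed), have_spare(false), spare(0.0) {}
  double unif() { // in (0, 1]
    uint64_t x = mt();
    return ((x >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
struct System {
  int n;                    // mobile beads
  int m;                    // fixed beads
  int active_dims;          // 1 (x only) or 3
  std::vector<double> fx;   // fixed coords, m x 3 row-major
  std::vector<double> mass; // n
  // bonds: i, j (0-based, mobile), k, r0
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  // per-bead external potential: quartic double-well along an axis, tether,
  // and an optional Gaussian pocket well
  std::vector<int> has_dw, dw_axis;
  std::vector<double> dw_a, dw_b, dw_c, dw_x0;
  std::vector<double> teth_k;  // n x 3
  std::vector<double> teth_c;  // n x 3
  std::vector<int> has_gw;
  std::vector<double> gw_depth, gw_width;
  std::vector<double> gw_c;    // n x 3
  // nonbonded parameter matrices (0 = none, 1 = LJ, 2 = repulsive r^-12)
  std::vector<int> type_mm;    // n x n
  std::vector<double> eps_mm, sig_mm;
  std::vector<int> type_mf;    // n x m
  std::vector<double> eps_mf, sig_mf;
  std::vector<int> mol;        // molecule id per mobile bead (for wrapping)
  double box[3];               // 0 => non-periodic
};

struct Restraint {
  int kind; // 1 fb_pair, 2 com_hold, 3 cylinder, 4 umbrella, 5 position_hold
  int i, jfixed, j;
  double lo, hi, k;
  std::vector<int> idx;
  double origin[3], axis[3];
  double radius, center, flat_r;
  std::vector<double> ref; // position_hold reference coords
};

// B(E) on [emin, emax] with linear extrapolation outside; either a
// polynomial in E or a piecewise-linear grid (the default representation).
struct Bias {
  bool grid_mode;
  std::vector<double> coef;   // ascending powers (poly mode)
  std::vector<double> ge, gb; // grid mode: energies (sorted) and values
  double emin, emax, b_lo, b_hi, slope_lo, slope_hi;
  double max_scale; // stability clamp on the force scale |1 + dB/dE|
  double force_scale(double e) const {
    double s = 1.0 + deriv(e);
    if (s > max_scale) s = max_scale;
    if (s < -max_scale) s = -max_scale;
    return s;
  }
  int seg(double e) const { // grid segment index for emin <= e <= emax
    int lo = 0, hi = (int)ge.size() - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (ge[mid] <= e) lo = mid; else hi = mid;
    }
    return lo;
  }
  double value(double e) const {
    if (e < emin) return b_lo + slope_lo * (e - emin);
    if (e > emax) return b_hi + slope_hi * (e - emax);
    if (grid_mode) {
      int s = seg(e);
      double t = (e - ge[s]) / (ge[s + 1] - ge[s]);
      return gb[s] + t * (gb[s + 1] - gb[s]);
    }
    double v = 0.0, p = 1.0;
    for (size_t i = 0; i < coef.size(); ++i) { v += coef[i] * p; p *= e; }
    return v;
  }
  double deriv(double e) const {
    if (e < emin) return slope_lo;
    if (e > emax) return slope_hi;
    if (grid_mode) {
      int s = seg(e);
      return (gb[s + 1] - gb[s]) / (ge[s + 1] - ge[s]);
    }
    double v = 0.0, p = 1.0;
    for (size_t i = 1; i < coef.size(); ++i) { v += i * coef[i] * p; p *= e; }
    return v;
  }
};

static inline void min_image(double* d, const double* box) {
  for (int k = 0; k < 3; ++k)
    if (box[k] > 0.0) d[k] -= box[k] * std::round(d[k] / box[k]);
}

static System parse_system(const List& sys) {
  System S;
  NumericMatrix fx = sys["fixed"];
  S.m = fx.nrow();
  S.fx.resize(S.m * 3);
  for (int i = 0; i < S.m; ++i)
    for (int k = 0; k < 3; ++k) S.fx[3 * i + k] = fx(i, k);
  NumericVector mass = sys["mass"];
  S.n = mass.size();
  S.mass.assign(mass.begin(), mass.end());
  S.active_dims = as<int>(sys["active_dims"]);
  NumericVector box = sys["box"];
  for (int k = 0; k < 3; ++k) S.box[k] = box[k];
  NumericMatrix bonds = sys["bonds"];
  for (int r = 0; r < bonds.nrow(); ++r) {
    S.bi.push_back((int)bonds(r, 0) - 1);
    S.bj.push_back((int)bonds(r, 1) - 1);
    S.bk.push_back(bonds(r, 2));
    S.br0.push_back(bonds(r, 3));
  }
  NumericMatrix ext = sys["ext"]; // n x 18
  S.has_dw.resize(S.n); S.dw_axis.resize(S.n);
  S.dw_a.resize(S.n); S.dw_b.resize(S.n); S.dw_c.resize(S.n); S.dw_x0.resize(S.n);
  S.teth_k.resize(S.n * 3); S.teth_c.resize(S.n * 3);
  S.has_gw.resize(S.n); S.gw_depth.resize(S.n); S.gw_width.resize(S.n);
  S.gw_c.resize(S.n * 3);
  bool wide = ext.ncol() >= 18;
  for (int i = 0; i < S.n; ++i) {
    S.has_dw[i] = (int)ext(i, 0);
    S.dw_axis[i] = (int)ext(i, 1);
    S.dw_a[i] = ext(i, 2); S.dw_b[i] = ext(i, 3);
    S.dw_c[i] = ext(i, 4); S.dw_x0[i] = ext(i, 5);
    for (int k = 0; k < 3; ++k) {
      S.teth_k[3 * i + k] = ext(i, 6 + k);
      S.teth_c[3 * i + k] = ext(i, 9 + k);
    }
    S.has_gw[i] = wide ? (int)ext(i, 12) : 0;
    if (S.has_gw[i]) {
      S.gw_depth[i] = ext(i, 13); S.gw_width[i] = ext(i, 14);
      for (int k = 0; k < 3; ++k) S.gw_c[3 * i + k] = ext(i, 15 + k);
    }
  }
  IntegerMatrix tmm = sys["type_mm"];
  NumericMatrix emm = sys["eps_mm"], smm = sys["sig_mm"];
  S.type_mm.resize(S.n * S.n); S.eps_mm.resize(S.n * S.n); S.sig_mm.resize(S.n * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int j = 0; j < S.n; ++j) {
      S.type_mm[i * S.n + j] = tmm(i, j);
      S.eps_mm[i * S.n + j] = emm(i, j);
      S.sig_mm[i * S.n + j] = smm(i, j);
    }
  S.mol.resize(S.n);
  if (sys.containsElementNamed("mol") && !Rf_isNull(sys["mol"])) {
    IntegerVector mol = sys["mol"];
    for (int i = 0; i < S.n; ++i) S.mol[i] = mol[i];
  } else {
    for (int i = 0; i < S.n; ++i) S.mol[i] = i;
  }
  IntegerMatrix tmf = sys["type_mf"];
  NumericMatrix emf = sys["eps_mf"], smf = sys["sig_mf"];
  S.type_mf.resize(S.n * S.m); S.eps_mf.resize(S.n * S.m); S.sig_mf.resize(S.n * S.m);
  for (int i = 0; i < S.n; ++i)
    for (int j = 0; j < S.m; ++j) {
      S.type_mf[i * S.m + j] = tmf(i, j);
      S.eps_mf[i * S.m + j] = emf(i, j);
      S.sig_mf[i * S.m + j] = smf(i, j);
    }
  return S;
}

static std::vector<Restraint> parse_restraints(const List& rl) {
  std::vector<Restraint> out;
  for (int r = 0; r < rl.size(); ++r) {
    List el = rl[r];
    Restraint R;
    std::string kind = as<std::string>(el["kind"]);
    if (kind == "flat_bottom_pair") {
      R.kind = 1;
      R.i = as<int>(el["i"]) - 1;
      R.jfixed = as<std::string>(el["j_kind"]) == "fixed" ? 1 : 0;
      R.j = as<int>(el["j"]) - 1;
      R.lo = as<double>(el["lo"]); R.hi = as<double>(el["hi"]);
      R.k = as<double>(el["k"]);
    } else if (kind == "com_hold" || kind == "cylinder" || kind == "umbrella_lambda") {
      IntegerVector idx = el["idx"];
      for (int q = 0; q < idx.size(); ++q) R.idx.push_back(idx[q] - 1);
      NumericVector o = el["origin"];
      for (int k = 0; k < 3; ++k) R.origin[k] = o[k];
      R.k = as<double>(el["k"]);
      if (kind == "com_hold") {
        R.kind = 2; R.flat_r = as<double>(el["flat_radius"]);
      } else {
        NumericVector a = el["axis"];
        double nrm = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
        for (int k = 0; k < 3; ++k) R.axis[k] = a[k] / nrm;
        if (kind == "cylinder") { R.kind = 3; R.radius = as<double>(el["radius"]); }
        else { R.kind = 4; R.center = as<double>(el["center"]); }
      }
    } else if (kind == "position_hold") {
      R.kind = 5;
      IntegerVector idx = el["idx"];
      for (int q = 0; q < idx.size(); ++q) R.idx.push_back(idx[q] - 1);
      NumericMatrix ref = el["ref"];
      for (int q = 0; q < ref.nrow(); ++q)
        for (int k = 0; k < 3; ++k) R.ref.push_back(ref(q, k));
      R.k = as<double>(el["k"]);
    } else {
      stop("unknown restraint kind: " + kind);
    }
    out.push_back(R);
  }
  return out;
}

static Bias parse_bias(const List& bl) {
  Bias B;
  B.grid_mode = false;
  if (bl.containsElementNamed("grid_e") && !Rf_isNull(bl["grid_e"])) {
    B.grid_mode = true;
    NumericVector ge = bl["grid_e"], gb = bl["grid_b"];
    B.ge.assign(ge.begin(), ge.end());
    B.gb.assign(gb.begin(), gb.end());
  } else {
    NumericVector coef = bl["coef"];
    B.coef.assign(coef.begin(), coef.end());
  }
  B.emin = as<double>(bl["emin"]); B.emax = as<double>(bl["emax"]);
  // continuity values/slopes at the edges
  B.slope_lo = 0.0; B.slope_hi = 0.0;
  if (!B.grid_mode) {
    double p = 1.0, v = 0.0;
    for (size_t i = 1; i < B.coef.size(); ++i) { v += i * B.coef[i] * p; p *= B.emin; }
    B.slope_lo = v;
    p = 1.0; v = 0.0;
    for (size_t i = 1; i < B.coef.size(); ++i) { v += i * B.coef[i] * p; p *= B.emax; }
    B.slope_hi = v;
  }
  if (bl.containsElementNamed("slope_lo") && !Rf_isNull(bl["slope_lo"]))
    B.slope_lo = as<double>(bl["slope_lo"]);
  if (bl.containsElementNamed("slope_hi") && !Rf_isNull(bl["slope_hi"]))
    B.slope_hi = as<double>(bl["slope_hi"]);
  B.max_scale = 4.0;
  if (bl.containsElementNamed("max_scale") && !Rf_isNull(bl["max_scale"]))
    B.max_scale = as<double>(bl["max_scale"]);
  if (B.grid_mode) {
    B.b_lo = B.gb.front();
    B.b_hi = B.gb.back();
  } else {
    double p = 1.0; B.b_lo = 0.0;
    for (size_t i = 0; i < B.coef.size(); ++i) { B.b_lo += B.coef[i] * p; p *= B.emin; }
    p = 1.0; B.b_hi = 0.0;
    for (size_t i = 0; i < B.coef.size(); ++i) { B.b_hi += B.coef[i] * p; p *= B.emax; }
  }
  return B;
}

// energy + forces; returns physical and restraint parts separately.
// f (n x 3) is overwritten with -dE/dx of (physical + restraint) terms.
static void eval_energy(const System& S, const std::vector<Restraint>& rs,
                        const double* x, double* f,
                        double& e_phys, double& e_restr) {
  const int n = S.n;
  e_phys = 0.0; e_restr = 0.0;
  for (int i = 0; i < 3 * n; ++i) f[i] = 0.0;

  // bonds
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
    min_image(d, S.box);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double dr = r - S.br0[b];
    e_phys += S.bk[b] * dr * dr;
    if (r > 1e-12) {
      double g = 2.0 * S.bk[b] * dr / r;
      for (int k = 0; k < 3; ++k) { f[3*i+k] -= g * d[k]; f[3*j+k] += g * d[k]; }
    }
  }

  // per-bead external terms
  for (int i = 0; i < n; ++i) {
    if (S.has_dw[i]) {
      int ax = S.dw_axis[i];
      double s = x[3*i + ax] - S.dw_x0[i];
      double q = s * s - S.dw_b[i] * S.dw_b[i];
      e_phys += S.dw_a[i] * q * q + S.dw_c[i] * s;
      f[3*i + ax] -= 4.0 * S.dw_a[i] * q * s + S.dw_c[i];
    }
    for (int k = 0; k < 3; ++k) {
      double kk = S.teth_k[3*i+k];
      if (kk > 0.0) {
        double d = x[3*i+k] - S.teth_c[3*i+k];
        e_phys += kk * d * d;
        f[3*i+k] -= 2.0 * kk * d;
      }
    }
    if (S.has_gw[i]) {
      double d[3] = { x[3*i] - S.gw_c[3*i], x[3*i+1] - S.gw_c[3*i+1],
                      x[3*i+2] - S.gw_c[3*i+2] };
      min_image(d, S.box);
      double w2 = S.gw_width[i] * S.gw_width[i];
      double g = std::exp(-(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]) / (2.0 * w2));
      e_phys += -S.gw_depth[i] * g;
      for (int k = 0; k < 3; ++k)
        f[3*i+k] -= S.gw_depth[i] * g * d[k] / w2;
    }
  }

  // nonbonded mobile-mobile
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int t = S.type_mm[i * n + j];
      if (t == 0) continue;
      double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
      min_image(d, S.box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < 1e-12) r2 = 1e-12;
      double sig = S.sig_mm[i * n + j], eps = S.eps_mm[i * n + j];
      double s2 = sig * sig / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
      double e, dEdr2; // dE/d(r^2)
      if (t == 1) { e = eps * (s12 - 2.0 * s6); dEdr2 = eps * (-12.0*s12 + 12.0*s6) / (2.0*r2); }
      else        { e = eps * s12;              dEdr2 = eps * (-12.0*s12) / (2.0*r2); }
      e_phys += e;
      double g = 2.0 * dEdr2;
      for (int k = 0; k < 3; ++k) { f[3*i+k] -= g * d[k]; f[3*j+k] += g * d[k]; }
    }

  // nonbonded mobile-fixed
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S.m; ++j) {
      int t = S.type_mf[i * S.m + j];
      if (t == 0) continue;
      double d[3] = { x[3*i] - S.fx[3*j], x[3*i+1] - S.fx[3*j+1], x[3*i+2] - S.fx[3*j+2] };
      min_image(d, S.box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < 1e-12) r2 = 1e-12;
      double sig = S.sig_mf[i * S.m + j], eps = S.eps_mf[i * S.m + j];
      double s2 = sig * sig / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
      double e, dEdr2;
      if (t == 1) { e = eps * (s12 - 2.0 * s6); dEdr2 = eps * (-12.0*s12 + 12.0*s6) / (2.0*r2); }
      else        { e = eps * s12;              dEdr2 = eps * (-12.0*s12) / (2.0*r2); }
      e_phys += e;
      double g = 2.0 * dEdr2;
      for (int k = 0; k < 3; ++k) f[3*i+k] -= g * d[k];
    }

  // restraints
  for (size_t r = 0; r < rs.size(); ++r) {
    const Restraint& R = rs[r];
    if (R.kind == 1) {
      double xj[3];
      if (R.jfixed) for (int k = 0; k < 3; ++k) xj[k] = S.fx[3*R.j+k];
      else          for (int k = 0; k < 3; ++k) xj[k] = x[3*R.j+k];
      double d[3] = { x[3*R.i] - xj[0], x[3*R.i+1] - xj[1], x[3*R.i+2] - xj[2] };
      min_image(d, S.box);
      double dist = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      double dr = 0.0;
      if (dist > R.hi) dr = dist - R.hi;
      else if (dist < R.lo) dr = dist - R.lo;
      if (dr != 0.0) {
        e_restr += R.k * dr * dr;
        if (dist > 1e-12) {
          double g = 2.0 * R.k * dr / dist;
          for (int k = 0; k < 3; ++k) {
            f[3*R.i+k] -= g * d[k];
            if (!R.jfixed) f[3*R.j+k] += g * d[k];
          }
        }
      }
    } else if (R.kind == 2 || R.kind == 3 || R.kind == 4) {
      double com[3] = {0, 0, 0}, mtot = 0.0;
      for (size_t q = 0; q < R.idx.size(); ++q) {
        int i = R.idx[q];
        for (int k = 0; k < 3; ++k) com[k] += S.mass[i] * x[3*i+k];
        mtot += S.mass[i];
      }
      for (int k = 0; k < 3; ++k) com[k] /= mtot;
      double dcom[3] = {0, 0, 0}; // dE/dcom
      if (R.kind == 2) {
        double d[3] = { com[0]-R.origin[0], com[1]-R.origin[1], com[2]-R.origin[2] };
        double dist = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        if (dist > R.flat_r) {
          double dr = dist - R.flat_r;
          e_restr += R.k * dr * dr;
          double g = 2.0 * R.k * dr / std::max(dist, 1e-12);
          for (int k = 0; k < 3; ++k) dcom[k] = g * d[k];
        }
      } else if (R.kind == 3) {
        double d[3] = { com[0]-R.origin[0], com[1]-R.origin[1], com[2]-R.origin[2] };
        double lam = d[0]*R.axis[0] + d[1]*R.axis[1] + d[2]*R.axis[2];
        double dp[3] = { d[0]-lam*R.axis[0], d[1]-lam*R.axis[1], d[2]-lam*R.axis[2] };
        double rho = std::sqrt(dp[0]*dp[0] + dp[1]*dp[1] + dp[2]*dp[2]);
        if (rho > R.radius) {
          double dr = rho - R.radius;
          e_restr += R.k * dr * dr;
          double g = 2.0 * R.k * dr / std::max(rho, 1e-12);
          for (int k = 0; k < 3; ++k) dcom[k] = g * dp[k];
        }
      } else {
        double d[3] = { com[0]-R.origin[0], com[1]-R.origin[1], com[2]-R.origin[2] };
        double lam = d[0]*R.axis[0] + d[1]*R.axis[1] + d[2]*R.axis[2];
        double dl = lam - R.center;
        e_restr += R.k * dl * dl;
        for (int k = 0; k < 3; ++k) dcom[k] = 2.0 * R.k * dl * R.axis[k];
      }
      for (size_t q = 0; q < R.idx.size(); ++q) {
        int i = R.idx[q];
        double w = S.mass[i] / mtot;
        for (int k = 0; k < 3; ++k) f[3*i+k] -= w * dcom[k];
      }
    } else if (R.kind == 5) {
      for (size_t q = 0; q < R.idx.size(); ++q) {
        int i = R.idx[q];
        for (int k = 0; k < 3; ++k) {
          double d = x[3*i+k] - R.ref[3*q+k];
          e_restr += R.k * d * d;
          f[3*i+k] -= 2.0 * R.k * d;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List energy_cpp(List sys, NumericMatrix coords, List restraints) {
  System S = parse_system(sys);
  if (coords.nrow() != S.n) stop("coordinate/selection mismatch: expected %d mobile beads, got %d rows", S.n, coords.nrow());
  std::vector<Restraint> rs = parse_restraints(restraints);
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  double ep, er;
  eval_energy(S, rs, x.data(), f.data(), ep, er);
  NumericMatrix force(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) force(i, k) = f[3*i+k];
  return List::create(_["physical"] = ep, _["restraint"] = er,
                      _["total"] = ep + er, _["force"] = force);
}

// [[Rcpp::export]]
List run_dynamics_cpp(List sys, List restraints, SEXP bias_sexp,
                      NumericMatrix init_coords, SEXP init_vel_sexp,
                      int n_steps, double dt, double gamma,
                      NumericVector temperature, // scalar or length n_steps
                      int save_every, double seed,
                      List observer) {
  System S = parse_system(sys);
  std::vector<Restraint> rs = parse_restraints(restraints);
  bool has_bias = !Rf_isNull(bias_sexp);
  Bias B;
  if (has_bias) B = parse_bias(List(bias_sexp));

  const int n = S.n;
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = init_coords(i, k);

  Rng rng((uint64_t)seed);
  double T0 = temperature[0];
  bool tvec = temperature.size() > 1;
  if (tvec && temperature.size() != n_steps) stop("temperature vector must have length n_steps");

  int adim = S.active_dims;
  if (!Rf_isNull(init_vel_sexp)) {
    NumericMatrix iv(init_vel_sexp);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k) v[3*i+k] = iv(i, k);
  } else if (T0 > 0.0) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k)
        v[3*i+k] = std::sqrt(RGAS * T0 / S.mass[i]) * rng.norm();
  }

  // observer: optional lambda = dot(com(idx) - origin, axis) time series
  bool has_obs = observer.size() > 0;
  std::vector<int> obs_idx;
  double obs_origin[3] = {0,0,0}, obs_axis[3] = {0,0,0};
  int obs_every = 0;
  if (has_obs) {
    IntegerVector oi = observer["idx"];
    for (int q = 0; q < oi.size(); ++q) obs_idx.push_back(oi[q] - 1);
    NumericVector oo = observer["origin"], oa = observer["axis"];
    double nrm = std::sqrt(oa[0]*oa[0] + oa[1]*oa[1] + oa[2]*oa[2]);
    for (int k = 0; k < 3; ++k) { obs_origin[k] = oo[k]; obs_axis[k] = oa[k] / nrm; }
    obs_every = as<int>(observer["every"]);
  }

  int n_save = n_steps / save_every;
  NumericMatrix out_x(n_save, 3 * n);
  NumericVector out_ep(n_save), out_er(n_save), out_eb(n_save), out_ek(n_save);
  IntegerVector out_step(n_save);
  std::vector<double> lam_series;

  double ep, er;
  eval_energy(S, rs, x.data(), f.data(), ep, er);
  if (!std::isfinite(ep + er)) stop("non-finite energy at step 0 (overlapping configuration?)");
  double scale = has_bias ? B.force_scale(ep + er) : 1.0;

  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double T = tvec ? temperature[step - 1] : T0;
    double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
    double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;

    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k)
        v[3*i+k] += 0.5 * dt * scale * f[3*i+k] / S.mass[i];
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k) x[3*i+k] += 0.5 * dt * v[3*i+k];
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = (T > 0.0) ? std::sqrt(RGAS * T / S.mass[i]) : 0.0;
        for (int k = 0; k < adim; ++k)
          v[3*i+k] = c1 * v[3*i+k] + c2 * sd * rng.norm();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k) x[3*i+k] += 0.5 * dt * v[3*i+k];
    // force refresh + B: half kick
    eval_energy(S, rs, x.data(), f.data(), ep, er);
    if (!std::isfinite(ep + er))
      stop("non-finite energy at step %d (overlapping configuration?)", step);
    scale = has_bias ? B.force_scale(ep + er) : 1.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < adim; ++k)
        v[3*i+k] += 0.5 * dt * scale * f[3*i+k] / S.mass[i];

    if (has_obs && (step % obs_every == 0)) {
      double com[3] = {0,0,0}, mt = 0.0;
      for (size_t q = 0; q < obs_idx.size(); ++q) {
        int i = obs_idx[q];
        for (int k = 0; k < 3; ++k) com[k] += S.mass[i] * x[3*i+k];
        mt += S.mass[i];
      }
      double lam = 0.0;
      for (int k = 0; k < 3; ++k) lam += (com[k] / mt - obs_origin[k]) * obs_axis[k];
      lam_series.push_back(lam);
    }

    if (step % save_every == 0) {
      double ek = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < adim; ++k)
          ek += 0.5 * S.mass[i] * v[3*i+k] * v[3*i+k];
      // wrap whole molecules: the first bead of each molecule anchors it in
      // the box; the rest follow by minimum image so COMs stay meaningful
      {
        std::vector<int> anchor(n, -1);
        for (int i = 0; i < n; ++i) {
          int a = -1;
          for (int j = 0; j < i; ++j)
            if (S.mol[j] == S.mol[i]) { a = j; break; }
          if (a < 0) {
            for (int k = 0; k < 3; ++k) {
              double xx = x[3*i+k];
              if (S.box[k] > 0.0) xx -= S.box[k] * std::round(xx / S.box[k]);
              out_x(isave, 3*i+k) = xx;
            }
          } else {
            double d[3] = { x[3*i] - x[3*a], x[3*i+1] - x[3*a+1],
                            x[3*i+2] - x[3*a+2] };
            min_image(d, S.box);
            for (int k = 0; k < 3; ++k)
              out_x(isave, 3*i+k) = out_x(isave, 3*a+k) + d[k];
          }
        }
      }
      out_ep[isave] = ep;
      out_er[isave] = er;
      out_eb[isave] = has_bias ? B.value(ep + er) : 0.0;
      out_ek[isave] = ek;
      out_step[isave] = step;
      ++isave;
    }
  }

  NumericMatrix fin_x(n, 3), fin_v(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { fin_x(i, k) = x[3*i+k]; fin_v(i, k) = v[3*i+k]; }

  return List::create(
    _["coords"] = out_x, _["step"] = out_step,
    _["energy"] = out_ep, _["restraint_energy"] = out_er,
    _["bias_energy"] = out_eb, _["kinetic_energy"] = out_ek,
    _["final_coords"] = fin_x, _["final_vel"] = fin_v,
    _["lambda_series"] = wrap(lam_series));
}
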