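// Compiled core: OPLS-form energy/analytic forces for periodic systems,
// velocity-Verlet MD with Berendsen/Langevin/Nose-Hoover thermostats, an
// isotropic Nose-Hoover-style barostat, SHAKE/RATTLE constraints, TIP4P-style
// virtual sites, steepest-descent minimization and distance histogramming.
//
// Internal units: Angstrom, amu, e, kJ/mol, time unit 100 fs (consistent:
// 1 amu A^2 / (100 fs)^2 = 1 kJ/mol to 4e-8 relative).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double KE_COUL = 1389.35457644382; // kJ mol^-1 A e^-2
static const double KB = 0.008314462618153;     // kJ mol^-1 K^-1
static const double TWO_OVER_SQRTPI = 1.1283791670955126;

// ---------------------------------------------------------------- RNG ------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t res = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return res;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool has_g = false; double g_cache = 0.0;
  double norm() {
    if (has_g) { has_g = false; return g_cache; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    g_cache = r * std::sin(2.0 * M_PI * u2);
    has_g = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------- topology -------
struct Topo {
  int n = 0;
  std::vector<double> q, sig, eps, mass, invm;
  std::vector<int> is_virtual;
  // special (scaled/excluded) pairs, CSR over i with i < j
  std::vector<int> sp_start, sp_j;
  std::vector<double> sp_f;
  // bonded
  std::vector<int> b_i, b_j; std::vector<double> b_l0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_k2;
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_v1, d_v2, d_v3, d_v4;
  // constraints
  std::vector<int> c_i, c_j; std::vector<double> c_d;
  // virtual sites
  std::vector<int> v_idx, v_o, v_h1, v_h2; std::vector<double> v_g;
  // molecule ids (0-based) for the molecular-virial pressure
  std::vector<int> mol;
  int nmol = 0;
  // LJ type compression: per-atom type id and combined sigma_ij^2 / eps_ij
  std::vector<int> ljt;
  int nljt = 0;
  std::vector<double> s2tab, etab;
};

static Topo build_topo(const List& sysl) {
  Topo T;
  NumericVector q = sysl["q"], sig = sysl["sigma"], eps = sysl["epsilon"],
                mass = sysl["mass"];
  IntegerVector virt = sysl["virtual"];
  T.n = q.size();
  T.q.assign(q.begin(), q.end());
  T.sig.assign(sig.begin(), sig.end());
  T.eps.assign(eps.begin(), eps.end());
  T.mass.assign(mass.begin(), mass.end());
  T.is_virtual.assign(virt.begin(), virt.end());
  T.invm.resize(T.n);
  for (int i = 0; i < T.n; ++i)
    T.invm[i] = (T.is_virtual[i] || T.mass[i] <= 0) ? 0.0 : 1.0 / T.mass[i];

  // special pairs -> CSR (ensure i < j)
  IntegerVector spi = sysl["sp_i"], spj = sysl["sp_j"];
  NumericVector spf = sysl["sp_f"];
  std::vector<std::vector<std::pair<int, double>>> by_i(T.n);
  for (int r = 0; r < spi.size(); ++r) {
    int i = spi[r] - 1, j = spj[r] - 1;
    if (i > j) std::swap(i, j);
    by_i[i].push_back({j, spf[r]});
  }
  T.sp_start.assign(T.n + 1, 0);
  for (int i = 0; i < T.n; ++i) {
    std::sort(by_i[i].begin(), by_i[i].end());
    T.sp_start[i + 1] = T.sp_start[i] + (int)by_i[i].size();
  }
  for (int i = 0; i < T.n; ++i)
    for (auto& p : by_i[i]) { T.sp_j.push_back(p.first); T.sp_f.push_back(p.second); }

  IntegerVector bi = sysl["b_i"], bj = sysl["b_j"];
  NumericVector bl = sysl["b_l0"], bk = sysl["b_kl"];
  for (int r = 0; r < bi.size(); ++r) {
    T.b_i.push_back(bi[r] - 1); T.b_j.push_back(bj[r] - 1);
    T.b_l0.push_back(bl[r]); T.b_k.push_back(bk[r]);
  }
  IntegerVector ai = sysl["a_i"], aj = sysl["a_j"], ak = sysl["a_k"];
  NumericVector at = sysl["a_theta0"], akk = sysl["a_ktheta"];
  for (int r = 0; r < ai.size(); ++r) {
    T.a_i.push_back(ai[r] - 1); T.a_j.push_back(aj[r] - 1);
    T.a_k.push_back(ak[r] - 1);
    T.a_t0.push_back(at[r] * M_PI / 180.0); T.a_k2.push_back(akk[r]);
  }
  IntegerVector di = sysl["d_i"], dj = sysl["d_j"], dk = sysl["d_k"], dl = sysl["d_l"];
  NumericVector v1 = sysl["d_v1"], v2 = sysl["d_v2"], v3 = sysl["d_v3"], v4 = sysl["d_v4"];
  for (int r = 0; r < di.size(); ++r) {
    T.d_i.push_back(di[r] - 1); T.d_j.push_back(dj[r] - 1);
    T.d_k.push_back(dk[r] - 1); T.d_l.push_back(dl[r] - 1);
    T.d_v1.push_back(v1[r]); T.d_v2.push_back(v2[r]);
    T.d_v3.push_back(v3[r]); T.d_v4.push_back(v4[r]);
  }
  IntegerVector ci = sysl["c_i"], cj = sysl["c_j"];
  NumericVector cd = sysl["c_d"];
  for (int r = 0; r < ci.size(); ++r) {
    T.c_i.push_back(ci[r] - 1); T.c_j.push_back(cj[r] - 1); T.c_d.push_back(cd[r]);
  }
  IntegerVector vi = sysl["vs_idx"], vo = sysl["vs_o"], vh1 = sysl["vs_h1"],
                vh2 = sysl["vs_h2"];
  NumericVector vg = sysl["vs_gamma"];
  for (int r = 0; r < vi.size(); ++r) {
    T.v_idx.push_back(vi[r] - 1); T.v_o.push_back(vo[r] - 1);
    T.v_h1.push_back(vh1[r] - 1); T.v_h2.push_back(vh2[r] - 1);
    T.v_g.push_back(vg[r]);
  }

  IntegerVector mid = sysl["mol_id"];
  T.mol.resize(T.n);
  for (int i = 0; i < T.n; ++i) T.mol[i] = mid[i] - 1;
  T.nmol = T.n ? *std::max_element(T.mol.begin(), T.mol.end()) + 1 : 0;

  // compress LJ parameters to distinct (sigma, eps) types and precombine
  std::vector<std::pair<double, double>> types;
  T.ljt.resize(T.n);
  for (int i = 0; i < T.n; ++i) {
    std::pair<double, double> key(T.sig[i], T.eps[i]);
    int id = -1;
    for (size_t t = 0; t < types.size(); ++t)
      if (types[t] == key) { id = (int)t; break; }
    if (id < 0) { id = (int)types.size(); types.push_back(key); }
    T.ljt[i] = id;
  }
  T.nljt = (int)types.size();
  T.s2tab.assign(T.nljt * T.nljt, 0.0);
  T.etab.assign(T.nljt * T.nljt, 0.0);
  for (int a = 0; a < T.nljt; ++a)
    for (int b = 0; b < T.nljt; ++b) {
      T.s2tab[a * T.nljt + b] = types[a].first * types[b].first;   // sigma_ij^2
      T.etab[a * T.nljt + b] = std::sqrt(types[a].second * types[b].second);
    }
  return T;
}

// tabulated DSF Coulomb kernel on an r^2 grid (MD fast path); e/f are the
// energy and force-magnitude factors per unit ke*qi*qj
struct CoulTab {
  int n = 0; double rc2 = 0, inv_du = 0;
  std::vector<double> e, f;
  bool active = false;
};

static void build_coultab(double alpha, double rcc, int n, CoulTab& ct) {
  ct.n = n;
  ct.rc2 = rcc * rcc;
  ct.inv_du = n / ct.rc2;
  ct.e.assign(n + 2, 0.0);
  ct.f.assign(n + 2, 0.0);
  const double erfc_rc = std::erfc(alpha * rcc) / rcc;
  const double fshift = erfc_rc / rcc +
      alpha * TWO_OVER_SQRTPI * std::exp(-alpha * alpha * rcc * rcc) / rcc;
  for (int k = 1; k <= n + 1; ++k) {
    double u = k / ct.inv_du;
    double r = std::sqrt(u);
    double er = std::erfc(alpha * r) / r;
    ct.e[k] = er - erfc_rc + fshift * (r - rcc);
    double dudr = -(er / r +
        alpha * TWO_OVER_SQRTPI * std::exp(-alpha * alpha * u) / r) + fshift;
    ct.f[k] = -dudr / r;
  }
  ct.e[0] = ct.e[1]; ct.f[0] = ct.f[1];
  ct.active = true;
}

static inline double pair_factor(const Topo& T, int i, int j) {
  if (i > j) std::swap(i, j);
  int lo = T.sp_start[i], hi = T.sp_start[i + 1];
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (T.sp_j[mid] < j) lo = mid + 1; else hi = mid;
  }
  if (lo < T.sp_start[i + 1] && T.sp_j[lo] == j) return T.sp_f[lo];
  return 1.0;
}

static inline void min_image(double& dx, double& dy, double& dz, double L) {
  if (L > 0) {
    dx -= L * std::round(dx / L);
    dy -= L * std::round(dy / L);
    dz -= L * std::round(dz / L);
  }
}

// nonbonded method codes
enum { M_CUTOFF = 0, M_DSF = 1, M_EWALD = 2 };

struct EnergyOpts {
  int method = M_DSF;
  double rc_lj = 8.0;     // A
  double rc_coul = 8.0;   // A (cutoff / dsf)
  double alpha = 0.25;    // 1/A (dsf damping or ewald splitting)
  int kmax = 8;           // ewald reciprocal cutoff (integer shells)
  bool lj_tail = false;   // analytic LJ tail correction
};

struct EFState {
  double ebond = 0, eangle = 0, etors = 0, elj = 0, ecoul = 0;
  double virial = 0;      // sum r.f over interactions
  std::vector<double> f;  // 3n
};

// place virtual sites from parents
static void update_vsites(const Topo& T, std::vector<double>& x) {
  for (size_t v = 0; v < T.v_idx.size(); ++v) {
    int m = T.v_idx[v], o = T.v_o[v], h1 = T.v_h1[v], h2 = T.v_h2[v];
    double g = T.v_g[v];
    for (int c = 0; c < 3; ++c)
      x[3 * m + c] = x[3 * o + c] +
        g * (x[3 * h1 + c] + x[3 * h2 + c] - 2.0 * x[3 * o + c]);
  }
}

// fold virtual-site forces back onto parents
static void spread_vsite_forces(const Topo& T, std::vector<double>& f) {
  for (size_t v = 0; v < T.v_idx.size(); ++v) {
    int m = T.v_idx[v], o = T.v_o[v], h1 = T.v_h1[v], h2 = T.v_h2[v];
    double g = T.v_g[v];
    for (int c = 0; c < 3; ++c) {
      double fm = f[3 * m + c];
      f[3 * o + c] += (1.0 - 2.0 * g) * fm;
      f[3 * h1 + c] += g * fm;
      f[3 * h2 + c] += g * fm;
      f[3 * m + c] = 0.0;
    }
  }
}

// optional Verlet neighbor list (CSR over i, entries j > i, sorted)
struct NbrList {
  std::vector<int> start, j;
  bool active = false;
};

static void build_nbrlist(const Topo& T, const std::vector<double>& x,
                          double L, double rlist, NbrList& nl) {
  const int n = T.n;
  const double rl2 = rlist * rlist;
  nl.start.assign(n + 1, 0);
  nl.j.clear();
  nl.j.reserve(n * 64);
  for (int i = 0; i < n - 1; ++i) {
    for (int jj = i + 1; jj < n; ++jj) {
      double dx = x[3*i] - x[3*jj], dy = x[3*i+1] - x[3*jj+1],
             dz = x[3*i+2] - x[3*jj+2];
      min_image(dx, dy, dz, L);
      if (dx*dx + dy*dy + dz*dz <= rl2) nl.j.push_back(jj);
    }
    nl.start[i + 1] = (int)nl.j.size();
  }
  nl.start[n] = (int)nl.j.size();
  nl.active = true;
}

static void compute_ef(const Topo& T, std::vector<double>& x, double L,
                       const EnergyOpts& opt, EFState& S,
                       const NbrList* nl = nullptr,
                       const CoulTab* ct = nullptr) {
  const int n = T.n;
  S.ebond = S.eangle = S.etors = S.elj = S.ecoul = 0;
  S.virial = 0;
  S.f.assign(3 * n, 0.0);
  update_vsites(T, const_cast<std::vector<double>&>(x));

  // ---- bonds: k (l - l0)^2 (no 1/2 prefactor) ----
  for (size_t r = 0; r < T.b_i.size(); ++r) {
    int i = T.b_i[r], j = T.b_j[r];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    min_image(dx, dy, dz, L);
    double l = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (l < 1e-12) stop("bond with zero length");
    double dl = l - T.b_l0[r];
    S.ebond += T.b_k[r] * dl * dl;
    double fmag = -2.0 * T.b_k[r] * dl / l;  // along (i-j)
    double fx = fmag * dx, fy = fmag * dy, fz = fmag * dz;
    S.f[3*i] += fx; S.f[3*i+1] += fy; S.f[3*i+2] += fz;
    S.f[3*j] -= fx; S.f[3*j+1] -= fy; S.f[3*j+2] -= fz;
    S.virial += fx * dx + fy * dy + fz * dz;
  }

  // ---- angles: k (theta - theta0)^2 ----
  for (size_t r = 0; r < T.a_i.size(); ++r) {
    int i = T.a_i[r], j = T.a_j[r], k = T.a_k[r];
    double r1x = x[3*i] - x[3*j], r1y = x[3*i+1] - x[3*j+1], r1z = x[3*i+2] - x[3*j+2];
    double r2x = x[3*k] - x[3*j], r2y = x[3*k+1] - x[3*j+1], r2z = x[3*k+2] - x[3*j+2];
    min_image(r1x, r1y, r1z, L);
    min_image(r2x, r2y, r2z, L);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    double ct = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - T.a_t0[r];
    S.eangle += T.a_k2[r] * dth * dth;
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dEdth = 2.0 * T.a_k2[r] * dth;
    double coef = dEdth / st;   // F_i = -dE/dr_i = (dE/dth / sin th) dcos/dr_i
    // dcos/dri etc.
    double dth_ix = (r2x / (n1 * n2) - ct * r1x / (n1 * n1));
    double dth_iy = (r2y / (n1 * n2) - ct * r1y / (n1 * n1));
    double dth_iz = (r2z / (n1 * n2) - ct * r1z / (n1 * n1));
    double dth_kx = (r1x / (n1 * n2) - ct * r2x / (n2 * n2));
    double dth_ky = (r1y / (n1 * n2) - ct * r2y / (n2 * n2));
    double dth_kz = (r1z / (n1 * n2) - ct * r2z / (n2 * n2));
    double fix = coef * dth_ix, fiy = coef * dth_iy, fiz = coef * dth_iz;
    double fkx = coef * dth_kx, fky = coef * dth_ky, fkz = coef * dth_kz;
    S.f[3*i] += fix; S.f[3*i+1] += fiy; S.f[3*i+2] += fiz;
    S.f[3*k] += fkx; S.f[3*k+1] += fky; S.f[3*k+2] += fkz;
    S.f[3*j] -= fix + fkx; S.f[3*j+1] -= fiy + fky; S.f[3*j+2] -= fiz + fkz;
    S.virial += fix * r1x + fiy * r1y + fiz * r1z
              + fkx * r2x + fky * r2y + fkz * r2z;
  }

  // ---- torsions: OPLS 4-term Fourier sum ----
  for (size_t r = 0; r < T.d_i.size(); ++r) {
    int i = T.d_i[r], j = T.d_j[r], k = T.d_k[r], l = T.d_l[r];
    double b1x = x[3*j] - x[3*i], b1y = x[3*j+1] - x[3*i+1], b1z = x[3*j+2] - x[3*i+2];
    double b2x = x[3*k] - x[3*j], b2y = x[3*k+1] - x[3*j+1], b2z = x[3*k+2] - x[3*j+2];
    double b3x = x[3*l] - x[3*k], b3y = x[3*l+1] - x[3*k+1], b3z = x[3*l+2] - x[3*k+2];
    min_image(b1x, b1y, b1z, L);
    min_image(b2x, b2y, b2z, L);
    min_image(b3x, b3y, b3z, L);
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z, n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z, n2z = b2x*b3y - b2y*b3x;
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    double b2n = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    if (n1sq < 1e-10 || n2sq < 1e-10) continue;   // collinear; zero-measure
    double cphi = (n1x*n2x + n1y*n2y + n1z*n2z) / std::sqrt(n1sq * n2sq);
    cphi = std::max(-1.0, std::min(1.0, cphi));
    double sphi = (n1x*b3x + n1y*b3y + n1z*b3z) * b2n / std::sqrt(n1sq * n2sq);
    double phi = std::atan2(sphi, cphi);
    const double V1 = T.d_v1[r], V2 = T.d_v2[r], V3 = T.d_v3[r], V4 = T.d_v4[r];
    S.etors += 0.5 * (V1 * (1 + std::cos(phi)) + V2 * (1 - std::cos(2*phi)) +
                      V3 * (1 + std::cos(3*phi)) + V4 * (1 - std::cos(4*phi)));
    double dEdphi = 0.5 * (-V1 * std::sin(phi) + 2*V2 * std::sin(2*phi)
                           - 3*V3 * std::sin(3*phi) + 4*V4 * std::sin(4*phi));
    // Allen & Tildesley force distribution
    double fix =  dEdphi * b2n / n1sq * n1x;
    double fiy =  dEdphi * b2n / n1sq * n1y;
    double fiz =  dEdphi * b2n / n1sq * n1z;
    double flx = -dEdphi * b2n / n2sq * n2x;
    double fly = -dEdphi * b2n / n2sq * n2y;
    double flz = -dEdphi * b2n / n2sq * n2z;
    double b12 = b1x*b2x + b1y*b2y + b1z*b2z;
    double b32 = b3x*b2x + b3y*b2y + b3z*b2z;
    double t = b12 / (b2n * b2n), s = b32 / (b2n * b2n);
    double fjx = -(1.0 + t) * fix + s * flx;
    double fjy = -(1.0 + t) * fiy + s * fly;
    double fjz = -(1.0 + t) * fiz + s * flz;
    double fkx = t * fix - (1.0 + s) * flx;
    double fky = t * fiy - (1.0 + s) * fly;
    double fkz = t * fiz - (1.0 + s) * flz;
    S.f[3*i] += fix; S.f[3*i+1] += fiy; S.f[3*i+2] += fiz;
    S.f[3*j] += fjx; S.f[3*j+1] += fjy; S.f[3*j+2] += fjz;
    S.f[3*k] += fkx; S.f[3*k+1] += fky; S.f[3*k+2] += fkz;
    S.f[3*l] += flx; S.f[3*l+1] += fly; S.f[3*l+2] += flz;
    // virial via absolute positions (terms are translation invariant)
    S.virial += fix * (-b1x) + flx * (b3x + b2x)
              + fiy * (-b1y) + fly * (b3y + b2y)
              + fiz * (-b1z) + flz * (b3z + b2z)
              + fkx * b2x + fky * b2y + fkz * b2z;
  }

  // ---- nonbonded pair loop ----
  const double rc2 = opt.rc_lj * opt.rc_lj;
  const double rcc = opt.rc_coul, rcc2 = rcc * rcc;
  const double alpha = opt.alpha;
  // DSF shift constants
  const double erfc_rc = std::erfc(alpha * rcc) / rcc;
  const double fshift = erfc_rc / rcc +
      alpha * TWO_OVER_SQRTPI * std::exp(-alpha * alpha * rcc * rcc) / rcc;

  const bool use_nl = (nl != nullptr && nl->active);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
    const double qi = T.q[i];
    int lo = T.sp_start[i], hi = T.sp_start[i + 1];
    const int jn = use_nl ? (nl->start[i + 1] - nl->start[i]) : (n - 1 - i);
    const int* jptr = use_nl ? nl->j.data() + nl->start[i] : nullptr;
    for (int jc = 0; jc < jn; ++jc) {
      const int j = use_nl ? jptr[jc] : (i + 1 + jc);
      double fij = 1.0;
      while (lo < hi && T.sp_j[lo] < j) ++lo;
      if (lo < hi && T.sp_j[lo] == j) fij = T.sp_f[lo];
      bool skip_pair = (fij == 0.0 && opt.method != M_EWALD);
      if (skip_pair) continue;
      double dx = xi - x[3*j], dy = yi - x[3*j+1], dz = zi - x[3*j+2];
      min_image(dx, dy, dz, L);
      double r2 = dx*dx + dy*dy + dz*dz;
      double rmax2 = std::max(rc2, rcc2);
      if (r2 > rmax2) continue;
      if (r2 < 1e-4) stop("overlapping atoms (r < 1 pm): atoms %d and %d",
                          i + 1, j + 1);
      double fmag = 0.0;  // dU/dr * (-1/r), multiplies (dx,dy,dz)
      double ljfac = (opt.method == M_EWALD && fij == 0.0) ? 0.0 : fij;
      if (r2 <= rc2 && ljfac > 0) {
        double eij = T.etab[T.ljt[i] * T.nljt + T.ljt[j]];
        if (eij > 0) {
          double sr2 = T.s2tab[T.ljt[i] * T.nljt + T.ljt[j]] / r2;
          double sr6 = sr2 * sr2 * sr2;
          S.elj += ljfac * 4.0 * eij * (sr6 * sr6 - sr6);
          fmag += ljfac * 24.0 * eij * (2.0 * sr6 * sr6 - sr6) / r2;
        }
      }
      double qq = KE_COUL * qi * T.q[j];
      if (qq != 0.0 && r2 <= rcc2) {
        if (opt.method == M_DSF && ct != nullptr && ct->active) {
          // interpolated kernel (MD fast path)
          double uu = r2 * ct->inv_du;
          int k = (int)uu;
          double w = uu - k;
          S.ecoul += fij * qq * (ct->e[k] + (ct->e[k + 1] - ct->e[k]) * w);
          fmag += fij * qq * (ct->f[k] + (ct->f[k + 1] - ct->f[k]) * w);
        } else if (opt.method == M_CUTOFF) {
          double r = std::sqrt(r2);
          S.ecoul += fij * qq / r;
          fmag += fij * qq / (r2 * r);
        } else if (opt.method == M_DSF) {
          double r = std::sqrt(r2);
          double er = std::erfc(alpha * r) / r;
          S.ecoul += fij * qq * (er - erfc_rc + fshift * (r - rcc));
          double dudr = -(er / r +
              alpha * TWO_OVER_SQRTPI * std::exp(-alpha * alpha * r2) / r) + fshift;
          fmag += -fij * qq * dudr / r;
        } else { // Ewald real space: full erfc for all pairs, corrections later
          double r = std::sqrt(r2);
          double er = std::erfc(alpha * r) / r;
          S.ecoul += qq * er;
          fmag += qq * (er / r +
              alpha * TWO_OVER_SQRTPI * std::exp(-alpha * alpha * r2) / r) / r;
        }
      }
      if (fmag != 0.0) {
        double fx = fmag * dx, fy = fmag * dy, fz = fmag * dz;
        S.f[3*i] += fx; S.f[3*i+1] += fy; S.f[3*i+2] += fz;
        S.f[3*j] -= fx; S.f[3*j+1] -= fy; S.f[3*j+2] -= fz;
        S.virial += fx * dx + fy * dy + fz * dz;
      }
    }
  }

  if (opt.method == M_DSF) {
    // DSF self term
    double q2 = 0;
    for (int i = 0; i < n; ++i) q2 += T.q[i] * T.q[i];
    S.ecoul -= KE_COUL * (erfc_rc / 2.0 + alpha / std::sqrt(M_PI)) * q2;
  }

  if (opt.method == M_EWALD) {
    if (L <= 0) stop("Ewald requires a periodic box");
    const double V = L * L * L;
    const double pref = KE_COUL * 2.0 * M_PI / V;
    const double g2fac = 1.0 / (4.0 * alpha * alpha);
    for (int kx = 0; kx <= opt.kmax; ++kx) {
      int ky_lo = (kx == 0) ? 0 : -opt.kmax;
      for (int ky = ky_lo; ky <= opt.kmax; ++ky) {
        int kz_lo = (kx == 0 && ky == 0) ? 1 : -opt.kmax;
        for (int kz = kz_lo; kz <= opt.kmax; ++kz) {
          if (kx * kx + ky * ky + kz * kz > opt.kmax * opt.kmax) continue;
          double gx = 2.0 * M_PI * kx / L, gy = 2.0 * M_PI * ky / L,
                 gz = 2.0 * M_PI * kz / L;
          double g2 = gx * gx + gy * gy + gz * gz;
          double ak = std::exp(-g2 * g2fac) / g2;
          double sre = 0, sim = 0;
          for (int i = 0; i < n; ++i) {
            double ph = gx * x[3*i] + gy * x[3*i+1] + gz * x[3*i+2];
            sre += T.q[i] * std::cos(ph);
            sim += T.q[i] * std::sin(ph);
          }
          // factor 2: half-space sum
          S.ecoul += 2.0 * pref * ak * (sre * sre + sim * sim);
          for (int i = 0; i < n; ++i) {
            double ph = gx * x[3*i] + gy * x[3*i+1] + gz * x[3*i+2];
            double fcomp = 2.0 * pref * ak * 2.0 * T.q[i] *
                (std::sin(ph) * sre - std::cos(ph) * sim);
            S.f[3*i] += fcomp * gx;
            S.f[3*i+1] += fcomp * gy;
            S.f[3*i+2] += fcomp * gz;
          }
        }
      }
    }
    // self energy
    double q2 = 0;
    for (int i = 0; i < n; ++i) q2 += T.q[i] * T.q[i];
    S.ecoul -= KE_COUL * alpha / std::sqrt(M_PI) * q2;
    // scaled/excluded intramolecular pairs: remove (1 - f) of the plain
    // Coulomb interaction of the primary image
    for (int i = 0; i < n; ++i) {
      for (int s = T.sp_start[i]; s < T.sp_start[i + 1]; ++s) {
        int j = T.sp_j[s];
        double f = T.sp_f[s];
        if (f >= 1.0) continue;
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        min_image(dx, dy, dz, L);
        double r2 = dx*dx + dy*dy + dz*dz;
        double r = std::sqrt(r2);
        double qq = KE_COUL * T.q[i] * T.q[j];
        S.ecoul -= (1.0 - f) * qq / r;
        double fmag = -(1.0 - f) * qq / (r2 * r);
        S.f[3*i] += fmag * dx; S.f[3*i+1] += fmag * dy; S.f[3*i+2] += fmag * dz;
        S.f[3*j] -= fmag * dx; S.f[3*j+1] -= fmag * dy; S.f[3*j+2] -= fmag * dz;
      }
    }
  }

  if (opt.lj_tail && L > 0) {
    // mean-field LJ tail over LJ type pairs (geometric combination)
    std::vector<double> cnt(T.nljt, 0.0);
    for (int i = 0; i < n; ++i) cnt[T.ljt[i]] += 1.0;
    const double rc3 = opt.rc_lj * opt.rc_lj * opt.rc_lj;
    double acc = 0;
    for (int a = 0; a < T.nljt; ++a) {
      for (int b = a; b < T.nljt; ++b) {
        double eij = T.etab[a * T.nljt + b];
        if (eij <= 0) continue;
        double npairs = (a == b) ? cnt[a] * (cnt[a] - 1) / 2.0 : cnt[a] * cnt[b];
        double s3 = std::pow(T.s2tab[a * T.nljt + b], 1.5);
        double sr3 = s3 / rc3;
        acc += npairs * (8.0 / 3.0) * M_PI * eij * s3 *
               (sr3 * sr3 * sr3 / 3.0 - sr3);
      }
    }
    double etail = 2.0 * acc / (L * L * L);
    S.elj += etail;
    // homogeneous tail: E ~ 1/V, so P_tail = E_tail/V, i.e. W_tail = 3 E_tail
    S.virial += 3.0 * etail;
  }

  spread_vsite_forces(T, S.f);
}

// -------------------------------------------------------- SHAKE/RATTLE ------
static void shake(const Topo& T, const std::vector<double>& xref,
                  std::vector<double>& x, double tol, int maxit,
                  double dt = 0.0, double* cons_virial = nullptr) {
  if (T.c_i.empty()) return;
  std::vector<double> gsum(T.c_i.size(), 0.0);
  bool converged = false;
  for (int it = 0; it < maxit && !converged; ++it) {
    double worst = 0;
    for (size_t c = 0; c < T.c_i.size(); ++c) {
      int i = T.c_i[c], j = T.c_j[c];
      double d2 = T.c_d[c] * T.c_d[c];
      double rx = x[3*i] - x[3*j], ry = x[3*i+1] - x[3*j+1], rz = x[3*i+2] - x[3*j+2];
      double r2 = rx*rx + ry*ry + rz*rz;
      double diff = r2 - d2;
      worst = std::max(worst, std::fabs(diff) / d2);
      if (std::fabs(diff) / d2 < tol) continue;
      double sx = xref[3*i] - xref[3*j], sy = xref[3*i+1] - xref[3*j+1],
             sz = xref[3*i+2] - xref[3*j+2];
      double dot = sx * rx + sy * ry + sz * rz;
      if (std::fabs(dot) < 1e-12) dot = (dot >= 0 ? 1e-12 : -1e-12);
      double g = diff / (2.0 * dot * (T.invm[i] + T.invm[j]));
      gsum[c] += g;
      x[3*i]   -= g * T.invm[i] * sx;
      x[3*i+1] -= g * T.invm[i] * sy;
      x[3*i+2] -= g * T.invm[i] * sz;
      x[3*j]   += g * T.invm[j] * sx;
      x[3*j+1] += g * T.invm[j] * sy;
      x[3*j+2] += g * T.invm[j] * sz;
    }
    if (worst < tol) converged = true;
  }
  if (converged) {
    if (cons_virial != nullptr && dt > 0) {
      // constraint force on i is -gsum * s / dt^2; accumulate pair virial
      double wc = 0;
      for (size_t c = 0; c < T.c_i.size(); ++c) {
        int i = T.c_i[c], j = T.c_j[c];
        double sx = xref[3*i] - xref[3*j], sy = xref[3*i+1] - xref[3*j+1],
               sz = xref[3*i+2] - xref[3*j+2];
        double rx = x[3*i] - x[3*j], ry = x[3*i+1] - x[3*j+1],
               rz = x[3*i+2] - x[3*j+2];
        wc -= gsum[c] * (sx * rx + sy * ry + sz * rz) / (dt * dt);
      }
      *cons_virial = wc;
    }
    return;
  }
  // report the worst violation
  double worst = 0; int wc = 0;
  for (size_t c = 0; c < T.c_i.size(); ++c) {
    int i = T.c_i[c], j = T.c_j[c];
    double rx = x[3*i] - x[3*j], ry = x[3*i+1] - x[3*j+1], rz = x[3*i+2] - x[3*j+2];
    double dev = std::fabs(std::sqrt(rx*rx + ry*ry + rz*rz) - T.c_d[c]);
    if (dev > worst) { worst = dev; wc = (int)c; }
  }
  stop("SHAKE did not converge in %d iterations; worst violation %g A on constraint %d",
       maxit, worst, wc + 1);
}

static void rattle_v(const Topo& T, const std::vector<double>& x,
                     std::vector<double>& v, double tol, int maxit) {
  if (T.c_i.empty()) return;
  for (int it = 0; it < maxit; ++it) {
    double worst = 0;
    for (size_t c = 0; c < T.c_i.size(); ++c) {
      int i = T.c_i[c], j = T.c_j[c];
      double rx = x[3*i] - x[3*j], ry = x[3*i+1] - x[3*j+1], rz = x[3*i+2] - x[3*j+2];
      double vx = v[3*i] - v[3*j], vy = v[3*i+1] - v[3*j+1], vz = v[3*i+2] - v[3*j+2];
      double rv = rx*vx + ry*vy + rz*vz;
      double d2 = T.c_d[c] * T.c_d[c];
      double lam = rv / (d2 * (T.invm[i] + T.invm[j]));
      worst = std::max(worst, std::fabs(rv) / d2);
      v[3*i]   -= lam * T.invm[i] * rx;
      v[3*i+1] -= lam * T.invm[i] * ry;
      v[3*i+2] -= lam * T.invm[i] * rz;
      v[3*j]   += lam * T.invm[j] * rx;
      v[3*j+1] += lam * T.invm[j] * ry;
      v[3*j+2] += lam * T.invm[j] * rz;
    }
    if (worst < tol) return;
  }
}

// ------------------------------------------------------------ exports ------

static EnergyOpts parse_opts(const List& opts) {
  EnergyOpts o;
  std::string m = as<std::string>(opts["method"]);
  o.method = (m == "cutoff") ? M_CUTOFF : (m == "dsf") ? M_DSF : M_EWALD;
  o.rc_lj = as<double>(opts["rc_lj"]);
  o.rc_coul = as<double>(opts["rc_coul"]);
  o.alpha = as<double>(opts["alpha"]);
  o.kmax = as<int>(opts["kmax"]);
  o.lj_tail = as<bool>(opts["lj_tail"]);
  return o;
}

// [[Rcpp::export]]
List cpp_energy_forces(List sysl, NumericMatrix pos, double box, List opts) {
  Topo T = build_topo(sysl);
  if (pos.nrow() != T.n) stop("position matrix does not match topology");
  std::vector<double> x(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = pos(i, c);
  EnergyOpts o = parse_opts(opts);
  EFState S;
  compute_ef(T, x, box, o, S);
  NumericMatrix f(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) f(i, c) = S.f[3*i+c];
  return List::create(
    _["bond"] = S.ebond, _["angle"] = S.eangle, _["torsion"] = S.etors,
    _["lj"] = S.elj, _["coulomb"] = S.ecoul,
    _["total"] = S.ebond + S.eangle + S.etors + S.elj + S.ecoul,
    _["forces"] = f, _["virial"] = S.virial);
}

// [[Rcpp::export]]
List cpp_minimize(List sysl, NumericMatrix pos, double box, List opts,
                  int steps, double max_disp, double ftol) {
  Topo T = build_topo(sysl);
  std::vector<double> x(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = pos(i, c);
  EnergyOpts o = parse_opts(opts);
  EFState S;
  double gamma = 1e-4;
  compute_ef(T, x, box, o, S);
  double e_prev = S.ebond + S.eangle + S.etors + S.elj + S.ecoul;
  for (int s = 0; s < steps; ++s) {
    std::vector<double> xold = x;
    double fmax = 0;
    for (int i = 0; i < 3 * T.n; ++i) fmax = std::max(fmax, std::fabs(S.f[i]));
    if (fmax < ftol) break;
    double scale = std::min(gamma, max_disp / fmax);
    for (int i = 0; i < T.n; ++i) {
      if (T.is_virtual[i]) continue;
      for (int c = 0; c < 3; ++c) x[3*i+c] += scale * S.f[3*i+c];
    }
    shake(T, xold, x, 1e-8, 500);
    update_vsites(T, x);
    compute_ef(T, x, box, o, S);
    double e = S.ebond + S.eangle + S.etors + S.elj + S.ecoul;
    if (e < e_prev) { gamma *= 1.2; e_prev = e; }
    else { x = xold; gamma *= 0.5; compute_ef(T, x, box, o, S); }
    if (gamma < 1e-12) break;
  }
  NumericMatrix out(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3*i+c];
  return List::create(_["pos"] = out, _["energy"] = e_prev);
}

// thermostat codes
enum { TH_NONE = 0, TH_BERENDSEN = 1, TH_LANGEVIN = 2, TH_NOSEHOOVER = 3 };

// [[Rcpp::export]]
List cpp_md_run(List sysl, NumericMatrix pos, NumericMatrix vel, double box,
                List opts, List cfg) {
  Topo T = build_topo(sysl);
  const int n = T.n;
  EnergyOpts o = parse_opts(opts);

  const double dt = as<double>(cfg["dt"]);          // internal (100 fs) units
  const int nsteps = as<int>(cfg["nsteps"]);
  const int thermostat = as<int>(cfg["thermostat"]);
  const double tauT = as<double>(cfg["tau_t"]);
  const double T0 = as<double>(cfg["temperature"]);
  const bool barostat = as<bool>(cfg["barostat"]);
  const double tauP = as<double>(cfg["tau_p"]);
  const double P0 = as<double>(cfg["pressure"]);
  const int save_every = as<int>(cfg["save_every"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  const double shake_tol = as<double>(cfg["shake_tol"]);
  const int com_every = as<int>(cfg["com_every"]);
  const double skin = as<double>(cfg["nlist_skin"]);
  const int nlist_every = as<int>(cfg["nlist_every"]);
  double L = box;

  if (barostat && o.method == M_EWALD)
    stop("the barostat requires a pairwise electrostatics method (cutoff/dsf)");

  Xoshiro rng(seed);
  std::vector<double> x(3 * n), v(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { x[3*i+c] = pos(i, c); v[3*i+c] = vel(i, c); }

  int nreal = 0;
  double mtot = 0;
  for (int i = 0; i < n; ++i) if (!T.is_virtual[i]) { ++nreal; mtot += T.mass[i]; }
  const int nf = 3 * nreal - (int)T.c_i.size() - 3;
  const double kT = KB * T0;

  // Nose-Hoover chain (length 2)
  double vxi1 = 0, vxi2 = 0;
  const double Q1 = nf * kT * tauT * tauT;
  const double Q2 = kT * tauT * tauT;
  // barostat strain rate
  double veps = 0;
  const double W = (nf + 3) * kT * tauP * tauP;

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      ke += T.mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    }
    return 0.5 * ke;
  };
  auto nhc_half = [&](double dth) {
    double dt2 = dth, dt4 = dth / 2, dt8 = dth / 4;
    double ke2 = 2.0 * kinetic();
    double g2 = (Q1 * vxi1 * vxi1 - kT) / Q2;
    vxi2 += g2 * dt4;
    vxi1 *= std::exp(-vxi2 * dt8);
    double g1 = (ke2 - nf * kT) / Q1;
    vxi1 += g1 * dt4;
    vxi1 *= std::exp(-vxi2 * dt8);
    double sc = std::exp(-vxi1 * dt2);
    for (int i = 0; i < 3 * n; ++i) v[i] *= sc;
    ke2 *= sc * sc;
    vxi1 *= std::exp(-vxi2 * dt8);
    g1 = (ke2 - nf * kT) / Q1;
    vxi1 += g1 * dt4;
    vxi1 *= std::exp(-vxi2 * dt8);
    g2 = (Q1 * vxi1 * vxi1 - kT) / Q2;
    vxi2 += g2 * dt4;
  };
  auto remove_com = [&]() {
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      px += T.mass[i] * v[3*i]; py += T.mass[i] * v[3*i+1]; pz += T.mass[i] * v[3*i+2];
    }
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      v[3*i] -= px / mtot; v[3*i+1] -= py / mtot; v[3*i+2] -= pz / mtot;
    }
  };

  EFState S;
  double cons_virial = 0.0;
  // molecular-virial pressure: exact for flexible, constrained and
  // virtual-site molecules alike (intramolecular forces cancel)
  std::vector<double> molmass(T.nmol, 0.0);
  for (int i = 0; i < n; ++i) molmass[T.mol[i]] += T.mass[i];
  std::vector<double> rcom(3 * T.nmol), vcom(3 * T.nmol);
  auto pressure = [&](double V) {
    std::fill(rcom.begin(), rcom.end(), 0.0);
    std::fill(vcom.begin(), vcom.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int mnum = T.mol[i];
      for (int c = 0; c < 3; ++c) {
        rcom[3*mnum+c] += T.mass[i] * x[3*i+c];
        vcom[3*mnum+c] += T.mass[i] * v[3*i+c];
      }
    }
    double kcom = 0;
    for (int mnum = 0; mnum < T.nmol; ++mnum) {
      for (int c = 0; c < 3; ++c) {
        rcom[3*mnum+c] /= molmass[mnum];
        vcom[3*mnum+c] /= molmass[mnum];
      }
      kcom += 0.5 * molmass[mnum] *
        (vcom[3*mnum]*vcom[3*mnum] + vcom[3*mnum+1]*vcom[3*mnum+1] +
         vcom[3*mnum+2]*vcom[3*mnum+2]);
    }
    double corr = 0;
    for (int i = 0; i < n; ++i) {
      int mnum = T.mol[i];
      for (int c = 0; c < 3; ++c)
        corr += S.f[3*i+c] * (rcom[3*mnum+c] - x[3*i+c]);
    }
    return (2.0 * kcom + S.virial + corr) / (3.0 * V);
  };
  update_vsites(T, x);
  NbrList nl;
  const double rlist = std::max(o.rc_lj, o.rc_coul) + skin;
  const bool use_list = (L > 0 && nlist_every > 0 && rlist < L / 2);
  if (use_list) build_nbrlist(T, x, L, rlist, nl);
  CoulTab ct;
  if (o.method == M_DSF) build_coultab(o.alpha, o.rc_coul, 8192, ct);
  compute_ef(T, x, L, o, S, use_list ? &nl : nullptr, &ct);

  const int nframes = nsteps / std::max(1, save_every) + 1;
  NumericMatrix frames(nframes, 3 * n);
  NumericVector fr_time(nframes), fr_box(nframes), fr_temp(nframes),
                fr_press(nframes), fr_epot(nframes), fr_ekin(nframes),
                fr_virial(nframes), fr_wc(nframes);
  int fr = 0;
  auto record = [&](int step) {
    for (int i = 0; i < 3 * n; ++i) frames(fr, i) = x[i];
    double ke = kinetic();
    double V = (L > 0) ? L * L * L : 1.0;
    fr_time[fr] = step * dt;
    fr_box[fr] = L;
    fr_temp[fr] = 2.0 * ke / (nf * KB);
    fr_press[fr] = (L > 0) ? pressure(V) : 0.0;
    fr_epot[fr] = S.ebond + S.eangle + S.etors + S.elj + S.ecoul;
    fr_ekin[fr] = ke;
    fr_virial[fr] = S.virial;
    fr_wc[fr] = cons_virial;
    ++fr;
  };
  record(0);

  for (int step = 1; step <= nsteps; ++step) {
    if (thermostat == TH_NOSEHOOVER) nhc_half(dt / 2);
    // half kick
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      for (int c = 0; c < 3; ++c) v[3*i+c] += 0.5 * dt * S.f[3*i+c] * T.invm[i];
    }
    // drift (+ barostat scaling applied to box and coordinates)
    std::vector<double> xref = x;
    if (barostat) {
      double sc = std::exp(veps * dt);
      L *= sc;
      for (int i = 0; i < 3 * n; ++i) x[i] *= sc;
      for (int i = 0; i < 3 * n; ++i) v[i] *= 1.0 / sc;
      for (int i = 0; i < 3 * n; ++i) xref[i] *= sc;
    }
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      for (int c = 0; c < 3; ++c) x[3*i+c] += dt * v[3*i+c];
    }
    if (!T.c_i.empty()) {
      std::vector<double> xun = x;
      cons_virial = 0.0;
      shake(T, xref, x, shake_tol, 500, dt, &cons_virial);
      // constraint velocity update
      for (int i = 0; i < 3 * n; ++i) v[i] += (x[i] - xun[i]) / dt;
    }
    update_vsites(T, x);
    if (use_list && step % nlist_every == 0) build_nbrlist(T, x, L, rlist, nl);
    compute_ef(T, x, L, o, S, use_list ? &nl : nullptr, &ct);
    // half kick
    for (int i = 0; i < n; ++i) {
      if (T.is_virtual[i]) continue;
      for (int c = 0; c < 3; ++c) v[3*i+c] += 0.5 * dt * S.f[3*i+c] * T.invm[i];
    }
    if (!T.c_i.empty()) rattle_v(T, x, v, 1e-10, 200);
    if (thermostat == TH_NOSEHOOVER) nhc_half(dt / 2);
    else if (thermostat == TH_BERENDSEN) {
      double Tn = 2.0 * kinetic() / (nf * KB);
      if (Tn > 1e-12) {
        double lam = std::sqrt(std::max(0.0, 1.0 + dt / tauT * (T0 / Tn - 1.0)));
        for (int i = 0; i < 3 * n; ++i) v[i] *= lam;
      }
    } else if (thermostat == TH_LANGEVIN) {
      double c1 = std::exp(-dt / tauT);
      double c2 = std::sqrt(1.0 - c1 * c1);
      for (int i = 0; i < n; ++i) {
        if (T.is_virtual[i]) continue;
        double sg = c2 * std::sqrt(kT * T.invm[i]);
        v[3*i]   = c1 * v[3*i]   + sg * rng.norm();
        v[3*i+1] = c1 * v[3*i+1] + sg * rng.norm();
        v[3*i+2] = c1 * v[3*i+2] + sg * rng.norm();
      }
      if (!T.c_i.empty()) rattle_v(T, x, v, 1e-10, 200);
      if (com_every > 0 && step % com_every == 0) remove_com();
    }
    if (barostat) {
      double V = L * L * L;
      double P = pressure(V);
      veps += dt * 3.0 * V * (P - P0) / W;
    }
    double etot = S.ebond + S.eangle + S.etors + S.elj + S.ecoul + kinetic();
    if (!std::isfinite(etot) || std::fabs(etot) > 1e14)
      stop("energy blow-up at step %d (E = %g kJ/mol); reduce the timestep or "
           "relax the starting configuration", step, etot);
    if (step % std::max(1, save_every) == 0 && fr < nframes) record(step);
  }

  NumericMatrix vout(n, 3), xout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { vout(i, c) = v[3*i+c]; xout(i, c) = x[3*i+c]; }
  return List::create(
    _["frames"] = frames, _["time"] = fr_time, _["box"] = fr_box,
    _["temperature"] = fr_temp, _["pressure"] = fr_press,
    _["epot"] = fr_epot, _["ekin"] = fr_ekin,
    _["virial"] = fr_virial, _["cons_virial"] = fr_wc,
    _["final_pos"] = xout, _["final_vel"] = vout, _["final_box"] = L,
    _["nframes"] = fr);
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_shake(List sysl, NumericMatrix pos, double tol, int maxit) {
  Topo T = build_topo(sysl);
  std::vector<double> x(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = pos(i, c);
  std::vector<double> xref = x;
  shake(T, xref, x, tol, maxit);
  update_vsites(T, x);
  NumericMatrix out(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3*i+c];
  return out;
}

// minimum-image distance histogram between two index sets for one frame
// [[Rcpp::export]]
NumericVector cpp_bin_distances(NumericMatrix pos, double box,
                                IntegerVector idx_a, IntegerVector idx_b,
                                IntegerVector mol_id, bool exclude_intra,
                                double bin_width, int nbins) {
  NumericVector counts(nbins);
  for (int a = 0; a < idx_a.size(); ++a) {
    int i = idx_a[a] - 1;
    for (int b = 0; b < idx_b.size(); ++b) {
      int j = idx_b[b] - 1;
      if (i == j) continue;
      if (exclude_intra && mol_id[i] == mol_id[j]) continue;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      min_image(dx, dy, dz, box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      int bin = (int)(r / bin_width);
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}

// per-frame hydrogen-bond indicator: donor-H ... acceptor geometry
// angle is the deviation from linearity at H: 0 deg = linear D-H...A
// [[Rcpp::export]]
LogicalMatrix cpp_hbond_indicator(NumericMatrix pos, double box,
                                  IntegerVector don, IntegerVector hyd,
                                  IntegerVector acc, IntegerVector mol_id,
                                  double rmax, double amax_deg) {
  int nh = hyd.size(), na = acc.size();
  LogicalMatrix out(nh, na);
  double camin = std::cos(amax_deg * M_PI / 180.0);
  for (int h = 0; h < nh; ++h) {
    int ih = hyd[h] - 1, id = don[h] - 1;
    for (int a = 0; a < na; ++a) {
      int ia = acc[a] - 1;
      if (ia == ih || ia == id) { out(h, a) = false; continue; }
      if (mol_id[ia] == mol_id[ih]) { out(h, a) = false; continue; }
      double dx = pos(ia, 0) - pos(ih, 0), dy = pos(ia, 1) - pos(ih, 1),
             dz = pos(ia, 2) - pos(ih, 2);
      min_image(dx, dy, dz, box);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > rmax * rmax) { out(h, a) = false; continue; }
      double ux = pos(ih, 0) - pos(id, 0), uy = pos(ih, 1) - pos(id, 1),
             uz = pos(ih, 2) - pos(id, 2);
      min_image(ux, uy, uz, box);
      double un = std::sqrt(ux*ux + uy*uy + uz*uz);
      double rn = std::sqrt(r2);
      double ca = (ux * dx + uy * dy + uz * dz) / (un * rn);
      out(h, a) = (ca >= camin);
    }
  }
  return out;
}
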