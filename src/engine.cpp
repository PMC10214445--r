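// Coarse-grained Langevin engine: one-particle-thick fluid membrane vesicle
// (orientation-dependent pair potential), volume-exclusion solutes that set
// the pressure difference across the membrane, and an adhesive rigid
// dumbbell colloid. Reduced units: bead diameter sigma_b, energy eps,
// time tau0 = sigma_b sqrt(m/eps) with bead mass m = 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- deterministic RNG (xoshiro256++, splitmix64 seeding) ----------------
struct XRng {
  uint64_t s[4];
  double cached; bool has;
  explicit XRng(uint64_t x = 1) { seed(x); }
  void seed(uint64_t x) {
    has = false;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  double norm() {
    if (has) { has = false; return cached; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2); has = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct Vec { double x, y, z; };
static inline Vec vadd(Vec a, Vec b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline Vec vsub(Vec a, Vec b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline Vec vscale(Vec a, double k) { return {a.x*k, a.y*k, a.z*k}; }
static inline double vdot(Vec a, Vec b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline Vec vcross(Vec a, Vec b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vnorm(Vec a) { return std::sqrt(vdot(a, a)); }
static inline Vec vunit(Vec a) { double n = vnorm(a); return vscale(a, 1.0/n); }

// rotate v about omega (angle |omega|*dt) by Rodrigues' formula
static inline Vec rotate_by(Vec v, Vec omega, double dt) {
  double w = vnorm(omega);
  double th = w * dt;
  if (th < 1e-14) return v;
  Vec k = vscale(omega, 1.0 / w);
  double c = std::cos(th), s = std::sin(th);
  Vec kxv = vcross(k, v);
  double kdv = vdot(k, v);
  return vadd(vadd(vscale(v, c), vscale(kxv, s)), vscale(k, kdv * (1 - c)));
}

// ---- membrane pair potential (one-particle-thick fluid membrane) ---------
struct PotParams {
  double eps, mu, zeta, st0, rmin, rcut;
};

// c^(2 zeta - 1) with fast integer exponentiation when possible
static inline double pow_2zm1(double c, double zeta) {
  double k2 = 2.0 * zeta - 1.0;
  int k = (int)k2;
  if ((double)k == k2 && k >= 0 && k <= 32) {
    double r = 1.0, b = c;
    while (k) { if (k & 1) r *= b; b *= b; k >>= 1; }
    return r;
  }
  return std::pow(c, k2);
}

// Energy of a bead pair plus gradients. rv = x_j - x_i. Outputs: force on j
// is -grad_j U (force on i is +grad_j U); gni = dU/dn_i, gnj = dU/dn_j.
static inline double pair_eval(const Vec& rv, const Vec& ni, const Vec& nj,
                               const PotParams& P,
                               Vec& grad_j, Vec& gni, Vec& gnj) {
  double r = vnorm(rv);
  Vec rh = vscale(rv, 1.0 / r);
  double nidr = vdot(ni, rh), njdr = vdot(nj, rh), ninj = vdot(ni, nj);
  double st0 = P.st0;
  double a = ninj - nidr * njdr + st0 * (njdr - nidr) - st0 * st0;
  double U, dUdr, dUda;
  if (r < P.rmin) {
    double q2 = (P.rmin / r) * (P.rmin / r);
    double phi = 1.0 + P.mu * (a - 1.0);
    U = P.eps * (q2 * q2 - 2.0 * q2) + (1.0 - phi) * P.eps;
    dUdr = P.eps * 4.0 * (q2 / r) * (1.0 - q2);
    dUda = -P.mu * P.eps;
  } else {
    double t = (r - P.rmin) / (P.rcut - P.rmin);
    double xi = 0.5 * M_PI * t;
    double c = std::cos(xi);
    double phi = 1.0 + P.mu * (a - 1.0);
    double c2z1 = pow_2zm1(c, P.zeta);
    U = -P.eps * c2z1 * c * phi;
    dUdr = P.eps * phi * P.zeta * M_PI / (P.rcut - P.rmin) * c2z1 * std::sin(xi);
    dUda = -P.eps * c2z1 * c * P.mu;
  }
  // da/dn_i, da/dn_j, da/drhat
  Vec dani = vsub(vsub(nj, vscale(rh, njdr)), vscale(rh, st0));
  Vec danj = vadd(vsub(ni, vscale(rh, nidr)), vscale(rh, st0));
  Vec dar  = vadd(vscale(vadd(vscale(nj, nidr), vscale(ni, njdr)), -1.0),
                  vscale(vsub(nj, ni), st0));
  // grad_{x_j} a = (da/drhat - rhat (rhat . da/drhat)) / r
  Vec ga = vscale(vsub(dar, vscale(rh, vdot(rh, dar))), 1.0 / r);
  grad_j = vadd(vscale(rh, dUdr), vscale(ga, dUda));
  gni = vscale(dani, dUda);
  gnj = vscale(danj, dUda);
  return U;
}

// [[Rcpp::export]]
List pair_potential_cpp(NumericVector rvec, NumericVector ni, NumericVector nj,
                        double eps, double mu, double zeta, double theta0,
                        double rmin, double rcut) {
  Vec rv = {rvec[0], rvec[1], rvec[2]};
  double r = vnorm(rv);
  if (r <= 0) stop("zero-length separation: overlapping beads");
  PotParams P = {eps, mu, zeta, std::sin(theta0), rmin, rcut};
  Vec niv = {ni[0], ni[1], ni[2]}, njv = {nj[0], nj[1], nj[2]};
  Vec gj{0,0,0}, gni{0,0,0}, gnj{0,0,0};
  double U = 0.0;
  if (r < rcut) U = pair_eval(rv, niv, njv, P, gj, gni, gnj);
  else { gj = {0,0,0}; gni = {0,0,0}; gnj = {0,0,0}; }
  return List::create(
    _["energy"] = U,
    _["force_i"] = NumericVector::create(gj.x, gj.y, gj.z),
    _["force_j"] = NumericVector::create(-gj.x, -gj.y, -gj.z),
    _["dU_dni"] = NumericVector::create(gni.x, gni.y, gni.z),
    _["dU_dnj"] = NumericVector::create(gnj.x, gnj.y, gnj.z));
}

// WCA (purely repulsive, truncated-shifted at its minimum)
static inline double wca_eval(double r, double sig, double eps,
                              double& dUdr) {
  double s2 = (sig * sig) / (r * r);
  double s6 = s2 * s2 * s2;
  dUdr = 4.0 * eps * (-12.0 * s6 * s6 + 6.0 * s6) / r;
  return 4.0 * eps * (s6 * s6 - s6) + eps;
}

// adhesion well between a membrane bead and the nearest dumbbell lobe
// surface: minimum -eps_ad at contact distance h0, smooth cosine well out to
// rcut_ad, capped harmonic repulsion inside contact.
static inline double adhesion_eval(double h, double h0, double eps_ad,
                                   double rcut_ad, double k_rep, double f_cap,
                                   double& dUdh) {
  if (h >= rcut_ad) { dUdh = 0.0; return 0.0; }
  if (h >= h0) {
    double w = 0.5 * M_PI / (rcut_ad - h0);
    double xi = w * (h - h0);
    double c = std::cos(xi);
    dUdh = eps_ad * w * std::sin(2.0 * xi);
    return -eps_ad * c * c;
  }
  double f = k_rep * (h - h0);       // negative: pushes outward
  if (f < -f_cap) f = -f_cap;
  dUdh = f;
  double U = -eps_ad + 0.5 * k_rep * (h - h0) * (h - h0);
  return U;
}

// ---- cell list over beads + solutes --------------------------------------
struct CellList {
  double lo, cell;
  int G;
  std::vector<int> head, nxt;
  void build(const std::vector<Vec>& x, double box_half, double cutoff) {
    lo = -box_half;
    G = std::max(3, (int)std::floor(2.0 * box_half / cutoff));
    cell = 2.0 * box_half / G;
    head.assign(G * G * G, -1);
    nxt.assign(x.size(), -1);
    for (size_t i = 0; i < x.size(); ++i) {
      int cx = idx(x[i].x), cy = idx(x[i].y), cz = idx(x[i].z);
      int c = (cz * G + cy) * G + cx;
      nxt[i] = head[c]; head[c] = i;
    }
  }
  inline int idx(double v) const {
    int k = (int)std::floor((v - lo) / cell);
    if (k < 0) k = 0; if (k >= G) k = G - 1;
    return k;
  }
};

struct Diag {
  double pe = 0.0;
  double f_rad_in = 0.0, f_rad_out = 0.0; // radial solute force on membrane
};

struct Sim {
  // state
  std::vector<Vec> xb, nb, vb, wb;      // beads
  std::vector<Vec> xs, vs;              // solutes (inner first)
  int n_in = 0, n_out = 0;
  bool has_dumb = false;
  Vec cd{0,0,0}, ax{0,0,1}, vd{0,0,0}, wd{0,0,0};
  double a_lobe = 0.0;
  // params
  PotParams P;
  double dt, kBT, gamma_t, gamma_r;
  double eps_ad, rcut_ad, h0, k_rep, f_cap;
  double R_wall, k_wall;
  double m_s, In, Md, Id;
  bool interactions;
  XRng rng;
  // force arrays
  std::vector<Vec> fb, gn, fs;
  Vec fd{0,0,0}, td{0,0,0};
  CellList cl;

  Vec vesicle_center() const {
    Vec c{0,0,0};
    for (const Vec& p : xb) c = vadd(c, p);
    return vscale(c, 1.0 / xb.size());
  }

  double forces(Diag* diag) {
    size_t Nb = xb.size(), Ns = xs.size();
    fb.assign(Nb, Vec{0,0,0});
    gn.assign(Nb, Vec{0,0,0});
    fs.assign(Ns, Vec{0,0,0});
    fd = {0,0,0}; td = {0,0,0};
    if (diag) { diag->pe = 0.0; diag->f_rad_in = 0.0; diag->f_rad_out = 0.0; }
    double pe = 0.0;
    if (!interactions) return 0.0;

    Vec cves{0,0,0};
    double Rves = 1.0;
    if (diag && Ns > 0) {
      cves = vesicle_center();
      double acc = 0.0;
      for (const Vec& p : xb) acc += vnorm(vsub(p, cves));
      Rves = acc / Nb;
    }

    // combined positions for the cell list
    std::vector<Vec> all(Nb + Ns);
    for (size_t i = 0; i < Nb; ++i) all[i] = xb[i];
    for (size_t i = 0; i < Ns; ++i) all[Nb + i] = xs[i];
    double box_half = R_wall + 3.0;
    cl.build(all, box_half, std::max(P.rcut, 1.2));

    const double wca_bs_sig = 0.75, wca_bs_cut2 = std::pow(std::pow(2.,1./6)*0.75, 2);
    const double wca_ss_sig = 0.5,  wca_ss_cut2 = std::pow(std::pow(2.,1./6)*0.5, 2);
    double rcut2 = P.rcut * P.rcut;
    int G = cl.G;
    auto do_pair = [&](int i, int j) {
      Vec rv = vsub(all[j], all[i]);
      double r2 = vdot(rv, rv);
      bool ib = (size_t)i < Nb, jb = (size_t)j < Nb;
      if (ib && jb) {
        if (r2 >= rcut2) return;
        Vec gj, g1, g2;
        pe += pair_eval(rv, nb[i], nb[j], P, gj, g1, g2);
        fb[i] = vadd(fb[i], gj);
        fb[j] = vsub(fb[j], gj);
        gn[i] = vadd(gn[i], g1);
        gn[j] = vadd(gn[j], g2);
      } else if (!ib && !jb) {
        if (r2 >= wca_ss_cut2) return;
        double r = std::sqrt(r2), d;
        pe += wca_eval(r, wca_ss_sig, P.eps, d);
        Vec f = vscale(rv, -d / r); // force on j
        fs[j - Nb] = vadd(fs[j - Nb], f);
        fs[i - Nb] = vsub(fs[i - Nb], f);
      } else {
        if (r2 >= wca_bs_cut2) return;
        int bi = ib ? i : j;           // bead index
        int si = (ib ? j : i) - Nb;    // solute index
        Vec rbs = vsub(xs[si], xb[bi]); // bead -> solute
        double r = vnorm(rbs);
        double d;
        pe += wca_eval(r, wca_bs_sig, P.eps, d);
        Vec f_sol = vscale(rbs, -d / r);
        fs[si] = vadd(fs[si], f_sol);
        Vec f_bead = vscale(f_sol, -1.0);
        fb[bi] = vadd(fb[bi], f_bead);
        if (diag) {
          Vec rh = vunit(vsub(xb[bi], cves));
          double fr = vdot(f_bead, rh);
          if (si < n_in) diag->f_rad_in += fr;
          else diag->f_rad_out += fr;
        }
      }
    };
    // half stencil: each pair of cells visited once
    static const int OFF[13][3] = {
      {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
      {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
      {-1,1,1}, {0,1,1}, {1,1,1}};
    for (int cz = 0; cz < G; ++cz)
    for (int cy = 0; cy < G; ++cy)
    for (int cx = 0; cx < G; ++cx) {
      int c = (cz * G + cy) * G + cx;
      int hi = cl.head[c];
      if (hi < 0) continue;
      for (int i = hi; i >= 0; i = cl.nxt[i])
        for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
          do_pair(i, j);
      for (int k = 0; k < 13; ++k) {
        int nx = cx + OFF[k][0], ny = cy + OFF[k][1], nz = cz + OFF[k][2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= G || ny >= G || nz >= G)
          continue;
        int c2 = (nz * G + ny) * G + nx;
        if (cl.head[c2] < 0) continue;
        for (int i = hi; i >= 0; i = cl.nxt[i])
          for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j])
            do_pair(i, j);
      }
    }

    // dumbbell interactions
    if (has_dumb) {
      Vec c1 = vadd(cd, vscale(ax, a_lobe));
      Vec c2 = vsub(cd, vscale(ax, a_lobe));
      double reach = a_lobe + std::max(rcut_ad, 1.0) + 0.5;
      double reach2 = reach * reach;
      for (size_t i = 0; i < Nb; ++i) {
        Vec r1 = vsub(xb[i], c1), r2v = vsub(xb[i], c2);
        double d1sq = vdot(r1, r1), d2sq = vdot(r2v, r2v);
        bool near1 = d1sq <= d2sq;
        double dsq = near1 ? d1sq : d2sq;
        if (dsq > reach2) continue;
        double d = std::sqrt(dsq);
        double h = d - a_lobe;
        double dUdh;
        double U = adhesion_eval(h, h0, eps_ad, rcut_ad, k_rep, f_cap, dUdh);
        pe += U;
        Vec u = vscale(near1 ? r1 : r2v, 1.0 / d);
        Vec f_bead = vscale(u, -dUdh);
        fb[i] = vadd(fb[i], f_bead);
        Vec f_d = vscale(f_bead, -1.0);
        fd = vadd(fd, f_d);
        Vec arm = vsub(near1 ? c1 : c2, cd);
        td = vadd(td, vcross(arm, f_d));
      }
      // keep solutes out of the colloid
      for (size_t si = 0; si < Ns; ++si) {
        Vec r1 = vsub(xs[si], c1), r2v = vsub(xs[si], c2);
        double d1sq = vdot(r1, r1), d2sq = vdot(r2v, r2v);
        bool near1 = d1sq <= d2sq;
        double d = std::sqrt(near1 ? d1sq : d2sq);
        double h = d - a_lobe;
        if (h < 0.25) {
          double f = k_rep * (h - 0.25);
          if (f < -f_cap) f = -f_cap;
          pe += 0.5 * k_rep * (h - 0.25) * (h - 0.25);
          Vec u = vscale(near1 ? r1 : r2v, 1.0 / d);
          Vec f_sol = vscale(u, -f);
          fs[si] = vadd(fs[si], f_sol);
          Vec f_d = vscale(f_sol, -1.0);
          fd = vadd(fd, f_d);
          Vec arm = vsub(near1 ? c1 : c2, cd);
          td = vadd(td, vcross(arm, f_d));
        }
      }
    }

    // confining wall for solutes
    for (size_t si = 0; si < Ns; ++si) {
      double r = vnorm(xs[si]);
      if (r > R_wall) {
        double f = k_wall * (r - R_wall);
        pe += 0.5 * k_wall * (r - R_wall) * (r - R_wall);
        fs[si] = vsub(fs[si], vscale(xs[si], f / r));
      }
    }
    if (diag) diag->pe = pe;
    return pe;
  }

  void half_kick() {
    double h = 0.5 * dt;
    size_t Nb = xb.size();
    for (size_t i = 0; i < Nb; ++i) {
      vb[i] = vadd(vb[i], vscale(fb[i], h));        // m_b = 1
      Vec tau = vscale(vcross(nb[i], gn[i]), -1.0); // torque on the normal
      Vec w = vadd(wb[i], vscale(tau, h / In));
      wb[i] = vsub(w, vscale(nb[i], vdot(w, nb[i])));
    }
    for (size_t i = 0; i < xs.size(); ++i)
      vs[i] = vadd(vs[i], vscale(fs[i], h / m_s));
    if (has_dumb) {
      vd = vadd(vd, vscale(fd, h / Md));
      Vec w = vadd(wd, vscale(td, h / Id));
      wd = vsub(w, vscale(ax, vdot(w, ax)));
    }
  }

  void drift(double h) {
    size_t Nb = xb.size();
    for (size_t i = 0; i < Nb; ++i) {
      xb[i] = vadd(xb[i], vscale(vb[i], h));
      nb[i] = vunit(rotate_by(nb[i], wb[i], h));
    }
    for (size_t i = 0; i < xs.size(); ++i)
      xs[i] = vadd(xs[i], vscale(vs[i], h));
    if (has_dumb) {
      cd = vadd(cd, vscale(vd, h));
      ax = vunit(rotate_by(ax, wd, h));
    }
  }

  void o_step() {
    if (gamma_t <= 0.0 && gamma_r <= 0.0) return;
    double c1 = std::exp(-gamma_t * dt);
    double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
    double c1r = std::exp(-gamma_r * dt);
    double c2r = std::sqrt(std::max(0.0, 1.0 - c1r * c1r));
    double sb = std::sqrt(kBT);            // m_b = 1
    double sn = std::sqrt(kBT / In);
    double ss = std::sqrt(kBT / m_s);
    size_t Nb = xb.size();
    for (size_t i = 0; i < Nb; ++i) {
      vb[i] = {c1 * vb[i].x + c2 * sb * rng.norm(),
               c1 * vb[i].y + c2 * sb * rng.norm(),
               c1 * vb[i].z + c2 * sb * rng.norm()};
      Vec w = {c1r * wb[i].x + c2r * sn * rng.norm(),
               c1r * wb[i].y + c2r * sn * rng.norm(),
               c1r * wb[i].z + c2r * sn * rng.norm()};
      wb[i] = vsub(w, vscale(nb[i], vdot(w, nb[i])));
    }
    for (size_t i = 0; i < xs.size(); ++i) {
      vs[i] = {c1 * vs[i].x + c2 * ss * rng.norm(),
               c1 * vs[i].y + c2 * ss * rng.norm(),
               c1 * vs[i].z + c2 * ss * rng.norm()};
    }
    if (has_dumb) {
      double sd = std::sqrt(kBT / Md), sw = std::sqrt(kBT / Id);
      vd = {c1 * vd.x + c2 * sd * rng.norm(),
            c1 * vd.y + c2 * sd * rng.norm(),
            c1 * vd.z + c2 * sd * rng.norm()};
      Vec w = {c1r * wd.x + c2r * sw * rng.norm(),
               c1r * wd.y + c2r * sw * rng.norm(),
               c1r * wd.z + c2r * sw * rng.norm()};
      wd = vsub(w, vscale(ax, vdot(w, ax)));
    }
  }

  // neighbour counts of beads within the membrane cutoff (rupture check)
  IntegerVector neighbour_counts() {
    size_t Nb = xb.size();
    cl.build(xb, R_wall + 3.0, P.rcut);
    IntegerVector cnt(Nb);
    double rcut2 = P.rcut * P.rcut;
    int G = cl.G;
    for (int cz = 0; cz < G; ++cz)
    for (int cy = 0; cy < G; ++cy)
    for (int cx = 0; cx < G; ++cx) {
      int c = (cz * G + cy) * G + cx;
      for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
        for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx + dx, ny = cy + dy, nz = cz + dz;
          if (nx < 0 || ny < 0 || nz < 0 || nx >= G || ny >= G || nz >= G)
            continue;
          int c2 = (nz * G + ny) * G + nx;
          for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j]) {
            if (j <= i) continue;
            Vec rv = vsub(xb[j], xb[i]);
            if (vdot(rv, rv) < rcut2) { cnt[i]++; cnt[j]++; }
          }
        }
      }
    }
    return cnt;
  }
};

static std::vector<Vec> mat_to_vec(const NumericMatrix& m) {
  std::vector<Vec> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = {m(i,0), m(i,1), m(i,2)};
  return v;
}
static NumericMatrix vec_to_mat(const std::vector<Vec>& v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i,0) = v[i].x; m(i,1) = v[i].y; m(i,2) = v[i].z;
  }
  return m;
}

// [[Rcpp::export]]
List run_dynamics_cpp(NumericMatrix beads, NumericMatrix normals,
                      NumericMatrix solutes_in, NumericMatrix solutes_out,
                      List dumbbell, List pot, List sim) {
  Sim S;
  S.xb = mat_to_vec(beads);
  S.nb = mat_to_vec(normals);
  size_t Nb = S.xb.size();
  S.n_in = solutes_in.nrow();
  S.n_out = solutes_out.nrow();
  S.xs.resize(S.n_in + S.n_out);
  for (int i = 0; i < S.n_in; ++i)
    S.xs[i] = {solutes_in(i,0), solutes_in(i,1), solutes_in(i,2)};
  for (int i = 0; i < S.n_out; ++i)
    S.xs[S.n_in + i] = {solutes_out(i,0), solutes_out(i,1), solutes_out(i,2)};

  S.P = {as<double>(pot["epsilon"]), as<double>(pot["mu"]),
         as<double>(pot["zeta"]), std::sin(as<double>(pot["theta0"])),
         as<double>(pot["r_min"]), as<double>(pot["r_cut"])};
  S.dt = as<double>(sim["dt"]);
  S.kBT = as<double>(sim["kBT"]);
  S.gamma_t = as<double>(sim["gamma_t"]);
  S.gamma_r = as<double>(sim["gamma_r"]);
  S.eps_ad = as<double>(sim["epsilon_ad"]);
  S.rcut_ad = as<double>(sim["r_cut_ad"]);
  S.h0 = as<double>(sim["contact_h"]);
  S.k_rep = as<double>(sim["k_rep"]);
  S.f_cap = as<double>(sim["f_cap"]);
  S.R_wall = as<double>(sim["R_wall"]);
  S.k_wall = as<double>(sim["k_wall"]);
  S.m_s = as<double>(sim["m_solute"]);
  S.In = as<double>(sim["inertia_n"]);
  S.interactions = as<bool>(sim["interactions"]);
  S.rng.seed((uint64_t)as<double>(sim["seed"]));
  int n_steps = as<int>(sim["n_steps"]);
  int stride = as<int>(sim["stride"]);
  int diag_stride = as<int>(sim["diag_stride"]);
  bool store_solutes = as<bool>(sim["store_solutes"]);
  bool rupture_on = as<bool>(sim["rupture_check"]);
  int rupture_every = as<int>(sim["rupture_every"]);
  bool thermal_init = as<bool>(sim["thermal_init"]);

  S.has_dumb = dumbbell.size() > 0;
  if (S.has_dumb) {
    NumericVector c0 = dumbbell["center"], a0 = dumbbell["axis"];
    S.cd = {c0[0], c0[1], c0[2]};
    S.ax = vunit(Vec{a0[0], a0[1], a0[2]});
    S.a_lobe = as<double>(dumbbell["a"]);
    double ml = 8.0 * S.a_lobe * S.a_lobe * S.a_lobe; // bead-density lobes
    S.Md = 2.0 * ml;
    S.Id = 2.8 * ml * S.a_lobe * S.a_lobe;
  } else { S.Md = 1.0; S.Id = 1.0; }

  // initial velocities
  S.vb.assign(Nb, Vec{0,0,0});
  S.wb.assign(Nb, Vec{0,0,0});
  S.vs.assign(S.xs.size(), Vec{0,0,0});
  if (thermal_init && S.kBT > 0) {
    double sb = std::sqrt(S.kBT), sn = std::sqrt(S.kBT / S.In);
    double ss = std::sqrt(S.kBT / S.m_s);
    for (size_t i = 0; i < Nb; ++i) {
      S.vb[i] = {sb*S.rng.norm(), sb*S.rng.norm(), sb*S.rng.norm()};
      Vec w = {sn*S.rng.norm(), sn*S.rng.norm(), sn*S.rng.norm()};
      S.wb[i] = vsub(w, vscale(S.nb[i], vdot(w, S.nb[i])));
    }
    for (size_t i = 0; i < S.xs.size(); ++i)
      S.vs[i] = {ss*S.rng.norm(), ss*S.rng.norm(), ss*S.rng.norm()};
  }

  int n_snap = n_steps / stride + 1;
  List snap_beads(n_snap), snap_normals(n_snap), snap_solutes(n_snap);
  NumericMatrix snap_cd(n_snap, 3), snap_ax(n_snap, 3);
  NumericVector snap_t(n_snap);
  int n_diag_max = n_steps / diag_stride + 2;
  NumericVector d_t(n_diag_max), d_pe(n_diag_max), d_ke(n_diag_max),
                d_kerot(n_diag_max), d_pin(n_diag_max), d_pout(n_diag_max);
  int isnap = 0, idiag = 0;
  bool ruptured = false;
  int rupture_step = -1;
  std::vector<int> low_since(Nb, 0);

  Diag dg;
  S.forces(&dg);

  auto record_snap = [&](double tnow) {
    snap_beads[isnap] = vec_to_mat(S.xb);
    snap_normals[isnap] = vec_to_mat(S.nb);
    if (store_solutes) snap_solutes[isnap] = vec_to_mat(S.xs);
    snap_cd(isnap,0)=S.cd.x; snap_cd(isnap,1)=S.cd.y; snap_cd(isnap,2)=S.cd.z;
    snap_ax(isnap,0)=S.ax.x; snap_ax(isnap,1)=S.ax.y; snap_ax(isnap,2)=S.ax.z;
    snap_t[isnap] = tnow;
    ++isnap;
  };
  auto record_diag = [&](double tnow) {
    double ke = 0, kerot = 0;
    for (size_t i = 0; i < Nb; ++i) {
      ke += 0.5 * vdot(S.vb[i], S.vb[i]);
      kerot += 0.5 * S.In * vdot(S.wb[i], S.wb[i]);
    }
    d_t[idiag] = tnow; d_pe[idiag] = dg.pe;
    d_ke[idiag] = ke; d_kerot[idiag] = kerot;
    // instantaneous pressures from radial solute force on the membrane
    Vec cv = S.vesicle_center();
    double Racc = 0;
    for (const Vec& p : S.xb) Racc += vnorm(vsub(p, cv));
    double Rv = Racc / Nb;
    double area = 4.0 * M_PI * Rv * Rv;
    d_pin[idiag] = dg.f_rad_in / area;
    d_pout[idiag] = -dg.f_rad_out / area;
    ++idiag;
  };

  record_snap(0.0);
  record_diag(0.0);

  for (int step = 1; step <= n_steps; ++step) {
    S.half_kick();
    S.drift(0.5 * S.dt);
    S.o_step();
    S.drift(0.5 * S.dt);
    bool want_diag = (step % diag_stride == 0);
    S.forces(want_diag ? &dg : nullptr);
    S.half_kick();
    double tnow = step * S.dt;
    if (want_diag) record_diag(tnow);
    if (step % stride == 0) record_snap(tnow);
    if (rupture_on && step % rupture_every == 0) {
      IntegerVector cnt = S.neighbour_counts();
      bool bad = false;
      for (size_t i = 0; i < Nb; ++i) {
        if (cnt[i] < 3) {
          low_since[i] += rupture_every;
          if (low_since[i] > 100) bad = true;
        } else low_since[i] = 0;
      }
      if (bad) { ruptured = true; rupture_step = step; break; }
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // trim snapshot lists if terminated early
  if (isnap < n_snap) {
    snap_beads = snap_beads[Range(0, isnap - 1)];
    snap_normals = snap_normals[Range(0, isnap - 1)];
    if (store_solutes) snap_solutes = snap_solutes[Range(0, isnap - 1)];
  }

  NumericMatrix xs_in(S.n_in, 3), xs_out(S.n_out, 3);
  for (int i = 0; i < S.n_in; ++i) {
    xs_in(i,0)=S.xs[i].x; xs_in(i,1)=S.xs[i].y; xs_in(i,2)=S.xs[i].z;
  }
  for (int i = 0; i < S.n_out; ++i) {
    xs_out(i,0)=S.xs[S.n_in+i].x; xs_out(i,1)=S.xs[S.n_in+i].y;
    xs_out(i,2)=S.xs[S.n_in+i].z;
  }

  return List::create(
    _["times"] = snap_t[Range(0, isnap - 1)],
    _["beads"] = snap_beads,
    _["normals"] = snap_normals,
    _["solutes"] = snap_solutes,
    _["dumbbell_center"] = snap_cd(Range(0, isnap - 1), _),
    _["dumbbell_axis"] = snap_ax(Range(0, isnap - 1), _),
    _["diag"] = List::create(
      _["time"] = d_t[Range(0, idiag - 1)],
      _["pe"] = d_pe[Range(0, idiag - 1)],
      _["ke_trans"] = d_ke[Range(0, idiag - 1)],
      _["ke_rot"] = d_kerot[Range(0, idiag - 1)],
      _["p_in"] = d_pin[Range(0, idiag - 1)],
      _["p_out"] = d_pout[Range(0, idiag - 1)]),
    _["final"] = List::create(
      _["beads"] = vec_to_mat(S.xb), _["normals"] = vec_to_mat(S.nb),
      _["solutes_in"] = xs_in, _["solutes_out"] = xs_out,
      _["dumbbell_center"] = NumericVector::create(S.cd.x, S.cd.y, S.cd.z),
      _["dumbbell_axis"] = NumericVector::create(S.ax.x, S.ax.y, S.ax.z)),
    _["ruptured"] = ruptured,
    _["rupture_step"] = rupture_step);
}
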