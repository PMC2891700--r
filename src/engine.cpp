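// Langevin CG-MD engine: tabulated nonbonded pair forces (force column is
// primary; energies are exact integrals of the linearly interpolated force,
// so forces are exact negative gradients of the energy by construction),
// polynomial bond/angle terms, cosine-series torsions, harmonic impropers
// and position restraints. BAOAB splitting; reduces to velocity Verlet at
// zero friction. Uses R's RNG so set.seed() gives bitwise-reproducible
// trajectories.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/(mol K)

struct PairTable {
  double r0, dr, rmax;
  std::vector<double> f;  // force at knots
  std::vector<double> I;  // integral of f from knot k to last knot
  // energy and force at distance r (zero beyond rmax; linear force
  // continuation below r0)
  inline void eval(double r, double &e, double &fr, int &wall) const {
    if (r >= rmax) { e = 0.0; fr = 0.0; return; }
    if (r < r0) {
      ++wall;
      e = I[0] + f[0] * (r0 - r);
      fr = f[0];
      return;
    }
    double s = (r - r0) / dr;
    int k = (int)s;
    if (k >= (int)f.size() - 1) k = f.size() - 2;
    double t = s - k;
    double fk = f[k] + t * (f[k + 1] - f[k]);
    // integral from r to knot k+1 of linear force
    double seg = (1.0 - t) * dr * 0.5 * (fk + f[k + 1]);
    e = I[k + 1] + seg;
    fr = fk;
  }
};

struct System {
  int n;
  std::vector<double> mass;
  std::vector<int> type;            // 0-based type index per site
  std::vector<int> paircol;         // K*K -> table index (-1 none)
  int K;
  std::vector<PairTable> tables;
  double cutoff;
  std::vector<std::vector<int> > excl; // sorted exclusion partners per site
  bool has_box;
  double box[3];
  // bonded
  std::vector<int> bond_i, bond_j;
  std::vector<std::array<double,6> > bond_c;   // x0,c0..c4 in r (nm)
  std::vector<int> ang_i, ang_j, ang_k;
  std::vector<std::array<double,6> > ang_c;    // x0,c0..c4 in theta (rad)
  std::vector<int> tor_i, tor_j, tor_k, tor_l;
  std::vector<std::array<double,5> > tor_a;    // a0..a4 cosine series
  std::vector<std::array<double,4> > tor_b;    // b1..b4 sine series
  std::vector<int> imp_i, imp_j, imp_k, imp_l;
  std::vector<std::array<double,2> > imp_p;    // k, phi0 (rad)
  std::vector<int> rst_i;
  std::vector<std::array<double,4> > rst_p;    // k, x0,y0,z0
};

static inline void min_image(const System &S, double *d) {
  if (!S.has_box) return;
  for (int c = 0; c < 3; ++c) d[c] -= S.box[c] * std::round(d[c] / S.box[c]);
}

static inline bool excluded(const System &S, int i, int j) {
  const std::vector<int> &e = S.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

static System build_system(const List &sys) {
  System S;
  S.mass = as<std::vector<double> >(sys["mass"]);
  S.n = S.mass.size();
  S.type = as<std::vector<int> >(sys["type"]);        // 0-based
  S.paircol = as<std::vector<int> >(sys["paircol"]);  // 0-based, -1 = none
  S.K = as<int>(sys["K"]);
  S.cutoff = as<double>(sys["cutoff"]);
  List tl = sys["tables"];
  for (int t = 0; t < tl.size(); ++t) {
    List one = tl[t];
    PairTable pt;
    pt.r0 = as<double>(one["r0"]);
    pt.dr = as<double>(one["dr"]);
    pt.f = as<std::vector<double> >(one["f"]);
    pt.rmax = pt.r0 + pt.dr * (pt.f.size() - 1);
    pt.I.assign(pt.f.size(), 0.0);
    for (int k = (int)pt.f.size() - 2; k >= 0; --k)
      pt.I[k] = pt.I[k + 1] + pt.dr * 0.5 * (pt.f[k] + pt.f[k + 1]);
    S.tables.push_back(pt);
  }
  S.excl.resize(S.n);
  IntegerMatrix ex = sys["exclusions"];
  for (int r = 0; r < ex.nrow(); ++r) {
    int a = ex(r, 0) - 1, b = ex(r, 1) - 1;
    S.excl[a].push_back(b);
    S.excl[b].push_back(a);
  }
  for (int i = 0; i < S.n; ++i) std::sort(S.excl[i].begin(), S.excl[i].end());
  NumericVector bx = sys["box"];
  S.has_box = bx.size() == 3;
  if (S.has_box) for (int c = 0; c < 3; ++c) S.box[c] = bx[c];
  IntegerMatrix bi = sys["bonds_idx"];
  NumericMatrix bc = sys["bonds_coef"];
  for (int r = 0; r < bi.nrow(); ++r) {
    S.bond_i.push_back(bi(r, 0) - 1);
    S.bond_j.push_back(bi(r, 1) - 1);
    std::array<double,6> c;
    for (int k = 0; k < 6; ++k) c[k] = bc(r, k);
    S.bond_c.push_back(c);
  }
  IntegerMatrix ai = sys["angles_idx"];
  NumericMatrix ac = sys["angles_coef"];
  for (int r = 0; r < ai.nrow(); ++r) {
    S.ang_i.push_back(ai(r, 0) - 1);
    S.ang_j.push_back(ai(r, 1) - 1);
    S.ang_k.push_back(ai(r, 2) - 1);
    std::array<double,6> c;
    for (int k = 0; k < 6; ++k) c[k] = ac(r, k);
    S.ang_c.push_back(c);
  }
  IntegerMatrix ti = sys["torsions_idx"];
  NumericMatrix ta = sys["torsions_cos"];
  NumericMatrix tb = sys["torsions_sin"];
  for (int r = 0; r < ti.nrow(); ++r) {
    S.tor_i.push_back(ti(r, 0) - 1);
    S.tor_j.push_back(ti(r, 1) - 1);
    S.tor_k.push_back(ti(r, 2) - 1);
    S.tor_l.push_back(ti(r, 3) - 1);
    std::array<double,5> a;
    for (int k = 0; k < 5; ++k) a[k] = ta(r, k);
    S.tor_a.push_back(a);
    std::array<double,4> b;
    for (int k = 0; k < 4; ++k) b[k] = tb(r, k);
    S.tor_b.push_back(b);
  }
  IntegerMatrix ii = sys["impropers_idx"];
  NumericMatrix ip = sys["impropers_par"];
  for (int r = 0; r < ii.nrow(); ++r) {
    S.imp_i.push_back(ii(r, 0) - 1);
    S.imp_j.push_back(ii(r, 1) - 1);
    S.imp_k.push_back(ii(r, 2) - 1);
    S.imp_l.push_back(ii(r, 3) - 1);
    S.imp_p.push_back({ip(r, 0), ip(r, 1)});
  }
  IntegerMatrix ri = sys["restraints_idx"];
  NumericMatrix rp = sys["restraints_par"];
  for (int r = 0; r < ri.nrow(); ++r) {
    S.rst_i.push_back(ri(r, 0) - 1);
    S.rst_p.push_back({rp(r, 0), rp(r, 1), rp(r, 2), rp(r, 3)});
  }
  return S;
}

// polynomial sum c_k (x-x0)^k and derivative
static inline void poly_eval(const std::array<double,6> &c, double x,
                             double &v, double &dv) {
  double u = x - c[0];
  v = c[1] + u * (c[2] + u * (c[3] + u * (c[4] + u * c[5])));
  dv = c[2] + u * (2 * c[3] + u * (3 * c[4] + u * 4 * c[5]));
}

struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref; // positions at build time
  double skin;
  void build(const System &S, const std::vector<double> &x) {
    pi.clear(); pj.clear();
    double rl = S.cutoff + skin;
    double rl2 = rl * rl;
    for (int i = 0; i < S.n; ++i) {
      for (int j = i + 1; j < S.n; ++j) {
        if (excluded(S, i, j)) continue;
        double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1],
                       x[3*i+2] - x[3*j+2]};
        min_image(S, d);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < rl2) { pi.push_back(i); pj.push_back(j); }
      }
    }
    ref = x;
  }
  bool stale(const System &S, const std::vector<double> &x) const {
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < S.n; ++i) {
      double d[3] = {x[3*i] - ref[3*i], x[3*i+1] - ref[3*i+1],
                     x[3*i+2] - ref[3*i+2]};
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 > lim) return true;
    }
    return false;
  }
};

struct Energies { double bonded, nonbonded, restraint; int wall; };

static Energies forces(const System &S, const NeighborList &nl,
                       const std::vector<double> &x,
                       std::vector<double> &F) {
  Energies E = {0.0, 0.0, 0.0, 0};
  std::fill(F.begin(), F.end(), 0.0);
  // nonbonded
  for (size_t p = 0; p < nl.pi.size(); ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    int col = S.paircol[S.type[i] * S.K + S.type[j]];
    if (col < 0) stop("missing pair table for types %d,%d", S.type[i] + 1,
                      S.type[j] + 1);
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    min_image(S, d);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (r2 >= S.cutoff * S.cutoff) continue;
    double r = std::sqrt(r2);
    double e, fr;
    S.tables[col].eval(r, e, fr, E.wall);
    E.nonbonded += e;
    double c = fr / r;
    for (int cdim = 0; cdim < 3; ++cdim) {
      F[3*i + cdim] += c * d[cdim];
      F[3*j + cdim] -= c * d[cdim];
    }
  }
  // bonds
  for (size_t b = 0; b < S.bond_i.size(); ++b) {
    int i = S.bond_i[b], j = S.bond_j[b];
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    min_image(S, d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double v, dv;
    poly_eval(S.bond_c[b], r, v, dv);
    E.bonded += v;
    double c = -dv / r;
    for (int cd = 0; cd < 3; ++cd) {
      F[3*i + cd] += c * d[cd];
      F[3*j + cd] -= c * d[cd];
    }
  }
  // angles
  for (size_t a = 0; a < S.ang_i.size(); ++a) {
    int i = S.ang_i[a], j = S.ang_j[a], k = S.ang_k[a];
    double u[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double v[3] = {x[3*k] - x[3*j], x[3*k+1] - x[3*j+1], x[3*k+2] - x[3*j+2]};
    min_image(S, u); min_image(S, v);
    double lu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    double lv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    double ct = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (lu * lv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    double ve, dv;
    poly_eval(S.ang_c[a], th, ve, dv);
    E.bonded += ve;
    double coef = -dv;
    for (int cd = 0; cd < 3; ++cd) {
      double gi = (ct * u[cd] / lu - v[cd] / lv) / (lu * st);
      double gk = (ct * v[cd] / lv - u[cd] / lu) / (lv * st);
      F[3*i + cd] += coef * gi;
      F[3*k + cd] += coef * gk;
      F[3*j + cd] -= coef * (gi + gk);
    }
  }
  // torsions + impropers share the dihedral machinery
  size_t ntor = S.tor_i.size(), nimp = S.imp_i.size();
  for (size_t t = 0; t < ntor + nimp; ++t) {
    bool imp = t >= ntor;
    int i = imp ? S.imp_i[t - ntor] : S.tor_i[t];
    int j = imp ? S.imp_j[t - ntor] : S.tor_j[t];
    int k = imp ? S.imp_k[t - ntor] : S.tor_k[t];
    int l = imp ? S.imp_l[t - ntor] : S.tor_l[t];
    double b1[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
    double b2[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
    double b3[3] = {x[3*l]-x[3*k], x[3*l+1]-x[3*k+1], x[3*l+2]-x[3*k+2]};
    min_image(S, b1); min_image(S, b2); min_image(S, b3);
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double lb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-14 || n2sq < 1e-14 || lb2 < 1e-8) continue;
    double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                    n1[0]*b2[1]-n1[1]*b2[0]};
    double xdot = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double ydot = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / lb2;
    double phi = std::atan2(ydot, xdot);
    double v, dvdphi;
    if (imp) {
      const std::array<double,2> &pp = S.imp_p[t - ntor];
      double dphi = phi - pp[1];
      while (dphi > M_PI) dphi -= 2 * M_PI;
      while (dphi < -M_PI) dphi += 2 * M_PI;
      v = 0.5 * pp[0] * dphi * dphi;
      dvdphi = pp[0] * dphi;
    } else {
      const std::array<double,5> &a = S.tor_a[t];
      const std::array<double,4> &bb = S.tor_b[t];
      v = 0.0; dvdphi = 0.0;
      for (int n = 0; n < 5; ++n) {
        v += a[n] * std::cos(n * phi);
        dvdphi -= a[n] * n * std::sin(n * phi);
      }
      for (int n = 1; n <= 4; ++n) {
        v += bb[n-1] * std::sin(n * phi);
        dvdphi += bb[n-1] * n * std::cos(n * phi);
      }
    }
    E.bonded += v;
    // gradients of phi (Blondel-Karplus): g_i = (|b2|/|n1|^2) n1,
    // g_l = -(|b2|/|n2|^2) n2, g_j = -(1+s) g_i + t g_l, sum g = 0
    double sdot = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (lb2*lb2);
    double tdot = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (lb2*lb2);
    for (int cd = 0; cd < 3; ++cd) {
      double gi = (lb2 / n1sq) * n1[cd];
      double gl = -(lb2 / n2sq) * n2[cd];
      double gj = -(1.0 + sdot) * gi + tdot * gl;
      double gk = -gi - gj - gl;
      F[3*i + cd] -= dvdphi * gi;
      F[3*j + cd] -= dvdphi * gj;
      F[3*k + cd] -= dvdphi * gk;
      F[3*l + cd] -= dvdphi * gl;
    }
  }
  // restraints
  for (size_t r = 0; r < S.rst_i.size(); ++r) {
    int i = S.rst_i[r];
    const std::array<double,4> &p = S.rst_p[r];
    double dx[3] = {x[3*i] - p[1], x[3*i+1] - p[2], x[3*i+2] - p[3]};
    E.restraint += 0.5 * p[0] * (dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2]);
    for (int cd = 0; cd < 3; ++cd) F[3*i + cd] -= p[0] * dx[cd];
  }
  return E;
}

// [[Rcpp::export(name = ".cg_forces_cpp")]]
List cg_forces_cpp(NumericMatrix pos, List sys) {
  System S = build_system(sys);
  if (pos.nrow() != S.n) stop("position/topology size mismatch");
  std::vector<double> x(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i + c] = pos(i, c);
  NeighborList nl;
  nl.skin = 0.0;
  nl.build(S, x);
  std::vector<double> F(3 * S.n);
  Energies E = forces(S, nl, x, F);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) Fm(i, c) = F[3*i + c];
  return List::create(_["forces"] = Fm, _["e_bonded"] = E.bonded,
                      _["e_nonbonded"] = E.nonbonded,
                      _["e_restraint"] = E.restraint,
                      _["wall_hits"] = E.wall);
}

// [[Rcpp::export(name = ".cg_run_cpp")]]
List cg_run_cpp(NumericMatrix pos, NumericMatrix vel, List sys,
                int n_steps, double dt, double gamma, double temperature,
                int stride, double skin) {
  System S = build_system(sys);
  if (pos.nrow() != S.n || vel.nrow() != S.n)
    stop("position/velocity/topology size mismatch");
  std::vector<double> x(3 * S.n), v(3 * S.n), F(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3*i + c] = pos(i, c);
      v[3*i + c] = vel(i, c);
    }
  NeighborList nl;
  nl.skin = skin;
  nl.build(S, x);
  Energies E = forces(S, nl, x, F);
  int n_frames = n_steps / stride + 1;
  NumericVector traj(Dimension(S.n, 3, n_frames));
  NumericMatrix en(n_frames, 5); // time, bonded, nonbonded, restraint, kin
  colnames(en) = CharacterVector::create("time", "bonded", "nonbonded",
                                         "restraint", "kinetic");
  long wall_total = 0;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  int frame = 0;
  RNGScope rngs;
  auto record = [&](int step) {
    double ekin = 0.0;
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        ekin += 0.5 * S.mass[i] * v[3*i + c] * v[3*i + c];
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        traj[frame * 3 * S.n + c * S.n + i] = x[3*i + c];
    en(frame, 0) = step * dt;
    en(frame, 1) = E.bonded;
    en(frame, 2) = E.nonbonded;
    en(frame, 3) = E.restraint;
    en(frame, 4) = ekin;
    ++frame;
  };
  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3*i + c] += 0.5 * dt * F[3*i + c] / S.mass[i];
    // A
    for (int i = 0; i < 3 * S.n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; ++i) {
        double sd = std::sqrt(KB * temperature / S.mass[i]);
        for (int c = 0; c < 3; ++c)
          v[3*i + c] = c1 * v[3*i + c] + c2 * sd * R::norm_rand();
      }
    }
    // A
    for (int i = 0; i < 3 * S.n; ++i) x[i] += 0.5 * dt * v[i];
    if (nl.skin > 0.0 ? nl.stale(S, x) : true) nl.build(S, x);
    E = forces(S, nl, x, F);
    wall_total += E.wall;
    for (int i = 0; i < 3 * S.n; ++i) {
      if (!std::isfinite(F[i]))
        stop("non-finite force at step %d (site %d)", step, i / 3 + 1);
    }
    // B
    for (int i = 0; i < S.n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3*i + c] += 0.5 * dt * F[3*i + c] / S.mass[i];
    if (step % stride == 0) record(step);
  }
  NumericMatrix xf(S.n, 3), vf(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) {
      xf(i, c) = x[3*i + c];
      vf(i, c) = v[3*i + c];
    }
  return List::create(_["positions"] = traj, _["energies"] = en,
                      _["final_pos"] = xf, _["final_vel"] = vf,
                      _["wall_hits"] = (double)wall_total);
}
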