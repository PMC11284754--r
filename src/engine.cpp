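// MD engine: Langevin dynamics of the 3-bead lipid membrane with a
// rigid nanoparticle, zero-tension XY barostat, Verlet neighbor list
// and stochastic ligand-receptor Morse bond kinetics.
//
// Conventions: periodic (minimum image) in X and Y only; Z is open.
// Kind codes (1-based from R): 1 lipid_head, 2 lipid_tail,
// 3 receptor_head, 4 np_surface, 5 ligand. All masses are 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <chrono>

using namespace Rcpp;

// ---------------------------------------------------------------------
// deterministic RNG: splitmix-seeded xoshiro256++, own Box-Muller
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_g = false;
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
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // zero-mean unit-variance uniform kick (thermostat random forces;
  // only the first two moments matter for Langevin thermalization)
  inline double rfrc() {
    return (2.0 * unif() - 1.0) * 1.7320508075688772;
  }
  bool have_g; double g2;
  inline double gauss() {
    if (have_g) { have_g = false; return g2; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    g2 = v * f; have_g = true;
    return u * f;
  }
};

struct PairTab {
  // 5x5 flattened tables (0-based kinds)
  int type[25];       // 0 none, 1 wca, 2 cos
  double b[25], wc[25];
  double rc2[25];     // squared WCA cutoff (2^(1/6) b)^2
  double rcut2[25];   // squared full cutoff (incl. cos tail)
  double b2[25];      // b^2
  // tabulated tail force fr(r^2) = (1/r) dU/dr for the cos region,
  // linear interpolation on an r^2 grid (forces only; energies are
  // always evaluated exactly)
  static const int NTAB = 4096;
  std::vector<std::vector<double> > ftab;
  std::vector<double> tab_lo, tab_inv;
  void build_tail_tables() {
    ftab.assign(25, std::vector<double>());
    tab_lo.assign(25, 0.0); tab_inv.assign(25, 0.0);
    for (int t = 0; t < 25; ++t) {
      if (type[t] != 2) continue;
      double lo = rc2[t], hi = rcut2[t];
      double rc = std::sqrt(rc2[t]);
      std::vector<double> &tb = ftab[t];
      tb.resize(NTAB + 2);
      for (int k = 0; k <= NTAB + 1; ++k) {
        double r2 = lo + (hi - lo) * k / NTAB;
        double r = std::sqrt(r2);
        double arg = M_PI * (r - rc) / (2.0 * wc[t]);
        tb[k] = M_PI / (2.0 * wc[t]) * std::sin(2.0 * arg) / r;
      }
      tab_lo[t] = lo;
      tab_inv[t] = NTAB / (hi - lo);
    }
  }
};

struct Engine {
  int n;
  std::vector<double> x, v, xu, f;   // 3n
  std::vector<int> kind;             // 0-based
  std::vector<int> b1, b2v;          // FENE bonds (0-based)
  std::vector<int> bn1, bn2;         // per-bead bonded neighbors (-1)
  std::vector<int> a1, a2, a3;       // angles
  std::vector<int> partner;          // per-bead LR partner (-1 none)
  std::vector<int> ligands, receptors;
  std::vector<int> rigid;            // particle bead indices
  std::vector<char> is_rigid;
  double Lx, Ly;
  PairTab pt;
  // bonded / morse parameters
  double K1, rmax2, K2, theta0;      // theta0 radians
  double m_eps, m_r0, m_alpha, m_rcut2;
  // integration
  double dt, T, gamma_, tauP, KA, target_tension;
  bool thermostat, barostat, rigid_mobile, debug;
  double fext[3];
  int bond_interval;
  double p_form, rform2, rbreak2;
  // neighbor list: pairs split by potential type with cached params;
  // short-range (WCA) and long-range (cos) pairs use separate Verlet
  // radii so the repulsive majority carries the short cutoff
  double rlist, rlist2, skin;
  double listlim2[25];  // per kind-pair squared list radius
  std::vector<int> nb_i, nb_j;          // receptor-ligand pairs (kinetics)
  std::vector<int> w_i, w_j;            // WCA-only pairs
  std::vector<unsigned char> w_t;       // kind-pair index per pair
  std::vector<int> c_i, c_j;            // cos (WCA core + tail) pairs
  std::vector<unsigned char> c_t;
  std::vector<double> xlist;
  long n_rebuilds = 0;
  long morse_evals = 0;
  double t_build = 0, t_force = 0, t_other = 0;
  long n_pairs_w = 0, n_pairs_c = 0;
  // rigid body
  double com[3], vcom[3], omega[3], Mbody, Ibody;
  // virial accumulators (pair + bond + angle + morse), lateral and zz
  double wlat, wzz;
  double morse_sum;                  // current bonded Morse energy
  Rng rng;

  Engine(uint64_t seed) : rng(seed) {}

  double invLx, invLy;
  inline void minimg(double &dx, double &dy) const {
    if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
    if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
  }
  inline void set_box(double lx, double ly) {
    Lx = lx; Ly = ly; invLx = 1.0 / lx; invLy = 1.0 / ly;
  }

  inline void add_pair(int i, int j) {
    int tij = kind[i] * 5 + kind[j];
    int ty = pt.type[tij];
    if (ty == 0) return;
    // 1-2 exclusion: directly bonded pairs interact through the FENE
    // bond (with its internal WCA core), not the pair table
    if (bn1[i] == j || bn2[i] == j) return;
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    minimg(dx, dy);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= listlim2[tij]) return;
    if (ty == 1) {
      w_i.push_back(i); w_j.push_back(j);
      w_t.push_back((unsigned char)tij);
      bool lr = (kind[i] == 4 && kind[j] == 2) ||
                (kind[i] == 2 && kind[j] == 4);
      if (lr) { nb_i.push_back(i); nb_j.push_back(j); }
    } else {
      c_i.push_back(i); c_j.push_back(j);
      c_t.push_back((unsigned char)tij);
    }
  }

  // per-pair-kind Verlet radii: WCA pairs list to their short cutoff,
  // cos pairs to the full attraction range, receptor-ligand pairs
  // additionally to the bond capture radius; cells use the maximum
  void set_list_radii(double rform) {
    double rmaxall = 0.0;
    for (int t = 0; t < 25; ++t) {
      if (pt.type[t] == 0) { listlim2[t] = 0.0; continue; }
      double lim = std::sqrt(pt.rcut2[t]);
      int ki = t / 5, kj = t % 5;
      bool lr = (ki == 4 && kj == 2) || (ki == 2 && kj == 4);
      if (lr && rform > lim) lim = rform;
      lim += skin;
      listlim2[t] = lim * lim;
      rmaxall = std::max(rmaxall, lim);
    }
    rlist = rmaxall;
    rlist2 = rlist * rlist;
  }

  void build_list() {
    auto tb0 = std::chrono::steady_clock::now();
    ++n_rebuilds;
    nb_i.clear(); nb_j.clear();
    w_i.clear(); w_j.clear(); w_t.clear();
    c_i.clear(); c_j.clear(); c_t.clear();
    // cells of ~rlist/2 with a range-2 half stencil: finer cells cut
    // the candidate volume per bead by ~2x versus rlist-sized cells
    const int rng_c = 2;
    double cell = rlist / rng_c;
    int ncx = std::max(1, (int)std::floor(Lx / cell));
    int ncy = std::max(1, (int)std::floor(Ly / cell));
    double zmin = 1e300, zmax = -1e300;
    for (int i = 0; i < n; ++i) {
      zmin = std::min(zmin, x[3 * i + 2]);
      zmax = std::max(zmax, x[3 * i + 2]);
    }
    int ncz = std::max(1, (int)std::floor((zmax - zmin + 1e-9) / cell) + 1);
    double czw = (zmax - zmin) / ncz + 1e-12;
    bool small = (ncx < 2 * rng_c + 1 || ncy < 2 * rng_c + 1);
    if (small) {
      // brute-force list for tiny boxes
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) add_pair(i, j);
      }
      xlist.assign(x.begin(), x.end());
      n_pairs_w = (long)w_i.size(); n_pairs_c = (long)c_i.size();
      t_build += std::chrono::duration<double>(std::chrono::steady_clock::now() - tb0).count();
      return;
    }
    std::vector<int> headc(ncx * ncy * ncz, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      double xi = x[3 * i], yi = x[3 * i + 1];
      xi -= Lx * std::floor(xi / Lx);
      yi -= Ly * std::floor(yi / Ly);
      int a = std::min(ncx - 1, (int)(xi / Lx * ncx));
      int b = std::min(ncy - 1, (int)(yi / Ly * ncy));
      int c = std::min(ncz - 1, (int)((x[3 * i + 2] - zmin) / czw));
      ci[i] = a; cj[i] = b; ck[i] = c;
      int id = (c * ncy + b) * ncx + a;
      nxt[i] = headc[id]; headc[id] = i;
    }
    // forward half stencil: offsets lexicographically above (0,0,0),
    // pruned to cells whose nearest corner is within rlist
    std::vector<int> sx, sy, sz;
    for (int dc = 0; dc <= rng_c; ++dc) {
      for (int db = (dc == 0 ? 0 : -rng_c); db <= rng_c; ++db) {
        for (int da = (dc == 0 && db == 0 ? 1 : -rng_c); da <= rng_c; ++da) {
          double gx = std::max(0, std::abs(da) - 1) * cell;
          double gy = std::max(0, std::abs(db) - 1) * cell;
          double gz = std::max(0, std::abs(dc) - 1) * cell;
          if (gx * gx + gy * gy + gz * gz > rlist2) continue;
          sx.push_back(da); sy.push_back(db); sz.push_back(dc);
        }
      }
    }
    const int nst = (int)sx.size();
    for (int i = 0; i < n; ++i) {
      for (int j = nxt[i]; j >= 0; j = nxt[j]) add_pair(i, j);
      for (int s = 0; s < nst; ++s) {
        int c = ck[i] + sz[s];
        if (c < 0 || c >= ncz) continue;
        int b = (cj[i] + sy[s] + ncy) % ncy;
        int a = (ci[i] + sx[s] + ncx) % ncx;
        for (int j = headc[(c * ncy + b) * ncx + a]; j >= 0; j = nxt[j]) {
          add_pair(i, j);
        }
      }
    }
    xlist.assign(x.begin(), x.end());
    n_pairs_w = (long)w_i.size(); n_pairs_c = (long)c_i.size();
    t_build += std::chrono::duration<double>(std::chrono::steady_clock::now() - tb0).count();
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - xlist[3 * i];
      double dy = x[3 * i + 1] - xlist[3 * i + 1];
      double dz = x[3 * i + 2] - xlist[3 * i + 2];
      // box rescales can alias displacement through the boundary;
      // minimum-image the lateral part
      if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
      if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // conservative forces + virial; returns -1 or index of overstretched
  // FENE bond
  int forces(double &epot, bool want_energy) {
    auto tf0 = std::chrono::steady_clock::now();
    std::fill(f.begin(), f.end(), 0.0);
    wlat = 0.0; wzz = 0.0; epot = 0.0; morse_sum = 0.0;
    // WCA-only pairs
    {
      const size_t np = w_i.size();
      const int *pi = w_i.data(), *pj = w_j.data();
      const unsigned char *ptid = w_t.data();
      for (size_t k = 0; k < np; ++k) {
        int i = pi[k], j = pj[k];
        double dx = x[3 * j] - x[3 * i];
        double dy = x[3 * j + 1] - x[3 * i + 1];
        double dz = x[3 * j + 2] - x[3 * i + 2];
        minimg(dx, dy);
        double r2 = dx * dx + dy * dy + dz * dz;
        int t = ptid[k];
        if (r2 >= pt.rc2[t]) continue;
        double inv2 = pt.b2[t] / r2;
        double s6 = inv2 * inv2 * inv2;
        double fr = -24.0 * (2.0 * s6 * s6 - s6) / r2;  // dU/dr / r
        if (want_energy) epot += 4.0 * (s6 * s6 - s6) + 1.0;
        double fx = -fr * dx, fy = -fr * dy, fz = -fr * dz;
        f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
        f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
        wlat += fx * dx + fy * dy; wzz += fz * dz;
      }
    }
    // cos-attraction pairs (WCA core + smooth tail)
    {
      const size_t np = c_i.size();
      const int *pi = c_i.data(), *pj = c_j.data();
      const unsigned char *ptid = c_t.data();
      for (size_t k = 0; k < np; ++k) {
        int i = pi[k], j = pj[k];
        double dx = x[3 * j] - x[3 * i];
        double dy = x[3 * j + 1] - x[3 * i + 1];
        double dz = x[3 * j + 2] - x[3 * i + 2];
        minimg(dx, dy);
        double r2 = dx * dx + dy * dy + dz * dz;
        int t = ptid[k];
        if (r2 >= pt.rcut2[t]) continue;
        double fr;
        if (r2 < pt.rc2[t]) {
          double inv2 = pt.b2[t] / r2;
          double s6 = inv2 * inv2 * inv2;
          fr = -24.0 * (2.0 * s6 * s6 - s6) / r2;
          if (want_energy) epot += 4.0 * (s6 * s6 - s6);  // +1 - 1 shift
        } else {
          // tail region: tabulated (1/r) dU/dr
          double u = (r2 - pt.tab_lo[t]) * pt.tab_inv[t];
          int k0 = (int)u;
          double wgt = u - k0;
          const double *tb = pt.ftab[t].data();
          fr = tb[k0] * (1.0 - wgt) + tb[k0 + 1] * wgt;
          if (want_energy) {
            double r = std::sqrt(r2);
            double rc = std::sqrt(pt.rc2[t]);
            double arg = M_PI * (r - rc) / (2.0 * pt.wc[t]);
            double c = std::cos(arg); epot += -c * c;
          }
        }
        double fx = -fr * dx, fy = -fr * dy, fz = -fr * dz;
        f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
        f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
        wlat += fx * dx + fy * dy; wzz += fz * dz;
      }
    }
    // FENE bonds (with the engine-convention WCA core, sigma = 1)
    const double bond_rc2 = std::pow(2.0, 1.0 / 3.0);
    for (size_t k = 0; k < b1.size(); ++k) {
      int i = b1[k], j = b2v[k];
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      minimg(dx, dy);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax2) return (int)k;
      double fr = K1 / (1.0 - r2 / rmax2); // dU/dr / r = K1/(1-(r/rmax)^2)
      if (want_energy) epot += -0.5 * K1 * rmax2 * std::log(1.0 - r2 / rmax2);
      if (r2 < bond_rc2) {
        double inv2 = 1.0 / r2;
        double s6 = inv2 * inv2 * inv2;
        fr += -24.0 * (2.0 * s6 * s6 - s6) / r2;
        if (want_energy) epot += 4.0 * (s6 * s6 - s6) + 1.0;
      }
      double fx = -fr * dx, fy = -fr * dy, fz = -fr * dz;
      f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
      f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
      wlat += fx * dx + fy * dy; wzz += fz * dz;
    }
    // harmonic angles about theta0 (i-j-k with j central)
    for (size_t t = 0; t < a1.size(); ++t) {
      int i = a1[t], j = a2[t], k = a3[t];
      double d1x = x[3 * i] - x[3 * j], d1y = x[3 * i + 1] - x[3 * j + 1];
      double d1z = x[3 * i + 2] - x[3 * j + 2];
      double d2x = x[3 * k] - x[3 * j], d2y = x[3 * k + 1] - x[3 * j + 1];
      double d2z = x[3 * k + 2] - x[3 * j + 2];
      minimg(d1x, d1y); minimg(d2x, d2y);
      double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
      double r2l = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
      double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2l);
      if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double th = std::acos(c);
      double dU = 2.0 * K2 * (th - theta0);   // dU/dtheta
      if (want_energy) epot += K2 * (th - theta0) * (th - theta0);
      double coef = dU / s;
      double f1x = coef * (d2x / (r1 * r2l) - c * d1x / (r1 * r1));
      double f1y = coef * (d2y / (r1 * r2l) - c * d1y / (r1 * r1));
      double f1z = coef * (d2z / (r1 * r2l) - c * d1z / (r1 * r1));
      double f2x = coef * (d1x / (r1 * r2l) - c * d2x / (r2l * r2l));
      double f2y = coef * (d1y / (r1 * r2l) - c * d2y / (r2l * r2l));
      double f2z = coef * (d1z / (r1 * r2l) - c * d2z / (r2l * r2l));
      f[3 * i] += f1x; f[3 * i + 1] += f1y; f[3 * i + 2] += f1z;
      f[3 * k] += f2x; f[3 * k + 1] += f2y; f[3 * k + 2] += f2z;
      f[3 * j] -= f1x + f2x; f[3 * j + 1] -= f1y + f2y; f[3 * j + 2] -= f1z + f2z;
      wlat += f1x * d1x + f1y * d1y + f2x * d2x + f2y * d2y;
      wzz += f1z * d1z + f2z * d2z;
    }
    // Morse on bonded LR pairs (evaluation cutoff = break distance)
    for (size_t k = 0; k < ligands.size(); ++k) {
      int i = ligands[k], j = partner[i];
      if (j < 0) continue;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      minimg(dx, dy);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= m_rcut2) continue;
      ++morse_evals;
      double r = std::sqrt(r2);
      double e = std::exp(-m_alpha * (r - m_r0));
      double u = m_eps * ((1.0 - e) * (1.0 - e) - 1.0);
      morse_sum += u;
      if (want_energy) epot += u;
      double du = 2.0 * m_eps * m_alpha * e * (1.0 - e); // dU/dr
      double fr = du / r;
      double fx = -fr * dx, fy = -fr * dy, fz = -fr * dz;
      f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
      f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
      wlat += fx * dx + fy * dy; wzz += fz * dz;
    }
    t_force += std::chrono::duration<double>(std::chrono::steady_clock::now() - tf0).count();
    // external force on the rigid body (Newton-check utility)
    if (!rigid.empty()) {
      double pershare = 1.0 / rigid.size();
      for (size_t k = 0; k < rigid.size(); ++k) {
        int i = rigid[k];
        f[3 * i] += fext[0] * pershare;
        f[3 * i + 1] += fext[1] * pershare;
        f[3 * i + 2] += fext[2] * pershare;
      }
    }
    return -1;
  }

  void body_setup() {
    Mbody = (double)rigid.size();
    com[0] = com[1] = com[2] = 0.0;
    for (size_t k = 0; k < rigid.size(); ++k) {
      int i = rigid[k];
      com[0] += x[3 * i]; com[1] += x[3 * i + 1]; com[2] += x[3 * i + 2];
    }
    for (int d = 0; d < 3; ++d) com[d] /= Mbody;
    double tr = 0.0;
    for (size_t k = 0; k < rigid.size(); ++k) {
      int i = rigid[k];
      double rx = x[3 * i] - com[0], ry = x[3 * i + 1] - com[1],
             rz = x[3 * i + 2] - com[2];
      tr += rx * rx + ry * ry + rz * rz;
    }
    Ibody = std::max(1e-12, 2.0 / 3.0 * tr); // isotropic inertia approx
    vcom[0] = vcom[1] = vcom[2] = 0.0;
    omega[0] = omega[1] = omega[2] = 0.0;
  }

  void body_step() {
    if (rigid.empty() || !rigid_mobile) return;
    double F[3] = {0, 0, 0}, tq[3] = {0, 0, 0};
    for (size_t k = 0; k < rigid.size(); ++k) {
      int i = rigid[k];
      double rx = x[3 * i] - com[0], ry = x[3 * i + 1] - com[1],
             rz = x[3 * i + 2] - com[2];
      F[0] += f[3 * i]; F[1] += f[3 * i + 1]; F[2] += f[3 * i + 2];
      tq[0] += ry * f[3 * i + 2] - rz * f[3 * i + 1];
      tq[1] += rz * f[3 * i] - rx * f[3 * i + 2];
      tq[2] += rx * f[3 * i + 1] - ry * f[3 * i];
    }
    if (thermostat) {
      double st = std::sqrt(2.0 * gamma_ * Mbody * T / dt);
      double sr = std::sqrt(2.0 * gamma_ * Ibody * T / dt);
      for (int d = 0; d < 3; ++d) {
        F[d] += -gamma_ * Mbody * vcom[d] + st * rng.rfrc();
        tq[d] += -gamma_ * Ibody * omega[d] + sr * rng.rfrc();
      }
    }
    for (int d = 0; d < 3; ++d) {
      vcom[d] += dt * F[d] / Mbody;
      omega[d] += dt * tq[d] / Ibody;
    }
    double dcom[3] = {dt * vcom[0], dt * vcom[1], dt * vcom[2]};
    // rotate beads about the (moved) COM by |omega| dt (Rodrigues)
    double wnorm = std::sqrt(omega[0] * omega[0] + omega[1] * omega[1] +
                             omega[2] * omega[2]);
    double ang = wnorm * dt;
    double kx = 0, ky = 0, kz = 1, ca = 1, sa = 0;
    if (ang > 1e-14) {
      kx = omega[0] / wnorm; ky = omega[1] / wnorm; kz = omega[2] / wnorm;
      ca = std::cos(ang); sa = std::sin(ang);
    }
    for (size_t k = 0; k < rigid.size(); ++k) {
      int i = rigid[k];
      double rx = x[3 * i] - com[0], ry = x[3 * i + 1] - com[1],
             rz = x[3 * i + 2] - com[2];
      double cx = ky * rz - kz * ry, cy = kz * rx - kx * rz,
             cz = kx * ry - ky * rx;
      double dot = kx * rx + ky * ry + kz * rz;
      double nx = rx * ca + cx * sa + kx * dot * (1 - ca);
      double ny = ry * ca + cy * sa + ky * dot * (1 - ca);
      double nz = rz * ca + cz * sa + kz * dot * (1 - ca);
      double newx = com[0] + dcom[0] + nx;
      double newy = com[1] + dcom[1] + ny;
      double newz = com[2] + dcom[2] + nz;
      xu[3 * i] += newx - x[3 * i];
      xu[3 * i + 1] += newy - x[3 * i + 1];
      xu[3 * i + 2] += newz - x[3 * i + 2];
      x[3 * i] = newx; x[3 * i + 1] = newy; x[3 * i + 2] = newz;
      // bead velocity = vcom + omega x r (for output/energy only)
      v[3 * i] = vcom[0] + omega[1] * nz - omega[2] * ny;
      v[3 * i + 1] = vcom[1] + omega[2] * nx - omega[0] * nz;
      v[3 * i + 2] = vcom[2] + omega[0] * ny - omega[1] * nx;
    }
    for (int d = 0; d < 3; ++d) com[d] += dcom[d];
  }

  void update_bonds() {
    // break: any bond stretched beyond the break distance
    for (size_t k = 0; k < ligands.size(); ++k) {
      int i = ligands[k], j = partner[i];
      if (j < 0) continue;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      minimg(dx, dy);
      if (dx * dx + dy * dy + dz * dz > rbreak2) {
        partner[i] = -1; partner[j] = -1;
      }
    }
    // form: unbound-unbound pairs within the capture radius, random
    // order, coin flip per pair, valence preserved
    std::vector<int> ci, cj;
    for (size_t k = 0; k < nb_i.size(); ++k) {
      int i = nb_i[k], j = nb_j[k];
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      minimg(dx, dy);
      if (dx * dx + dy * dy + dz * dz <= rform2) {
        ci.push_back(i); cj.push_back(j);
      }
    }
    int m = (int)ci.size();
    for (int k = m - 1; k > 0; --k) { // Fisher-Yates
      int r = (int)(rng.unif() * (k + 1));
      if (r > k) r = k;
      std::swap(ci[k], ci[r]); std::swap(cj[k], cj[r]);
    }
    for (int k = 0; k < m; ++k) {
      int i = ci[k], j = cj[k];
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      if (rng.unif() < p_form) { partner[i] = j; partner[j] = i; }
    }
    if (debug) {
      // valence audit: injective both ways
      for (size_t k = 0; k < ligands.size(); ++k) {
        int i = ligands[k], j = partner[i];
        if (j >= 0 && partner[j] != i) stop("valence violation detected");
      }
      for (size_t k = 0; k < receptors.size(); ++k) {
        int j = receptors[k], i = partner[j];
        if (i >= 0 && partner[i] != j) stop("valence violation detected");
      }
    }
  }
};

static void unpack_tables(Engine &E, List ffpack) {
  IntegerMatrix tt = ffpack["pair_type_code"]; // 5x5: 0 none 1 wca 2 cos
  NumericMatrix bb = ffpack["pair_b"];
  NumericMatrix ww = ffpack["pair_wc"];
  for (int i = 0; i < 5; ++i) for (int j = 0; j < 5; ++j) {
    int id = i * 5 + j;
    E.pt.type[id] = tt(i, j);
    E.pt.b[id] = bb(i, j);
    E.pt.wc[id] = ww(i, j);
    double rc = std::pow(2.0, 1.0 / 6.0) * bb(i, j);
    E.pt.rc2[id] = rc * rc;
    double full = (tt(i, j) == 2) ? rc + ww(i, j) : rc;
    if (tt(i, j) == 0) full = 0.0;
    E.pt.rcut2[id] = full * full;
    E.pt.b2[id] = bb(i, j) * bb(i, j);
  }
  E.K1 = as<double>(ffpack["K1"]);
  double rmax = as<double>(ffpack["fene_rmax"]);
  E.rmax2 = rmax * rmax;
  E.K2 = as<double>(ffpack["K2"]);
  E.theta0 = as<double>(ffpack["theta0"]) * M_PI / 180.0;
  E.m_eps = as<double>(ffpack["morse_eps"]);
  E.m_r0 = as<double>(ffpack["morse_r0"]);
  E.m_alpha = as<double>(ffpack["morse_alpha"]);
  double mc = as<double>(ffpack["morse_rcut"]);
  E.m_rcut2 = mc * mc;
  E.pt.build_tail_tables();
}

static void load_state(Engine &E, NumericMatrix pos, NumericMatrix vel,
                       NumericMatrix xuM, IntegerVector kinds,
                       IntegerMatrix bonds, IntegerMatrix angles,
                       IntegerVector lr, IntegerVector rigid_idx,
                       NumericVector box) {
  E.n = pos.nrow();
  E.x.resize(3 * E.n); E.v.resize(3 * E.n);
  E.xu.resize(3 * E.n); E.f.assign(3 * E.n, 0.0);
  E.kind.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      E.x[3 * i + d] = pos(i, d);
      E.v[3 * i + d] = vel(i, d);
      E.xu[3 * i + d] = xuM(i, d);
    }
    E.kind[i] = kinds[i] - 1;
  }
  E.bn1.assign(E.n, -1); E.bn2.assign(E.n, -1);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    E.b1.push_back(i); E.b2v.push_back(j);
    (E.bn1[i] < 0 ? E.bn1[i] : E.bn2[i]) = j;
    (E.bn1[j] < 0 ? E.bn1[j] : E.bn2[j]) = i;
  }
  for (int k = 0; k < angles.nrow(); ++k) {
    E.a1.push_back(angles(k, 0) - 1);
    E.a2.push_back(angles(k, 1) - 1);
    E.a3.push_back(angles(k, 2) - 1);
  }
  E.partner.assign(E.n, -1);
  for (int i = 0; i < E.n; ++i) {
    if (lr[i] > 0) E.partner[i] = lr[i] - 1;
    if (E.kind[i] == 4) E.ligands.push_back(i);
    if (E.kind[i] == 2) E.receptors.push_back(i);
  }
  E.is_rigid.assign(E.n, 0);
  for (int k = 0; k < rigid_idx.size(); ++k) {
    E.rigid.push_back(rigid_idx[k] - 1);
    E.is_rigid[rigid_idx[k] - 1] = 1;
  }
  E.set_box(box[0], box[1]);
}

// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, NumericMatrix xuM,
                IntegerVector kinds, IntegerMatrix bonds,
                IntegerMatrix angles, IntegerVector lr,
                IntegerVector rigid_idx, NumericVector box,
                List ffpack, List params) {
  Engine E((uint64_t)as<double>(params["seed"]));
  unpack_tables(E, ffpack);
  load_state(E, pos, vel, xuM, kinds, bonds, angles, lr, rigid_idx, box);
  E.dt = as<double>(params["dt"]);
  E.T = as<double>(params["temperature"]);
  E.gamma_ = as<double>(params["gamma"]);
  E.tauP = as<double>(params["barostat_damp"]);
  E.KA = as<double>(params["area_modulus"]);
  E.target_tension = as<double>(params["target_tension"]);
  E.thermostat = as<bool>(params["thermostat"]);
  E.barostat = as<bool>(params["barostat"]);
  E.rigid_mobile = as<bool>(params["rigid_mobile"]);
  E.debug = as<bool>(params["debug"]);
  E.bond_interval = as<int>(params["bond_check_interval"]);
  double rform = as<double>(params["r_form"]);
  E.rform2 = rform * rform;
  E.p_form = as<double>(params["p_form"]);
  double rbreak = as<double>(params["r_break"]);
  E.rbreak2 = rbreak * rbreak;
  NumericVector fe = params["f_ext"];
  E.fext[0] = fe[0]; E.fext[1] = fe[1]; E.fext[2] = fe[2];
  bool kinetics_on = as<bool>(params["kinetics"]);
  int nsteps = as<int>(params["nsteps"]);
  int obs_stride = as<int>(params["obs_stride"]);
  int frame_stride = as<int>(params["frame_stride"]);
  E.skin = as<double>(params["skin"]);
  E.set_list_radii(rform);

  if (!E.rigid.empty()) E.body_setup();
  E.build_list();
  double epot = 0.0;
  int bad = E.forces(epot, false);
  if (bad >= 0) stop("FENE bond overstretched at step 0 (bond %d)", bad + 1);

  int nfree = 0;
  for (int i = 0; i < E.n; ++i) if (!E.is_rigid[i]) ++nfree;
  // Gronbech-Jensen/Farago Langevin parameters: unbiased configurational
  // sampling and an unbiased half-step velocity estimator at finite dt
  const double gj_a = (1.0 - E.gamma_ * E.dt / 2.0) /
                      (1.0 + E.gamma_ * E.dt / 2.0);
  const double gj_b = 1.0 / (1.0 + E.gamma_ * E.dt / 2.0);
  const double beta_s = E.thermostat ?
      std::sqrt(2.0 * E.gamma_ * E.T * E.dt) : 0.0;
  std::vector<double> fold(E.f), beta(3 * E.n, 0.0);
  double sum_dx2 = 0.0;   // for the half-step kinetic temperature
  double baro_acc = 0.0; int baro_cnt = 0; const int baro_every = 10;

  std::vector<double> ob_t, ob_T, ob_A, ob_ten, ob_wf, ob_nb, ob_epot;
  List frames;
  std::vector<double> frame_times;
  double time0 = 0.0;
  int n_lig = (int)E.ligands.size();

  auto record_obs = [&](double tnow) {
    // half-step (GJF) velocity estimator: unbiased kinetic temperature
    double Tkin = nfree > 0 ?
        sum_dx2 / (gj_b * E.dt * E.dt) / (3.0 * nfree) : 0.0;
    double A = E.Lx * E.Ly;
    double klat = 0.0, kzz = 0.0;
    for (int i = 0; i < E.n; ++i) {
      klat += E.v[3 * i] * E.v[3 * i] + E.v[3 * i + 1] * E.v[3 * i + 1];
      kzz += E.v[3 * i + 2] * E.v[3 * i + 2];
    }
    double tension = ((kzz + E.wzz) - 0.5 * (klat + E.wlat)) / A;
    int nbonds = 0;
    for (int k = 0; k < n_lig; ++k) if (E.partner[E.ligands[k]] >= 0) ++nbonds;
    double wf = 0.0;
    if (n_lig > 0) {
      wf = -E.morse_sum / (n_lig * E.m_eps);
      if (wf < 0) wf = 0; if (wf > 1) wf = 1;
    }
    ob_t.push_back(tnow); ob_T.push_back(Tkin); ob_A.push_back(A);
    ob_ten.push_back(tension); ob_wf.push_back(wf);
    ob_nb.push_back(nbonds); ob_epot.push_back(epot);
  };

  for (int step = 1; step <= nsteps; ++step) {
    // GJF position update (+ periodic wrap in XY)
    sum_dx2 = 0.0;
    for (int i = 0; i < E.n; ++i) {
      if (E.is_rigid[i]) continue;
      for (int d = 0; d < 3; ++d) {
        double bt = beta_s > 0.0 ? beta_s * E.rng.rfrc() : 0.0;
        beta[3 * i + d] = bt;
        double dxd = gj_b * E.dt * E.v[3 * i + d] +
                     0.5 * gj_b * E.dt * E.dt * E.f[3 * i + d] +
                     0.5 * gj_b * E.dt * bt;
        E.x[3 * i + d] += dxd;
        E.xu[3 * i + d] += dxd;
        sum_dx2 += dxd * dxd;
      }
      if (E.x[3 * i] < 0) E.x[3 * i] += E.Lx;
      else if (E.x[3 * i] >= E.Lx) E.x[3 * i] -= E.Lx;
      if (E.x[3 * i + 1] < 0) E.x[3 * i + 1] += E.Ly;
      else if (E.x[3 * i + 1] >= E.Ly) E.x[3 * i + 1] -= E.Ly;
    }
    // rigid body: uses forces from the previous evaluation
    E.body_step();

    if (E.need_rebuild()) E.build_list();
    bool want_e = (obs_stride > 0 && step % obs_stride == 0);
    int bad = E.forces(epot, want_e);
    if (bad >= 0) {
      stop("integration failure: FENE bond %d overstretched at step %d",
           bad + 1, step);
    }
    // barostat: average the noisy instantaneous tension over a short
    // interval, then rescale; per-step rescaling against instantaneous
    // fluctuations does correlated work on the system and heats it
    if (E.barostat) {
      double klat = 0.0, kzz = 0.0;
      for (int i = 0; i < E.n; ++i) {
        klat += E.v[3 * i] * E.v[3 * i] + E.v[3 * i + 1] * E.v[3 * i + 1];
        kzz += E.v[3 * i + 2] * E.v[3 * i + 2];
      }
      double A = E.Lx * E.Ly;
      double tension = ((kzz + E.wzz) - 0.5 * (klat + E.wlat)) / A;
      baro_acc += tension;
      ++baro_cnt;
      if (baro_cnt < baro_every) goto after_barostat;
      tension = baro_acc / baro_cnt;
      baro_acc = 0.0; baro_cnt = 0;
      double dA = -(baro_every * E.dt) / (E.tauP * E.KA) *
                  (tension - E.target_tension);
      if (dA > 0.01) dA = 0.01; if (dA < -0.01) dA = -0.01;
      double mu = std::sqrt(1.0 + dA);
      E.set_box(E.Lx * mu, E.Ly * mu);
      if (E.Lx < 4.0 || E.Ly < 4.0) stop("barostat collapse: box below 4 sigma");
      for (int i = 0; i < E.n; ++i) {
        if (E.is_rigid[i]) continue;
        E.x[3 * i] *= mu; E.x[3 * i + 1] *= mu;
        E.xu[3 * i] *= mu; E.xu[3 * i + 1] *= mu;
      }
      if (!E.rigid.empty()) {
        // rigid body: scale the COM only, preserving shape
        double dcx = E.com[0] * (mu - 1.0), dcy = E.com[1] * (mu - 1.0);
        for (size_t k = 0; k < E.rigid.size(); ++k) {
          int i = E.rigid[k];
          E.x[3 * i] += dcx; E.x[3 * i + 1] += dcy;
          E.xu[3 * i] += dcx; E.xu[3 * i + 1] += dcy;
        }
        E.com[0] += dcx; E.com[1] += dcy;
      }
    }
    after_barostat:;
    // GJF velocity update from old and new conservative forces
    for (int i = 0; i < E.n; ++i) {
      if (E.is_rigid[i]) continue;
      for (int d = 0; d < 3; ++d) {
        E.v[3 * i + d] = gj_a * E.v[3 * i + d] +
                         0.5 * E.dt * (gj_a * fold[3 * i + d] + E.f[3 * i + d]) +
                         gj_b * beta[3 * i + d];
      }
    }
    fold = E.f;
    if (kinetics_on && E.bond_interval > 0 && step % E.bond_interval == 0) {
      E.update_bonds();
    }
    double tnow = time0 + step * E.dt;
    if (obs_stride > 0 && step % obs_stride == 0) record_obs(tnow);
    if (frame_stride > 0 && step % frame_stride == 0) {
      NumericMatrix fx(E.n, 3), fxu(E.n, 3);
      for (int i = 0; i < E.n; ++i) for (int d = 0; d < 3; ++d) {
        fx(i, d) = E.x[3 * i + d]; fxu(i, d) = E.xu[3 * i + d];
      }
      IntegerVector flr(E.n);
      for (int i = 0; i < E.n; ++i) flr[i] = E.partner[i] + 1;
      frames.push_back(List::create(_["time"] = tnow, _["x"] = fx,
                                    _["xu"] = fxu,
                                    _["box"] = NumericVector::create(E.Lx, E.Ly),
                                    _["lr_bonds"] = flr));
      frame_times.push_back(tnow);
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < 3 * E.n; ++i) {
        if (!std::isfinite(E.x[i])) {
          stop("integration failure: non-finite coordinate at step %d", step);
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix outx(E.n, 3), outv(E.n, 3), outxu(E.n, 3);
  for (int i = 0; i < E.n; ++i) for (int d = 0; d < 3; ++d) {
    outx(i, d) = E.x[3 * i + d];
    outv(i, d) = E.v[3 * i + d];
    outxu(i, d) = E.xu[3 * i + d];
  }
  IntegerVector outlr(E.n);
  for (int i = 0; i < E.n; ++i) outlr[i] = E.partner[i] + 1;
  DataFrame obs = DataFrame::create(
    _["time"] = ob_t, _["temperature"] = ob_T, _["area"] = ob_A,
    _["tension"] = ob_ten, _["wrap_fraction"] = ob_wf,
    _["bond_count"] = ob_nb, _["potential_energy"] = ob_epot);
  return List::create(
    _["x"] = outx, _["v"] = outv, _["xu"] = outxu,
    _["box"] = NumericVector::create(E.Lx, E.Ly),
    _["lr_bonds"] = outlr, _["obs"] = obs, _["frames"] = frames,
    _["n_rebuilds"] = (double)E.n_rebuilds,
    _["morse_evals"] = (double)E.morse_evals,
    _["t_build"] = E.t_build, _["t_force"] = E.t_force,
    _["n_pairs_w"] = (double)E.n_pairs_w,
    _["n_pairs_c"] = (double)E.n_pairs_c);
}

// total nonbonded energy via the neighbor-list path (oracle comparisons)
// [[Rcpp::export]]
double nb_energy_cpp(NumericMatrix pos, IntegerVector kinds,
                     NumericVector box, List ffpack) {
  Engine E(1);
  unpack_tables(E, ffpack);
  int n = pos.nrow();
  E.n = n;
  E.x.resize(3 * n); E.v.assign(3 * n, 0.0); E.xu.assign(3 * n, 0.0);
  E.f.assign(3 * n, 0.0);
  E.kind.resize(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) E.x[3 * i + d] = pos(i, d);
    E.kind[i] = kinds[i] - 1;
  }
  E.partner.assign(n, -1);
  E.bn1.assign(n, -1); E.bn2.assign(n, -1);
  E.set_box(box[0], box[1]);
  E.skin = 0.4;
  E.set_list_radii(0.0);
  E.build_list();
  double epot = 0.0;
  // pairs only (no bonds/angles registered)
  E.forces(epot, true);
  return epot;
}

// conservative forces (pairs + bonds + angles + bonded Morse), for
// finite-difference validation
// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerVector kinds,
                         IntegerMatrix bonds, IntegerMatrix angles,
                         IntegerVector lr, NumericVector box, List ffpack) {
  Engine E(1);
  unpack_tables(E, ffpack);
  NumericMatrix vel(pos.nrow(), 3), xuM(pos.nrow(), 3);
  load_state(E, pos, vel, xuM, kinds, bonds, angles, lr,
             IntegerVector(0), box);
  E.fext[0] = E.fext[1] = E.fext[2] = 0.0;
  E.skin = 0.4;
  E.set_list_radii(0.0);
  E.build_list();
  double epot = 0.0;
  int bad = E.forces(epot, true);
  if (bad >= 0) stop("FENE bond overstretched");
  NumericMatrix out(E.n, 3);
  for (int i = 0; i < E.n; ++i) for (int d = 0; d < 3; ++d) {
    out(i, d) = E.f[3 * i + d];
  }
  out.attr("potential_energy") = epot;
  return out;
}

// total bonded + nonbonded potential energy (same paths as the engine)
// [[Rcpp::export]]
double energy_cpp(NumericMatrix pos, IntegerVector kinds,
                  IntegerMatrix bonds, IntegerMatrix angles,
                  IntegerVector lr, NumericVector box, List ffpack) {
  Engine E(1);
  unpack_tables(E, ffpack);
  NumericMatrix vel(pos.nrow(), 3), xuM(pos.nrow(), 3);
  load_state(E, pos, vel, xuM, kinds, bonds, angles, lr,
             IntegerVector(0), box);
  E.fext[0] = E.fext[1] = E.fext[2] = 0.0;
  E.skin = 0.4;
  E.set_list_radii(0.0);
  E.build_list();
  double epot = 0.0;
  int bad = E.forces(epot, true);
  if (bad >= 0) stop("FENE bond overstretched");
  return epot;
}

// one stochastic bond-kinetics update on a static configuration
// [[Rcpp::export]]
List update_lr_bonds_cpp(NumericMatrix pos, IntegerVector kinds,
                         IntegerVector lr, NumericVector box, List ffpack,
                         double r_form, double p_form, double r_break,
                         double seed) {
  Engine E((uint64_t)seed);
  unpack_tables(E, ffpack);
  NumericMatrix vel(pos.nrow(), 3), xuM(pos.nrow(), 3);
  IntegerMatrix nob(0, 2), noa(0, 3);
  load_state(E, pos, vel, xuM, kinds, nob, noa, lr, IntegerVector(0), box);
  E.rform2 = r_form * r_form;
  E.p_form = p_form;
  E.rbreak2 = r_break * r_break;
  E.debug = true;
  E.skin = 0.4;
  E.set_list_radii(r_form);
  E.build_list();
  E.update_bonds();
  IntegerVector outlr(E.n);
  for (int i = 0; i < E.n; ++i) outlr[i] = E.partner[i] + 1;
  return List::create(_["lr_bonds"] = outlr);
}
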