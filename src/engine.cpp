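// Compiled core of the chromatin/TF polymer model: pair + bonded forcefield,
// Verlet-list neighbour search, BAOAB Langevin integration, stochastic TF
// switching, and transcription recording.  All quantities are in reduced
// units (sigma = kBT = m = gamma = 1 unless overridden).
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops", "no-math-errno")
#endif
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <chrono>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64, with a Marsaglia-Tsang ziggurat
// normal sampler.  Self-contained so that runs are reproducible from a single
// integer seed independently of R's RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {            // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int32_t next_i32() { return (int32_t)(next() >> 32); }
};

// ziggurat tables (128 layers), built once
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_init() {
  if (zig_ready) return;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3, m1 = 2147483648.0;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

static inline double rnorm_zig(Xoshiro &rng) {
  const double r = 3.442619855899;
  for (;;) {
    int32_t hz = rng.next_i32();
    uint32_t iz = hz & 127;
    if ((uint32_t)std::abs(hz) < zig_kn[iz]) return hz * zig_wn[iz];
    if (iz == 0) {                     // base-strip tail
      double x, y;
      do {
        x = -std::log(rng.unif()) / r;
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -(r + x);
    }
    double x = hz * zig_wn[iz];
    if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    // otherwise loop and redraw
  }
}

// ---------------------------------------------------------------------------
// Interaction table.  Particle codes: 0 = euchromatin, 1 = TU,
// 2 = heterochromatin, 3 = inactive TF, 4 = active TF.
// Pair potential: truncated+shifted LJ, U = eps4*(s12 - s6) - shift,
// zero beyond rc; WCA is the rc = 2^(1/6) special case.
// ---------------------------------------------------------------------------

struct PairTab {
  double rc2[5][5];
  double eps4[5][5];
  double shift[5][5];
};

static inline double lj_shift(double eps4, double rc) {
  double ir6 = 1.0 / (rc * rc * rc * rc * rc * rc);
  return eps4 * (ir6 * ir6 - ir6);
}

static PairTab make_pair_tab(double kBT, double eps_strong, double eps_weak,
                             double rc_attr) {
  PairTab tab;
  const double rc_rep = std::pow(2.0, 1.0 / 6.0);
  for (int a = 0; a < 5; a++)
    for (int b = 0; b < 5; b++) {
      // default: WCA repulsion with eps = kBT
      double eps4 = 4.0 * kBT, rc = rc_rep;
      bool tf_a = a >= 3, tf_b = b >= 3;
      if (tf_a != tf_b) {             // TF - chromatin pair
        int chrom = tf_a ? b : a;
        int tf = tf_a ? a : b;
        if (tf == 4) {                // active TF
          if (chrom == 1 && eps_strong > 0) { eps4 = 4.0 * eps_strong; rc = rc_attr; }
          else if (chrom == 0 && eps_weak > 0) { eps4 = 4.0 * eps_weak; rc = rc_attr; }
          // heterochromatin: stays WCA
        }
      }
      tab.rc2[a][b] = rc * rc;
      tab.eps4[a][b] = eps4;
      tab.shift[a][b] = lj_shift(eps4, rc);
    }
  return tab;
}

// ---------------------------------------------------------------------------
// System container used internally during a run
// ---------------------------------------------------------------------------

struct System {
  int N;                 // total particles
  int M;                 // chromatin beads (first M particles)
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> code;              // 0..4
  // bonds
  std::vector<int> bi, bj, bkind;     // kind: 0 fene(+wca), 1 harm bb, 2 harm loop
  std::vector<int64_t> bonded_keys;   // sorted i*N+j (i<j) for exclusions
  // parameters
  double kBT, Kf, R02, Kh, Rbb, Rloop, Kang;
  PairTab tab;
  bool phantom = false;  // bonded + bending only (no non-bonded pairs)
  // confinement (ellipsoid); active if conf_on
  bool conf_on = false;
  double ca = 0, cb = 0, cc = 0;
  // neighbour list
  double skin = 0.6, skin_cc = 0.45, rc_big = 1.8;  // rc_big from rc_attr
  std::vector<int> nl_i, nl_j;        // pairs involving a TF
  std::vector<int> cc_i, cc_j;        // chromatin-chromatin pairs
  std::vector<double> xb, yb, zb;     // positions at last build
  long n_rebuilds = 0;

  inline bool excluded(int i, int j) const {
    if (j < i) std::swap(i, j);
    if (j == i + 1 && j < M) return true;   // consecutive backbone pair
    int64_t key = (int64_t)i * N + j;
    return std::binary_search(bonded_keys.begin(), bonded_keys.end(), key);
  }

  void build_neighbours() {
    n_rebuilds++;
    nl_i.clear(); nl_j.clear(); cc_i.clear(); cc_j.clear();
    const double rl_big = rc_big + skin;
    const double rl_small = std::pow(2.0, 1.0 / 6.0) + skin_cc;
    const double rl_big2 = rl_big * rl_big, rl_small2 = rl_small * rl_small;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0], zmin = z[0], zmax = z[0];
    for (int i = 1; i < N; i++) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    // cells sized for the chromatin-chromatin list; TF rows scan a wider
    // stencil so the attractive cutoff is covered
    const double cell = rl_small;
    int nx = std::max(1, (int)((xmax - xmin) / cell));
    int ny = std::max(1, (int)((ymax - ymin) / cell));
    int nz = std::max(1, (int)((zmax - zmin) / cell));
    while ((double)nx * ny * nz > 4e6) { nx = std::max(1, nx / 2); ny = std::max(1, ny / 2); nz = std::max(1, nz / 2); }
    double lx = (xmax - xmin) / nx + 1e-9, ly = (ymax - ymin) / ny + 1e-9,
           lz = (zmax - zmin) / nz + 1e-9;
    std::vector<int> head((size_t)nx * ny * nz, -1), nxt(N, -1), cix(N), ciy(N), ciz(N);
    for (int i = 0; i < N; i++) {
      int cx = std::min(nx - 1, (int)((x[i] - xmin) / lx));
      int cy = std::min(ny - 1, (int)((y[i] - ymin) / ly));
      int cz = std::min(nz - 1, (int)((z[i] - zmin) / lz));
      cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
      size_t c = (size_t)(cz * ny + cy) * nx + cx;
      nxt[i] = head[c]; head[c] = i;
    }
    // chromatin-chromatin pairs: forward half-stencil (13 cells + own cell
    // with j > i), so each candidate pair is visited once
    static const int hs[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int i = 0; i < M; i++) {
      const double xi = x[i], yi = y[i], zi = z[i];
      {
        size_t c = (size_t)(ciz[i] * ny + ciy[i]) * nx + cix[i];
        for (int j = head[c]; j >= 0; j = nxt[j]) {
          if (j <= i || j >= M) continue;
          double dx = xi - x[j], dy2 = yi - y[j], dz2 = zi - z[j];
          double r2 = dx * dx + dy2 * dy2 + dz2 * dz2;
          if (r2 < rl_small2 && !excluded(i, j)) { cc_i.push_back(i); cc_j.push_back(j); }
        }
      }
      for (int kcell = 0; kcell < 13; kcell++) {
        int cxn = cix[i] + hs[kcell][0];
        int cyn = ciy[i] + hs[kcell][1];
        int czn = ciz[i] + hs[kcell][2];
        if (cxn < 0 || cxn >= nx || cyn < 0 || cyn >= ny || czn < 0 || czn >= nz)
          continue;
        size_t c = (size_t)(czn * ny + cyn) * nx + cxn;
        for (int j = head[c]; j >= 0; j = nxt[j]) {
          if (j >= M) continue;
          double dx = xi - x[j], dy2 = yi - y[j], dz2 = zi - z[j];
          double r2 = dx * dx + dy2 * dy2 + dz2 * dz2;
          if (r2 < rl_small2 && !excluded(i, j)) { cc_i.push_back(i); cc_j.push_back(j); }
        }
      }
    }
    // pairs involving a TF (wider stencil covering the attractive range)
    const int reach = (int)std::ceil(rl_big / cell);
    for (int t = M; t < N; t++) {
      const double xt = x[t], yt = y[t], zt = z[t];
      for (int dz = -reach; dz <= reach; dz++) {
        int czn = ciz[t] + dz; if (czn < 0 || czn >= nz) continue;
        for (int dy = -reach; dy <= reach; dy++) {
          int cyn = ciy[t] + dy; if (cyn < 0 || cyn >= ny) continue;
          for (int dxc = -reach; dxc <= reach; dxc++) {
            int cxn = cix[t] + dxc; if (cxn < 0 || cxn >= nx) continue;
            size_t c = (size_t)(czn * ny + cyn) * nx + cxn;
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              if (j < M || j > t) {
                if (j == t) continue;
                double dx = xt - x[j], dy2 = yt - y[j], dz2 = zt - z[j];
                double r2 = dx * dx + dy2 * dy2 + dz2 * dz2;
                if (r2 < rl_big2) { nl_i.push_back(t); nl_j.push_back(j); }
              }
            }
          }
        }
      }
    }
    xb.assign(x.begin(), x.end());
    yb.assign(y.begin(), y.end());
    zb.assign(z.begin(), z.end());
  }

  bool needs_rebuild() const {
    // rebuild when the two largest displacements since the last build could
    // together have closed the skin gap
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < N; i++) {
      double dx = x[i] - xb[i], dy = y[i] - yb[i], dz = z[i] - zb[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) { m2 = d2; }
    }
    return std::sqrt(m1) + std::sqrt(m2) > skin_cc;
  }

  // returns total potential energy; with soft = true all non-bonded pairs
  // interact via a bounded soft-cosine repulsion (push-off phase)
  double soft_A = 100.0;
  double forces(bool soft = false) {
    return soft ? forces_tpl<true>() : forces_tpl<false>();
  }
  template <bool SOFT>
  double forces_tpl() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double U = 0.0;
    // chromatin-chromatin pairs: pure WCA with eps = kBT
    const double pi = 3.14159265358979323846;
    const double rc_soft = std::pow(2.0, 1.0 / 6.0);
    const double rc_rep2 = std::pow(2.0, 1.0 / 3.0);
    const double e4cc = 4.0 * kBT;
    if (!phantom) {
      const size_t np = cc_i.size();
      size_t k = 0;
      while (k < np) {
        const int i = cc_i[k];
        const double xi = x[i], yi = y[i], zi = z[i];
        double fxi = 0.0, fyi = 0.0, fzi = 0.0;
        do {
          int j = cc_j[k];
          double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (SOFT) {
            if (r2 < rc_rep2) {
              double r = std::sqrt(r2);
              U += soft_A * (1.0 + std::cos(pi * r / rc_soft));
              double fr = soft_A * (pi / rc_soft) * std::sin(pi * r / rc_soft) /
                          std::max(r, 1e-6);
              fxi += fr * dx; fyi += fr * dy; fzi += fr * dz;
              fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
            }
          } else if (r2 < rc_rep2) {
            double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
            U += e4cc * (s12 - s6) + kBT;
            double fr = e4cc * (12.0 * s12 - 6.0 * s6) * s2;
            fxi += fr * dx; fyi += fr * dy; fzi += fr * dz;
            fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
          }
          k++;
        } while (k < np && cc_i[k] == i);
        fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
      }
    }
    // pairs involving a TF: interaction from the class/state table
    if (!phantom) {
      const size_t np = nl_i.size();
      for (size_t k = 0; k < np; k++) {
        int i = nl_i[k], j = nl_j[k];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (SOFT) {
          if (r2 >= rc_rep2) continue;
          double r = std::sqrt(r2);
          U += soft_A * (1.0 + std::cos(pi * r / rc_soft));
          double fr = soft_A * (pi / rc_soft) * std::sin(pi * r / rc_soft) /
                      std::max(r, 1e-6);
          fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
          fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
          continue;
        }
        int a = code[i], b = code[j];
        if (r2 >= tab.rc2[a][b]) continue;
        double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
        double e4 = tab.eps4[a][b];
        U += e4 * (s12 - s6) - tab.shift[a][b];
        double fr = e4 * (12.0 * s12 - 6.0 * s6) * s2;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    // bonds
    for (size_t k = 0; k < bi.size(); k++) {
      int i = bi[k], j = bj[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double fr = 0.0;
      if (bkind[k] == 0) {            // FENE + WCA
        if (r2 >= R02)
          stop("FENE bond overstretched between beads %d and %d (r = %.3f >= R0)",
               i + 1, j + 1, std::sqrt(r2));
        double frac = r2 / R02;
        U += -0.5 * Kf * R02 * std::log(1.0 - frac);
        fr += -Kf / (1.0 - frac);
        if (r2 < rc_rep2) {
          double s2 = 1.0 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
          U += 4.0 * kBT * (s12 - s6) + kBT;
          fr += 4.0 * kBT * (12.0 * s12 - 6.0 * s6) * s2;
        }
      } else {                        // harmonic
        double Rbar = (bkind[k] == 1) ? Rbb : Rloop;
        double r = std::sqrt(r2);
        double dr = r - Rbar;
        U += Kh * dr * dr;
        fr = -2.0 * Kh * dr / r;
      }
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    // angles: Kratky-Porod on every consecutive chromatin triplet
    for (int i = 0; i + 2 < M; i++) {
      int j = i + 1, k2 = i + 2;
      double ax = x[j] - x[i], ay = y[j] - y[i], az = z[j] - z[i];
      double bx2 = x[k2] - x[j], by = y[k2] - y[j], bz = z[k2] - z[j];
      double a2 = ax * ax + ay * ay + az * az;
      double b2 = bx2 * bx2 + by * by + bz * bz;
      double ab = ax * bx2 + ay * by + az * bz;
      double inva = 1.0 / std::sqrt(a2), invb = 1.0 / std::sqrt(b2);
      double c = ab * inva * invb;
      U += Kang * (1.0 - c);
      // F_i = -K * grad_a(cos), etc.
      double ga_x = (bx2 * inva * invb - c * ax * inva * inva) * Kang;
      double ga_y = (by * inva * invb - c * ay * inva * inva) * Kang;
      double ga_z = (bz * inva * invb - c * az * inva * inva) * Kang;
      double gb_x = (ax * inva * invb - c * bx2 * invb * invb) * Kang;
      double gb_y = (ay * inva * invb - c * by * invb * invb) * Kang;
      double gb_z = (az * inva * invb - c * bz * invb * invb) * Kang;
      fx[i] -= ga_x; fy[i] -= ga_y; fz[i] -= ga_z;
      fx[j] += ga_x - gb_x; fy[j] += ga_y - gb_y; fz[j] += ga_z - gb_z;
      fx[k2] += gb_x; fy[k2] += gb_y; fz[k2] += gb_z;
    }
    // ellipsoidal confinement: WCA-like inward push from the wall, measured
    // along the ray from the centre (exact for a sphere)
    if (conf_on) {
      const double hcut = std::pow(2.0, 1.0 / 6.0);
      // exact early-out: inside (min axis - cutoff) the wall force is zero
      const double rin = std::min(ca, std::min(cb, cc)) - hcut;
      const double rin2 = rin > 0 ? rin * rin : 0.0;
      for (int i = 0; i < N; i++) {
        double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
        if (r2 <= rin2 || r2 < 1e-12) continue;
        double r = std::sqrt(r2);
        double nxd = x[i] / r, nyd = y[i] / r, nzd = z[i] / r;
        double q = nxd * nxd / (ca * ca) + nyd * nyd / (cb * cb) + nzd * nzd / (cc * cc);
        double Rsurf = 1.0 / std::sqrt(q);
        double h = Rsurf - r;
        if (h >= hcut) continue;
        if (h < 0.6) h = 0.6;         // cap wall stiffness
        double s2 = 1.0 / (h * h), s6 = s2 * s2 * s2, s12 = s6 * s6;
        U += 4.0 * kBT * (s12 - s6) + kBT;
        double fmag = 4.0 * kBT * (12.0 * s12 - 6.0 * s6) / h;  // inward
        fx[i] -= fmag * nxd; fy[i] -= fmag * nyd; fz[i] -= fmag * nzd;
      }
    }
    return U;
  }
};

static System make_system(NumericMatrix pos, IntegerVector code,
                          IntegerVector bond_i, IntegerVector bond_j,
                          IntegerVector bond_kind, int n_beads, List params,
                          List conf) {
  System S;
  S.N = pos.nrow();
  S.M = n_beads;
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.vx.assign(S.N, 0.0); S.vy.assign(S.N, 0.0); S.vz.assign(S.N, 0.0);
  S.fx.resize(S.N); S.fy.resize(S.N); S.fz.resize(S.N);
  for (int i = 0; i < S.N; i++) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
  }
  S.code.assign(code.begin(), code.end());
  S.bi.resize(bond_i.size()); S.bj.resize(bond_i.size()); S.bkind.resize(bond_i.size());
  for (int k = 0; k < bond_i.size(); k++) {
    S.bi[k] = bond_i[k] - 1; S.bj[k] = bond_j[k] - 1; S.bkind[k] = bond_kind[k];
    int a = std::min(S.bi[k], S.bj[k]), b = std::max(S.bi[k], S.bj[k]);
    S.bonded_keys.push_back((int64_t)a * S.N + b);
  }
  std::sort(S.bonded_keys.begin(), S.bonded_keys.end());
  S.kBT = as<double>(params["kBT"]);
  S.Kf = as<double>(params["Kf"]);
  double R0 = as<double>(params["R0"]);
  S.R02 = R0 * R0;
  S.Kh = as<double>(params["Kh"]);
  S.Rbb = as<double>(params["Rbar_backbone"]);
  S.Rloop = as<double>(params["Rbar_loop"]);
  S.Kang = S.kBT * as<double>(params["lp"]);
  if (params.containsElementNamed("phantom"))
    S.phantom = as<bool>(params["phantom"]);
  double rc_attr = as<double>(params["rc_attr"]);
  S.rc_big = std::max(rc_attr, std::pow(2.0, 1.0 / 6.0));
  S.tab = make_pair_tab(S.kBT, as<double>(params["eps_strong"]),
                        as<double>(params["eps_weak"]), rc_attr);
  std::string ck = as<std::string>(conf["kind"]);
  if (ck == "ellipsoid") {
    NumericVector ax = conf["semi_axes"];
    S.conf_on = true;
    S.ca = ax[0]; S.cb = ax[1]; S.cc = ax[2];
  }
  return S;
}

// One-shot force/energy evaluation (used by R-level total_forces and tests)
// [[Rcpp::export(name = ".total_forces_cpp")]]
List total_forces_cpp(NumericMatrix pos, IntegerVector code,
                      IntegerVector bond_i, IntegerVector bond_j,
                      IntegerVector bond_kind, int n_beads, List params,
                      List conf) {
  zig_init();
  System S = make_system(pos, code, bond_i, bond_j, bond_kind, n_beads, params, conf);
  S.build_neighbours();
  double U = S.forces();
  NumericMatrix F(S.N, 3);
  for (int i = 0; i < S.N; i++) { F(i, 0) = S.fx[i]; F(i, 1) = S.fy[i]; F(i, 2) = S.fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = U);
}

// ---------------------------------------------------------------------------
// Main driver: push-off warm-up (capped forces), equilibration, production
// with TF switching and transcription sampling.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".run_sim_cpp")]]
List run_sim_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector code,
                 IntegerVector bond_i, IntegerVector bond_j,
                 IntegerVector bond_kind, int n_beads, IntegerVector record_idx,
                 List params, List conf, double dt, double gamma,
                 double temperature, int seed, int n_push, int n_equil,
                 int n_prod, int sample_every, int switch_every, double p_on,
                 double p_off, int traj_stride, double dmax, bool init_vel) {
  zig_init();
  System S = make_system(pos, code, bond_i, bond_j, bond_kind, n_beads, params, conf);
  Xoshiro rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 12345u);
  Xoshiro nstream[4] = {
      Xoshiro((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 101u),
      Xoshiro((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 202u),
      Xoshiro((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 303u),
      Xoshiro((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 404u)};
  const int N = S.N, M = S.M;
  const int n_tf = N - M;

  if (p_on > 1.0 || p_off > 1.0 || p_on < 0.0 || p_off < 0.0)
    stop("switching probability per attempt outside [0, 1]; reduce rates or interval");

  if (init_vel) {
    double sd = std::sqrt(temperature);
    for (int i = 0; i < N; i++) {
      S.vx[i] = sd * rnorm_zig(rng);
      S.vy[i] = sd * rnorm_zig(rng);
      S.vz[i] = sd * rnorm_zig(rng);
    }
  } else {
    for (int i = 0; i < N; i++) {
      S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    }
  }

  // recording setup
  const int n_rec = record_idx.size();
  std::vector<int> col_of(N, -1);
  for (int k = 0; k < n_rec; k++) col_of[record_idx[k] - 1] = k;
  int n_samples = (sample_every > 0 && n_prod > 0) ? n_prod / sample_every : 0;
  IntegerMatrix samples(n_samples, n_rec);
  NumericVector sample_time(n_samples);
  IntegerVector active_count(n_samples);

  int n_frames = (traj_stride > 0 && n_prod > 0) ? n_prod / traj_stride + 1 : 0;
  NumericVector traj(n_frames > 0 ? (R_xlen_t)n_frames * N * 3 : 0);
  int frame = 0;

  // Langevin velocity-Verlet: friction and noise enter the half-kicks as
  // forces; the noise is redrawn at every force evaluation with variance
  // 2*kBT*gamma/dt per component (discrete delta-correlation)
  const double sdR = gamma > 0 ? std::sqrt(2.0 * temperature * gamma / dt) : 0.0;
  const double half = 0.5 * dt;
  std::vector<double> rx(N, 0.0), ry(N, 0.0), rz(N, 0.0);
  auto draw_noise = [&]() {
    if (sdR == 0.0) return;
    // four independent generator streams interleaved for instruction-level
    // parallelism; assignment of stream to slot is fixed, so runs stay
    // reproducible from the seed
    int i = 0;
    for (; i + 4 <= N; i += 4) {
      rx[i] = sdR * rnorm_zig(nstream[0]);
      rx[i + 1] = sdR * rnorm_zig(nstream[1]);
      rx[i + 2] = sdR * rnorm_zig(nstream[2]);
      rx[i + 3] = sdR * rnorm_zig(nstream[3]);
      ry[i] = sdR * rnorm_zig(nstream[0]);
      ry[i + 1] = sdR * rnorm_zig(nstream[1]);
      ry[i + 2] = sdR * rnorm_zig(nstream[2]);
      ry[i + 3] = sdR * rnorm_zig(nstream[3]);
      rz[i] = sdR * rnorm_zig(nstream[0]);
      rz[i + 1] = sdR * rnorm_zig(nstream[1]);
      rz[i + 2] = sdR * rnorm_zig(nstream[2]);
      rz[i + 3] = sdR * rnorm_zig(nstream[3]);
    }
    for (; i < N; i++) {
      rx[i] = sdR * rnorm_zig(nstream[0]);
      ry[i] = sdR * rnorm_zig(nstream[1]);
      rz[i] = sdR * rnorm_zig(nstream[2]);
    }
  };

  S.build_neighbours();
  S.forces(n_push > 0);
  draw_noise();
  // during push-off, per-step particle displacement is limited to dmax by
  // velocity clamping (forces stay intact so bonds cannot overstretch)
  const double vlim = dmax > 0 ? dmax / dt : 0.0;


  double ke_acc = 0.0;                // mean KE per particle over production samples
  long ke_n = 0;

  double t_int = 0, t_nb = 0, t_force = 0;    // per-call phase timings
  auto now = []() { return std::chrono::steady_clock::now(); };
  auto step = [&](bool limited, bool soft) {
    auto c0 = now();
    // first half-kick + drift
    for (int i = 0; i < N; i++) {
      double vx2 = S.vx[i] + half * (S.fx[i] + rx[i] - gamma * S.vx[i]);
      double vy2 = S.vy[i] + half * (S.fy[i] + ry[i] - gamma * S.vy[i]);
      double vz2 = S.vz[i] + half * (S.fz[i] + rz[i] - gamma * S.vz[i]);
      if (limited) {
        double v2 = vx2 * vx2 + vy2 * vy2 + vz2 * vz2;
        if (v2 > vlim * vlim) {
          double sc = vlim / std::sqrt(v2);
          vx2 *= sc; vy2 *= sc; vz2 *= sc;
        }
      }
      S.vx[i] = vx2; S.vy[i] = vy2; S.vz[i] = vz2;
      S.x[i] += dt * vx2; S.y[i] += dt * vy2; S.z[i] += dt * vz2;
    }
    auto c1 = now();
    if (S.needs_rebuild()) S.build_neighbours();
    auto c2 = now();
    S.forces(soft);
    draw_noise();
    auto c3 = now();
    t_int += std::chrono::duration<double>(c1 - c0).count();
    t_nb += std::chrono::duration<double>(c2 - c1).count();
    t_force += std::chrono::duration<double>(c3 - c2).count();
    // second half-kick with the fresh forces/noise
    for (int i = 0; i < N; i++) {
      S.vx[i] += half * (S.fx[i] + rx[i] - gamma * S.vx[i]);
      S.vy[i] += half * (S.fy[i] + ry[i] - gamma * S.vy[i]);
      S.vz[i] += half * (S.fz[i] + rz[i] - gamma * S.vz[i]);
    }
  };

  auto switch_tfs = [&]() {
    for (int i = M; i < N; i++) {
      if (S.code[i] == 4) {
        if (rng.unif() < p_off) S.code[i] = 3;
      } else {
        if (rng.unif() < p_on) S.code[i] = 4;
      }
    }
  };

  auto check_finite = [&](long stepno) {
    for (int i = 0; i < N; i++)
      if (!std::isfinite(S.x[i]) || !std::isfinite(S.y[i]) || !std::isfinite(S.z[i]))
        stop("non-finite coordinate for particle %d at step %ld", i + 1, stepno);
  };

  // push-off: soft pairs, displacement-limited (no switching); the soft
  // amplitude ramps up so early overlaps relax gently
  for (int t = 1; t <= n_push; t++) {
    S.soft_A = 1.0 + 99.0 * t / n_push;
    step(true, true);
  }
  if (n_push > 0) {
    check_finite(n_push);
    S.forces(false);                  // switch to the full potential
  }

  // equilibration (switching active)
  for (int t = 1; t <= n_equil; t++) {
    step(false, false);
    if (switch_every > 0 && t % switch_every == 0) switch_tfs();
  }
  if (n_equil > 0) check_finite(n_equil);

  // production
  if (n_frames > 0) {                 // initial frame
    for (int i = 0; i < N; i++) {
      traj[(R_xlen_t)frame * N * 3 + i] = S.x[i];
      traj[(R_xlen_t)frame * N * 3 + N + i] = S.y[i];
      traj[(R_xlen_t)frame * N * 3 + 2 * N + i] = S.z[i];
    }
    frame++;
  }
  int sample_i = 0;
  const double rc_tr2 = as<double>(params["rc_attr"]) * as<double>(params["rc_attr"]);
  for (int t = 1; t <= n_prod; t++) {
    step(false, false);
    if (switch_every > 0 && t % switch_every == 0) switch_tfs();
    if (sample_every > 0 && t % sample_every == 0 && sample_i < n_samples) {
      check_finite(t);
      // transcription read-out: recorded bead is on iff an ACTIVE TF centre
      // lies within rc of the bead centre; scan the current pair list
      std::vector<int> on(n_rec, 0);
      for (size_t k = 0; k < S.nl_i.size(); k++) {
        int i = S.nl_i[k], j = S.nl_j[k];
        int tf = -1, bead = -1;
        if (S.code[i] == 4 && S.code[j] < 3) { tf = i; bead = j; }
        else if (S.code[j] == 4 && S.code[i] < 3) { tf = j; bead = i; }
        else continue;
        int colk = col_of[bead];
        if (colk < 0 || on[colk]) continue;
        double dx = S.x[tf] - S.x[bead], dy = S.y[tf] - S.y[bead], dz = S.z[tf] - S.z[bead];
        if (dx * dx + dy * dy + dz * dz <= rc_tr2) on[colk] = 1;
      }
      for (int k = 0; k < n_rec; k++) samples(sample_i, k) = on[k];
      sample_time[sample_i] = t * dt;
      int na = 0;
      for (int i = M; i < N; i++) if (S.code[i] == 4) na++;
      active_count[sample_i] = na;
      sample_i++;
      double ke = 0.0;
      for (int i = 0; i < N; i++)
        ke += 0.5 * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i]);
      ke_acc += ke / N;
      ke_n++;
    }
    if (traj_stride > 0 && t % traj_stride == 0 && frame < n_frames) {
      for (int i = 0; i < N; i++) {
        traj[(R_xlen_t)frame * N * 3 + i] = S.x[i];
        traj[(R_xlen_t)frame * N * 3 + N + i] = S.y[i];
        traj[(R_xlen_t)frame * N * 3 + 2 * N + i] = S.z[i];
      }
      frame++;
    }
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3);
  for (int i = 0; i < N; i++) {
    pos_out(i, 0) = S.x[i]; pos_out(i, 1) = S.y[i]; pos_out(i, 2) = S.z[i];
    vel_out(i, 0) = S.vx[i]; vel_out(i, 1) = S.vy[i]; vel_out(i, 2) = S.vz[i];
  }
  LogicalVector tf_state(n_tf);
  for (int i = 0; i < n_tf; i++) tf_state[i] = (S.code[M + i] == 4);

  List out = List::create(
      _["samples"] = samples, _["sample_time"] = sample_time,
      _["active_tf_count"] = active_count, _["positions"] = pos_out,
      _["velocities"] = vel_out, _["tf_active"] = tf_state,
      _["n_rebuilds"] = (double)S.n_rebuilds,
      _["prof"] = NumericVector::create(t_int, t_nb, t_force),
      _["mean_ke_per_particle"] = ke_n > 0 ? ke_acc / ke_n : NA_REAL,
      _["n_frames"] = frame);
  if (n_frames > 0) {
    traj.attr("dim") = IntegerVector::create(N, 3, n_frames);
    out["trajectory"] = traj;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Contact-map helper: per-frame bead-bead contacts accumulated into genomic
// bins of `beads_per_bin` beads (chromatin beads only).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".contact_map_frame_cpp")]]
void contact_map_frame_cpp(NumericMatrix pos, int n_beads, double cutoff,
                           int beads_per_bin, NumericMatrix counts) {
  zig_init();
  const double c2 = cutoff * cutoff;
  // cell list over beads only
  int Nb = n_beads;
  std::vector<double> xs(Nb), ys(Nb), zs(Nb);
  for (int i = 0; i < Nb; i++) { xs[i] = pos(i, 0); ys[i] = pos(i, 1); zs[i] = pos(i, 2); }
  double xmin = xs[0], xmax = xs[0], ymin = ys[0], ymax = ys[0], zmin = zs[0], zmax = zs[0];
  for (int i = 1; i < Nb; i++) {
    xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
    ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
    zmin = std::min(zmin, zs[i]); zmax = std::max(zmax, zs[i]);
  }
  int nx = std::max(1, (int)((xmax - xmin) / cutoff));
  int ny = std::max(1, (int)((ymax - ymin) / cutoff));
  int nz = std::max(1, (int)((zmax - zmin) / cutoff));
  while ((double)nx * ny * nz > 4e6) { nx = std::max(1, nx / 2); ny = std::max(1, ny / 2); nz = std::max(1, nz / 2); }
  double lx = (xmax - xmin) / nx + 1e-9, ly = (ymax - ymin) / ny + 1e-9,
         lz = (zmax - zmin) / nz + 1e-9;
  std::vector<int> head((size_t)nx * ny * nz, -1), nxt(Nb, -1), cix(Nb), ciy(Nb), ciz(Nb);
  for (int i = 0; i < Nb; i++) {
    int cx = std::min(nx - 1, (int)((xs[i] - xmin) / lx));
    int cy = std::min(ny - 1, (int)((ys[i] - ymin) / ly));
    int cz = std::min(nz - 1, (int)((zs[i] - zmin) / lz));
    cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
    size_t c = (size_t)(cz * ny + cy) * nx + cx;
    nxt[i] = head[c]; head[c] = i;
  }
  for (int i = 0; i < Nb; i++) {
    for (int dz = -1; dz <= 1; dz++) {
      int czn = ciz[i] + dz; if (czn < 0 || czn >= nz) continue;
      for (int dy = -1; dy <= 1; dy++) {
        int cyn = ciy[i] + dy; if (cyn < 0 || cyn >= ny) continue;
        for (int dxc = -1; dxc <= 1; dxc++) {
          int cxn = cix[i] + dxc; if (cxn < 0 || cxn >= nx) continue;
          size_t c = (size_t)(czn * ny + cyn) * nx + cxn;
          for (int j = head[c]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double dx = xs[i] - xs[j], dy2 = ys[i] - ys[j], dz2 = zs[i] - zs[j];
            if (dx * dx + dy2 * dy2 + dz2 * dz2 <= c2) {
              int bi2 = i / beads_per_bin, bj2 = j / beads_per_bin;
              counts(bi2, bj2) += 1.0;
              if (bi2 != bj2) counts(bj2, bi2) += 1.0;
            }
          }
        }
      }
    }
  }
}
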