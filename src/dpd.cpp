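// Core DPD engine: cell-list pair search, soft conservative/dissipative/random
// pair forces, harmonic bonds, harmonic angles, Groot-Warren modified velocity
// Verlet, and Mueller-Plathe momentum-swap shear. All quantities in reduced
// units (lengths in r_c, energies in kBT, masses m = 1, time in tau).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG. The pairwise noise zeta_ij must be (a) symmetric in
// (i, j) and (b) independent of the order in which pairs are enumerated, so
// the cell-list and brute-force paths agree bitwise. A keyed hash of
// (stream, step, min(i,j), max(i,j)) mapped through Box-Muller gives exactly
// that without any per-pair state.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t pair_key(uint64_t stream, long step, int i, int j, uint64_t salt) {
  if (i > j) std::swap(i, j);
  uint64_t k = splitmix64(stream ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(step + 1)) ^ salt);
  k = splitmix64(k ^ ((uint64_t)(i + 1) * 0xC2B2AE3D27D4EB4FULL));
  k = splitmix64(k ^ ((uint64_t)(j + 1) * 0x165667B19E3779F9ULL));
  return k;
}

static inline double u01(uint64_t k) {
  // strictly inside (0, 1)
  return ((double)(k >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double key_gauss(uint64_t k) {
  uint64_t k2 = splitmix64(k);
  double u1 = u01(k), u2 = u01(k2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586476925287 * u2);
}

static inline double pair_gauss(uint64_t stream, long step, int i, int j) {
  return key_gauss(pair_key(stream, step, i, j, 0x71C9B2ECULL));
}

static inline double min_img(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// ---------------------------------------------------------------------------
// Force evaluation
// ---------------------------------------------------------------------------

struct ForceParams {
  int n;
  const double *x, *y, *z;
  const double *vx, *vy, *vz;   // velocities used by the dissipative channel
  const int *species;           // 0-based
  double Lx, Ly, Lz;
  const double *a;              // ns x ns, column-major
  int ns;
  double gamma, sigma, rc;
  double inv_sqrt_dt;
  uint64_t stream;
  long step;
};

struct ForceAccum {
  std::vector<double> fx, fy, fz;
  double u_pair = 0.0, u_bond = 0.0, u_angle = 0.0;
  long n_overlap = 0;
  ForceAccum(int n) : fx(n, 0.0), fy(n, 0.0), fz(n, 0.0) {}
};

static inline void pair_interact(const ForceParams& p, ForceAccum& acc,
                                 int i, int j, double dx, double dy, double dz,
                                 double r2) {
  double r = std::sqrt(r2);
  double ex, ey, ez;
  if (r < 1e-12) {
    // overlapping beads: direction undefined; use a reproducible random unit
    // vector (soft cores make this event measure-zero in practice)
    uint64_t k = pair_key(p.stream, p.step, i, j, 0xDEADBEEFULL);
    ex = key_gauss(k);
    ey = key_gauss(splitmix64(k ^ 0x1ULL));
    ez = key_gauss(splitmix64(k ^ 0x2ULL));
    double nrm = std::sqrt(ex * ex + ey * ey + ez * ez);
    if (nrm < 1e-12) { ex = 1.0; ey = 0.0; ez = 0.0; nrm = 1.0; }
    ex /= nrm; ey /= nrm; ez /= nrm;
    acc.n_overlap++;
    r = 0.0;
  } else {
    ex = dx / r; ey = dy / r; ez = dz / r;
  }
  double w = 1.0 - r / p.rc;      // guaranteed r < rc on entry
  double aij = p.a[p.species[i] + p.ns * p.species[j]];
  double f = aij * w;             // conservative, repulsive along j->i
  if (p.gamma != 0.0) {
    double vdotr = (p.vx[i] - p.vx[j]) * ex + (p.vy[i] - p.vy[j]) * ey +
                   (p.vz[i] - p.vz[j]) * ez;
    f += -p.gamma * w * w * vdotr;
  }
  if (p.sigma != 0.0) {
    f += p.sigma * w * pair_gauss(p.stream, p.step, i, j) * p.inv_sqrt_dt;
  }
  acc.fx[i] += f * ex; acc.fy[i] += f * ey; acc.fz[i] += f * ez;
  acc.fx[j] -= f * ex; acc.fy[j] -= f * ey; acc.fz[j] -= f * ez;
  acc.u_pair += 0.5 * aij * p.rc * w * w;   // antiderivative of a*w(r)
}

// enumerate all pairs with min-image distance < rc; calls pair_interact
// cells must be at least rc wide; capping the grid near n^(1/3) keeps the
// cell count O(n) even for tiny cutoffs
static inline int n_cells(double L, double rc, int n) {
  int nc = (int)std::floor(L / rc);
  int cap = std::max(3, (int)std::cbrt((double)n) + 1);
  return std::min(nc, cap);
}

static void nonbonded_forces(const ForceParams& p, ForceAccum& acc, bool brute) {
  const double rc2 = p.rc * p.rc;
  int ncx = n_cells(p.Lx, p.rc, p.n);
  int ncy = n_cells(p.Ly, p.rc, p.n);
  int ncz = n_cells(p.Lz, p.rc, p.n);
  if (brute || ncx < 3 || ncy < 3 || ncz < 3) {
    for (int i = 0; i < p.n; ++i) {
      for (int j = i + 1; j < p.n; ++j) {
        double dx = min_img(p.x[i] - p.x[j], p.Lx);
        double dy = min_img(p.y[i] - p.y[j], p.Ly);
        double dz = min_img(p.z[i] - p.z[j], p.Lz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) pair_interact(p, acc, i, j, dx, dy, dz, r2);
      }
    }
    return;
  }
  const int ncells = ncx * ncy * ncz;
  std::vector<int> head(ncells, -1), nxt(p.n, -1);
  const double cwx = p.Lx / ncx, cwy = p.Ly / ncy, cwz = p.Lz / ncz;
  for (int i = 0; i < p.n; ++i) {
    int ix = (int)(p.x[i] / cwx); if (ix >= ncx) ix = ncx - 1; if (ix < 0) ix = 0;
    int iy = (int)(p.y[i] / cwy); if (iy >= ncy) iy = ncy - 1; if (iy < 0) iy = 0;
    int iz = (int)(p.z[i] / cwz); if (iz >= ncz) iz = ncz - 1; if (iz < 0) iz = 0;
    int c = ix + ncx * (iy + ncy * iz);
    nxt[i] = head[c]; head[c] = i;
  }
  // half stencil: self + 13 neighbours
  static const int OFF[13][3] = {
    {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
    {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
    {-1,1,1}, {0,1,1}, {1,1,1}};
  for (int iz = 0; iz < ncz; ++iz) {
    for (int iy = 0; iy < ncy; ++iy) {
      for (int ix = 0; ix < ncx; ++ix) {
        int c = ix + ncx * (iy + ncy * iz);
        // intra-cell pairs
        for (int i = head[c]; i != -1; i = nxt[i]) {
          for (int j = nxt[i]; j != -1; j = nxt[j]) {
            double dx = min_img(p.x[i] - p.x[j], p.Lx);
            double dy = min_img(p.y[i] - p.y[j], p.Ly);
            double dz = min_img(p.z[i] - p.z[j], p.Lz);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < rc2) pair_interact(p, acc, i, j, dx, dy, dz, r2);
          }
        }
        // neighbour cells
        for (int o = 0; o < 13; ++o) {
          int jx = (ix + OFF[o][0] + ncx) % ncx;
          int jy = (iy + OFF[o][1] + ncy) % ncy;
          int jz = (iz + OFF[o][2] + ncz) % ncz;
          int c2 = jx + ncx * (jy + ncy * jz);
          for (int i = head[c]; i != -1; i = nxt[i]) {
            for (int j = head[c2]; j != -1; j = nxt[j]) {
              double dx = min_img(p.x[i] - p.x[j], p.Lx);
              double dy = min_img(p.y[i] - p.y[j], p.Ly);
              double dz = min_img(p.z[i] - p.z[j], p.Lz);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rc2) pair_interact(p, acc, i, j, dx, dy, dz, r2);
            }
          }
        }
      }
    }
  }
}

static void bonded_forces(const ForceParams& p, ForceAccum& acc,
                          const int* bi, const int* bj, const double* bk,
                          const double* br0, int nb) {
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx = min_img(p.x[i] - p.x[j], p.Lx);
    double dy = min_img(p.y[i] - p.y[j], p.Ly);
    double dz = min_img(p.z[i] - p.z[j], p.Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex, ey, ez;
    if (r < 1e-12) {
      uint64_t k = pair_key(p.stream, p.step, i, j, 0xB0BDULL);
      ex = key_gauss(k); ey = key_gauss(splitmix64(k ^ 1ULL));
      ez = key_gauss(splitmix64(k ^ 2ULL));
      double nrm = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (nrm < 1e-12) { ex = 1.0; ey = 0.0; ez = 0.0; nrm = 1.0; }
      ex /= nrm; ey /= nrm; ez /= nrm;
      acc.n_overlap++;
      r = 0.0;
    } else {
      ex = dx / r; ey = dy / r; ez = dz / r;
    }
    double s = 1.0 - r / br0[b];
    double f = bk[b] * s;                 // along j->i: repulsive when r < r0
    acc.fx[i] += f * ex; acc.fy[i] += f * ey; acc.fz[i] += f * ez;
    acc.fx[j] -= f * ex; acc.fy[j] -= f * ey; acc.fz[j] -= f * ez;
    acc.u_bond += 0.5 * bk[b] * br0[b] * s * s;
  }
}

static void angle_forces_core(const ForceParams& p, ForceAccum& acc,
                              const int* ai, const int* aj, const int* ak,
                              const double* kth, const double* th0, int na) {
  for (int t = 0; t < na; ++t) {
    int i = ai[t], j = aj[t], k = ak[t];   // j is the centre bead
    double d1x = min_img(p.x[i] - p.x[j], p.Lx);
    double d1y = min_img(p.y[i] - p.y[j], p.Ly);
    double d1z = min_img(p.z[i] - p.z[j], p.Lz);
    double d2x = min_img(p.x[k] - p.x[j], p.Lx);
    double d2y = min_img(p.y[k] - p.y[j], p.Ly);
    double d2z = min_img(p.z[k] - p.z[j], p.Lz);
    double r1sq = d1x * d1x + d1y * d1y + d1z * d1z;
    double r2sq = d2x * d2x + d2y * d2y + d2z * d2z;
    double r1 = std::sqrt(r1sq), r2 = std::sqrt(r2sq);
    if (r1 < 1e-12 || r2 < 1e-12)
      stop("angle with zero-length arm at triple %d-%d-%d", i + 1, j + 1, k + 1);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double theta = std::acos(c);
    double dth = theta - th0[t];
    acc.u_angle += kth[t] * dth * dth;
    double aa = -2.0 * kth[t] * dth / s;
    double a11 = aa * c / r1sq;
    double a12 = -aa / (r1 * r2);
    double a22 = aa * c / r2sq;
    double f1x = a11 * d1x + a12 * d2x;
    double f1y = a11 * d1y + a12 * d2y;
    double f1z = a11 * d1z + a12 * d2z;
    double f3x = a22 * d2x + a12 * d1x;
    double f3y = a22 * d2y + a12 * d1y;
    double f3z = a22 * d2z + a12 * d1z;
    acc.fx[i] += f1x; acc.fy[i] += f1y; acc.fz[i] += f1z;
    acc.fx[k] += f3x; acc.fy[k] += f3y; acc.fz[k] += f3z;
    acc.fx[j] -= f1x + f3x; acc.fy[j] -= f1y + f3y; acc.fz[j] -= f1z + f3z;
  }
}

// [[Rcpp::export(name = ".compute_forces_cpp")]]
List compute_forces_cpp(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector vx, NumericVector vy, NumericVector vz,
                        IntegerVector species, NumericVector box,
                        NumericMatrix amat, double gamma, double sigma,
                        double rc, double dt,
                        IntegerVector bond_i, IntegerVector bond_j,
                        NumericVector bond_k, NumericVector bond_r0,
                        IntegerVector ang_i, IntegerVector ang_j,
                        IntegerVector ang_k, NumericVector ang_kth,
                        NumericVector ang_th0,
                        double stream, int step, bool brute) {
  int n = x.size();
  ForceParams p;
  p.n = n;
  p.x = x.begin(); p.y = y.begin(); p.z = z.begin();
  p.vx = vx.begin(); p.vy = vy.begin(); p.vz = vz.begin();
  p.species = species.begin();
  p.Lx = box[0]; p.Ly = box[1]; p.Lz = box[2];
  p.a = amat.begin(); p.ns = amat.nrow();
  p.gamma = gamma; p.sigma = sigma; p.rc = rc;
  p.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  p.stream = (uint64_t)stream; p.step = step;
  ForceAccum acc(n);
  nonbonded_forces(p, acc, brute);
  bonded_forces(p, acc, bond_i.begin(), bond_j.begin(),
                bond_k.begin(), bond_r0.begin(), bond_i.size());
  angle_forces_core(p, acc, ang_i.begin(), ang_j.begin(), ang_k.begin(),
                    ang_kth.begin(), ang_th0.begin(), ang_i.size());
  return List::create(
    _["fx"] = NumericVector(acc.fx.begin(), acc.fx.end()),
    _["fy"] = NumericVector(acc.fy.begin(), acc.fy.end()),
    _["fz"] = NumericVector(acc.fz.begin(), acc.fz.end()),
    _["u_pair"] = acc.u_pair, _["u_bond"] = acc.u_bond,
    _["u_angle"] = acc.u_angle, _["n_overlap"] = (double)acc.n_overlap);
}

// ---------------------------------------------------------------------------
// Pair enumeration (exposed for cell-list vs brute-force property tests)
// ---------------------------------------------------------------------------

struct PairCollector {
  std::vector<int> pi, pj;
};

// [[Rcpp::export(name = ".pairs_cpp")]]
IntegerMatrix pairs_cpp(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector box, double rc, bool brute) {
  int n = x.size();
  std::vector<int> pi, pj;
  const double rc2 = rc * rc;
  auto consider = [&](int i, int j) {
    double dx = min_img(x[i] - x[j], box[0]);
    double dy = min_img(y[i] - y[j], box[1]);
    double dz = min_img(z[i] - z[j], box[2]);
    if (dx * dx + dy * dy + dz * dz < rc2) {
      pi.push_back(std::min(i, j) + 1);
      pj.push_back(std::max(i, j) + 1);
    }
  };
  int ncx = n_cells(box[0], rc, n);
  int ncy = n_cells(box[1], rc, n);
  int ncz = n_cells(box[2], rc, n);
  if (brute || ncx < 3 || ncy < 3 || ncz < 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  } else {
    int ncells = ncx * ncy * ncz;
    std::vector<int> head(ncells, -1), nxt(n, -1);
    double cwx = box[0] / ncx, cwy = box[1] / ncy, cwz = box[2] / ncz;
    for (int i = 0; i < n; ++i) {
      int ix = std::min((int)(x[i] / cwx), ncx - 1);
      int iy = std::min((int)(y[i] / cwy), ncy - 1);
      int iz = std::min((int)(z[i] / cwz), ncz - 1);
      int c = ix + ncx * (iy + ncy * iz);
      nxt[i] = head[c]; head[c] = i;
    }
    static const int OFF[13][3] = {
      {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
      {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
      {-1,1,1}, {0,1,1}, {1,1,1}};
    for (int iz = 0; iz < ncz; ++iz)
      for (int iy = 0; iy < ncy; ++iy)
        for (int ix = 0; ix < ncx; ++ix) {
          int c = ix + ncx * (iy + ncy * iz);
          for (int i = head[c]; i != -1; i = nxt[i])
            for (int j = nxt[i]; j != -1; j = nxt[j]) consider(i, j);
          for (int o = 0; o < 13; ++o) {
            int jx = (ix + OFF[o][0] + ncx) % ncx;
            int jy = (iy + OFF[o][1] + ncy) % ncy;
            int jz = (iz + OFF[o][2] + ncz) % ncz;
            int c2 = jx + ncx * (jy + ncy * jz);
            for (int i = head[c]; i != -1; i = nxt[i])
              for (int j = head[c2]; j != -1; j = nxt[j]) consider(i, j);
          }
        }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) { out(r, 0) = pi[r]; out(r, 1) = pj[r]; }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components of the contact graph (union-find over the pair stream)
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export(name = ".cluster_cpp")]]
IntegerVector cluster_cpp(NumericVector x, NumericVector y, NumericVector z,
                          NumericVector box, double cutoff) {
  int n = x.size();
  IntegerMatrix prs = pairs_cpp(x, y, z, box, cutoff, false);
  std::vector<int> par(n);
  for (int i = 0; i < n; ++i) par[i] = i;
  for (int r = 0; r < prs.nrow(); ++r) {
    int a = uf_find(par, prs(r, 0) - 1), b = uf_find(par, prs(r, 1) - 1);
    if (a != b) par[a] = b;
  }
  // relabel components 1..k in order of first appearance
  std::vector<int> label(n, 0);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int r = uf_find(par, i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Integrator + shear protocol
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".dpd_run_cpp")]]
List dpd_run_cpp(NumericVector x0, NumericVector y0, NumericVector z0,
                 NumericVector vx0, NumericVector vy0, NumericVector vz0,
                 IntegerVector species, NumericVector box,
                 NumericMatrix amat, double gamma, double sigma, double rc,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_k, NumericVector bond_r0,
                 IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
                 NumericVector ang_kth, NumericVector ang_th0,
                 int n_steps, double dt, double lambda,
                 int sample_every, int frame_every,
                 int swap_every, int n_slabs, double stream_seed, int step0,
                 NumericVector f0x, NumericVector f0y, NumericVector f0z) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      z(z0.begin(), z0.end());
  std::vector<double> vx(vx0.begin(), vx0.end()), vy(vy0.begin(), vy0.end()),
      vz(vz0.begin(), vz0.end());
  std::vector<double> px(n), py(n), pz(n);  // lambda-predicted velocities
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const uint64_t stream = (uint64_t)stream_seed;

  ForceParams p;
  p.n = n;
  p.x = x.data(); p.y = y.data(); p.z = z.data();
  p.species = species.begin();
  p.Lx = Lx; p.Ly = Ly; p.Lz = Lz;
  p.a = amat.begin(); p.ns = amat.nrow();
  p.gamma = gamma; p.sigma = sigma; p.rc = rc;
  p.inv_sqrt_dt = 1.0 / std::sqrt(dt);

  auto eval_forces = [&](ForceAccum& acc, const double* ux, const double* uy,
                         const double* uz, long step) {
    p.vx = ux; p.vy = uy; p.vz = uz;
    p.step = step; p.stream = stream;
    nonbonded_forces(p, acc, false);
    bonded_forces(p, acc, bond_i.begin(), bond_j.begin(),
                  bond_k.begin(), bond_r0.begin(), bond_i.size());
    angle_forces_core(p, acc, ang_i.begin(), ang_j.begin(), ang_k.begin(),
                      ang_kth.begin(), ang_th0.begin(), ang_i.size());
  };

  ForceAccum f(n);
  long n_overlap = 0;
  if (f0x.size() == n) {
    // continuing from a checkpoint: reuse the stored entering forces (they
    // were evaluated at the lambda-predicted velocities of the last step)
    std::copy(f0x.begin(), f0x.end(), f.fx.begin());
    std::copy(f0y.begin(), f0y.end(), f.fy.begin());
    std::copy(f0z.begin(), f0z.end(), f.fz.begin());
  } else {
    eval_forces(f, vx.data(), vy.data(), vz.data(), step0);
    n_overlap = f.n_overlap;
  }

  // observable rows
  std::vector<double> ob_step, ob_time, ob_ke, ob_upair, ob_ubond, ob_uangle,
      ob_px, ob_py, ob_pz, ob_swap_px;
  // profile rows (per-slab time-averaged vx between samples)
  std::vector<double> prof_v, prof_n;
  std::vector<double> prof_acc_v(n_slabs > 0 ? n_slabs : 1, 0.0);
  std::vector<double> prof_acc_n(n_slabs > 0 ? n_slabs : 1, 0.0);
  // swap log
  std::vector<double> sw_step, sw_ilo, sw_iup, sw_dpx, sw_ke_before, sw_ke_after,
      sw_px_before, sw_px_after;

  List frames;
  std::vector<NumericMatrix> frame_store;
  std::vector<int> frame_steps;

  double swap_px_accum = 0.0;
  long skipped_swaps = 0;

  auto slab_of = [&](double zz) {
    int k = (int)(zz / Lz * n_slabs);
    if (k >= n_slabs) k = n_slabs - 1;
    if (k < 0) k = 0;
    return k;
  };

  auto record_sample = [&](long step) {
    double ke = 0, sx = 0, sy = 0, sz = 0;
    for (int i = 0; i < n; ++i) {
      ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      sx += vx[i]; sy += vy[i]; sz += vz[i];
    }
    if (!std::isfinite(ke) || !std::isfinite(f.u_pair) ||
        !std::isfinite(f.u_bond) || !std::isfinite(f.u_angle))
      stop("non-finite energy at step %ld", step);
    ob_step.push_back((double)step);
    ob_time.push_back(step * dt);
    ob_ke.push_back(ke);
    ob_upair.push_back(f.u_pair);
    ob_ubond.push_back(f.u_bond);
    ob_uangle.push_back(f.u_angle);
    ob_px.push_back(sx); ob_py.push_back(sy); ob_pz.push_back(sz);
    ob_swap_px.push_back(swap_px_accum);
    if (n_slabs > 0) {
      for (int k = 0; k < n_slabs; ++k) {
        prof_v.push_back(prof_acc_n[k] > 0 ? prof_acc_v[k] / prof_acc_n[k] : NA_REAL);
        prof_n.push_back(prof_acc_n[k]);
        prof_acc_v[k] = 0.0; prof_acc_n[k] = 0.0;
      }
    }
  };

  auto record_frame = [&](long step) {
    NumericMatrix fr(n, 6);
    for (int i = 0; i < n; ++i) {
      fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
      fr(i, 3) = vx[i]; fr(i, 4) = vy[i]; fr(i, 5) = vz[i];
    }
    frame_store.push_back(fr);
    frame_steps.push_back((int)step);
  };

  for (int s = 0; s < n_steps; ++s) {
    long g = step0 + s;   // step being advanced

    // Mueller-Plathe momentum swap, executed before integration
    if (swap_every > 0 && (g % swap_every == 0)) {
      int ilo = -1, iup = -1;
      double vlo = R_PosInf, vup = R_NegInf;
      int upper = n_slabs / 2;
      for (int i = 0; i < n; ++i) {
        int k = slab_of(z[i]);
        if (k == 0 && vx[i] < vlo) { vlo = vx[i]; ilo = i; }
        if (k == upper && vx[i] > vup) { vup = vx[i]; iup = i; }
      }
      if (ilo < 0 || iup < 0) {
        skipped_swaps++;
      } else {
        double keb = 0.5 * (vx[ilo] * vx[ilo] + vx[iup] * vx[iup]);
        double pxb = vx[ilo] + vx[iup];
        double tmp = vx[ilo]; vx[ilo] = vx[iup]; vx[iup] = tmp;
        double kea = 0.5 * (vx[ilo] * vx[ilo] + vx[iup] * vx[iup]);
        double pxa = vx[ilo] + vx[iup];
        double dpx = vup - vlo;   // x-momentum handed to the lower slab (m = 1)
        swap_px_accum += dpx;
        sw_step.push_back((double)g);
        sw_ilo.push_back((double)(ilo + 1));
        sw_iup.push_back((double)(iup + 1));
        sw_dpx.push_back(dpx);
        sw_ke_before.push_back(keb); sw_ke_after.push_back(kea);
        sw_px_before.push_back(pxb); sw_px_after.push_back(pxa);
      }
    }

    // Groot-Warren modified velocity Verlet
    const double h2 = 0.5 * dt * dt, lh = lambda * dt, hh = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      x[i] += dt * vx[i] + h2 * f.fx[i];
      y[i] += dt * vy[i] + h2 * f.fy[i];
      z[i] += dt * vz[i] + h2 * f.fz[i];
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      z[i] -= Lz * std::floor(z[i] / Lz);
      px[i] = vx[i] + lh * f.fx[i];
      py[i] = vy[i] + lh * f.fy[i];
      pz[i] = vz[i] + lh * f.fz[i];
    }
    ForceAccum fn(n);
    eval_forces(fn, px.data(), py.data(), pz.data(), g + 1);
    n_overlap += fn.n_overlap;
    for (int i = 0; i < n; ++i) {
      vx[i] += hh * (f.fx[i] + fn.fx[i]);
      vy[i] += hh * (f.fy[i] + fn.fy[i]);
      vz[i] += hh * (f.fz[i] + fn.fz[i]);
    }
    f.fx.swap(fn.fx); f.fy.swap(fn.fy); f.fz.swap(fn.fz);
    f.u_pair = fn.u_pair; f.u_bond = fn.u_bond; f.u_angle = fn.u_angle;

    long done = g + 1;
    if (n_slabs > 0) {
      for (int i = 0; i < n; ++i) {
        int k = slab_of(z[i]);
        prof_acc_v[k] += vx[i];
        prof_acc_n[k] += 1.0;
      }
    }
    if (sample_every > 0 &&
        (done % sample_every == 0 || s == n_steps - 1))
      if (ob_step.empty() || ob_step.back() != (double)done)
        record_sample(done);
    if (frame_every > 0 && (done % frame_every == 0 || s == n_steps - 1))
      if (frame_steps.empty() || frame_steps.back() != (int)done)
        record_frame(done);
    if ((s & 1023) == 1023) Rcpp::checkUserInterrupt();
  }

  int nsamp = ob_step.size();
  NumericMatrix obs(nsamp, 10);
  for (int r = 0; r < nsamp; ++r) {
    obs(r, 0) = ob_step[r]; obs(r, 1) = ob_time[r]; obs(r, 2) = ob_ke[r];
    obs(r, 3) = ob_upair[r]; obs(r, 4) = ob_ubond[r]; obs(r, 5) = ob_uangle[r];
    obs(r, 6) = ob_px[r]; obs(r, 7) = ob_py[r]; obs(r, 8) = ob_pz[r];
    obs(r, 9) = ob_swap_px[r];
  }
  colnames(obs) = CharacterVector::create(
      "step", "time", "e_kinetic", "e_pair", "e_bond", "e_angle",
      "px", "py", "pz", "swap_px");

  NumericMatrix prof_vm(0, 0), prof_nm(0, 0);
  if (n_slabs > 0 && nsamp > 0) {
    prof_vm = NumericMatrix(nsamp, n_slabs);
    prof_nm = NumericMatrix(nsamp, n_slabs);
    for (int r = 0; r < nsamp; ++r)
      for (int k = 0; k < n_slabs; ++k) {
        prof_vm(r, k) = prof_v[r * n_slabs + k];
        prof_nm(r, k) = prof_n[r * n_slabs + k];
      }
  }

  int nsw = sw_step.size();
  NumericMatrix swm(nsw, 8);
  for (int r = 0; r < nsw; ++r) {
    swm(r, 0) = sw_step[r]; swm(r, 1) = sw_ilo[r]; swm(r, 2) = sw_iup[r];
    swm(r, 3) = sw_dpx[r]; swm(r, 4) = sw_ke_before[r]; swm(r, 5) = sw_ke_after[r];
    swm(r, 6) = sw_px_before[r]; swm(r, 7) = sw_px_after[r];
  }
  colnames(swm) = CharacterVector::create(
      "step", "i_lower", "i_upper", "dpx", "ke_pair_before", "ke_pair_after",
      "px_pair_before", "px_pair_after");

  List frame_list(frame_store.size());
  for (size_t r = 0; r < frame_store.size(); ++r) frame_list[r] = frame_store[r];

  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["z"] = NumericVector(z.begin(), z.end()),
      _["vx"] = NumericVector(vx.begin(), vx.end()),
      _["vy"] = NumericVector(vy.begin(), vy.end()),
      _["vz"] = NumericVector(vz.begin(), vz.end()),
      _["fx"] = NumericVector(f.fx.begin(), f.fx.end()),
      _["fy"] = NumericVector(f.fy.begin(), f.fy.end()),
      _["fz"] = NumericVector(f.fz.begin(), f.fz.end()),
      _["obs"] = obs, _["profile_v"] = prof_vm, _["profile_n"] = prof_nm,
      _["swaps"] = swm, _["frames"] = frame_list,
      _["frame_steps"] = IntegerVector(frame_steps.begin(), frame_steps.end()),
      _["step_end"] = (double)(step0 + n_steps),
      _["swap_px_accum"] = swap_px_accum,
      _["skipped_swaps"] = (double)skipped_swaps,
      _["n_overlap"] = (double)n_overlap);
}
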