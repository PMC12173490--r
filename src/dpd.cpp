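// DPD solvent kernels: pairwise conservative/dissipative/random forces with
// a counter-based (hash) random stream so that xi_ij = xi_ji holds without
// storage and runs are bit-reproducible, a linked-cell neighbour search, and
// a self-contained velocity-Verlet driver for pure-fluid measurements
// (equilibrium temperature, periodic-Poiseuille viscosity).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// standard normal from the hash of (seed, step, ordered pair)
static inline double pair_gauss(uint64_t seed, uint64_t step, int i, int j) {
  if (i > j) std::swap(i, j);
  uint64_t k = sm64(seed ^ (step * 0xd6e8feb86659fd93ULL));
  k = sm64(k ^ ((uint64_t)i * 0xa0761d6478bd642fULL) ^
           ((uint64_t)j * 0xe7037ed1a0b428dbULL));
  uint64_t r1 = sm64(k);
  uint64_t r2 = sm64(k ^ 0x94d049bb133111ebULL);
  double u1 = ((r1 >> 11) + 1.0) * 1.1102230246251565e-16;  // (0,1]
  double u2 = (r2 >> 11) * 1.1102230246251565e-16;          // [0,1)
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

struct CellList {
  int nc[3];
  double cw[3];
  std::vector<int> head, next;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const double* box, double rcut) {
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(box[d] / rcut));
      cw[d] = box[d] / nc[d];
    }
    int ntot = nc[0] * nc[1] * nc[2];
    head.assign(ntot, -1);
    int n = x.size();
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] / cw[0]) % nc[0];
      int cy = (int)(y[i] / cw[1]) % nc[1];
      int cz = (int)(z[i] / cw[2]) % nc[2];
      if (cx < 0) cx += nc[0];
      if (cy < 0) cy += nc[1];
      if (cz < 0) cz += nc[2];
      int c = (cz * nc[1] + cy) * nc[0] + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

struct PairPar {
  double a, gamma, sigma, s, rc;
};

template <class PairFun>
static void for_all_pairs(const std::vector<double>& wx,
                          const std::vector<double>& wy,
                          const std::vector<double>& wz, const double* box,
                          double rcmax, PairFun f) {
  int n = wx.size();
  CellList cl;
  cl.build(wx, wy, wz, box, rcmax);
  bool small = (cl.nc[0] < 3 || cl.nc[1] < 3 || cl.nc[2] < 3);
  if (small) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) f(i, j);
    return;
  }
  // half stencil: same cell (j > i) plus 13 neighbour cells
  static const int off[13][3] = {{1, 0, 0},  {0, 1, 0},   {0, 0, 1},
                                 {1, 1, 0},  {1, -1, 0},  {1, 0, 1},
                                 {1, 0, -1}, {0, 1, 1},   {0, 1, -1},
                                 {1, 1, 1},  {1, 1, -1},  {1, -1, 1},
                                 {1, -1, -1}};
  for (int cz = 0; cz < cl.nc[2]; ++cz)
    for (int cy = 0; cy < cl.nc[1]; ++cy)
      for (int cx = 0; cx < cl.nc[0]; ++cx) {
        int c = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
        for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
          for (int j = cl.next[i]; j >= 0; j = cl.next[j]) f(i, j);
          for (int q = 0; q < 13; ++q) {
            int ax = (cx + off[q][0] + cl.nc[0]) % cl.nc[0];
            int ay = (cy + off[q][1] + cl.nc[1]) % cl.nc[1];
            int az = (cz + off[q][2] + cl.nc[2]) % cl.nc[2];
            int c2 = (az * cl.nc[1] + ay) * cl.nc[0] + ax;
            for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) f(i, j);
          }
        }
      }
}

// periodic wrap into [0, L) without fmod
static inline double wrap0(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;
  if (v < 0.0) v += L;
  return v;
}

static inline double minimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// DPD forces for a mixed fluid/swimmer system.  `type` is 0 for fluid and 1
// for swimmer particles; `pars` has rows (ff, fs, ss) of (a, gamma, sigma,
// s, rc).  A row with rc <= 0 disables that pair class.
// [[Rcpp::export]]
NumericMatrix cpp_dpd_forces(NumericMatrix pos, NumericMatrix vel,
                             IntegerVector type, NumericVector box,
                             NumericMatrix pars, double dt, double step,
                             double seed) {
  int n = pos.nrow();
  std::vector<double> wx(n), wy(n), wz(n);
  double B[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    wx[i] = wrap0(pos(i, 0), B[0]);
    wy[i] = wrap0(pos(i, 1), B[1]);
    wz[i] = wrap0(pos(i, 2), B[2]);
  }
  PairPar pp[3];
  double rcmax = 0.0;
  for (int r = 0; r < 3; ++r) {
    pp[r].a = pars(r, 0); pp[r].gamma = pars(r, 1); pp[r].sigma = pars(r, 2);
    pp[r].s = pars(r, 3); pp[r].rc = pars(r, 4);
    if (pp[r].rc > rcmax) rcmax = pp[r].rc;
  }
  NumericMatrix F(n, 3);
  double isqdt = 1.0 / std::sqrt(dt);
  uint64_t sd = (uint64_t)seed, st = (uint64_t)step;
  for_all_pairs(wx, wy, wz, B, rcmax, [&](int i, int j) {
    int cls = type[i] + type[j];
    const PairPar& p = pp[cls];
    if (p.rc <= 0.0) return;
    double dx = minimg(wx[i] - wx[j], B[0]);
    double dy = minimg(wy[i] - wy[j], B[1]);
    double dz = minimg(wz[i] - wz[j], B[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= p.rc * p.rc || r2 == 0.0) return;
    double r = std::sqrt(r2);
    double ex = dx / r, ey = dy / r, ez = dz / r;
    double omr = 1.0 - r / p.rc;
    double wr = std::pow(omr, p.s);
    double vx = vel(i, 0) - vel(j, 0);
    double vy = vel(i, 1) - vel(j, 1);
    double vz = vel(i, 2) - vel(j, 2);
    double vr = vx * ex + vy * ey + vz * ez;
    double xi = pair_gauss(sd, st, i, j);
    double fmag = p.a * omr - p.gamma * wr * wr * vr +
                  p.sigma * wr * xi * isqdt;
    F(i, 0) += fmag * ex; F(i, 1) += fmag * ey; F(i, 2) += fmag * ez;
    F(j, 0) -= fmag * ex; F(j, 1) -= fmag * ey; F(j, 2) -= fmag * ez;
  });
  return F;
}

// Self-contained pure-fluid driver: DPD velocity-Verlet (dissipative force
// recomputed with half-step velocities), optional periodic-Poiseuille body
// force +/- fbody e_x in the two z-halves, accumulation of the binned
// velocity profile and of kinetic-temperature statistics.
// [[Rcpp::export]]
List cpp_fluid_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector box,
                   double a, double gamma, double s, double rc, double kBT,
                   double dt, int nsteps, double seed, double step0,
                   double fbody, int nbins, int burn, int sample_every) {
  int n = pos0.nrow();
  double B[3] = {box[0], box[1], box[2]};
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), fx(n), fy(n),
      fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  double sigma = std::sqrt(2.0 * gamma * kBT);
  double isqdt = 1.0 / std::sqrt(dt);
  uint64_t sd = (uint64_t)seed;

  std::vector<double> bn(nbins, 0.0), bvx(nbins, 0.0), bvx2(nbins, 0.0),
      bvy2(nbins, 0.0), bvz2(nbins, 0.0);
  std::vector<double> tser;

  auto forces = [&](uint64_t st) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for_all_pairs(x, y, z, B, rc, [&](int i, int j) {
      double dx = minimg(x[i] - x[j], B[0]);
      double dy = minimg(y[i] - y[j], B[1]);
      double dz = minimg(z[i] - z[j], B[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc || r2 == 0.0) return;
      double r = std::sqrt(r2);
      double ex = dx / r, ey = dy / r, ez = dz / r;
      double omr = 1.0 - r / rc;
      double wr = std::pow(omr, s);
      double vr = (vx[i] - vx[j]) * ex + (vy[i] - vy[j]) * ey +
                  (vz[i] - vz[j]) * ez;
      double xi = pair_gauss(sd, st, i, j);
      double fm = a * omr - gamma * wr * wr * vr + sigma * wr * xi * isqdt;
      fx[i] += fm * ex; fy[i] += fm * ey; fz[i] += fm * ez;
      fx[j] -= fm * ex; fy[j] -= fm * ey; fz[j] -= fm * ez;
    });
    if (fbody != 0.0) {
      double fsum = 0.0;
      for (int i = 0; i < n; ++i)
        fsum += (z[i] < 0.5 * B[2]) ? fbody : -fbody;
      double fcorr = fsum / n;  // keep net momentum exactly constant
      for (int i = 0; i < n; ++i)
        fx[i] += ((z[i] < 0.5 * B[2]) ? fbody : -fbody) - fcorr;
    }
  };

  forces((uint64_t)step0);
  for (int t = 0; t < nsteps; ++t) {
    uint64_t st = (uint64_t)step0 + t;
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
      x[i] = wrap0(x[i], B[0]);
      y[i] = wrap0(y[i], B[1]);
      z[i] = wrap0(z[i], B[2]);
    }
    forces(st + 1);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      if (!std::isfinite(vx[i]) || std::fabs(vx[i]) > 1e3)
        stop("integrator instability at step %d", t);
    }
    if (t >= burn) {
      for (int i = 0; i < n; ++i) {
        int b = (int)(z[i] / B[2] * nbins);
        if (b < 0) b = 0;
        if (b >= nbins) b = nbins - 1;
        bn[b] += 1.0;
        bvx[b] += vx[i];
        bvx2[b] += vx[i] * vx[i];
        bvy2[b] += vy[i] * vy[i];
        bvz2[b] += vz[i] * vz[i];
      }
    }
    if (sample_every > 0 && (t + 1) % sample_every == 0) {
      double sx = 0, sy = 0, sz = 0, s2 = 0;
      for (int i = 0; i < n; ++i) {
        sx += vx[i]; sy += vy[i]; sz += vz[i];
      }
      sx /= n; sy /= n; sz /= n;
      for (int i = 0; i < n; ++i)
        s2 += (vx[i] - sx) * (vx[i] - sx) + (vy[i] - sy) * (vy[i] - sy) +
              (vz[i] - sz) * (vz[i] - sz);
      tser.push_back(s2 / (3.0 * n - 3.0));
    }
  }
  NumericMatrix pos(n, 3), vel(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i]; pos(i, 1) = y[i]; pos(i, 2) = z[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
  }
  return List::create(
      _["pos"] = pos, _["vel"] = vel, _["bin_n"] = wrap(bn),
      _["bin_vx"] = wrap(bvx), _["bin_vx2"] = wrap(bvx2),
      _["bin_vy2"] = wrap(bvy2), _["bin_vz2"] = wrap(bvz2),
      _["temperature_series"] = wrap(tser), _["steps"] = nsteps);
}
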