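// Membrane kernels: WLC-POW bonds, discrete Helfrich bending on the
// cotangent dual lattice, and global area / local area / volume constraints.
// Bond and constraint forces are analytic gradients; the bending force uses
// forward-mode dual numbers over the one-ring stencil of each vertex.
#include <Rcpp.h>
#include "dual.h"
using namespace Rcpp;

static const int MESHW = 33;  // 3 * (1 + max ring size 10)

template <class T>
static V3<T> getv(const T* X, int k) {
  return V3<T>(X[3 * k], X[3 * k + 1], X[3 * k + 2]);
}

// Per-vertex bending energy over the one-ring.  X holds the vertex itself
// (slot 0) followed by its ring in cyclic outward-oriented order.
template <class T>
static T vertex_bend(const T* X, int d, double H0, double kappa, T* Hout,
                     T* sigout) {
  V3<T> xi = getv(X, 0);
  V3<T> N(T(0.0), T(0.0), T(0.0));
  for (int k = 0; k < d; ++k) {
    V3<T> e1 = getv(X, 1 + k) - xi;
    V3<T> e2 = getv(X, 1 + (k + 1) % d) - xi;
    N = N + cross(e1, e2);
  }
  T Nn = norm(N);
  V3<T> n = (1.0 / Nn) * N;

  V3<T> S(T(0.0), T(0.0), T(0.0));
  T sig(0.0);
  for (int k = 0; k < d; ++k) {
    V3<T> xj = getv(X, 1 + k);
    V3<T> xa = getv(X, 1 + (k - 1 + d) % d);
    V3<T> xb = getv(X, 1 + (k + 1) % d);
    V3<T> ia = xi - xa, ja = xj - xa;
    V3<T> ib = xi - xb, jb = xj - xb;
    T cota = dot(ia, ja) / norm(cross(ia, ja));
    T cotb = dot(ib, jb) / norm(cross(ib, jb));
    T w = 0.5 * (cota + cotb);
    V3<T> rij = xi - xj;
    T r = norm(rij);
    S = S + w * rij;
    sig += 0.25 * w * (r * r);
  }
  // negative cotangent sums from obtuse pairs are kept (they preserve the
  // exact partition of the surface area over the dual lattice); only a
  // non-positive vertex area signals a degenerate fan
  if (sig.v <= 0.0) Rcpp::stop("degenerate dual area at a mesh vertex");
  T H = dot(n, S) / sig;
  if (Hout) *Hout = H;
  if (sigout) *sigout = sig;
  T dH = H - H0;
  return (0.5 * kappa) * sig * (dH * dH);
}

// plain-double overload used for geometry measurements
static double vertex_bend_d(const double* X, int d, double H0, double kappa,
                            double* Hout, double* sigout) {
  typedef double T;
  V3<T> xi = getv(X, 0);
  V3<T> N(0, 0, 0);
  for (int k = 0; k < d; ++k) {
    V3<T> e1 = getv(X, 1 + k) - xi;
    V3<T> e2 = getv(X, 1 + (k + 1) % d) - xi;
    N = N + cross(e1, e2);
  }
  double Nn = norm(N);
  V3<T> n = (1.0 / Nn) * N;
  V3<T> S(0, 0, 0);
  double sig = 0;
  for (int k = 0; k < d; ++k) {
    V3<T> xj = getv(X, 1 + k);
    V3<T> xa = getv(X, 1 + (k - 1 + d) % d);
    V3<T> xb = getv(X, 1 + (k + 1) % d);
    V3<T> ia = xi - xa, ja = xj - xa;
    V3<T> ib = xi - xb, jb = xj - xb;
    double cota = dot(ia, ja) / norm(cross(ia, ja));
    double cotb = dot(ib, jb) / norm(cross(ib, jb));
    double w = 0.5 * (cota + cotb);
    V3<T> rij = xi - xj;
    double r = norm(rij);
    S = S + w * rij;
    sig += 0.25 * w * r * r;
  }
  if (sig <= 0.0) Rcpp::stop("degenerate dual area at a mesh vertex");
  double H = dot(n, S) / sig;
  if (Hout) *Hout = H;
  if (sigout) *sigout = sig;
  double dH = H - H0;
  return 0.5 * kappa * sig * dH * dH;
}

// [[Rcpp::export]]
List cpp_mesh_geometry(NumericMatrix pos, List rings) {
  int nv = pos.nrow();
  NumericVector H(nv), sig(nv);
  NumericMatrix nrm(nv, 3);
  std::vector<double> X(3 * 16);
  for (int i = 0; i < nv; ++i) {
    IntegerVector ring = rings[i];
    int d = ring.size();
    X.resize(3 * (d + 1));
    for (int c = 0; c < 3; ++c) X[c] = pos(i, c);
    for (int k = 0; k < d; ++k)
      for (int c = 0; c < 3; ++c) X[3 * (k + 1) + c] = pos(ring[k] - 1, c);
    double Hi, si;
    vertex_bend_d(X.data(), d, 0.0, 1.0, &Hi, &si);
    H[i] = Hi;
    sig[i] = si;
    // recompute normal for output
    V3<double> xi = getv(X.data(), 0), N(0, 0, 0);
    for (int k = 0; k < d; ++k) {
      V3<double> e1 = getv(X.data(), 1 + k) - xi;
      V3<double> e2 = getv(X.data(), 1 + (k + 1) % d) - xi;
      N = N + cross(e1, e2);
    }
    double Nn = norm(N);
    nrm(i, 0) = N.x / Nn;
    nrm(i, 1) = N.y / Nn;
    nrm(i, 2) = N.z / Nn;
  }
  return List::create(_["H"] = H, _["sigma"] = sig, _["normal"] = nrm);
}

// [[Rcpp::export]]
List cpp_mesh_bending(NumericMatrix pos, List rings, NumericVector H0,
                      double kappa) {
  int nv = pos.nrow();
  double U = 0.0;
  NumericMatrix F(nv, 3);
  typedef Dual<MESHW> D;
  std::vector<D> X(1 + 10);
  for (int i = 0; i < nv; ++i) {
    IntegerVector ring = rings[i];
    int d = ring.size();
    if (3 * (d + 1) > MESHW) stop("vertex degree too large for bending kernel");
    X.resize(d + 1);
    std::vector<D> Xc(3 * (d + 1));
    for (int c = 0; c < 3; ++c) Xc[c] = D::var(pos(i, c), c);
    for (int k = 0; k < d; ++k)
      for (int c = 0; c < 3; ++c)
        Xc[3 * (k + 1) + c] = D::var(pos(ring[k] - 1, c), 3 * (k + 1) + c);
    D u = vertex_bend<D>(Xc.data(), d, H0[i], kappa, nullptr, nullptr);
    U += u.v;
    for (int c = 0; c < 3; ++c) F(i, c) -= u.g[c];
    for (int k = 0; k < d; ++k)
      for (int c = 0; c < 3; ++c) F(ring[k] - 1, c) -= u.g[3 * (k + 1) + c];
  }
  return List::create(_["energy"] = U, _["forces"] = F);
}

// WLC attraction + inverse-power (kp / l) repulsion per edge
// [[Rcpp::export]]
List cpp_mesh_bonds(NumericMatrix pos, IntegerMatrix edges, NumericVector lmax,
                    NumericVector kp, double p, double kBT) {
  int ne = edges.nrow(), nv = pos.nrow();
  double U = 0.0;
  NumericMatrix F(nv, 3);
  int bad = 0;
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double x = l / lmax[e];
    if (x >= 1.0) {
      bad = e + 1;
      break;
    }
    double om = 1.0 - x;
    U += kBT * lmax[e] / (4.0 * p) * (3.0 * x * x - 2.0 * x * x * x) / om +
         kp[e] / l;
    // dU/dl
    double gp = (6.0 * x - 9.0 * x * x + 4.0 * x * x * x) / (om * om);
    double dUdl = kBT / (4.0 * p) * gp - kp[e] / (l * l);
    double f = -dUdl / l;  // along rij on i
    F(i, 0) += f * dx;
    F(i, 1) += f * dy;
    F(i, 2) += f * dz;
    F(j, 0) -= f * dx;
    F(j, 1) -= f * dy;
    F(j, 2) -= f * dz;
  }
  return List::create(_["energy"] = U, _["forces"] = F, _["bad_edge"] = bad);
}

// [[Rcpp::export]]
List cpp_mesh_constraints(NumericMatrix pos, IntegerMatrix tris, double ka,
                          double kd, double kv, double A0, NumericVector Am0,
                          double V0) {
  int nt = tris.nrow(), nv = pos.nrow();
  std::vector<double> Am(nt);
  std::vector<V3<double> > nface(nt);
  double A = 0.0, V = 0.0;
  for (int t = 0; t < nt; ++t) {
    V3<double> a(pos(tris(t, 0) - 1, 0), pos(tris(t, 0) - 1, 1),
                 pos(tris(t, 0) - 1, 2));
    V3<double> b(pos(tris(t, 1) - 1, 0), pos(tris(t, 1) - 1, 1),
                 pos(tris(t, 1) - 1, 2));
    V3<double> c(pos(tris(t, 2) - 1, 0), pos(tris(t, 2) - 1, 1),
                 pos(tris(t, 2) - 1, 2));
    V3<double> N = cross(b - a, c - a);
    double Nn = norm(N);
    Am[t] = 0.5 * Nn;
    nface[t] = (1.0 / Nn) * N;
    A += Am[t];
    V += dot(a, cross(b, c)) / 6.0;
  }
  double U = ka * (A - A0) * (A - A0) / (2.0 * A0) +
             kv * (V - V0) * (V - V0) / (2.0 * V0);
  double cA = ka * (A - A0) / A0;
  double cV = kv * (V - V0) / V0;
  NumericMatrix F(nv, 3);
  for (int t = 0; t < nt; ++t) {
    int ia = tris(t, 0) - 1, ib = tris(t, 1) - 1, ic = tris(t, 2) - 1;
    V3<double> a(pos(ia, 0), pos(ia, 1), pos(ia, 2));
    V3<double> b(pos(ib, 0), pos(ib, 1), pos(ib, 2));
    V3<double> c(pos(ic, 0), pos(ic, 1), pos(ic, 2));
    double cL = kd * (Am[t] - Am0[t]) / Am0[t];
    U += kd * (Am[t] - Am0[t]) * (Am[t] - Am0[t]) / (2.0 * Am0[t]);
    double cc = cA + cL;
    // area gradients
    V3<double> ga = 0.5 * cross(nface[t], c - b);
    V3<double> gb = 0.5 * cross(nface[t], a - c);
    V3<double> gc = 0.5 * cross(nface[t], b - a);
    // volume gradients
    V3<double> va = (1.0 / 6.0) * cross(b, c);
    V3<double> vb = (1.0 / 6.0) * cross(c, a);
    V3<double> vc = (1.0 / 6.0) * cross(a, b);
    F(ia, 0) -= cc * ga.x + cV * va.x;
    F(ia, 1) -= cc * ga.y + cV * va.y;
    F(ia, 2) -= cc * ga.z + cV * va.z;
    F(ib, 0) -= cc * gb.x + cV * vb.x;
    F(ib, 1) -= cc * gb.y + cV * vb.y;
    F(ib, 2) -= cc * gb.z + cV * vb.z;
    F(ic, 0) -= cc * gc.x + cV * vc.x;
    F(ic, 1) -= cc * gc.y + cV * vc.y;
    F(ic, 2) -= cc * gc.z + cV * vc.z;
  }
  return List::create(_["energy"] = U, _["forces"] = F, _["area"] = A,
                      _["volume"] = V);
}

// generic harmonic springs U = k/2 (l - l0)^2 (flagellum octahedra)
// [[Rcpp::export]]
List cpp_springs(NumericMatrix pos, IntegerMatrix pairs, NumericVector k,
                 NumericVector l0) {
  int np = pairs.nrow(), nv = pos.nrow();
  double U = 0.0;
  NumericMatrix F(nv, 3);
  for (int e = 0; e < np; ++e) {
    int i = pairs(e, 0) - 1, j = pairs(e, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dl = l - l0[e];
    U += 0.5 * k[e] * dl * dl;
    double f = -k[e] * dl / l;
    F(i, 0) += f * dx;
    F(i, 1) += f * dy;
    F(i, 2) += f * dz;
    F(j, 0) -= f * dx;
    F(j, 1) -= f * dy;
    F(j, 2) -= f * dz;
  }
  return List::create(_["energy"] = U, _["forces"] = F);
}
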