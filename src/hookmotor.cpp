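// Hook angle potential (dual-number gradients) and WCA excluded-volume
// interactions between flagella and between flagella and the body.
#include <Rcpp.h>
#include "dual.h"
using namespace Rcpp;

// U = Khook * sum_j (theta_j - pi/2)^2 with theta_j the angle between
// (r_j - r_i) and (r_{2,0} - r_i)
// [[Rcpp::export]]
List cpp_hook(NumericVector ri, NumericMatrix ring, NumericVector r2,
              double Khook) {
  typedef Dual<9> D;
  int m = ring.nrow();
  double U = 0.0;
  NumericVector Fi(3), F2(3);
  NumericMatrix Fr(m, 3);
  const double pih = M_PI / 2.0;
  for (int j = 0; j < m; ++j) {
    D X[9];
    for (int c = 0; c < 3; ++c) {
      X[c] = D::var(ri[c], c);
      X[3 + c] = D::var(ring(j, c), 3 + c);
      X[6 + c] = D::var(r2[c], 6 + c);
    }
    V3<D> u(X[3] - X[0], X[4] - X[1], X[5] - X[2]);
    V3<D> w(X[6] - X[0], X[7] - X[1], X[8] - X[2]);
    D cth = dot(u, w) / (norm(u) * norm(w));
    D th = acos_clamped(cth);
    D d = th - pih;
    D e = Khook * (d * d);
    U += e.v;
    for (int c = 0; c < 3; ++c) {
      Fi[c] -= e.g[c];
      Fr(j, c) -= e.g[3 + c];
      F2[c] -= e.g[6 + c];
    }
  }
  return List::create(_["energy"] = U, _["f_anchor"] = Fi, _["f_ring"] = Fr,
                      _["f_first"] = F2);
}

// Purely repulsive (WCA) Lennard-Jones between particles of different
// flagella and between flagella and body particles.  fid = 0 marks a
// particle with no flagellum affiliation; body anchors carry the fid of
// their flagellum so bonded neighbourhoods are excluded.
// [[Rcpp::export]]
List cpp_lj(NumericMatrix pos, IntegerVector isbody, IntegerVector fid,
            double eps, double sigma) {
  int n = pos.nrow();
  double rc2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  double U = 0.0;
  NumericMatrix F(n, 3);
  double s2 = sigma * sigma;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (isbody[i] && isbody[j]) continue;
      if (fid[i] > 0 && fid[i] == fid[j]) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 <= 0.0) continue;
      double sr2 = s2 / r2;
      double sr6 = sr2 * sr2 * sr2;
      U += 4.0 * eps * (sr6 * sr6 - sr6 + 0.25);
      double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
      F(i, 0) += fmag * dx;
      F(i, 1) += fmag * dy;
      F(i, 2) += fmag * dz;
      F(j, 0) -= fmag * dx;
      F(j, 1) -= fmag * dy;
      F(j, 2) -= fmag * dz;
    }
  }
  return List::create(_["energy"] = U, _["forces"] = F);
}
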