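// Forward-mode dual numbers with a fixed-capacity gradient, used to obtain
// machine-precision gradients of the geometrically involved energy terms
// (discrete Helfrich bending, rod twist/bend strain, hook angles).  The
// gradient width W is a compile-time bound on 3 x (stencil size).
#ifndef ECOLISWIM_DUAL_H
#define ECOLISWIM_DUAL_H

#include <cmath>
#include <cstring>

template <int W>
struct Dual {
  double v;
  double g[W];

  Dual() : v(0.0) { std::memset(g, 0, sizeof(g)); }
  Dual(double x) : v(x) { std::memset(g, 0, sizeof(g)); }

  static Dual var(double x, int i) {
    Dual d(x);
    d.g[i] = 1.0;
    return d;
  }

  Dual& operator+=(const Dual& o) {
    v += o.v;
    for (int i = 0; i < W; ++i) g[i] += o.g[i];
    return *this;
  }
  Dual& operator-=(const Dual& o) {
    v -= o.v;
    for (int i = 0; i < W; ++i) g[i] -= o.g[i];
    return *this;
  }
};

template <int W>
inline Dual<W> operator+(const Dual<W>& a, const Dual<W>& b) {
  Dual<W> r;
  r.v = a.v + b.v;
  for (int i = 0; i < W; ++i) r.g[i] = a.g[i] + b.g[i];
  return r;
}
template <int W>
inline Dual<W> operator-(const Dual<W>& a, const Dual<W>& b) {
  Dual<W> r;
  r.v = a.v - b.v;
  for (int i = 0; i < W; ++i) r.g[i] = a.g[i] - b.g[i];
  return r;
}
template <int W>
inline Dual<W> operator-(const Dual<W>& a) {
  Dual<W> r;
  r.v = -a.v;
  for (int i = 0; i < W; ++i) r.g[i] = -a.g[i];
  return r;
}
template <int W>
inline Dual<W> operator*(const Dual<W>& a, const Dual<W>& b) {
  Dual<W> r;
  r.v = a.v * b.v;
  for (int i = 0; i < W; ++i) r.g[i] = a.g[i] * b.v + a.v * b.g[i];
  return r;
}
template <int W>
inline Dual<W> operator*(double s, const Dual<W>& a) {
  Dual<W> r;
  r.v = s * a.v;
  for (int i = 0; i < W; ++i) r.g[i] = s * a.g[i];
  return r;
}
template <int W>
inline Dual<W> operator*(const Dual<W>& a, double s) { return s * a; }
template <int W>
inline Dual<W> operator/(const Dual<W>& a, const Dual<W>& b) {
  Dual<W> r;
  const double inv = 1.0 / b.v;
  r.v = a.v * inv;
  for (int i = 0; i < W; ++i) r.g[i] = (a.g[i] - r.v * b.g[i]) * inv;
  return r;
}
template <int W>
inline Dual<W> operator/(const Dual<W>& a, double s) { return (1.0 / s) * a; }
template <int W>
inline Dual<W> operator/(double s, const Dual<W>& b) {
  Dual<W> r;
  const double inv = 1.0 / b.v;
  r.v = s * inv;
  for (int i = 0; i < W; ++i) r.g[i] = -r.v * inv * b.g[i];
  return r;
}
template <int W>
inline Dual<W> operator+(const Dual<W>& a, double s) {
  Dual<W> r = a;
  r.v += s;
  return r;
}
template <int W>
inline Dual<W> operator+(double s, const Dual<W>& a) { return a + s; }
template <int W>
inline Dual<W> operator-(const Dual<W>& a, double s) { return a + (-s); }
template <int W>
inline Dual<W> operator-(double s, const Dual<W>& a) { return (-a) + s; }

template <int W>
inline Dual<W> sqrt(const Dual<W>& a) {
  Dual<W> r;
  r.v = std::sqrt(a.v);
  const double d = 0.5 / r.v;
  for (int i = 0; i < W; ++i) r.g[i] = d * a.g[i];
  return r;
}
template <int W>
inline Dual<W> acos_clamped(const Dual<W>& a) {
  // derivative clamped away from |x| = 1 to keep forces finite on the
  // (measure-zero) degenerate configurations
  Dual<W> r;
  double x = a.v;
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  r.v = std::acos(x);
  double den = 1.0 - x * x;
  if (den < 1e-14) den = 1e-14;
  const double d = -1.0 / std::sqrt(den);
  for (int i = 0; i < W; ++i) r.g[i] = d * a.g[i];
  return r;
}
template <int W>
inline Dual<W> atan2(const Dual<W>& y, const Dual<W>& x) {
  Dual<W> r;
  r.v = std::atan2(y.v, x.v);
  const double den = x.v * x.v + y.v * y.v;
  for (int i = 0; i < W; ++i) r.g[i] = (x.v * y.g[i] - y.v * x.g[i]) / den;
  return r;
}

// minimal 3-vector templated on scalar type (double or Dual)
template <class T>
struct V3 {
  T x, y, z;
  V3() : x(0.0), y(0.0), z(0.0) {}
  V3(T a, T b, T c) : x(a), y(b), z(c) {}
};
template <class T>
inline V3<T> operator+(const V3<T>& a, const V3<T>& b) {
  return V3<T>(a.x + b.x, a.y + b.y, a.z + b.z);
}
template <class T>
inline V3<T> operator-(const V3<T>& a, const V3<T>& b) {
  return V3<T>(a.x - b.x, a.y - b.y, a.z - b.z);
}
template <class T, class S>
inline V3<T> operator*(const S& s, const V3<T>& a) {
  return V3<T>(s * a.x, s * a.y, s * a.z);
}
template <class T>
inline T dot(const V3<T>& a, const V3<T>& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
template <class T>
inline V3<T> cross(const V3<T>& a, const V3<T>& b) {
  return V3<T>(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
               a.x * b.y - a.y * b.x);
}
template <class T>
inline T norm(const V3<T>& a) { return sqrt(dot(a, a)); }
inline double norm(const V3<double>& a) { return std::sqrt(dot(a, a)); }

#endif
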