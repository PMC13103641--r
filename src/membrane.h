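#ifndef VESIFORM_MEMBRANE_H
#define VESIFORM_MEMBRANE_H

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

// Small fixed-size 3-vector helpers (hot path; avoid arma overhead).
struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  V3& operator+=(const V3& o) { x += o.x; y += o.y; z += o.z; return *this; }
};
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }

// Extended Nagata edge interpolant
//   phi(t) = xA + (d - c1 - c2) t + c1 t^2 + c2 t^3,  d = xB - xA
// with endpoint tangents orthogonal to the vertex normals (n.t = 0) and to the
// binormal estimates ((d x n).t = 0). The 4x6 system is underdetermined and is
// solved minimum-norm via c = A' (A A')^+ b with a relative SVD cutoff.
struct EdgeCoef { V3 c1, c2; };

inline EdgeCoef nagataEdge(const V3& xA, const V3& xB, const V3& nA, const V3& nB,
                           double svdTol = 1e-8) {
  V3 d = xB - xA;
  V3 bA = cross(d, nA);
  V3 bB = cross(d, nB);
  // rows of A (over unknowns [c1; c2]): [nA nA], [nB 2nB], [bA bA], [bB 2bB]
  const V3 r1a = nA, r2a = nB, r3a = bA, r4a = bB;
  const double m2[4] = {1.0, 2.0, 1.0, 2.0};  // multiplier on the c2 block
  const V3 rows[4] = {r1a, r2a, r3a, r4a};
  arma::mat S(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      S(i, j) = dot(rows[i], rows[j]) * (1.0 + m2[i] * m2[j]);
  arma::vec b(4);
  b(0) = dot(nA, d);
  b(1) = -dot(nB, d);
  b(2) = dot(bA, d);
  b(3) = -dot(bB, d);
  arma::mat Sp = arma::pinv(S, svdTol * arma::norm(S, 2));
  arma::vec lam = Sp * b;
  EdgeCoef ec;
  for (int i = 0; i < 4; ++i) {
    ec.c1 += rows[i] * lam(i);
    ec.c2 += rows[i] * (lam(i) * m2[i]);
  }
  return ec;
}

// Parameter reversal t -> 1 - t maps (c1, c2) to (c1 + 3 c2, -c2).
inline EdgeCoef reverseEdge(const EdgeCoef& e) {
  EdgeCoef r;
  r.c1 = e.c1 + e.c2 * 3.0;
  r.c2 = e.c2 * (-1.0);
  return r;
}

// Symmetric triangle quadrature rules (barycentric points, weights sum to 1).
struct QuadRule {
  int n;
  const double* pts;  // n x 3 barycentric
  const double* wts;
};

namespace quadrules {
static const double p1[] = {1. / 3, 1. / 3, 1. / 3};
static const double w1[] = {1.0};
static const double p2[] = {2. / 3, 1. / 6, 1. / 6, 1. / 6, 2. / 3, 1. / 6,
                            1. / 6, 1. / 6, 2. / 3};
static const double w2[] = {1. / 3, 1. / 3, 1. / 3};
static const double p3[] = {1. / 3, 1. / 3, 1. / 3, 0.6, 0.2, 0.2,
                            0.2,     0.6,     0.2,     0.2, 0.2, 0.6};
static const double w3[] = {-27. / 48, 25. / 48, 25. / 48, 25. / 48};
// Dunavant degree 4 (6 points) and degree 5 (7 points)
static const double a4 = 0.108103018168070, b4 = 0.445948490915965;
static const double c4 = 0.816847572980459, d4 = 0.091576213509771;
static const double p4[] = {a4, b4, b4, b4, a4, b4, b4, b4, a4,
                            c4, d4, d4, d4, c4, d4, d4, d4, c4};
static const double w4[] = {0.223381589678011, 0.223381589678011, 0.223381589678011,
                            0.109951743655322, 0.109951743655322, 0.109951743655322};
static const double a5 = 0.059715871789770, b5 = 0.470142064105115;
static const double c5 = 0.797426985353087, d5 = 0.101286507323456;
static const double p5[] = {1. / 3, 1. / 3, 1. / 3, a5, b5, b5, b5, a5, b5,
                            b5,     b5,     a5,     c5, d5, d5, d5, c5, d5,
                            d5,     d5,     c5};
static const double w5[] = {0.225,
                            0.132394152788506, 0.132394152788506, 0.132394152788506,
                            0.125939180544827, 0.125939180544827, 0.125939180544827};
}  // namespace quadrules

inline QuadRule quadRule(int order) {
  using namespace quadrules;
  switch (order) {
    case 1: return {1, p1, w1};
    case 2: return {3, p2, w2};
    case 3: return {4, p3, w3};
    case 4: return {6, p4, w4};
    default: return {7, p5, w5};
  }
}

// Curved triangular patch assembled from the three edge interpolants, in
// barycentric coordinates (u0, u1, u2) with independent parameters v = u1,
// w = u2. Directed edges (0->1), (1->2), (0->2) carry coefficients (cA),
// (cB), (cC). The patch restricts exactly to the edge curves on the boundary.
struct PatchEval {
  V3 P, Pv, Pw, Pvv, Pvw, Pww;
};

inline PatchEval evalPatch(const V3& x0, const V3& x1, const V3& x2,
                           const EdgeCoef& cA, const EdgeCoef& cB,
                           const EdgeCoef& cC, double v, double w) {
  const double u0 = 1.0 - v - w;
  PatchEval r;
  // linear part
  r.P = x0 * u0 + x1 * v + x2 * w;
  r.Pv = x1 - x0;
  r.Pw = x2 - x0;
  // edge 0->1: f = u0*v, g = f*(1+v)
  {
    double f = u0 * v, fv = 1.0 - 2.0 * v - w, fw = -v;
    double g = f * (1.0 + v);
    double gv = fv * (1.0 + v) + f, gw = fw * (1.0 + v);
    double fvv = -2.0, fvw = -1.0, fww = 0.0;
    double gvv = fvv * (1.0 + v) + 2.0 * fv, gvw = fvw * (1.0 + v) + fw, gww = 0.0;
    r.P += cA.c1 * (-f) + cA.c2 * (-g);
    r.Pv += cA.c1 * (-fv) + cA.c2 * (-gv);
    r.Pw += cA.c1 * (-fw) + cA.c2 * (-gw);
    r.Pvv += cA.c1 * (-fvv) + cA.c2 * (-gvv);
    r.Pvw += cA.c1 * (-fvw) + cA.c2 * (-gvw);
    r.Pww += cA.c1 * (-fww) + cA.c2 * (-gww);
  }
  // edge 1->2: f = v*w, g = v*w*(1+w)
  {
    double f = v * w, fv = w, fw = v;
    double g = f * (1.0 + w);
    double gv = w * (1.0 + w), gw = v * (1.0 + 2.0 * w);
    double gvw = 1.0 + 2.0 * w, gww = 2.0 * v;
    r.P += cB.c1 * (-f) + cB.c2 * (-g);
    r.Pv += cB.c1 * (-fv) + cB.c2 * (-gv);
    r.Pw += cB.c1 * (-fw) + cB.c2 * (-gw);
    r.Pvw += cB.c1 * (-1.0) + cB.c2 * (-gvw);
    r.Pww += cB.c2 * (-gww);
  }
  // edge 0->2: f = u0*w, g = f*(1+w)
  {
    double f = u0 * w, fv = -w, fw = 1.0 - v - 2.0 * w;
    double g = f * (1.0 + w);
    double gv = fv * (1.0 + w), gw = fw * (1.0 + w) + f;
    double fvw = -1.0, fww = -2.0;
    double gvw = fvw * (1.0 + w) + fv, gww = fww * (1.0 + w) + 2.0 * fw;
    r.P += cC.c1 * (-f) + cC.c2 * (-g);
    r.Pv += cC.c1 * (-fv) + cC.c2 * (-gv);
    r.Pw += cC.c1 * (-fw) + cC.c2 * (-gw);
    r.Pvw += cC.c1 * (-fvw) + cC.c2 * (-gvw);
    r.Pww += cC.c1 * (-fww) + cC.c2 * (-gww);
  }
  return r;
}

// Integrated face quantities. H and KG are area-weighted quadrature means
// (sign convention: H > 0 for a sphere with outward normals, CCW faces);
// intH2 = \int H^2 dA is kept so the curvature energy can be integrated
// pointwise -- using the face-mean H alone would make intra-face curvature
// oscillations (S-shaped patches with zero mean) energetically free.
struct FaceGeom {
  double area, H, KG, volC, intH2;
  bool ok;
};

inline FaceGeom faceGeometry(const V3& x0, const V3& x1, const V3& x2,
                             const EdgeCoef& cA, const EdgeCoef& cB,
                             const EdgeCoef& cC, int order) {
  QuadRule q = quadRule(order);
  double area = 0, volC = 0, Hsum = 0, H2sum = 0, Ksum = 0, wsum = 0;
  bool ok = true;
  for (int k = 0; k < q.n; ++k) {
    double v = q.pts[3 * k + 1], w = q.pts[3 * k + 2];
    PatchEval pe = evalPatch(x0, x1, x2, cA, cB, cC, v, w);
    V3 m = cross(pe.Pv, pe.Pw);
    double J = norm3(m);
    double E = dot(pe.Pv, pe.Pv), F = dot(pe.Pv, pe.Pw), G = dot(pe.Pw, pe.Pw);
    double det = E * G - F * F;
    if (!(det > 1e-14 * (E + G) * (E + G)) || J <= 0) { ok = false; continue; }
    V3 nh = m * (1.0 / J);
    double e = dot(pe.Pvv, nh), f = dot(pe.Pvw, nh), g = dot(pe.Pww, nh);
    double H = -(e * G - 2.0 * f * F + g * E) / (2.0 * det);
    double K = (e * g - f * f) / det;
    double wj = q.wts[k] * 0.5 * J;  // reference triangle area 1/2
    area += wj;
    volC += q.wts[k] * 0.5 * dot(pe.P, m) / 3.0;
    Hsum += wj * H;
    H2sum += wj * H * H;
    Ksum += wj * K;
    wsum += wj;
  }
  FaceGeom fg;
  fg.area = area;
  fg.volC = volC;
  fg.H = (wsum > 0) ? Hsum / wsum : 0.0;
  fg.KG = (wsum > 0) ? Ksum / wsum : 0.0;
  fg.intH2 = H2sum;
  fg.ok = ok && area > 0 && std::isfinite(fg.H) && std::isfinite(fg.KG) &&
          std::isfinite(fg.intH2);
  return fg;
}

#endif
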