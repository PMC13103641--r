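// [[Rcpp::depends(RcppArmadillo)]]
#include "membrane.h"
using namespace Rcpp;

static V3 rowV3(const NumericMatrix& M, int i) {
  return V3(M(i, 0), M(i, 1), M(i, 2));
}

// [[Rcpp::export]]
List cppEdgeCoefficients(NumericVector xA, NumericVector xB,
                         NumericVector nA, NumericVector nB, double svdTol) {
  EdgeCoef ec = nagataEdge(V3(xA[0], xA[1], xA[2]), V3(xB[0], xB[1], xB[2]),
                           V3(nA[0], nA[1], nA[2]), V3(nB[0], nB[1], nB[2]), svdTol);
  return List::create(_["c1"] = NumericVector::create(ec.c1.x, ec.c1.y, ec.c1.z),
                      _["c2"] = NumericVector::create(ec.c2.x, ec.c2.y, ec.c2.z));
}

// [[Rcpp::export]]
NumericMatrix cppEdgeEval(NumericVector xA, NumericVector xB,
                          NumericVector c1, NumericVector c2, NumericVector t) {
  V3 a(xA[0], xA[1], xA[2]), b(xB[0], xB[1], xB[2]);
  V3 C1(c1[0], c1[1], c1[2]), C2(c2[0], c2[1], c2[2]);
  V3 d = b - a;
  V3 lin = d - C1 - C2;
  NumericMatrix out(t.size(), 3);
  for (int i = 0; i < t.size(); ++i) {
    double s = t[i];
    V3 p = a + lin * s + C1 * (s * s) + C2 * (s * s * s);
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
  }
  return out;
}

// Edge coefficients for all edges, canonical direction EV[,1] -> EV[,2] (1-based in).
// [[Rcpp::export]]
NumericMatrix cppAllEdgeCoefficients(NumericMatrix V, NumericMatrix N,
                                     IntegerMatrix EV, double svdTol) {
  int ne = EV.nrow();
  NumericMatrix C(ne, 6);
  for (int e = 0; e < ne; ++e) {
    int a = EV(e, 0) - 1, b = EV(e, 1) - 1;
    EdgeCoef ec = nagataEdge(rowV3(V, a), rowV3(V, b), rowV3(N, a), rowV3(N, b), svdTol);
    C(e, 0) = ec.c1.x; C(e, 1) = ec.c1.y; C(e, 2) = ec.c1.z;
    C(e, 3) = ec.c2.x; C(e, 4) = ec.c2.y; C(e, 5) = ec.c2.z;
  }
  return C;
}

static EdgeCoef coefRow(const NumericMatrix& C, int e) {
  EdgeCoef ec;
  ec.c1 = V3(C(e, 0), C(e, 1), C(e, 2));
  ec.c2 = V3(C(e, 3), C(e, 4), C(e, 5));
  return ec;
}

// Face-local directed coefficients for face (i0,i1,i2): directions 0->1, 1->2, 0->2.
static void faceCoefs(const IntegerMatrix& F, const IntegerMatrix& EV,
                      const IntegerMatrix& FE, const NumericMatrix& C, int f,
                      EdgeCoef& cA, EdgeCoef& cB, EdgeCoef& cC) {
  int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
  int eA = FE(f, 0) - 1, eB = FE(f, 1) - 1, eC = FE(f, 2) - 1;  // (v0v1),(v1v2),(v2v0)
  cA = coefRow(C, eA);
  if (EV(eA, 0) - 1 != i0) cA = reverseEdge(cA);
  cB = coefRow(C, eB);
  if (EV(eB, 0) - 1 != i1) cB = reverseEdge(cB);
  cC = coefRow(C, eC);               // stored on edge (v2,v0); need direction v0->v2
  if (EV(eC, 0) - 1 != i0) cC = reverseEdge(cC);
  (void)i2;
}

// Per-face area, mean curvature, Gaussian curvature, signed volume contribution.
// [[Rcpp::export]]
NumericMatrix cppMeshGeometry(NumericMatrix V, NumericMatrix N, IntegerMatrix F,
                              IntegerMatrix EV, IntegerMatrix FE, int order,
                              double svdTol) {
  NumericMatrix C = cppAllEdgeCoefficients(V, N, EV, svdTol);
  int nf = F.nrow();
  NumericMatrix G(nf, 5);
  colnames(G) = CharacterVector::create("area", "H", "KG", "volume", "ok");
  for (int f = 0; f < nf; ++f) {
    EdgeCoef cA, cB, cC;
    faceCoefs(F, EV, FE, C, f, cA, cB, cC);
    FaceGeom fg = faceGeometry(rowV3(V, F(f, 0) - 1), rowV3(V, F(f, 1) - 1),
                               rowV3(V, F(f, 2) - 1), cA, cB, cC, order);
    G(f, 0) = fg.area; G(f, 1) = fg.H; G(f, 2) = fg.KG; G(f, 3) = fg.volC;
    G(f, 4) = fg.ok ? 1.0 : 0.0;
  }
  return G;
}

// Evaluate one face patch at supplied barycentric points (columns u0,u1,u2).
// [[Rcpp::export]]
NumericMatrix cppPatchEval(NumericMatrix V, NumericMatrix N, IntegerMatrix F,
                           IntegerMatrix EV, IntegerMatrix FE, int face,
                           NumericMatrix bary, double svdTol) {
  NumericMatrix C = cppAllEdgeCoefficients(V, N, EV, svdTol);
  int f = face - 1;
  EdgeCoef cA, cB, cC;
  faceCoefs(F, EV, FE, C, f, cA, cB, cC);
  V3 x0 = rowV3(V, F(f, 0) - 1), x1 = rowV3(V, F(f, 1) - 1), x2 = rowV3(V, F(f, 2) - 1);
  NumericMatrix out(bary.nrow(), 3);
  for (int i = 0; i < bary.nrow(); ++i) {
    PatchEval pe = evalPatch(x0, x1, x2, cA, cB, cC, bary(i, 1), bary(i, 2));
    out(i, 0) = pe.P.x; out(i, 1) = pe.P.y; out(i, 2) = pe.P.z;
  }
  return out;
}

// Build edge topology from a triangle list. Returns EV (a<b), EF (two incident
// faces, 0 marks a boundary slot), FE (edge ids per face in order (v0v1),(v1v2),(v2v0)).
// [[Rcpp::export]]
List cppBuildTopology(IntegerMatrix F, int nv) {
  int nf = F.nrow();
  std::vector<std::vector<std::pair<int, int>>> bucket(nv);  // (other vertex, edge id)
  std::vector<int> ea, eb;
  std::vector<int> ef1, ef2;
  IntegerMatrix FE(nf, 3);
  auto findEdge = [&](int a, int b) -> int {
    int lo = std::min(a, b), hi = std::max(a, b);
    for (auto& pr : bucket[lo])
      if (pr.first == hi) return pr.second;
    return -1;
  };
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int a = F(f, k) - 1, b = F(f, (k + 1) % 3) - 1;
      if (a == b) stop("degenerate face with repeated vertex");
      int e = findEdge(a, b);
      if (e < 0) {
        e = (int)ea.size();
        int lo = std::min(a, b), hi = std::max(a, b);
        ea.push_back(lo); eb.push_back(hi);
        ef1.push_back(f); ef2.push_back(-1);
        bucket[lo].push_back({hi, e});
      } else {
        if (ef2[e] != -1) stop("non-manifold edge (more than two incident faces)");
        ef2[e] = f;
      }
      FE(f, k) = e + 1;
    }
  }
  int ne = (int)ea.size();
  IntegerMatrix EV(ne, 2), EF(ne, 2);
  for (int e = 0; e < ne; ++e) {
    EV(e, 0) = ea[e] + 1; EV(e, 1) = eb[e] + 1;
    EF(e, 0) = ef1[e] + 1; EF(e, 1) = ef2[e] + 1;  // 0 if boundary
  }
  return List::create(_["EV"] = EV, _["EF"] = EF, _["FE"] = FE);
}
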