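#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Constant-strain tetrahedron (TET4) machinery for isotropic linear
// elasticity. Shape-function gradients g_i are constant per element; the
// element stiffness in compact form is
//   K[3i+p, 3j+q] = V * ( lambda g_i[p] g_j[q] + mu g_i[q] g_j[p]
//                         + mu delta_pq (g_i . g_j) )

static double tet_grads(const double* X /*4x3 row-major*/, double g[4][3]) {
  // Jacobian columns: x2-x1, x3-x1, x4-x1
  double J[3][3];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      J[r][c] = X[3 * (c + 1) + r] - X[r];
  double det =
      J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
      J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
      J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  double inv[3][3];
  double id = 1.0 / det;
  inv[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
  inv[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]) * id;
  inv[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
  inv[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]) * id;
  inv[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
  inv[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]) * id;
  inv[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
  inv[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]) * id;
  inv[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
  // grad N_{j+1} = row j of inv^T = column j of inv
  for (int j = 0; j < 3; ++j)
    for (int p = 0; p < 3; ++p)
      g[j + 1][p] = inv[j][p];
  for (int p = 0; p < 3; ++p)
    g[0][p] = -(g[1][p] + g[2][p] + g[3][p]);
  return det / 6.0;  // signed volume
}

// [[Rcpp::export]]
List cpp_fem_assemble(NumericMatrix nodes, IntegerMatrix elems,
                      NumericVector E, NumericVector nu) {
  const int m = elems.nrow();
  const R_xlen_t ntrip = (R_xlen_t)m * 144;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tx(ntrip);
  NumericVector vols(m);
  double X[12];
  double g[4][3];
  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a);
      X[3 * a + 0] = nodes(nd, 0);
      X[3 * a + 1] = nodes(nd, 1);
      X[3 * a + 2] = nodes(nd, 2);
    }
    double V = tet_grads(X, g);
    vols[e] = V;
    if (V <= 0) stop("element %d has non-positive volume", e + 1);
    double lam = E[e] * nu[e] / ((1 + nu[e]) * (1 - 2 * nu[e]));
    double mu = E[e] / (2 * (1 + nu[e]));
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double dot = g[a][0] * g[b][0] + g[a][1] * g[b][1] + g[a][2] * g[b][2];
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q) {
            double kk = lam * g[a][p] * g[b][q] + mu * g[a][q] * g[b][p];
            if (p == q) kk += mu * dot;
            ti[pos] = 3 * elems(e, a) + p;
            tj[pos] = 3 * elems(e, b) + q;
            tx[pos] = V * kk;
            ++pos;
          }
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx, _["vol"] = vols);
}

// Per-element stress from nodal displacements u (length 3n, node-major).
// Returns m x 6 matrix: sxx syy szz sxy syz szx.
// [[Rcpp::export]]
NumericMatrix cpp_fem_stress(NumericMatrix nodes, IntegerMatrix elems,
                             NumericVector E, NumericVector nu,
                             NumericVector u) {
  const int m = elems.nrow();
  NumericMatrix S(m, 6);
  double X[12];
  double g[4][3];
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a);
      X[3 * a + 0] = nodes(nd, 0);
      X[3 * a + 1] = nodes(nd, 1);
      X[3 * a + 2] = nodes(nd, 2);
    }
    tet_grads(X, g);
    double eps[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a);
      for (int p = 0; p < 3; ++p)
        for (int q = 0; q < 3; ++q)
          eps[p][q] += 0.5 * (g[a][p] * u[3 * nd + q] + g[a][q] * u[3 * nd + p]);
    }
    double lam = E[e] * nu[e] / ((1 + nu[e]) * (1 - 2 * nu[e]));
    double mu = E[e] / (2 * (1 + nu[e]));
    double tr = eps[0][0] + eps[1][1] + eps[2][2];
    S(e, 0) = lam * tr + 2 * mu * eps[0][0];
    S(e, 1) = lam * tr + 2 * mu * eps[1][1];
    S(e, 2) = lam * tr + 2 * mu * eps[2][2];
    S(e, 3) = 2 * mu * eps[0][1];
    S(e, 4) = 2 * mu * eps[1][2];
    S(e, 5) = 2 * mu * eps[2][0];
  }
  return S;
}
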