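#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Matrix-free linear-elastic solver on a regular voxel grid of 8-node
// trilinear hexahedra. Every element shares one reference stiffness
// matrix ke (24 x 24, unit modulus, unit edge); the per-element modulus
// and the edge length scale it (K_e = E_e * h * ke). The global system is
// solved with Jacobi-preconditioned conjugate gradients; Dirichlet
// constraints are imposed by projection (constrained rows/columns removed
// from the operator, prescribed values moved to the right-hand side).

// Local node order (bit pattern gives offsets):
// (0,0,0)(1,0,0)(1,1,0)(0,1,0)(0,0,1)(1,0,1)(1,1,1)(0,1,1)
static const int NODE_OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

struct Grid {
  int ex, ey, ez;      // element counts
  int nnx, nny, nnz;   // node counts
  int64_t nnode, ndof;
};

static inline int64_t node_lin(const Grid &g, int i, int j, int k) {
  return static_cast<int64_t>(i) +
         static_cast<int64_t>(j) * g.nnx +
         static_cast<int64_t>(k) * g.nnx * static_cast<int64_t>(g.nny);
}

static void gather_dofs(const Grid &g, int ei, int ej, int ek, int64_t *dofs) {
  for (int a = 0; a < 8; ++a) {
    int64_t nl = node_lin(g, ei + NODE_OFF[a][0], ej + NODE_OFF[a][1],
                          ek + NODE_OFF[a][2]);
    dofs[3 * a] = 3 * nl;
    dofs[3 * a + 1] = 3 * nl + 1;
    dofs[3 * a + 2] = 3 * nl + 2;
  }
}

// y = K x over all elements (no constraint handling).
static void matvec_full(const Grid &g, const double *E, const double *ke,
                        double scale, const double *x, double *y) {
  std::fill(y, y + g.ndof, 0.0);
  double ue[24], fe[24];
  int64_t dofs[24];
  int64_t e = 0;
  for (int ek = 0; ek < g.ez; ++ek)
    for (int ej = 0; ej < g.ey; ++ej)
      for (int ei = 0; ei < g.ex; ++ei, ++e) {
        const double Ee = E[e] * scale;
        if (Ee == 0.0) continue;
        gather_dofs(g, ei, ej, ek, dofs);
        for (int a = 0; a < 24; ++a) ue[a] = x[dofs[a]];
        for (int a = 0; a < 24; ++a) {
          const double *row = ke + 24 * a;
          double acc = 0;
          for (int b = 0; b < 24; ++b) acc += row[b] * ue[b];
          fe[a] = Ee * acc;
        }
        for (int a = 0; a < 24; ++a) y[dofs[a]] += fe[a];
      }
}

// [[Rcpp::export(name = ".cpp_hex_solve")]]
List cpp_hex_solve(IntegerVector edims, NumericVector Evox,
                   NumericMatrix ke, double h,
                   LogicalVector fixed, NumericVector u0,
                   double tol, int maxit) {
  Grid g;
  g.ex = edims[0]; g.ey = edims[1]; g.ez = edims[2];
  g.nnx = g.ex + 1; g.nny = g.ey + 1; g.nnz = g.ez + 1;
  g.nnode = static_cast<int64_t>(g.nnx) * g.nny * g.nnz;
  g.ndof = 3 * g.nnode;

  std::vector<double> kev(24 * 24);
  for (int a = 0; a < 24; ++a)
    for (int b = 0; b < 24; ++b) kev[24 * a + b] = ke(a, b);

  const double *E = REAL(Evox);
  std::vector<double> x(g.ndof), b(g.ndof), r(g.ndof), z(g.ndof),
      p(g.ndof), Ap(g.ndof), diag(g.ndof, 0.0);

  // Jacobi diagonal.
  {
    int64_t dofs[24];
    int64_t e = 0;
    for (int ek = 0; ek < g.ez; ++ek)
      for (int ej = 0; ej < g.ey; ++ej)
        for (int ei = 0; ei < g.ex; ++ei, ++e) {
          const double Ee = E[e] * h;
          if (Ee == 0.0) continue;
          gather_dofs(g, ei, ej, ek, dofs);
          for (int a = 0; a < 24; ++a) diag[dofs[a]] += Ee * kev[24 * a + a];
        }
    for (int64_t i = 0; i < g.ndof; ++i)
      if (fixed[i] || diag[i] <= 0) diag[i] = 1.0;
  }

  // RHS: b = -K u0, projected to free dofs.
  std::vector<double> u0v(u0.begin(), u0.end());
  matvec_full(g, E, kev.data(), h, u0v.data(), b.data());
  for (int64_t i = 0; i < g.ndof; ++i) b[i] = fixed[i] ? 0.0 : -b[i];

  double bnorm = 0;
  for (int64_t i = 0; i < g.ndof; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);

  std::fill(x.begin(), x.end(), 0.0);
  double relres = 0;
  int it = 0;
  bool converged = true;
  if (bnorm > 0) {
    converged = false;
    std::copy(b.begin(), b.end(), r.begin());
    for (int64_t i = 0; i < g.ndof; ++i) z[i] = r[i] / diag[i];
    std::copy(z.begin(), z.end(), p.begin());
    double rz = 0;
    for (int64_t i = 0; i < g.ndof; ++i) rz += r[i] * z[i];
    for (it = 1; it <= maxit; ++it) {
      matvec_full(g, E, kev.data(), h, p.data(), Ap.data());
      for (int64_t i = 0; i < g.ndof; ++i) if (fixed[i]) Ap[i] = 0.0;
      double pAp = 0;
      for (int64_t i = 0; i < g.ndof; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0) break;
      const double alpha = rz / pAp;
      double rnorm = 0;
      for (int64_t i = 0; i < g.ndof; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm += r[i] * r[i];
      }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres < tol) { converged = true; break; }
      double rznew = 0;
      for (int64_t i = 0; i < g.ndof; ++i) {
        z[i] = r[i] / diag[i];
        rznew += r[i] * z[i];
      }
      const double beta = rznew / rz;
      rz = rznew;
      for (int64_t i = 0; i < g.ndof; ++i) p[i] = z[i] + beta * p[i];
    }
  }

  NumericVector u(g.ndof);
  for (int64_t i = 0; i < g.ndof; ++i) u[i] = x[i] + u0v[i];
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["relres"] = relres, _["converged"] = converged);
}

// Internal nodal force vector f = K u (full operator, no constraints):
// used for reaction-force extraction on constrained faces.
// [[Rcpp::export(name = ".cpp_hex_forces")]]
NumericVector cpp_hex_forces(IntegerVector edims, NumericVector Evox,
                             NumericMatrix ke, double h, NumericVector u) {
  Grid g;
  g.ex = edims[0]; g.ey = edims[1]; g.ez = edims[2];
  g.nnx = g.ex + 1; g.nny = g.ey + 1; g.nnz = g.ez + 1;
  g.nnode = static_cast<int64_t>(g.nnx) * g.nny * g.nnz;
  g.ndof = 3 * g.nnode;
  std::vector<double> kev(24 * 24);
  for (int a = 0; a < 24; ++a)
    for (int b = 0; b < 24; ++b) kev[24 * a + b] = ke(a, b);
  NumericVector f(g.ndof);
  std::vector<double> uv(u.begin(), u.end()), fv(g.ndof);
  matvec_full(g, REAL(Evox), kev.data(), h, uv.data(), fv.data());
  std::copy(fv.begin(), fv.end(), f.begin());
  return f;
}

// Element-centroid strains: eps = Bc * u_e for every element, with Bc the
// 6 x 24 strain-displacement matrix at the element center (physical
// units). Returns a 6 x nelem matrix.
// [[Rcpp::export(name = ".cpp_hex_strains")]]
NumericMatrix cpp_hex_strains(IntegerVector edims, NumericMatrix Bc,
                              NumericVector u) {
  Grid g;
  g.ex = edims[0]; g.ey = edims[1]; g.ez = edims[2];
  g.nnx = g.ex + 1; g.nny = g.ey + 1; g.nnz = g.ez + 1;
  g.nnode = static_cast<int64_t>(g.nnx) * g.nny * g.nnz;
  g.ndof = 3 * g.nnode;
  const int64_t nel = static_cast<int64_t>(g.ex) * g.ey * g.ez;
  NumericMatrix eps(6, nel);
  double ue[24];
  int64_t dofs[24];
  int64_t e = 0;
  for (int ek = 0; ek < g.ez; ++ek)
    for (int ej = 0; ej < g.ey; ++ej)
      for (int ei = 0; ei < g.ex; ++ei, ++e) {
        gather_dofs(g, ei, ej, ek, dofs);
        for (int a = 0; a < 24; ++a) ue[a] = u[dofs[a]];
        for (int c = 0; c < 6; ++c) {
          double acc = 0;
          for (int a = 0; a < 24; ++a) acc += Bc(c, a) * ue[a];
          eps(c, e) = acc;
        }
      }
  return eps;
}
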