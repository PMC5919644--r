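#include <Rcpp.h>
using namespace Rcpp;

// Steady state of D * lap(p) = Mmax * s * p / (p + km) on a periodic n x n
// grid with Dirichlet vessel pixels clamped at p0. Red-black SOR with the
// Michaelis-Menten sink linearized about the current iterate, which keeps
// the local update positive and the field within [0, p0].
//
// field: initial guess, modified in place semantics avoided (cloned).
// vessel: 1 where the pixel lies inside a vessel disk.
// Returns the converged field; attribute "iterations" and "residual".
// [[Rcpp::export]]
NumericMatrix solvePO2SOR(NumericMatrix field, IntegerMatrix vessel,
                          double h, double diffusivity, double consumption,
                          double km, double p0,
                          int maxIter, double tol, double omega) {
  int n = field.nrow();
  NumericMatrix p = clone(field);
  double c0 = consumption * h * h / diffusivity; // sink scale per pixel
  double maxd = 0.0;
  int iter = 0;
  for (iter = 0; iter < maxIter; ++iter) {
    maxd = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int j = 0; j < n; ++j) {
        int jm = (j == 0) ? n - 1 : j - 1;
        int jp = (j == n - 1) ? 0 : j + 1;
        for (int i = 0; i < n; ++i) {
          if (((i + j) & 1) != color) continue;
          if (vessel(i, j)) { p(i, j) = p0; continue; }
          int im = (i == 0) ? n - 1 : i - 1;
          int ip = (i == n - 1) ? 0 : i + 1;
          double nb = p(im, j) + p(ip, j) + p(i, jm) + p(i, jp);
          double pij = p(i, j);
          double denom = 4.0 + c0 / (pij + km);
          double pnew = nb / denom;
          pnew = pij + omega * (pnew - pij);
          if (pnew < 0.0) pnew = 0.0;
          if (pnew > p0) pnew = p0;
          double d = fabs(pnew - pij);
          if (d > maxd) maxd = d;
          p(i, j) = pnew;
        }
      }
    }
    if (maxd < tol) break;
  }
  p.attr("iterations") = iter + 1;
  p.attr("residual") = maxd;
  return p;
}
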