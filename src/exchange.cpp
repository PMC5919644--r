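#include <Rcpp.h>
using namespace Rcpp;

// Conservative cell exchange between face neighbors, two phases.
//
// Push: voxels with occupancy above capacity K push their mobile excess
// (viable + dead, proportional composition) to neighbors in proportion to
// the neighbors' free space; if no neighbor has free space the excess is
// split equally among in-lattice neighbors.
//
// Pull (cohesive compaction): tumor voxels (viable + dead > eps) below
// capacity absorb pullRate * deficit per call from neighboring tumor
// voxels that are strictly less occupied, drawing viable, dead and
// capillary cells in the donor's proportions; a donor never gives more
// than half its tissue.
//
// nb: n x 6 matrix of 1-based neighbor indices, 0 = outside the lattice.
// [[Rcpp::export]]
List exchangeKernel(NumericVector viable, NumericVector dead,
                    NumericVector capillary, IntegerMatrix nb,
                    double K, double pullRate) {
  const double eps = 1e-12, tumorEps = 1e-9;
  int n = viable.size();
  NumericVector vv = clone(viable), dd_ = clone(dead), cc = clone(capillary);
  double *v = REAL(vv), *d = REAL(dd_), *c = REAL(cc);
  const int *nbp = INTEGER(nb);   // column-major: neighbor k of i at nbp[k*n+i]

  // ---- push ---------------------------------------------------------------
  {
    std::vector<double> occ(n), deficit(n);
    for (int i = 0; i < n; ++i) {
      occ[i] = v[i] + d[i] + c[i];
      deficit[i] = occ[i] < K ? K - occ[i] : 0.0;
    }
    std::vector<double> dv(n, 0.0), dd(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double mob = v[i] + d[i];
      double excess = occ[i] - K;
      if (excess <= eps || mob <= 0) continue;
      if (excess > mob) excess = mob;
      double w[6], ws = 0.0;
      int inLat = 0;
      for (int k = 0; k < 6; ++k) {
        int t = nbp[k * n + i];
        w[k] = (t > 0) ? deficit[t - 1] : 0.0;
        ws += w[k];
        if (t > 0) ++inLat;
      }
      if (ws <= eps) {               // neighbors all full: split equally
        for (int k = 0; k < 6; ++k) w[k] = nbp[k * n + i] > 0 ? 1.0 : 0.0;
        ws = inLat;
      }
      double vfrac = v[i] / mob;
      for (int k = 0; k < 6; ++k) {
        int t = nbp[k * n + i];
        if (t <= 0 || w[k] <= 0) continue;
        double amt = excess * w[k] / ws;
        dv[t - 1] += amt * vfrac;
        dd[t - 1] += amt * (1.0 - vfrac);
      }
      double keep = 1.0 - excess / mob;
      dv[i] += v[i] * keep - v[i];
      dd[i] += d[i] * keep - d[i];
    }
    for (int i = 0; i < n; ++i) { v[i] += dv[i]; d[i] += dd[i]; }
  }

  // ---- pull: compaction up the occupancy gradient -------------------------
  {
    std::vector<double> occ(n), tis(n);
    for (int i = 0; i < n; ++i) {
      occ[i] = v[i] + d[i] + c[i];
      tis[i] = occ[i];
    }
    // requested flow recipient i <- neighbor k, then donor capping
    std::vector<double> req(n * 6, 0.0), asked(n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (v[i] + d[i] <= tumorEps) continue;
      double deficit = K - occ[i];
      if (deficit <= eps) continue;
      double w[6], ws = 0.0;
      for (int k = 0; k < 6; ++k) {
        w[k] = 0.0;
        int t = nbp[k * n + i];
        if (t <= 0) continue;
        int j = t - 1;
        if (v[j] + d[j] <= tumorEps) continue;   // host tissue stays put
        if (occ[j] >= occ[i]) continue;          // strictly up-gradient
        w[k] = tis[j] / 2.0;
        ws += w[k];
      }
      if (ws <= eps) continue;
      double want = pullRate * deficit;
      if (want > ws) want = ws;
      double scale = want / ws;
      for (int k = 0; k < 6; ++k) {
        if (w[k] <= 0) continue;
        double r = w[k] * scale;
        req[i * 6 + k] = r;
        asked[nbp[k * n + i] - 1] += r;
      }
    }
    std::vector<double> dv(n, 0.0), dd(n, 0.0), dc(n, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 6; ++k) {
        double r = req[i * 6 + k];
        if (r <= 0) continue;
        int j = nbp[k * n + i] - 1;
        double cap = tis[j] / 2.0;
        double scale = asked[j] > cap ? cap / asked[j] : 1.0;
        double amt = r * scale;
        if (tis[j] <= 0) continue;
        double fv = v[j] / tis[j], fd = d[j] / tis[j], fc = c[j] / tis[j];
        dv[i] += amt * fv; dv[j] -= amt * fv;
        dd[i] += amt * fd; dd[j] -= amt * fd;
        dc[i] += amt * fc; dc[j] -= amt * fc;
      }
    }
    for (int i = 0; i < n; ++i) {
      v[i] += dv[i]; if (v[i] < 0) v[i] = 0;
      d[i] += dd[i]; if (d[i] < 0) d[i] = 0;
      c[i] += dc[i]; if (c[i] < 0) c[i] = 0;
    }
  }

  return List::create(_["viable"] = vv, _["dead"] = dd_, _["capillary"] = cc);
}
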