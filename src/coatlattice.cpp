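#include <Rcpp.h>
using namespace Rcpp;

// Rotation-minimizing frames by the double-reflection method.
// tangents: n x 3 unit tangents at consecutive points pts (n x 3),
// n0: initial unit normal orthogonal to tangents(0,_).
// Returns n x 3 transported normals.
// [[Rcpp::export(name = ".pt_frames")]]
NumericMatrix pt_frames(NumericMatrix pts, NumericMatrix tangents,
                        NumericVector n0) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double x[3] = {n0[0], n0[1], n0[2]};
  for (int k = 0; k < 3; ++k) out(0, k) = x[k];
  for (int i = 0; i + 1 < n; ++i) {
    double v1[3], tL[3], xL[3], v2[3];
    double c1 = 0.0;
    for (int k = 0; k < 3; ++k) {
      v1[k] = pts(i + 1, k) - pts(i, k);
      c1 += v1[k] * v1[k];
    }
    if (c1 < 1e-30) {
      for (int k = 0; k < 3; ++k) out(i + 1, k) = x[k];
      continue;
    }
    double d1x = 0.0, d1t = 0.0;
    for (int k = 0; k < 3; ++k) d1x += v1[k] * x[k];
    for (int k = 0; k < 3; ++k) d1t += v1[k] * tangents(i, k);
    for (int k = 0; k < 3; ++k) {
      xL[k] = x[k] - (2.0 / c1) * d1x * v1[k];
      tL[k] = tangents(i, k) - (2.0 / c1) * d1t * v1[k];
    }
    double c2 = 0.0, d2x = 0.0;
    for (int k = 0; k < 3; ++k) {
      v2[k] = tangents(i + 1, k) - tL[k];
      c2 += v2[k] * v2[k];
    }
    if (c2 < 1e-30) {
      for (int k = 0; k < 3; ++k) x[k] = xL[k];
    } else {
      for (int k = 0; k < 3; ++k) d2x += v2[k] * xL[k];
      for (int k = 0; k < 3; ++k) x[k] = xL[k] - (2.0 / c2) * d2x * v2[k];
    }
    // re-orthogonalise against the tangent to stop drift
    double dt = 0.0, nrm = 0.0;
    for (int k = 0; k < 3; ++k) dt += x[k] * tangents(i + 1, k);
    for (int k = 0; k < 3; ++k) x[k] -= dt * tangents(i + 1, k);
    for (int k = 0; k < 3; ++k) nrm += x[k] * x[k];
    nrm = std::sqrt(nrm);
    for (int k = 0; k < 3; ++k) {
      x[k] /= nrm;
      out(i + 1, k) = x[k];
    }
  }
  return out;
}

// Greedy best-first suppression: rows of pos are already sorted by
// decreasing priority (cc, ties broken upstream). A row is accepted iff no
// previously accepted row lies within `range`. Returns a logical vector in
// the given row order.
// [[Rcpp::export(name = ".greedy_suppress")]]
LogicalVector greedy_suppress(NumericMatrix pos, double range) {
  int n = pos.nrow();
  LogicalVector keep(n);
  std::vector<int> acc;
  acc.reserve(n);
  double r2 = range * range;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t j = 0; j < acc.size(); ++j) {
      int a = acc[j];
      double dx = pos(i, 0) - pos(a, 0);
      double dy = pos(i, 1) - pos(a, 1);
      double dz = pos(i, 2) - pos(a, 2);
      if (dx * dx + dy * dy + dz * dz < r2) { ok = false; break; }
    }
    keep[i] = ok;
    if (ok) acc.push_back(i);
  }
  return keep;
}
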