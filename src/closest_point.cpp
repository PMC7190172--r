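#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Closest point on triangle (a, b, c) to p, via barycentric region tests
// (Ericson, Real-Time Collision Detection, ch. 5). Exact for interior,
// edge and vertex regions; no tolerance games.
static inline void closest_on_triangle(const double *p,
                                       const double *a, const double *b,
                                       const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Exact nearest point on a triangle mesh for each query point.
// Pruning: per-triangle bounding sphere (centroid + circumscribed radius)
// gives a lower bound on the attainable distance; a vertex scan gives an
// initial upper bound. Lossless -- every triangle whose bound beats the
// incumbent is tested exactly.
// [[Rcpp::export]]
List cpp_nearest_on_mesh(NumericMatrix points, NumericMatrix vertices,
                         IntegerMatrix triangles) {
  const int k = points.nrow();
  const int nv = vertices.nrow();
  const int m = triangles.nrow();
  if (m == 0 || nv == 0) stop("empty mesh");

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = vertices(i, 0);
    vy[i] = vertices(i, 1);
    vz[i] = vertices(i, 2);
  }
  std::vector<int> ia(m), ib(m), ic(m);
  std::vector<double> cx(m), cy(m), cz(m), rad(m), rad2(m);
  for (int t = 0; t < m; ++t) {
    int a = triangles(t, 0), b = triangles(t, 1), c = triangles(t, 2);
    if (a < 0 || b < 0 || c < 0 || a >= nv || b >= nv || c >= nv)
      stop("triangle index out of range");
    ia[t] = a; ib[t] = b; ic[t] = c;
    double gx = (vx[a] + vx[b] + vx[c]) / 3.0;
    double gy = (vy[a] + vy[b] + vy[c]) / 3.0;
    double gz = (vz[a] + vz[b] + vz[c]) / 3.0;
    cx[t] = gx; cy[t] = gy; cz[t] = gz;
    double r2 = 0.0;
    const int idx[3] = {a, b, c};
    for (int j = 0; j < 3; ++j) {
      double dx = vx[idx[j]] - gx, dy = vy[idx[j]] - gy, dz = vz[idx[j]] - gz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
    rad2[t] = r2;
  }

  NumericVector dist(k);
  NumericMatrix closest(k, 3);
  double q[3], cand[3], va[3], vb[3], vcc[3];

  for (int i = 0; i < k; ++i) {
    q[0] = points(i, 0); q[1] = points(i, 1); q[2] = points(i, 2);

    // incumbent: nearest mesh vertex (always an attainable surface point)
    double best2 = R_PosInf;
    int bestv = 0;
    for (int v = 0; v < nv; ++v) {
      double dx = vx[v] - q[0], dy = vy[v] - q[1], dz = vz[v] - q[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2) { best2 = d2; bestv = v; }
    }
    double best = std::sqrt(best2);
    double bx = vx[bestv], by = vy[bestv], bz = vz[bestv];

    for (int t = 0; t < m; ++t) {
      double dx = cx[t] - q[0], dy = cy[t] - q[1], dz = cz[t] - q[2];
      double d2c = dx * dx + dy * dy + dz * dz;
      // sqrt-free lossless prune: triangle can beat `best` only if the
      // centroid distance is below best + rad, i.e. d2c < (best + rad)^2
      if (d2c >= best * best + 2.0 * best * rad[t] + rad2[t]) continue;
      va[0] = vx[ia[t]]; va[1] = vy[ia[t]]; va[2] = vz[ia[t]];
      vb[0] = vx[ib[t]]; vb[1] = vy[ib[t]]; vb[2] = vz[ib[t]];
      vcc[0] = vx[ic[t]]; vcc[1] = vy[ic[t]]; vcc[2] = vz[ic[t]];
      closest_on_triangle(q, va, vb, vcc, cand);
      double ex = cand[0] - q[0], ey = cand[1] - q[1], ez = cand[2] - q[2];
      double d = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (d < best) {
        best = d;
        bx = cand[0]; by = cand[1]; bz = cand[2];
      }
    }
    dist[i] = best;
    closest(i, 0) = bx; closest(i, 1) = by; closest(i, 2) = bz;
  }
  return List::create(_["distances"] = dist, _["closest"] = closest);
}
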