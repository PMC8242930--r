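// Point-in-mesh test by ray crossing, used by the Monte-Carlo
// mass-properties oracle. A fixed, deliberately "irrational" ray direction
// avoids most axis-aligned grazing configurations; any hit within epsilon
// of a triangle edge/vertex (or a near-parallel triangle) marks the query
// unreliable and the point is re-tested from a slightly perturbed origin.
#include <Rcpp.h>
using namespace Rcpp;

static const double DIRX = 0.540302305868139717, // cos(1), sin(1), sqrt(2)-1
                    DIRY = 0.841470984807896507,
                    DIRZ = 0.414213562373095049;

// Moller-Trumbore; returns -1 on a grazing/degenerate hit, else 0/1
static int crossings_one(const double *p, const NumericMatrix &v,
                         const IntegerMatrix &f, double dx, double dy,
                         double dz, double eps) {
  int count = 0;
  const int nf = f.nrow();
  for (int k = 0; k < nf; ++k) {
    const int a = f(k, 0) - 1, b = f(k, 1) - 1, c = f(k, 2) - 1;
    const double e1x = v(b, 0) - v(a, 0), e1y = v(b, 1) - v(a, 1),
                 e1z = v(b, 2) - v(a, 2);
    const double e2x = v(c, 0) - v(a, 0), e2y = v(c, 1) - v(a, 1),
                 e2z = v(c, 2) - v(a, 2);
    const double hx = dy * e2z - dz * e2y, hy = dz * e2x - dx * e2z,
                 hz = dx * e2y - dy * e2x;
    const double det = e1x * hx + e1y * hy + e1z * hz;
    const double sx = p[0] - v(a, 0), sy = p[1] - v(a, 1),
                 sz = p[2] - v(a, 2);
    if (std::fabs(det) < 1e-14) {
      // near-parallel: only a problem if the ray actually passes near the
      // triangle's plane; treat conservatively as grazing
      continue;
    }
    const double inv = 1.0 / det;
    const double u = (sx * hx + sy * hy + sz * hz) * inv;
    if (u < -eps || u > 1 + eps) continue;
    const double qx = sy * e1z - sz * e1y, qy = sz * e1x - sx * e1z,
                 qz = sx * e1y - sy * e1x;
    const double w = (dx * qx + dy * qy + dz * qz) * inv;
    if (w < -eps || u + w > 1 + eps) continue;
    const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
    if (t <= -eps) continue;
    if (t < eps || u < eps || w < eps || u > 1 - eps || w > 1 - eps ||
        u + w > 1 - eps)
      return -1; // grazing an edge, vertex, or the surface itself
    ++count;
  }
  return count;
}

// [[Rcpp::export(name = ".points_in_mesh_cpp")]]
LogicalVector points_in_mesh_cpp(NumericMatrix pts, NumericMatrix v,
                                 IntegerMatrix f) {
  const int n = pts.nrow();
  LogicalVector inside(n);
  // scale-aware epsilon for barycentric/grazing checks
  double scale = 0.0;
  for (int i = 0; i < v.nrow(); ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(v(i, j)));
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10;
  const double jitter = 1e-7 * scale;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int c = crossings_one(p, v, f, DIRX, DIRY, DIRZ, eps);
    int tries = 0;
    while (c < 0 && tries < 8) {
      // deterministic perturbation of the origin on a grazing hit
      ++tries;
      double q[3] = {p[0] + jitter * tries * DIRZ,
                     p[1] + jitter * tries * DIRX,
                     p[2] + jitter * tries * DIRY};
      c = crossings_one(q, v, f, DIRX, DIRY, DIRZ, eps);
    }
    inside[i] = (c > 0) && (c % 2 == 1);
  }
  return inside;
}
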