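#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First intersection of each ray with a triangle mesh (Moller-Trumbore).
// Triangle data (base vertex + edge vectors) is flattened and precomputed
// once, and triangles are bucketed along a pruning axis so each ray only
// tests triangles whose axial span overlaps its own axial position
// (in-plane rays stay near their own MPR slice).
//
// V: n x 3 vertices, F: m x 3 1-based faces, O/D: k x 3 ray origins and
// unit directions, axis: pruning axis (unit), slack: axial half-window (mm),
// tmax: maximum hit distance. Returns hit distance per ray, or NA on miss.
// [[Rcpp::export]]
NumericVector cpp_ray_mesh_first_hit(NumericMatrix V, IntegerMatrix F,
                                     NumericMatrix O, NumericMatrix D,
                                     NumericVector axis, double slack,
                                     double tmax) {
  const int nf = F.nrow(), nr = O.nrow(), nv = V.nrow();
  const double ax = axis[0], ay = axis[1], az = axis[2];

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  // per-triangle: base vertex p0 and edges e1 = p1-p0, e2 = p2-p0
  std::vector<double> T(9 * (size_t)nf);
  std::vector<double> smin(nf), smax(nf);
  double lo = R_PosInf, hi = R_NegInf;
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double *t = &T[9 * (size_t)f];
    t[0] = vx[i0]; t[1] = vy[i0]; t[2] = vz[i0];
    t[3] = vx[i1] - vx[i0]; t[4] = vy[i1] - vy[i0]; t[5] = vz[i1] - vz[i0];
    t[6] = vx[i2] - vx[i0]; t[7] = vy[i2] - vy[i0]; t[8] = vz[i2] - vz[i0];
    double s0 = vx[i0] * ax + vy[i0] * ay + vz[i0] * az;
    double s1 = vx[i1] * ax + vy[i1] * ay + vz[i1] * az;
    double s2 = vx[i2] * ax + vy[i2] * ay + vz[i2] * az;
    double mn = std::min(s0, std::min(s1, s2));
    double mx = std::max(s0, std::max(s1, s2));
    smin[f] = mn; smax[f] = mx;
    if (mn < lo) lo = mn;
    if (mx > hi) hi = mx;
  }
  const double binw = 2.0;
  int nbins = std::max(1, (int)std::ceil((hi - lo) / binw) + 1);
  std::vector< std::vector<int> > bins(nbins);
  for (int f = 0; f < nf; ++f) {
    int b0 = std::max(0, (int)std::floor((smin[f] - lo) / binw));
    int b1 = std::min(nbins - 1, (int)std::floor((smax[f] - lo) / binw));
    for (int b = b0; b <= b1; ++b) bins[b].push_back(f);
  }

  NumericVector out(nr, NA_REAL);
  const double eps = 1e-9;
  for (int r = 0; r < nr; ++r) {
    const double ox = O(r, 0), oy = O(r, 1), oz = O(r, 2);
    const double dx = D(r, 0), dy = D(r, 1), dz = D(r, 2);
    double s0 = ox * ax + oy * ay + oz * az;
    int b0 = std::max(0, (int)std::floor((s0 - slack - lo) / binw));
    int b1 = std::min(nbins - 1, (int)std::floor((s0 + slack - lo) / binw));
    if (b1 < 0 || b0 > nbins - 1) continue;
    double best = tmax;
    bool found = false;
    for (int b = b0; b <= b1; ++b) {
      const std::vector<int>& lst = bins[b];
      const int nl = (int)lst.size();
      for (int q = 0; q < nl; ++q) {
        // a triangle spanning several bins may be tested more than once per
        // ray; the min-reduction makes the repeat harmless
        const double *t = &T[9 * (size_t)lst[q]];
        const double e1x = t[3], e1y = t[4], e1z = t[5];
        const double e2x = t[6], e2y = t[7], e2z = t[8];
        const double px = dy * e2z - dz * e2y;
        const double py = dz * e2x - dx * e2z;
        const double pz = dx * e2y - dy * e2x;
        const double det = e1x * px + e1y * py + e1z * pz;
        if (std::fabs(det) < 1e-12) continue;
        const double inv = 1.0 / det;
        const double tx = ox - t[0], ty = oy - t[1], tz = oz - t[2];
        const double u = (tx * px + ty * py + tz * pz) * inv;
        if (u < -1e-9 || u > 1 + 1e-9) continue;
        const double qx = ty * e1z - tz * e1y;
        const double qy = tz * e1x - tx * e1z;
        const double qz = tx * e1y - ty * e1x;
        const double v = (dx * qx + dy * qy + dz * qz) * inv;
        if (v < -1e-9 || u + v > 1 + 1e-9) continue;
        const double th = (e2x * qx + e2y * qy + e2z * qz) * inv;
        if (th > eps && th < best) { best = th; found = true; }
      }
    }
    if (found) out[r] = best;
  }
  return out;
}

// Index (1-based) of the nearest row of V for every row of P; brute force on
// flattened coordinates.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix V, NumericMatrix P) {
  const int nv = V.nrow(), np = P.nrow();
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int v = 0; v < nv; ++v) {
      const double dx = vx[v] - px, dy = vy[v] - py, dz = vz[v] - pz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = v; }
    }
    out[i] = bi + 1;
  }
  return out;
}
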