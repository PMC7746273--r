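#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, ch. 5.1.5).  Writes the closest point into out[3].
static inline void closest_point_triangle(const double *p, const double *a,
                                          const double *b, const double *c,
                                          double *out) {
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

// Signed distance from each query point to a triangle mesh.  Sign is taken
// from the face normal at the nearest point; when several faces are
// (numerically) equally near — the query projects onto a shared edge or
// vertex — their normals are summed, which is the angle-agnostic analogue of
// the pseudonormal test and is robust on smooth closed meshes.
// [[Rcpp::export]]
NumericVector cpp_mesh_sdf(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);

  // flatten faces: per-face vertex coordinates and unit normals
  std::vector<double> fa(3 * nf), fb(3 * nf), fc(3 * nf), fn(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double e1[3], e2[3], n[3];
    for (int i = 0; i < 3; ++i) {
      fa[3 * f + i] = V(ia, i);
      fb[3 * f + i] = V(ib, i);
      fc[3 * f + i] = V(ic, i);
      e1[i] = V(ib, i) - V(ia, i);
      e2[i] = V(ic, i) - V(ia, i);
    }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (nn < 1e-14) stop("degenerate triangle in mesh (face %d)", f + 1);
    for (int i = 0; i < 3; ++i) fn[3 * f + i] = n[i] / nn;
  }

  double cp[3], best_cp[3];
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {pts(ip, 0), pts(ip, 1), pts(ip, 2)};
    double best = R_PosInf;
    int best_f = -1;
    for (int f = 0; f < nf; ++f) {
      // cheap reject: distance to vertex a minus max edge span bound
      closest_point_triangle(p, &fa[3 * f], &fb[3 * f], &fc[3 * f], cp);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - cp[i];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        best_f = f;
        for (int i = 0; i < 3; ++i) best_cp[i] = cp[i];
      }
    }
    // second pass: sum normals of all faces within tolerance of the minimum
    double tol = best * 1e-9 + 1e-18;
    double nsum[3] = {0.0, 0.0, 0.0};
    for (int f = 0; f < nf; ++f) {
      closest_point_triangle(p, &fa[3 * f], &fb[3 * f], &fc[3 * f], cp);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - cp[i];
        d2 += d * d;
      }
      if (d2 <= best + tol) {
        for (int i = 0; i < 3; ++i) nsum[i] += fn[3 * f + i];
      }
    }
    double s = 0.0;
    for (int i = 0; i < 3; ++i) s += (p[i] - best_cp[i]) * nsum[i];
    // if the summed normals nearly cancel (e.g. a point equidistant from a
    // whole ring of faces), fall back to the nearest face's own normal
    if (std::fabs(s) < 1e-6 * std::sqrt(best))
      s = (p[0] - best_cp[0]) * fn[3 * best_f + 0] +
          (p[1] - best_cp[1]) * fn[3 * best_f + 1] +
          (p[2] - best_cp[2]) * fn[3 * best_f + 2];
    double d = std::sqrt(best);
    out[ip] = (s < 0.0) ? -d : d;
  }
  return out;
}
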