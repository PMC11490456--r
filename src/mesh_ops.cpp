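#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Ray-triangle intersection (Moller-Trumbore) and exact point-triangle
// distances (Ericson's closest-point-on-triangle). Faces are 1-based.

// [[Rcpp::export(name = ".ray_mesh_hits")]]
NumericVector ray_mesh_hits(NumericVector origin, NumericVector dir,
                            NumericMatrix V, IntegerMatrix F) {
  const double eps = 1e-12;
  std::vector<double> ts;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double e1x = V(b,0)-V(a,0), e1y = V(b,1)-V(a,1), e1z = V(b,2)-V(a,2);
    double e2x = V(c,0)-V(a,0), e2y = V(c,1)-V(a,1), e2z = V(c,2)-V(a,2);
    double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z, pz = dx*e2y - dy*e2x;
    double det = e1x*px + e1y*py + e1z*pz;
    if (std::fabs(det) < eps) continue;
    double inv = 1.0/det;
    double tx = ox - V(a,0), ty = oy - V(a,1), tz = oz - V(a,2);
    double u = (tx*px + ty*py + tz*pz) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z, qz = tx*e1y - ty*e1x;
    double v = (dx*qx + dy*qy + dz*qz) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
    double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
    ts.push_back(t);
  }
  std::sort(ts.begin(), ts.end());
  return wrap(ts);
}

namespace {
inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// squared distance from point p to triangle (a,b,c); Ericson, RTCD 5.1.5
double pt_tri_d2(const double *p, const double *a, const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k]=b[k]-a[k]; ac[k]=c[k]-a[k]; ap[k]=p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) {
    for (int k=0;k<3;++k) q[k]=a[k];
  } else {
    double bp[3];
    for (int k=0;k<3;++k) bp[k]=p[k]-b[k];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) {
      for (int k=0;k<3;++k) q[k]=b[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int k=0;k<3;++k) q[k]=a[k]+v*ab[k];
      } else {
        double cp[3];
        for (int k=0;k<3;++k) cp[k]=p[k]-c[k];
        double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) {
          for (int k=0;k<3;++k) q[k]=c[k];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int k=0;k<3;++k) q[k]=a[k]+w*ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k=0;k<3;++k) q[k]=b[k]+w*(c[k]-b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k=0;k<3;++k) q[k]=a[k]+v*ab[k]+w*ac[k];
            }
          }
        }
      }
    }
  }
  double dx=p[0]-q[0], dy=p[1]-q[1], dz=p[2]-q[2];
  return dx*dx+dy*dy+dz*dz;
}
} // namespace

// Distance from each query point to the mesh surface, brute force over
// triangles with a centroid+circumradius lower-bound prune.
// [[Rcpp::export(name = ".points_mesh_dist")]]
NumericVector points_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<double> tri(9 * nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    double *t = &tri[9*f];
    for (int k=0;k<3;++k) { t[k]=V(a,k); t[3+k]=V(b,k); t[6+k]=V(c,k); }
    cx[f]=(t[0]+t[3]+t[6])/3.0; cy[f]=(t[1]+t[4]+t[7])/3.0; cz[f]=(t[2]+t[5]+t[8])/3.0;
    double r2 = 0;
    for (int v=0; v<3; ++v) {
      double dx=t[3*v]-cx[f], dy=t[3*v+1]-cy[f], dz=t[3*v+2]-cz[f];
      double d2=dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f]=std::sqrt(r2);
  }
  NumericVector out(np);
  double best = R_PosInf; // warm start across points (spatial coherence)
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dx=p[0]-cx[f], dy=p[1]-cy[f], dz=p[2]-cz[f];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - rad[f];
      if (dc*dc >= best && dc > 0) continue;
      double d2 = pt_tri_d2(p, &tri[9*f], &tri[9*f+3], &tri[9*f+6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
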