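#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Marching-tetrahedra isosurface extraction with linear edge interpolation.
// Each grid cell is split into six tetrahedra sharing the 0-6 diagonal, so
// the surface is watertight across cell faces and vertices land sub-voxel
// on the level crossing. Triangles are oriented with outward normals
// (pointing from values >= level towards values < level).

namespace {

struct MeshAcc {
  std::vector<double> verts;                 // x,y,z triplets
  std::vector<int> faces;                    // 0-based vertex id triplets
  std::unordered_map<uint64_t, int> edge_id; // grid-edge -> vertex id
};

inline uint64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint32_t>(b);
}

// grid node linear index -> world coordinate along one axis handled by caller
inline int vertex_on_edge(MeshAcc &m, int ia, int ib,
                          const double *pa, const double *pb,
                          double fa, double fb, double level) {
  uint64_t key = edge_key(ia, ib);
  auto it = m.edge_id.find(key);
  if (it != m.edge_id.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = static_cast<int>(m.verts.size() / 3);
  for (int k = 0; k < 3; ++k)
    m.verts.push_back(pa[k] + t * (pb[k] - pa[k]));
  m.edge_id.emplace(key, id);
  return id;
}

inline void add_tri(MeshAcc &m, int a, int b, int c,
                    const double *inside_pt) {
  // orient so the normal points away from the inside (>= level) corner
  const double *A = &m.verts[3 * a], *B = &m.verts[3 * b], *C = &m.verts[3 * c];
  double u[3], v[3], n[3], d[3];
  for (int k = 0; k < 3; ++k) { u[k] = B[k] - A[k]; v[k] = C[k] - A[k]; }
  n[0] = u[1] * v[2] - u[2] * v[1];
  n[1] = u[2] * v[0] - u[0] * v[2];
  n[2] = u[0] * v[1] - u[1] * v[0];
  for (int k = 0; k < 3; ++k)
    d[k] = (A[k] + B[k] + C[k]) / 3.0 - inside_pt[k];
  double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
  if (dot >= 0) { m.faces.push_back(a); m.faces.push_back(b); m.faces.push_back(c); }
  else          { m.faces.push_back(a); m.faces.push_back(c); m.faces.push_back(b); }
}

} // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector data, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *f = REAL(data);
  MeshAcc m;

  // cube corner offsets (x,y,z)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra sharing the 0-6 diagonal
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

  std::vector<int> lin(8);
  std::vector<double> val(8);
  double pos[8][3];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          lin[c] = ii + nx * (jj + ny * kk);
          val[c] = f[lin[c]];
          pos[c][0] = ox + ii * sx;
          pos[c][1] = oy + jj * sy;
          pos[c][2] = oz + kk * sz;
          if (val[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[idx[c]] >= level) ins[nin++] = idx[c];
            else outs[nout++] = idx[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = ins[0];
            int e1 = vertex_on_edge(m, lin[A], lin[outs[0]], pos[A], pos[outs[0]], val[A], val[outs[0]], level);
            int e2 = vertex_on_edge(m, lin[A], lin[outs[1]], pos[A], pos[outs[1]], val[A], val[outs[1]], level);
            int e3 = vertex_on_edge(m, lin[A], lin[outs[2]], pos[A], pos[outs[2]], val[A], val[outs[2]], level);
            add_tri(m, e1, e2, e3, pos[A]);
          } else if (nin == 3) {
            int D = outs[0];
            int e1 = vertex_on_edge(m, lin[ins[0]], lin[D], pos[ins[0]], pos[D], val[ins[0]], val[D], level);
            int e2 = vertex_on_edge(m, lin[ins[1]], lin[D], pos[ins[1]], pos[D], val[ins[1]], val[D], level);
            int e3 = vertex_on_edge(m, lin[ins[2]], lin[D], pos[ins[2]], pos[D], val[ins[2]], val[D], level);
            double cin[3];
            for (int kk2 = 0; kk2 < 3; ++kk2)
              cin[kk2] = (pos[ins[0]][kk2] + pos[ins[1]][kk2] + pos[ins[2]][kk2]) / 3.0;
            add_tri(m, e1, e2, e3, cin);
          } else { // 2-2 case -> quad split into two triangles
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eAC = vertex_on_edge(m, lin[A], lin[C], pos[A], pos[C], val[A], val[C], level);
            int eAD = vertex_on_edge(m, lin[A], lin[D], pos[A], pos[D], val[A], val[D], level);
            int eBD = vertex_on_edge(m, lin[B], lin[D], pos[B], pos[D], val[B], val[D], level);
            int eBC = vertex_on_edge(m, lin[B], lin[C], pos[B], pos[C], val[B], val[C], level);
            double cin[3];
            for (int kk2 = 0; kk2 < 3; ++kk2)
              cin[kk2] = (pos[A][kk2] + pos[B][kk2]) / 2.0;
            add_tri(m, eAC, eAD, eBD, cin);
            add_tri(m, eAC, eBD, eBC, cin);
          }
        }
      }

  int nv = static_cast<int>(m.verts.size() / 3);
  int nf = static_cast<int>(m.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v)
    for (int k = 0; k < 3; ++k) V(v, k) = m.verts[3 * v + k];
  for (int fi = 0; fi < nf; ++fi)
    for (int k = 0; k < 3; ++k) F(fi, k) = m.faces[3 * fi + k] + 1; // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Largest 6-connected component of a voxel mask.
// [[Rcpp::export(name = ".largest_component_mask")]]
LogicalVector largest_component_mask(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> label(n, 0);
  int best_label = 0, best_size = 0, cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    int size = 0;
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      ++size;
      int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int pp = ii + nx * (jj + ny * kk);
        if (mask[pp] && !label[pp]) { label[pp] = cur; stack.push_back(pp); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(n);
  for (int s = 0; s < n; ++s) out[s] = (label[s] == best_label && best_label > 0);
  return out;
}
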