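#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Brute-force Euclidean k-nearest neighbours on row coordinates.
// Self excluded; distance ties broken by lower index. Returns 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow();
  const int kk = std::min(k, n - 1);
  IntegerMatrix out(n, kk);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
      cand[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    cand[i].first = R_PosInf;  // exclude self
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    for (int m = 0; m < kk; ++m) out(i, m) = cand[m].second + 1;
  }
  return out;
}

// Nearest neighbour in B for every row of A: 1-based index + squared distance.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  IntegerVector idx(n);
  NumericVector d2(n);
  for (int i = 0; i < n; ++i) {
    const double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = B(j, 0) - xi, dy = B(j, 1) - yi, dz = B(j, 2) - zi;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// Squared distance from point p to triangle (a, b, c) (Ericson, RTCD 5.1.5).
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  }
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
    double q[3];
    for (int i = 0; i < 3; ++i) q[i] = ap[i] - v * ab[i];
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
    double q[3];
    for (int i = 0; i < 3; ++i) q[i] = ap[i] - w * ac[i];
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double den = (d4 - d3) + (d5 - d6);
    const double w = den != 0.0 ? clamp01((d4 - d3) / den) : 0.0;
    double q[3];
    for (int i = 0; i < 3; ++i) q[i] = bp[i] - w * (c[i] - b[i]);
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  const double denom = va + vb + vc;
  const double v = denom != 0.0 ? vb / denom : 0.0;
  const double w = denom != 0.0 ? vc / denom : 0.0;
  double q[3];
  for (int i = 0; i < 3; ++i) q[i] = ap[i] - v * ab[i] - w * ac[i];
  return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
}

// Minimum distance from each point to a triangle soup (exact, with a
// centroid-radius quick reject). F is 1-based.
// [[Rcpp::export]]
NumericVector cpp_point_tri_min_dist(NumericMatrix P, NumericMatrix V,
                                     IntegerMatrix F) {
  const int n = P.nrow(), t = F.nrow();
  std::vector<double> cx(t), cy(t), cz(t), rad(t);
  std::vector<double> A(3 * t), B(3 * t), C(3 * t);
  for (int f = 0; f < t; ++f) {
    const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      A[3 * f + d] = V(ia, d); B[3 * f + d] = V(ib, d); C[3 * f + d] = V(ic, d);
    }
    cx[f] = (A[3 * f] + B[3 * f] + C[3 * f]) / 3.0;
    cy[f] = (A[3 * f + 1] + B[3 * f + 1] + C[3 * f + 1]) / 3.0;
    cz[f] = (A[3 * f + 2] + B[3 * f + 2] + C[3 * f + 2]) / 3.0;
    double ra = 0, rb = 0, rc = 0;
    for (int d = 0; d < 3; ++d) {
      const double cc = (d == 0 ? cx[f] : d == 1 ? cy[f] : cz[f]);
      ra += (A[3 * f + d] - cc) * (A[3 * f + d] - cc);
      rb += (B[3 * f + d] - cc) * (B[3 * f + d] - cc);
      rc += (C[3 * f + d] - cc) * (C[3 * f + d] - cc);
    }
    rad[f] = std::sqrt(std::max(ra, std::max(rb, rc)));
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = R_PosInf;
    double bestd = R_PosInf;  // sqrt of best
    for (int f = 0; f < t; ++f) {
      const double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dc - rad[f] >= bestd) continue;
      const double d2 = pt_tri_d2(p, &A[3 * f], &B[3 * f], &C[3 * f]);
      if (d2 < best) { best = d2; bestd = std::sqrt(d2); }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// --- 3D topology-preserving thinning ---------------------------------------

struct Grid3 {
  const int *v;
  int nx, ny, nz;
  inline int at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return v[x + nx * (y + (size_t)ny * z)];
  }
};

// 26-connected foreground components in N26 \ {p}: must be exactly 1.
// 6-connected background components in N18 that are 6-adjacent to p: exactly 1.
static bool is_simple_point(const Grid3 &g, int x, int y, int z) {
  int fg[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        fg[(dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1))] =
            g.at(x + dx, y + dy, z + dz);
  fg[13] = 0;  // remove centre
  // foreground 26-CC count
  int seen[27] = {0};
  int ncc = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !fg[s] || seen[s]) continue;
    ++ncc;
    if (ncc > 1) return false;
    std::queue<int> q;
    q.push(s); seen[s] = 1;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      const int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int ux = cx + dx, uy = cy + dy, uz = cz + dz;
            if (ux < 0 || uy < 0 || uz < 0 || ux > 2 || uy > 2 || uz > 2)
              continue;
            const int u = ux + 3 * (uy + 3 * uz);
            if (u == 13 || seen[u] || !fg[u]) continue;
            seen[u] = 1; q.push(u);
          }
    }
  }
  if (ncc != 1) return false;
  // background 6-CC in N18 seeded from 6-neighbours of p
  int bg[27], inN18[27], seenb[27] = {0};
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int s = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
        const int nz_ = (dx != 0) + (dy != 0) + (dz != 0);
        inN18[s] = (nz_ <= 2 && s != 13);
        bg[s] = !g.at(x + dx, y + dy, z + dz);
      }
  const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  int nbcc = 0;
  for (int fi = 0; fi < 6; ++fi) {
    const int s = face[fi];
    if (!bg[s] || seenb[s]) continue;
    ++nbcc;
    if (nbcc > 1) return false;
    std::queue<int> q;
    q.push(s); seenb[s] = 1;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      const int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int m = 0; m < 6; ++m) {
        const int ux = cx + d6[m][0], uy = cy + d6[m][1], uz = cz + d6[m][2];
        if (ux < 0 || uy < 0 || uz < 0 || ux > 2 || uy > 2 || uz > 2) continue;
        const int u = ux + 3 * (uy + 3 * uz);
        if (!inN18[u] || !bg[u] || seenb[u]) continue;
        seenb[u] = 1; q.push(u);
      }
    }
  }
  return nbcc == 1;
}

// Surface-preserving end condition: a voxel already locally one voxel thick
// along some axis (background on both sides) is never removed.
static bool is_surface_voxel(const Grid3 &g, int x, int y, int z) {
  if (!g.at(x - 1, y, z) && !g.at(x + 1, y, z)) return true;
  if (!g.at(x, y - 1, z) && !g.at(x, y + 1, z)) return true;
  if (!g.at(x, y, z - 1) && !g.at(x, y, z + 1)) return true;
  return false;
}

// Sequential directional thinning to a medial surface. Deletion requires:
// border in the sweep direction, foreground behind, simple point, and not a
// surface voxel. Iterated to fixpoint.
// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector vox, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(vox);
  Grid3 g; g.v = INTEGER(out); g.nx = nx; g.ny = ny; g.nz = nz;
  int *buf = INTEGER(out);
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      const int ox = dirs[d][0], oy = dirs[d][1], oz = dirs[d][2];
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const size_t li = x + nx * (y + (size_t)ny * z);
            if (!buf[li]) continue;
            if (g.at(x + ox, y + oy, z + oz)) continue;       // not border
            if (!g.at(x - ox, y - oy, z - oz)) continue;      // thin already
            if (is_surface_voxel(g, x, y, z)) continue;
            if (!is_simple_point(g, x, y, z)) continue;
            buf[li] = 0;
            changed = true;
          }
    }
  }
  return out;
}

// --- Marching tetrahedra ----------------------------------------------------

// Decompose every grid cell into 6 tetrahedra and extract the iso-surface
// value == iso by linear interpolation along tet edges. Vertices returned in
// 0-based continuous index space; faces 1-based. Values strictly above iso
// count as inside.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vals);
  auto lin = [&](int x, int y, int z) -> int64_t {
    return x + (int64_t)nx * (y + (int64_t)ny * z);
  };
  // cube corner offsets, bit order (x, y, z)
  const int corner[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                            {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6-tet decomposition around main diagonal 0-7
  const int tets[6][4] = {{0,5,1,7},{0,1,3,7},{0,3,2,7},
                          {0,2,6,7},{0,6,4,7},{0,4,5,7}};
  std::unordered_map<int64_t, int> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  auto edge_point = [&](int64_t n1, int64_t n2, double v1, double v2) -> int {
    int64_t a = n1, b = n2;
    if (a > b) std::swap(a, b);
    const int64_t key = a * (int64_t)(nx * (int64_t)ny * nz) + b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    const double va = v[a], vb = v[b];
    double t = (vb - va) != 0.0 ? (iso - va) / (vb - va) : 0.5;
    t = clamp01(t);
    const int ax = (int)(a % nx), ay = (int)((a / nx) % ny), az = (int)(a / ((int64_t)nx * ny));
    const int bx = (int)(b % nx), by = (int)((b / nx) % ny), bz = (int)(b / ((int64_t)nx * ny));
    VX.push_back(ax + t * (bx - ax));
    VY.push_back(ay + t * (by - ay));
    VZ.push_back(az + t * (bz - az));
    const int id = (int)VX.size();  // 1-based
    edge_vert[key] = id;
    (void)v1; (void)v2;
    return id;
  };
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int64_t nid[8]; double cv[8]; bool in[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          nid[c] = lin(x + corner[c][0], y + corner[c][1], z + corner[c][2]);
          cv[c] = v[nid[c]];
          in[c] = cv[c] > iso;
          any = any || in[c];
          all = all && in[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int a = tets[t][0], b = tets[t][1], c = tets[t][2],
                    d = tets[t][3];
          const int idx4[4] = {a, b, c, d};
          int cnt = in[a] + in[b] + in[c] + in[d];
          if (cnt == 0 || cnt == 4) continue;
          if (cnt == 1 || cnt == 3) {
            const bool want = (cnt == 1);
            int lone = -1;
            for (int m = 0; m < 4; ++m) if (in[idx4[m]] == want) lone = m;
            const int L = idx4[lone];
            int oth[3], no = 0;
            for (int m = 0; m < 4; ++m) if (m != lone) oth[no++] = idx4[m];
            const int e1 = edge_point(nid[L], nid[oth[0]], cv[L], cv[oth[0]]);
            const int e2 = edge_point(nid[L], nid[oth[1]], cv[L], cv[oth[1]]);
            const int e3 = edge_point(nid[L], nid[oth[2]], cv[L], cv[oth[2]]);
            FA.push_back(e1); FB.push_back(e2); FC.push_back(e3);
          } else {  // cnt == 2
            int ins[2], outs[2], ni = 0, no = 0;
            for (int m = 0; m < 4; ++m) {
              if (in[idx4[m]]) ins[ni++] = idx4[m]; else outs[no++] = idx4[m];
            }
            const int e1 = edge_point(nid[ins[0]], nid[outs[0]], 0, 0);
            const int e2 = edge_point(nid[ins[0]], nid[outs[1]], 0, 0);
            const int e3 = edge_point(nid[ins[1]], nid[outs[1]], 0, 0);
            const int e4 = edge_point(nid[ins[1]], nid[outs[0]], 0, 0);
            FA.push_back(e1); FB.push_back(e2); FC.push_back(e3);
            FA.push_back(e1); FB.push_back(e3); FC.push_back(e4);
          }
        }
      }
  const int nv = (int)VX.size(), nf = (int)FA.size();
  NumericMatrix VM(nv, 3);
  for (int i = 0; i < nv; ++i) { VM(i,0)=VX[i]; VM(i,1)=VY[i]; VM(i,2)=VZ[i]; }
  IntegerMatrix FM(nf, 3);
  for (int i = 0; i < nf; ++i) { FM(i,0)=FA[i]; FM(i,1)=FB[i]; FM(i,2)=FC[i]; }
  return List::create(_["vertices"] = VM, _["faces"] = FM);
}

// Max over consecutive row-blocks of size g: (B*g) x C -> B x C, plus the
// argmax row offset (1..g) for the backward pass.
// [[Rcpp::export]]
List cpp_group_max(NumericMatrix x, int g) {
  const int n = x.nrow(), C = x.ncol();
  const int B = n / g;
  NumericMatrix val(B, C);
  IntegerMatrix arg(B, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const int base = b * g;
      double best = x(base, c); int bj = 1;
      for (int j = 1; j < g; ++j) {
        const double v = x(base + j, c);
        if (v > best) { best = v; bj = j + 1; }
      }
      val(b, c) = best;
      arg(b, c) = bj;
    }
  }
  return List::create(_["val"] = val, _["arg"] = arg);
}

// Column-wise max and 1-based argmax row.
// [[Rcpp::export]]
List cpp_col_max(NumericMatrix x) {
  const int n = x.nrow(), C = x.ncol();
  NumericVector val(C);
  IntegerVector arg(C);
  for (int c = 0; c < C; ++c) {
    double best = x(0, c); int bi = 1;
    for (int i = 1; i < n; ++i) {
      if (x(i, c) > best) { best = x(i, c); bi = i + 1; }
    }
    val[c] = best; arg[c] = bi;
  }
  return List::create(_["val"] = val, _["arg"] = arg);
}
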