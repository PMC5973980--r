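#include <RcppArmadillo.h>
#include <map>
#include <queue>
#include <utility>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D array (reflected borders).
// [[Rcpp::export(name = ".gaussian_smooth3")]]
NumericVector gaussian_smooth3(NumericVector arr, IntegerVector dim, double sigma) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if (sigma <= 0) return clone(arr);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;

  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  const long n01 = (long)d0 * d1;
  auto idx = [&](int i, int j, int l) { return (long)i + (long)d0 * j + n01 * l; };
  auto reflect = [](int i, int d) {
    if (i < 0) i = -i - 1;
    if (i >= d) i = 2 * d - i - 1;
    return i;
  };
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    for (int l = 0; l < d2; ++l)
      for (int j = 0; j < d1; ++j)
        for (int i = 0; i < d0; ++i) {
          double acc = 0.0;
          for (int o = -r; o <= r; ++o) {
            int ii = i, jj = j, ll = l;
            if (axis == 0) ii = reflect(i + o, d0);
            else if (axis == 1) jj = reflect(j + o, d1);
            else ll = reflect(l + o, d2);
            acc += k[o + r] * a[idx(ii, jj, ll)];
          }
          b[idx(i, j, l)] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Isosurface by marching tetrahedra on the Freudenthal (Kuhn) decomposition
// of the voxel lattice: each cell is split into 6 tetrahedra sharing the main
// diagonal, which triangulates space consistently so the result is a closed,
// consistently oriented triangle mesh whenever the iso-level is not attained
// on the array boundary. Vertices are linearly interpolated at iso crossings.
// Returns 1-based faces for R. Triangle normals point towards field < iso.
// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector field, IntegerVector dim, double iso,
                         NumericVector spacing, NumericVector origin) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const long n01 = (long)d0 * d1;
  auto gid = [&](int i, int j, int l) { return (long)i + (long)d0 * j + n01 * l; };

  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::map<std::pair<long, long>, int> edge2vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto corner_pos = [&](long g, double *p) {
    long l = g / n01, rem = g % n01;
    p[0] = (double)(rem % d0);
    p[1] = (double)(rem / d0);
    p[2] = (double)l;
  };

  // interpolated vertex on lattice edge (ga, gb); cached by edge key
  auto edge_vertex = [&](long ga, long gb, double va, double vb) {
    std::pair<long, long> key = ga < gb ? std::make_pair(ga, gb) : std::make_pair(gb, ga);
    auto it = edge2vid.find(key);
    if (it != edge2vid.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    double pa[3], pb[3];
    corner_pos(ga, pa);
    corner_pos(gb, pb);
    vx.push_back(origin[0] + spacing[0] * (pa[0] + t * (pb[0] - pa[0])));
    vy.push_back(origin[1] + spacing[1] * (pa[1] + t * (pb[1] - pa[1])));
    vz.push_back(origin[2] + spacing[2] * (pa[2] + t * (pb[2] - pa[2])));
    int id = (int)vx.size() - 1;
    edge2vid[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const double *inward, const double *outward) {
    // orient so the normal points from inside (>= iso) to outside
    double A[3] = {vx[a], vy[a], vz[a]};
    double u[3] = {vx[b] - A[0], vy[b] - A[1], vz[b] - A[2]};
    double w[3] = {vx[c] - A[0], vy[c] - A[1], vz[c] - A[2]};
    double nrm[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                     u[0] * w[1] - u[1] * w[0]};
    double d[3] = {outward[0] - inward[0], outward[1] - inward[1], outward[2] - inward[2]};
    double dp = nrm[0] * d[0] + nrm[1] * d[1] + nrm[2] * d[2];
    if (dp < 0) std::swap(b, c);
    f0.push_back(a + 1);
    f1.push_back(b + 1);
    f2.push_back(c + 1);
  };

  const double *fd = field.begin();
  for (int l = 0; l + 1 < d2; ++l)
    for (int j = 0; j + 1 < d1; ++j)
      for (int i = 0; i + 1 < d0; ++i) {
        // skip uniform cells fast
        double mn = 1e300, mx = -1e300;
        for (int c = 0; c < 8; ++c) {
          double v = fd[gid(i + (c & 1), j + ((c >> 1) & 1), l + ((c >> 2) & 1))];
          mn = std::min(mn, v);
          mx = std::max(mx, v);
        }
        if (mx < iso || mn >= iso) continue;
        for (int p = 0; p < 6; ++p) {
          // cumulative unit steps along the permuted axes: v0, v0+e_a, v0+e_a+e_b, v0+(1,1,1)
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
          off[1][perms[p][0]] = 1;
          off[2][perms[p][0]] = 1; off[2][perms[p][1]] = 1;
          off[3][0] = 1; off[3][1] = 1; off[3][2] = 1;
          long g[4];
          double v[4], pos[4][3];
          for (int c = 0; c < 4; ++c) {
            g[c] = gid(i + off[c][0], j + off[c][1], l + off[c][2]);
            v[c] = fd[g[c]];
            pos[c][0] = i + off[c][0];
            pos[c][1] = j + off[c][1];
            pos[c][2] = l + off[c][2];
          }
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = v[c] >= iso;
            nin += in[c];
          }
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            for (int s = 0; s < 3; ++s) {
              double w = origin[s] + spacing[s] * pos[c][s];
              if (in[c]) cin[s] += w; else cout[s] += w;
            }
            if (in[c]) ni++; else no++;
          }
          for (int s = 0; s < 3; ++s) {
            cin[s] /= ni;
            cout[s] /= no;
          }
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) apex = c;
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) others[m++] = c;
            int e0 = edge_vertex(g[apex], g[others[0]], v[apex], v[others[0]]);
            int e1 = edge_vertex(g[apex], g[others[1]], v[apex], v[others[1]]);
            int e2 = edge_vertex(g[apex], g[others[2]], v[apex], v[others[2]]);
            emit(e0, e1, e2, cin, cout);
          } else {
            int ia[2], oa[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c)
              if (in[c]) ia[mi++] = c; else oa[mo++] = c;
            int pac = edge_vertex(g[ia[0]], g[oa[0]], v[ia[0]], v[oa[0]]);
            int pad = edge_vertex(g[ia[0]], g[oa[1]], v[ia[0]], v[oa[1]]);
            int pbc = edge_vertex(g[ia[1]], g[oa[0]], v[ia[1]], v[oa[0]]);
            int pbd = edge_vertex(g[ia[1]], g[oa[1]], v[ia[1]], v[oa[1]]);
            // quad cycle pac - pad - pbd - pbc
            emit(pac, pad, pbd, cin, cout);
            emit(pac, pbd, pbc, cin, cout);
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  int nf = (int)f0.size();
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f0[i];
    F(i, 1) = f1[i];
    F(i, 2) = f2[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// 8-connected component labelling of a binary 2D mask (column-major matrix).
// [[Rcpp::export(name = ".label_components2d")]]
IntegerMatrix label_components2d(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++cur;
      lab(i, j) = cur;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = cur;
              q.push({ni, nj});
            }
          }
      }
    }
  return lab;
}
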