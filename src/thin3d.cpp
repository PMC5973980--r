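#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Parallel medial-axis thinning of a 3D binary mask with (26, 6) digital
// topology: foreground is 26-connected, background 6-connected. Points are
// removed only if "simple" (deletion preserves both connectivities locally,
// Malandain-Bertrand characterisation) and not curve end-points, in six
// directional sub-iterations with sequential re-checking, which drives the
// erosion symmetrically towards the medial axis and yields a unit-wide
// skeleton. The input is treated as 0/1; a one-voxel zero border is assumed
// to be added by the caller.

namespace {

inline int lidx(int x, int y, int z) { return (x + 1) + 3 * (y + 1) + 9 * (z + 1); }

// 26-neighbourhood foreground connectivity: exactly one component?
bool fg_one_component(const int nb[27]) {
  int seen[27] = {0};
  int start = -1, total = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) {
      ++total;
      if (start < 0) start = i;
    }
  if (total == 0) return false;
  std::vector<int> stack{start};
  seen[start] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int c = stack.back();
    stack.pop_back();
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx + dx, ny = cy + dy, nz = cz + dz;
          if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1) continue;
          int j = lidx(nx, ny, nz);
          if (j == 13 || seen[j] || !nb[j]) continue;
          seen[j] = 1;
          ++cnt;
          stack.push_back(j);
        }
  }
  return cnt == total;
}

// 6-connected background components within the 18-neighbourhood, counting
// only components that touch a face neighbour of the centre: exactly one?
bool bg_one_component(const int nb[27]) {
  static const int face[6] = {lidx(-1, 0, 0), lidx(1, 0, 0), lidx(0, -1, 0),
                              lidx(0, 1, 0),  lidx(0, 0, -1), lidx(0, 0, 1)};
  auto in18 = [](int i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    return m >= 1 && m <= 2;
  };
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = 0;
  int ncomp = 0;
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nb[s] || comp[s]) continue;
    ++ncomp;
    std::vector<int> stack{s};
    comp[s] = ncomp;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int step[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      for (auto &st : step) {
        int nx = cx + st[0], ny = cy + st[1], nz = cz + st[2];
        if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1) continue;
        int j = lidx(nx, ny, nz);
        if (j == 13 || !in18(j) || nb[j] || comp[j]) continue;
        comp[j] = ncomp;
        stack.push_back(j);
      }
    }
  }
  return ncomp == 1;
}

}  // namespace

// [[Rcpp::export(name = ".thin3d")]]
IntegerVector thin3d(IntegerVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const long n01 = (long)d0 * d1;
  std::vector<int> a(mask.begin(), mask.end());
  auto at = [&](int x, int y, int z) -> int & { return a[(long)x + (long)d0 * y + n01 * z]; };

  auto neighbours = [&](int x, int y, int z, int nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[lidx(dx, dy, dz)] = at(x + dx, y + dy, z + dz) != 0;
  };
  auto n26 = [&](const int nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i)
      if (i != 13 && nb[i]) ++c;
    return c;
  };
  auto deletable = [&](int x, int y, int z) {
    int nb[27];
    neighbours(x, y, z, nb);
    int n = n26(nb);
    if (n <= 1) return false;  // end-point or isolated
    return fg_one_component(nb) && bg_one_component(nb);
  };

  const int dirs[6][3] = {{0, 0, 1}, {0, 0, -1}, {0, 1, 0}, {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}};
  bool changed = true;
  std::vector<long> cand;
  while (changed) {
    changed = false;
    for (auto &d : dirs) {
      cand.clear();
      for (int z = 1; z + 1 < d2; ++z)
        for (int y = 1; y + 1 < d1; ++y)
          for (int x = 1; x + 1 < d0; ++x) {
            if (!at(x, y, z)) continue;
            if (at(x + d[0], y + d[1], z + d[2])) continue;  // not a border point for d
            if (deletable(x, y, z)) cand.push_back((long)x + (long)d0 * y + n01 * z);
          }
      // sequential re-check preserves topology within the parallel batch
      for (long g : cand) {
        int z = (int)(g / n01), rem = (int)(g % n01);
        int y = rem / d0, x = rem % d0;
        if (deletable(x, y, z)) {
          at(x, y, z) = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
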