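#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Linear index convention matches R arrays: idx = i + nx*(j + ny*k), 0-based.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 26- and 6-neighborhood offsets
static void neighbor_offsets(int connectivity, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        out.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector vol, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = k - 1;  // window is (2k-1)^3; edges replicate (clamped indices)
  NumericVector out(vol.size());
  std::vector<double> buf;
  const size_t wn = (size_t)(2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  buf.resize(wn);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t p = 0;
        for (int dz = z - r; dz <= z + r; ++dz) {
          int cz = std::min(nz - 1, std::max(0, dz));
          for (int dy = y - r; dy <= y + r; ++dy) {
            int cy = std::min(ny - 1, std::max(0, dy));
            for (int dx = x - r; dx <= x + r; ++dx) {
              int cx = std::min(nx - 1, std::max(0, dx));
              buf[p++] = vol[lin(cx, cy, cz, nx, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + wn / 2, buf.end());
        out[lin(x, y, z, nx, ny)] = buf[wn / 2];  // odd window: true median
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double lo, double hi,
                              int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(vol.size(), false);
  std::vector<std::array<int,3>> nb;
  neighbor_offsets(connectivity, nb);
  std::queue<std::array<int,3>> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    int id = lin(i, j, k, nx, ny);
    if (!out[id]) { out[id] = true; q.push({i, j, k}); }
  }
  while (!q.empty()) {
    auto p = q.front(); q.pop();
    for (auto& d : nb) {
      int i = p[0] + d[0], j = p[1] + d[1], k = p[2] + d[2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      int id = lin(i, j, k, nx, ny);
      if (out[id]) continue;
      double g = vol[id];
      if (g >= lo && g <= hi) { out[id] = true; q.push({i, j, k}); }
    }
  }
  return out;
}

// Connected-component labeling; labels assigned in linear-scan order (1..n).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int,3>> nb;
  neighbor_offsets(connectivity, nb);
  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int id = lin(x, y, z, nx, ny);
        if (!mask[id] || lab[id] != 0) continue;
        ++next;
        lab[id] = next;
        q.push({x, y, z});
        while (!q.empty()) {
          auto p = q.front(); q.pop();
          for (auto& d : nb) {
            int i = p[0] + d[0], j = p[1] + d[1], k = p[2] + d[2];
            if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
            int jd = lin(i, j, k, nx, ny);
            if (mask[jd] && lab[jd] == 0) { lab[jd] = next; q.push({i, j, k}); }
          }
        }
      }
  return lab;
}

// --- 3D thinning skeletonization -------------------------------------------
// A foreground voxel is "simple" if its removal preserves local topology:
//  (a) exactly one 26-connected foreground component in the 26-neighborhood,
//  (b) exactly one 6-connected background component in the 18-neighborhood
//      that is 6-adjacent to the voxel.

static bool is_simple(const std::vector<char>& local) {
  // local: 27 values indexed dx+1 + 3*(dy+1) + 9*(dz+1); center ignored.
  // (a) foreground components, 26-connectivity
  char seen[27] = {0};
  int fg_comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !local[s] || seen[s]) continue;
    ++fg_comp;
    if (fg_comp > 1) return false;
    std::queue<int> q; q.push(s); seen[s] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int t = x + 3 * y + 9 * z;
            if (t == 13 || t == c || !local[t] || seen[t]) continue;
            seen[t] = 1; q.push(t);
          }
    }
  }
  if (fg_comp != 1) return false;
  // (b) background components within the 18-neighborhood, 6-connectivity,
  //     counting only components containing a face neighbor of the center.
  char seenb[27] = {0};
  int bg_comp = 0;
  static const int face_idx[6] = {12, 14, 10, 16, 4, 22};
  for (int fi = 0; fi < 6; ++fi) {
    int s = face_idx[fi];
    if (local[s] || seenb[s]) continue;
    ++bg_comp;
    if (bg_comp > 1) return false;
    std::queue<int> q; q.push(s); seenb[s] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int d = 0; d < 6; ++d) {
        int x = cx + step[d][0], y = cy + step[d][1], z = cz + step[d][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int t = x + 3 * y + 9 * z;
        // stay inside the 18-neighborhood (exclude the 8 corners) and center
        int m = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
        if (t == 13 || m > 2 || local[t] || seenb[t]) continue;
        seenb[t] = 1; q.push(t);
      }
    }
  }
  return bg_comp == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = mask.size();
  std::vector<char> fg(n);
  for (int i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  // city-block distance from background (outside counts as background)
  std::vector<int> dist(n, -1);
  std::queue<int> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int id = lin(x, y, z, nx, ny);
        if (!fg[id]) { dist[id] = 0; continue; }
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1) {
          dist[id] = 1; q.push(id);
        }
      }
  // seed interior foreground adjacent to background
  const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int id = lin(x, y, z, nx, ny);
        if (!fg[id] || dist[id] == 1) continue;
        for (int d = 0; d < 6; ++d) {
          int i = x + step[d][0], j = y + step[d][1], k = z + step[d][2];
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
          if (!fg[lin(i, j, k, nx, ny)]) { dist[id] = 1; q.push(id); break; }
        }
      }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int i = x + step[d][0], j = y + step[d][1], k = z + step[d][2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      int jd = lin(i, j, k, nx, ny);
      if (fg[jd] && dist[jd] < 0) { dist[jd] = dist[id] + 1; q.push(jd); }
    }
  }

  auto fetch_local = [&](int x, int y, int z, std::vector<char>& local) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int i = x + dx, j = y + dy, k = z + dz;
          char v = 0;
          if (i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz)
            v = fg[lin(i, j, k, nx, ny)];
          local[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = v;
        }
  };
  auto n26 = [&](int x, int y, int z) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int i = x + dx, j = y + dy, k = z + dz;
          if (i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz)
            c += fg[lin(i, j, k, nx, ny)];
        }
    return c;
  };

  std::vector<char> local(27);
  bool changed = true;
  while (changed) {
    changed = false;
    // candidates: boundary foreground, processed in (distance, index) order
    std::vector<std::pair<int,int>> cand;
    for (int id = 0; id < n; ++id)
      if (fg[id] && dist[id] == 1) cand.push_back({dist[id], id});
    // also peel deeper layers once the shell is gone
    if (cand.empty())
      for (int id = 0; id < n; ++id)
        if (fg[id]) cand.push_back({dist[id], id});
    std::sort(cand.begin(), cand.end());
    for (auto& pr : cand) {
      int id = pr.second;
      if (!fg[id]) continue;
      int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
      if (n26(x, y, z) <= 1) continue;  // endpoint: keep
      fetch_local(x, y, z, local);
      if (!is_simple(local)) continue;
      fg[id] = 0;
      changed = true;
    }
    if (changed) {
      // refresh boundary distances: voxels now adjacent to background get dist 1
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int id = lin(x, y, z, nx, ny);
            if (!fg[id]) continue;
            bool b = (x == 0 || y == 0 || z == 0 ||
                      x == nx - 1 || y == ny - 1 || z == nz - 1);
            if (!b)
              for (int d = 0; d < 6; ++d) {
                int i = x + step[d][0], j = y + step[d][1], k = z + step[d][2];
                if (!fg[lin(i, j, k, nx, ny)]) { b = true; break; }
              }
            if (b) dist[id] = 1;
          }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}

// Affine resampling: for each output voxel (0-based index), source voxel
// coordinate s = A %*% c(i,j,k,1); trilinear or nearest lookup.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  IntegerVector outdim, NumericMatrix A,
                                  bool nearest, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((double)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        double v = fill;
        if (nearest) {
          int xi = (int)std::lround(sx), yj = (int)std::lround(sy), zk = (int)std::lround(sz);
          if (xi >= 0 && yj >= 0 && zk >= 0 && xi < nx && yj < ny && zk < nz)
            v = vol[lin(xi, yj, zk, nx, ny)];
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          if (x0 >= 0 && y0 >= 0 && z0 >= 0 &&
              x0 + 1 < nx && y0 + 1 < ny && z0 + 1 < nz) {
            double c00 = vol[lin(x0,y0,z0,nx,ny)]*(1-fx) + vol[lin(x0+1,y0,z0,nx,ny)]*fx;
            double c10 = vol[lin(x0,y0+1,z0,nx,ny)]*(1-fx) + vol[lin(x0+1,y0+1,z0,nx,ny)]*fx;
            double c01 = vol[lin(x0,y0,z0+1,nx,ny)]*(1-fx) + vol[lin(x0+1,y0,z0+1,nx,ny)]*fx;
            double c11 = vol[lin(x0,y0+1,z0+1,nx,ny)]*(1-fx) + vol[lin(x0+1,y0+1,z0+1,nx,ny)]*fx;
            v = (c00*(1-fy) + c10*fy)*(1-fz) + (c01*(1-fy) + c11*fy)*fz;
          } else if (x0 >= -1 && y0 >= -1 && z0 >= -1 &&
                     x0 < nx && y0 < ny && z0 < nz) {
            // border: clamp to nearest inside voxel
            int xi = std::min(nx - 1, std::max(0, (int)std::lround(sx)));
            int yj = std::min(ny - 1, std::max(0, (int)std::lround(sy)));
            int zk = std::min(nz - 1, std::max(0, (int)std::lround(sz)));
            v = vol[lin(xi, yj, zk, nx, ny)];
          }
        }
        out[lin(i, j, k, ox, oy)] = v;
      }
  return out;
}

// For each positive component id in comp, does any voxel have a neighbor
// carrying target label 1 (epiphysis) or 2 (metaphysis)?
// [[Rcpp::export]]
LogicalMatrix cpp_touch_labels(IntegerVector comp, IntegerVector labels,
                               IntegerVector dim, int ncomp, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalMatrix out(ncomp, 2);
  std::vector<std::array<int,3>> nb;
  neighbor_offsets(connectivity, nb);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int c = comp[lin(x, y, z, nx, ny)];
        if (c <= 0) continue;
        for (auto& d : nb) {
          int i = x + d[0], j = y + d[1], k = z + d[2];
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
          int l = labels[lin(i, j, k, nx, ny)];
          if (l == 1) out(c - 1, 0) = true;
          else if (l == 2) out(c - 1, 1) = true;
        }
      }
  return out;
}
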