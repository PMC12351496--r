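// Low-level image morphology shared by the 2D marker and 3D neurite
// pipelines.  Arrays arrive in R's column-major layout; dims give the
// extents with the first axis fastest.  All routines treat out-of-bounds
// voxels as background (labeling, thinning) or replicate the border
// (filters).

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <climits>

using namespace Rcpp;

namespace {

struct Grid {
  int nd;
  int d[3];
  long stride[3];
  Grid(const IntegerVector& dims) {
    nd = dims.size();
    long s = 1;
    for (int k = 0; k < 3; ++k) {
      d[k] = (k < nd) ? dims[k] : 1;
      stride[k] = s;
      s *= d[k];
    }
  }
  long size() const { return (long)d[0] * d[1] * d[2]; }
  long idx(int i, int j, int k) const {
    return i + (long)j * stride[1] + (long)k * stride[2];
  }
  bool inside(int i, int j, int k) const {
    return i >= 0 && i < d[0] && j >= 0 && j < d[1] && k >= 0 && k < d[2];
  }
};

// neighbourhood offsets for a given connectivity
std::vector<std::array<int, 3>> neighbour_offsets(int nd, int connectivity) {
  std::vector<std::array<int, 3>> out;
  if (nd == 2) {
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int manh = std::abs(di) + std::abs(dj);
        if (connectivity == 4 && manh > 1) continue;
        out.push_back({di, dj, 0});
      }
  } else {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
          if (connectivity == 6 && manh > 1) continue;
          if (connectivity == 18 && manh > 2) continue;
          out.push_back({di, dj, dk});
        }
  }
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// Connected-component labeling (BFS), 2D (4/8) or 3D (6/18/26).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  Grid g(dims);
  long n = g.size();
  if ((long)mask.size() != n) stop("mask length does not match dims");
  std::vector<std::array<int, 3>> offs = neighbour_offsets(g.nd, connectivity);
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<long> q;
  for (int k = 0; k < g.d[2]; ++k)
    for (int j = 0; j < g.d[1]; ++j)
      for (int i = 0; i < g.d[0]; ++i) {
        long p = g.idx(i, j, k);
        if (!mask[p] || lab[p]) continue;
        lab[p] = ++next;
        q.push(p);
        while (!q.empty()) {
          long c = q.front();
          q.pop();
          int ci = c % g.d[0];
          int cj = (c / g.stride[1]) % g.d[1];
          int ck = c / g.stride[2];
          for (const auto& o : offs) {
            int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
            if (!g.inside(ni, nj, nk)) continue;
            long np = g.idx(ni, nj, nk);
            if (mask[np] && !lab[np]) {
              lab[np] = next;
              q.push(np);
            }
          }
        }
      }
  lab.attr("n_labels") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by erosion: smallest J with marker >= J >= mask
// that is stable under J = max(erode(J), mask).  Sequential raster /
// anti-raster sweeps until stable (8-connectivity in 2D).  Used for the
// H-minima transform.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_erode(NumericVector marker, NumericVector mask,
                                    IntegerVector dims) {
  Grid g(dims);
  long n = g.size();
  if ((long)marker.size() != n || (long)mask.size() != n)
    stop("marker/mask length does not match dims");
  NumericVector J = clone(marker);
  std::vector<std::array<int, 3>> offs = neighbour_offsets(g.nd, g.nd == 2 ? 8 : 26);
  // split into already-scanned neighbours for forward / backward sweeps
  std::vector<std::array<int, 3>> fwd, bwd;
  for (const auto& o : offs) {
    long lin = o[0] + (long)o[1] * g.stride[1] + (long)o[2] * g.stride[2];
    if (lin < 0) fwd.push_back(o); else bwd.push_back(o);
  }
  bool changed = true;
  int pass = 0;
  while (changed && pass < 1000) {
    changed = false;
    ++pass;
    // forward
    for (int k = 0; k < g.d[2]; ++k)
      for (int j = 0; j < g.d[1]; ++j)
        for (int i = 0; i < g.d[0]; ++i) {
          long p = g.idx(i, j, k);
          double v = J[p];
          for (const auto& o : fwd) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            if (!g.inside(ni, nj, nk)) continue;
            double nv = J[g.idx(ni, nj, nk)];
            if (nv < v) v = nv;
          }
          v = std::max(v, mask[p]);
          if (v < J[p]) { J[p] = v; changed = true; }
        }
    // backward
    for (int k = g.d[2] - 1; k >= 0; --k)
      for (int j = g.d[1] - 1; j >= 0; --j)
        for (int i = g.d[0] - 1; i >= 0; --i) {
          long p = g.idx(i, j, k);
          double v = J[p];
          for (const auto& o : bwd) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            if (!g.inside(ni, nj, nk)) continue;
            double nv = J[g.idx(ni, nj, nk)];
            if (nv < v) v = nv;
          }
          v = std::max(v, mask[p]);
          if (v < J[p]) { J[p] = v; changed = true; }
        }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Separable box erosion/dilation (running min/max with a monotonic deque)
// along every axis; radius per axis.  Border replicated.  An opening with
// the box (erode then dilate) estimates the local background.

static void run_extreme_axis(std::vector<double>& x, const Grid& g, int ax,
                             int r, bool take_min) {
  if (r <= 0) return;
  int len = g.d[ax];
  long stride = g.stride[ax];
  long nlines = g.size() / len;
  std::vector<double> line(len), out(len);
  for (long l = 0; l < nlines; ++l) {
    // base index of this line
    long base;
    if (ax == 0) {
      base = (l % g.d[1]) * g.stride[1] + (l / g.d[1]) * g.stride[2];
    } else if (ax == 1) {
      base = (l % g.d[0]) + (l / g.d[0]) * g.stride[2];
    } else {
      base = (l % g.d[0]) + ((l / g.d[0]) % g.d[1]) * g.stride[1];
    }
    for (int i = 0; i < len; ++i) line[i] = x[base + i * stride];
    std::deque<int> dq;
    int hi = -1;
    for (int i = 0; i < len; ++i) {
      int want = std::min(i + r, len - 1);
      while (hi < want) {
        ++hi;
        double v = line[hi];
        while (!dq.empty() &&
               (take_min ? line[dq.back()] >= v : line[dq.back()] <= v))
          dq.pop_back();
        dq.push_back(hi);
      }
      while (!dq.empty() && dq.front() < i - r) dq.pop_front();
      out[i] = line[dq.front()];
    }
    for (int i = 0; i < len; ++i) x[base + i * stride] = out[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_extreme(NumericVector img, IntegerVector dims,
                              IntegerVector radius, bool take_min) {
  Grid g(dims);
  if ((long)img.size() != g.size()) stop("image length does not match dims");
  std::vector<double> x(img.begin(), img.end());
  for (int ax = 0; ax < g.nd; ++ax) {
    int r = (ax < radius.size()) ? radius[ax] : radius[radius.size() - 1];
    run_extreme_axis(x, g, ax, r, take_min);
  }
  return NumericVector(x.begin(), x.end());
}

// ---------------------------------------------------------------------------
// 2D median filter, square window of half-width r, replicated border.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2d(NumericMatrix img, int r) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  int w = 2 * r + 1;
  std::vector<double> buf(w * w);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj)
        for (int di = -r; di <= r; ++di) {
          int ii = std::min(std::max(i + di, 0), ny - 1);
          int jj = std::min(std::max(j + dj, 0), nx - 1);
          buf[m++] = img(ii, jj);
        }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  return out;
}

// ---------------------------------------------------------------------------
// 3D curve thinning by sequential deletion of simple, non-end points with
// six directional subiterations.  Deleting only simple points preserves
// homotopy (component count unchanged); keeping end points (<= 1 foreground
// 26-neighbour) preserves curve extremities.

namespace {

// local 3x3x3 occupancy, centre at index 13; out-of-bounds = background
inline void local_cube(const std::vector<char>& m, const Grid& g, int i,
                       int j, int k, char cube[27]) {
  int t = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++t) {
        int ni = i + di, nj = j + dj, nk = k + dk;
        cube[t] = g.inside(ni, nj, nk) ? m[g.idx(ni, nj, nk)] : 0;
      }
}

inline int cube_pos(int di, int dj, int dk) {
  return (di + 1) + (dj + 1) * 3 + (dk + 1) * 9;
}

// number of 26-connected foreground components among the 26 neighbours
int fg_components26(const char cube[27]) {
  char seen[27] = {0};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    ++ncomp;
    std::vector<int> stack = {s};
    seen[s] = 1;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj, nk = ck + dk;
            if (ni < 0 || ni > 2 || nj < 0 || nj > 2 || nk < 0 || nk > 2)
              continue;
            int np = ni + nj * 3 + nk * 9;
            if (np == 13 || seen[np] || !cube[np]) continue;
            seen[np] = 1;
            stack.push_back(np);
          }
    }
  }
  return ncomp;
}

// number of 6-connected background components within the 18-neighbourhood
// that touch a face neighbour of the centre
int bg_components6(const char cube[27]) {
  auto in18 = [](int p) {
    int di = p % 3 - 1, dj = (p / 3) % 3 - 1, dk = p / 9 - 1;
    int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
    return manh >= 1 && manh <= 2;
  };
  static const int faces[6] = {cube_pos(-1, 0, 0), cube_pos(1, 0, 0),
                               cube_pos(0, -1, 0), cube_pos(0, 1, 0),
                               cube_pos(0, 0, -1), cube_pos(0, 0, 1)};
  char seen[27] = {0};
  int ncomp = 0;
  for (int f = 0; f < 6; ++f) {
    int s = faces[f];
    if (cube[s] || seen[s]) continue;
    ++ncomp;
    std::vector<int> stack = {s};
    seen[s] = 1;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      const int d6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                            {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
      for (int t = 0; t < 6; ++t) {
        int ni = ci + d6[t][0], nj = cj + d6[t][1], nk = ck + d6[t][2];
        if (ni < 0 || ni > 2 || nj < 0 || nj > 2 || nk < 0 || nk > 2) continue;
        int np = ni + nj * 3 + nk * 9;
        if (np == 13 || seen[np] || cube[np] || !in18(np)) continue;
        seen[np] = 1;
        stack.push_back(np);
      }
    }
  }
  return ncomp;
}

inline int n_fg_neighbours(const char cube[27]) {
  int n = 0;
  for (int s = 0; s < 27; ++s)
    if (s != 13 && cube[s]) ++n;
  return n;
}

inline bool is_simple(const char cube[27]) {
  return fg_components26(cube) == 1 && bg_components6(cube) == 1;
}

}  // namespace

// ---------------------------------------------------------------------------
// Chamfer distance transform (3-4-5 weights, two raster sweeps): distance
// from each foreground voxel to the nearest background voxel.
// [[Rcpp::export]]
IntegerVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  long n = g.size();
  if ((long)mask.size() != n) stop("mask length does not match dims");
  const int BIG = INT_MAX / 4;
  IntegerVector dt(n);
  for (long p = 0; p < n; ++p) dt[p] = mask[p] ? BIG : 0;
  std::vector<std::array<int, 3>> offs = neighbour_offsets(3, 26);
  auto weight = [](const std::array<int, 3>& o) {
    int m = std::abs(o[0]) + std::abs(o[1]) + std::abs(o[2]);
    return m == 1 ? 3 : (m == 2 ? 4 : 5);
  };
  std::vector<std::array<int, 3>> fwd, bwd;
  for (const auto& o : offs) {
    long lin = o[0] + (long)o[1] * g.stride[1] + (long)o[2] * g.stride[2];
    if (lin < 0) fwd.push_back(o); else bwd.push_back(o);
  }
  for (int k = 0; k < g.d[2]; ++k)
    for (int j = 0; j < g.d[1]; ++j)
      for (int i = 0; i < g.d[0]; ++i) {
        long p = g.idx(i, j, k);
        if (!dt[p]) continue;
        int best = dt[p];
        for (const auto& o : fwd) {
          int ni = i + o[0], nj = j + o[1], nk = k + o[2];
          int v = g.inside(ni, nj, nk) ? dt[g.idx(ni, nj, nk)] : 0;
          v += weight(o);
          if (v < best) best = v;
        }
        dt[p] = best;
      }
  for (int k = g.d[2] - 1; k >= 0; --k)
    for (int j = g.d[1] - 1; j >= 0; --j)
      for (int i = g.d[0] - 1; i >= 0; --i) {
        long p = g.idx(i, j, k);
        if (!dt[p]) continue;
        int best = dt[p];
        for (const auto& o : bwd) {
          int ni = i + o[0], nj = j + o[1], nk = k + o[2];
          int v = g.inside(ni, nj, nk) ? dt[g.idx(ni, nj, nk)] : 0;
          v += weight(o);
          if (v < best) best = v;
        }
        dt[p] = best;
      }
  return dt;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims,
                         Nullable<NumericVector> priority = R_NilValue) {
  Grid g(dims);
  long n = g.size();
  if ((long)mask.size() != n) stop("mask length does not match dims");
  std::vector<char> m(n);
  for (long p = 0; p < n; ++p) m[p] = mask[p] ? 1 : 0;
  std::vector<double> prio;
  bool has_prio = priority.isNotNull();
  if (has_prio) {
    NumericVector pv(priority);
    if ((long)pv.size() != n) stop("priority length does not match dims");
    prio.assign(pv.begin(), pv.end());
  }
  char cube[27];
  if (has_prio) {
    // homotopic thinning by ordered erosion: border voxels enter a
    // min-heap keyed on intensity; the lowest is deleted when simple and
    // not an end point, so the surviving curve tracks the intensity
    // ridge (medial placement).  Stale heap entries are re-checked on
    // pop; neighbours of a deleted voxel are (re-)pushed.
    typedef std::pair<double, long> Item;
    std::priority_queue<Item, std::vector<Item>, std::greater<Item>> heap;
    auto is_border = [&](int i, int j, int k) {
      const int d6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                            {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
      for (int t = 0; t < 6; ++t) {
        int ni = i + d6[t][0], nj = j + d6[t][1], nk = k + d6[t][2];
        if (!g.inside(ni, nj, nk) || !m[g.idx(ni, nj, nk)]) return true;
      }
      return false;
    };
    for (int k = 0; k < g.d[2]; ++k)
      for (int j = 0; j < g.d[1]; ++j)
        for (int i = 0; i < g.d[0]; ++i) {
          long p = g.idx(i, j, k);
          if (m[p] && is_border(i, j, k)) heap.push({prio[p], p});
        }
    while (!heap.empty()) {
      long p = heap.top().second;
      heap.pop();
      if (!m[p]) continue;
      int i = p % g.d[0];
      int j = (p / g.stride[1]) % g.d[1];
      int k = p / g.stride[2];
      local_cube(m, g, i, j, k, cube);
      if (n_fg_neighbours(cube) <= 1) continue;  // end point
      if (!is_simple(cube)) continue;
      m[p] = 0;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = i + di, nj = j + dj, nk = k + dk;
            if ((di | dj | dk) == 0 || !g.inside(ni, nj, nk)) continue;
            long np = g.idx(ni, nj, nk);
            if (m[np]) heap.push({prio[np], np});
          }
    }
  } else {
    const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                            {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
    bool any_deleted = true;
    while (any_deleted) {
      any_deleted = false;
      for (int dctr = 0; dctr < 6; ++dctr) {
        // candidates: foreground voxels whose `dir` neighbour is background
        std::vector<long> cand;
        for (int k = 0; k < g.d[2]; ++k)
          for (int j = 0; j < g.d[1]; ++j)
            for (int i = 0; i < g.d[0]; ++i) {
              long p = g.idx(i, j, k);
              if (!m[p]) continue;
              int ni = i + dirs[dctr][0], nj = j + dirs[dctr][1],
                  nk = k + dirs[dctr][2];
              bool bg = !g.inside(ni, nj, nk) || !m[g.idx(ni, nj, nk)];
              if (bg) cand.push_back(p);
            }
        for (long p : cand) {
          if (!m[p]) continue;
          int i = p % g.d[0];
          int j = (p / g.stride[1]) % g.d[1];
          int k = p / g.stride[2];
          local_cube(m, g, i, j, k, cube);
          if (n_fg_neighbours(cube) <= 1) continue;  // end point
          if (is_simple(cube)) {
            m[p] = 0;
            any_deleted = true;
          }
        }
      }
    }
  }
  LogicalVector out(n);
  for (long p = 0; p < n; ++p) out[p] = m[p] != 0;
  return out;
}
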