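// Inner loops of the segmentation: max-min connectivity propagation from a
// seed (Dijkstra-style with a lazy max-heap) and the descending-threshold
// 26-adjacent region growth of the comparator.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Entry {
  double val;
  long long order;  // insertion counter; sign of tie_mode picks FIFO/LIFO
  int idx;
};
struct EntryLess {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.val != b.val) return a.val < b.val;
    return a.order > b.order;  // smaller order wins among equal values
  }
};

inline double affinity_of(int fc, int fe, double m, double s) {
  double t = ((fc + fe) / 2.0 - m) / s;
  return std::exp(-0.5 * t * t);
}

}  // namespace

// Max-min connectivity scene from one seed over a 6-adjacent 8-bit grid.
// values: intensities 0..255 (column-major, dims nx*ny*nz); seed0: 0-based
// linear index; lut: 256x256 affinity table (used when use_lut); otherwise
// the Gaussian pair-mean affinity of (m, s) is evaluated per link.
// aff_floor > 0 prunes links with affinity <= aff_floor. tie_mode flips the
// processing order of equal-priority queue entries (FIFO vs LIFO); the
// max-min fixpoint is provably order-invariant, the flag exists so tests
// can demonstrate that.
// [[Rcpp::export]]
NumericVector fc_propagate(IntegerVector values, IntegerVector dims,
                           int seed0, NumericMatrix lut, bool use_lut,
                           double m, double s, double aff_floor = 0.0,
                           int tie_mode = 0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  if (seed0 < 0 || seed0 >= n) stop("seed outside scene");
  NumericVector cs(n, 0.0);
  cs[seed0] = 1.0;

  std::priority_queue<Entry, std::vector<Entry>, EntryLess> q;
  long long counter = 0;
  const long long dir = (tie_mode == 0) ? 1 : -1;
  q.push({1.0, dir * counter++, seed0});

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;

  while (!q.empty()) {
    Entry top = q.top();
    q.pop();
    const int c = top.idx;
    if (top.val < cs[c]) continue;  // stale lazy-reinserted entry
    const int x = c % nx, y = (c / nx) % ny, z = static_cast<int>(c / plane);
    const int fc = values[c];
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int e = static_cast<int>(xx + static_cast<R_xlen_t>(nx) * yy +
                                     plane * zz);
      const int fe = values[e];
      const double aff =
          use_lut ? lut(fc, fe) : affinity_of(fc, fe, m, s);
      if (aff_floor > 0.0 && aff <= aff_floor) continue;
      const double fmin = (cs[c] < aff) ? cs[c] : aff;
      if (fmin > cs[e]) {
        cs[e] = fmin;
        q.push({fmin, dir * counter++, e});
      }
    }
  }
  return cs;
}

// Descending-threshold 26-adjacent region growth. Starting from the seed
// with theta_beg = f(seed), lowers theta one intensity step at a time down
// to theta_end, flooding all 26-connected voxels with intensity >= theta.
// Returns the cumulative region size per theta and, per voxel, the theta at
// which it joined (-1 if never), so any theta's region can be read back as
// join_theta >= theta. Growth stops early once the region exceeds
// max_voxels (the truncated trace is returned with attribute "truncated").
// [[Rcpp::export]]
List rrg_grow_cpp(IntegerVector values, IntegerVector dims, int seed0,
                  int theta_end, double max_voxels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  if (seed0 < 0 || seed0 >= n) stop("seed outside scene");
  const int theta_beg = values[seed0];
  if (theta_end > theta_beg) stop("theta_end exceeds the seed intensity");

  std::vector<int> join_theta(n, -1);
  // deferred[v]: frontier-adjacent voxels waiting for theta to drop to v
  std::vector<std::vector<int>> deferred(256);
  std::vector<int> stack;
  const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;

  std::vector<int> thetas, sizes;
  long long count = 0;
  bool truncated = false;

  join_theta[seed0] = theta_beg;
  ++count;
  stack.push_back(seed0);

  for (int theta = theta_beg; theta >= theta_end; --theta) {
    // admit deferred voxels whose intensity equals the new theta
    if (theta < theta_beg) {
      for (int v : deferred[theta]) {
        if (join_theta[v] < 0) {
          join_theta[v] = theta;
          ++count;
          stack.push_back(v);
        }
      }
      deferred[theta].clear();
    }
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      const int x = c % nx, y = (c / nx) % ny,
                z = static_cast<int>(c / plane);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            const int e = static_cast<int>(
                xx + static_cast<R_xlen_t>(nx) * yy + plane * zz);
            if (join_theta[e] >= 0) continue;
            const int fe = values[e];
            if (fe >= theta) {
              join_theta[e] = theta;
              ++count;
              stack.push_back(e);
            } else if (fe >= theta_end && fe >= 0 && fe < 256) {
              deferred[fe].push_back(e);
            }
          }
      }
    thetas.push_back(theta);
    sizes.push_back(static_cast<int>(count));
    if (count > max_voxels) {
      truncated = true;
      break;
    }
  }

  IntegerVector jt(join_theta.begin(), join_theta.end());
  return List::create(Named("thetas") = wrap(thetas),
                      Named("sizes") = wrap(sizes),
                      Named("join_theta") = jt,
                      Named("truncated") = truncated);
}
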