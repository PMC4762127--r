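#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Diamond lattice encoding: sites are integer triples reached from the origin
// by steps in {(+-1,+-1,+-1)} with an even number of -1's from the A sublattice
// and an odd number from B. Concretely:
//   A-site: x,y,z all even and x+y+z == 0 (mod 4); steps +(1,1,1),(1,-1,-1),(-1,1,-1),(-1,-1,1)
//   B-site: x,y,z all odd  and x+y+z == 3 (mod 4); steps are the negatives.
// Every site has exactly 4 neighbours and the bond length is sqrt(3) lattice units.

static const int STEP_A[4][3] = {{1,1,1},{1,-1,-1},{-1,1,-1},{-1,-1,1}};

static inline bool on_A(int x, int y, int z) {
  return ((x & 1) == 0) && (((x + y + z) % 4 + 4) % 4 == 0);
}

// Occupancy grid helper: cube of side 2*half+1 centred at (cx,cy,cz).
struct Grid {
  int half, dim, cx, cy, cz;
  std::vector<unsigned char> occ;
  Grid(int half_, int cx_, int cy_, int cz_)
    : half(half_), dim(2 * half_ + 1), cx(cx_), cy(cy_), cz(cz_),
      occ((size_t)dim * dim * dim, 0) {}
  inline size_t idx(int x, int y, int z) const {
    return (size_t)(x - cx + half) +
           (size_t)(y - cy + half) * dim +
           (size_t)(z - cz + half) * (size_t)dim * dim;
  }
  inline bool inside(int x, int y, int z) const {
    return std::abs(x - cx) <= half && std::abs(y - cy) <= half &&
           std::abs(z - cz) <= half;
  }
};

// ---- free coil: count SAWs of every length 1..max_steps from the origin ----

static void coil_dfs(Grid &g, int x, int y, int z, bool a_sub, int depth,
                     int max_steps, std::vector<double> &counts) {
  if (depth == max_steps) return;
  const int sgn = a_sub ? 1 : -1;
  for (int k = 0; k < 4; ++k) {
    int nx = x + sgn * STEP_A[k][0];
    int ny = y + sgn * STEP_A[k][1];
    int nz = z + sgn * STEP_A[k][2];
    size_t id = g.idx(nx, ny, nz);
    if (g.occ[id]) continue;
    counts[depth + 1] += 1.0;
    g.occ[id] = 1;
    coil_dfs(g, nx, ny, nz, !a_sub, depth + 1, max_steps, counts);
    g.occ[id] = 0;
  }
}

// Counts of self-avoiding walks from a fixed origin for each number of steps
// 1..max_steps. Symmetry reduction: the first bond is fixed (factor 4, the
// lattice coordination number) and, for walks of >= 2 steps, the second bond
// is fixed too (factor 3, the C3 symmetry about a lattice bond), so the DFS
// explores 1/12 of the full ensemble. Counts are returned as doubles; they
// are exact integers below 2^53.
// [[Rcpp::export(rng = false)]]
NumericVector saw_coil_counts(int max_steps) {
  if (max_steps < 1) stop("max_steps must be >= 1");
  std::vector<double> counts((size_t)max_steps + 1, 0.0);
  counts[1] = 4.0;
  if (max_steps >= 2) {
    Grid g(max_steps + 2, 0, 0, 0);
    // fixed prefix: (0,0,0) -> (1,1,1) -> (0,2,2)
    g.occ[g.idx(0, 0, 0)] = 1;
    g.occ[g.idx(1, 1, 1)] = 1;
    g.occ[g.idx(0, 2, 2)] = 1;
    std::vector<double> sub((size_t)max_steps + 1, 0.0);
    coil_dfs(g, 0, 2, 2, true, 2, max_steps, sub);
    counts[2] = 12.0;
    // sub[n] counts completions of the fixed 2-step prefix to length n
    for (int n = 3; n <= max_steps; ++n) counts[n] = 12.0 * sub[n];
  }
  NumericVector out(max_steps);
  for (int n = 1; n <= max_steps; ++n) out[n - 1] = counts[n];
  return out;
}

// ---- anchored walks with obstacles ----

struct AnchorCtx {
  Grid *g;
  int ex, ey, ez, n_steps;
  double count;
};

static void anchored_dfs(AnchorCtx &c, int x, int y, int z, bool a_sub,
                         int depth) {
  int rem = c.n_steps - depth;
  if (rem == 0) {
    if (x == c.ex && y == c.ey && z == c.ez) c.count += 1.0;
    return;
  }
  // reachability pruning: each step moves every coordinate by exactly 1
  int dx = std::abs(c.ex - x), dy = std::abs(c.ey - y), dz = std::abs(c.ez - z);
  if (dx > rem || dy > rem || dz > rem) return;
  if (((c.ex - x) - rem) & 1) return;  // parity per coordinate
  const int sgn = a_sub ? 1 : -1;
  Grid &g = *c.g;
  for (int k = 0; k < 4; ++k) {
    int nx = x + sgn * STEP_A[k][0];
    int ny = y + sgn * STEP_A[k][1];
    int nz = z + sgn * STEP_A[k][2];
    size_t id = g.idx(nx, ny, nz);
    if (g.occ[id]) continue;
    g.occ[id] = 1;
    anchored_dfs(c, nx, ny, nz, !a_sub, depth + 1);
    g.occ[id] = 0;
  }
}

// Exact count of self-avoiding walks of exactly n_steps from `start` to `end`
// avoiding `obstacles` (an integer matrix with one site per row). Anchors and
// obstacles use the integer site encoding described above. Returns 0 for
// parity-incompatible anchors.
// [[Rcpp::export(rng = false)]]
double saw_anchored_count(IntegerVector start, IntegerVector end, int n_steps,
                          IntegerMatrix obstacles) {
  if (start.size() != 3 || end.size() != 3) stop("anchors must be length-3 integer vectors");
  if (n_steps < 0) stop("n_steps must be >= 0");
  bool sa = on_A(start[0], start[1], start[2]);
  if (n_steps == 0)
    return (start[0] == end[0] && start[1] == end[1] && start[2] == end[2]) ? 1.0 : 0.0;
  // sublattice parity: even walks join like sublattices, odd walks unlike
  bool ea = on_A(end[0], end[1], end[2]);
  if (((n_steps % 2) == 0) != (sa == ea)) return 0.0;
  Grid g(n_steps + 2, start[0], start[1], start[2]);
  for (int i = 0; i < obstacles.nrow(); ++i) {
    int ox = obstacles(i, 0), oy = obstacles(i, 1), oz = obstacles(i, 2);
    if (ox == end[0] && oy == end[1] && oz == end[2]) return 0.0;
    if (ox == start[0] && oy == start[1] && oz == start[2]) return 0.0;
    if (g.inside(ox, oy, oz)) g.occ[g.idx(ox, oy, oz)] = 1;
  }
  if (!g.inside(end[0], end[1], end[2])) return 0.0;
  g.occ[g.idx(start[0], start[1], start[2])] = 1;
  AnchorCtx c{&g, end[0], end[1], end[2], n_steps, 0.0};
  anchored_dfs(c, start[0], start[1], start[2], sa, 0);
  return c.count;
}
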