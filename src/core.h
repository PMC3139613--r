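#ifndef MYXOGLIDE_CORE_H
#define MYXOGLIDE_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <array>

namespace myxo {

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64.  One independent stream per
// stochastic subsystem, so disabling one behavioral rule leaves the draw
// sequences of the others untouched (replayable mutant presets).
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t seed_val, uint64_t stream) {
    uint64_t x = seed_val ^ (0xA0761D6478BD642FULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t out = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return out;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double unif(double a, double b) { return a + (b - a) * unif(); }

  // standard normal: Box-Muller, no spare caching (fixed draw cost)
  double norm() {
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) *
           std::cos(6.283185307179586 * u2);
  }
  double norm(double mean, double sd) { return mean + sd * norm(); }

  // normal truncated to (lo, hi] by rejection
  double tnorm(double mean, double sd, double lo, double hi) {
    for (int i = 0; i < 10000; ++i) {
      double x = norm(mean, sd);
      if (x > lo && x <= hi) return x;
    }
    double mid = mean;
    if (mid <= lo) mid = lo + (hi - lo) * 1e-6;
    if (mid > hi) mid = hi;
    return mid;
  }

  bool coin() { return (next() & 1ULL) != 0; }
  // integer in [0, n)
  int below(int n) { return (int)(unif() * n) % n; }
};

// stream ids
enum Stream {
  STREAM_REVERSAL = 0,
  STREAM_TURNING = 1,
  STREAM_COLLISION = 2,
  STREAM_TIEBREAK = 3
};

// ---------------------------------------------------------------------------
// Periodic geometry
// ---------------------------------------------------------------------------
inline double wrap1(double x, double w) {
  double r = x - w * std::floor(x / w);
  if (r < 0) r += w;
  if (r >= w) r = 0.0;  // guard rounding at the boundary
  return r;
}

// minimum-image of a scalar displacement
inline double mimg1(double d, double w) {
  return d - w * std::round(d / w);
}

inline double deg2rad(double d) { return d * 0.017453292519943295; }
inline double rad2deg(double r) { return r * 57.29577951308232; }

// rotate unit vector by signed degrees (counterclockwise positive)
inline void rotate2(double vx, double vy, double deg, double &ox, double &oy) {
  double a = deg2rad(deg);
  double c = std::cos(a), s = std::sin(a);
  ox = c * vx - s * vy;
  oy = s * vx + c * vy;
}

// ---------------------------------------------------------------------------
// Slime sector accumulation: forward semicircle (acute to the heading) split
// into n_sectors angular sectors; winner = max count, ties to the smaller
// turning angle, remaining ties broken by caller-provided RNG.
// ---------------------------------------------------------------------------
struct SectorAcc {
  std::vector<double> cnt, sx, sy;
  int ns;
  explicit SectorAcc(int n_sectors)
      : cnt(n_sectors, 0.0), sx(n_sectors, 0.0), sy(n_sectors, 0.0),
        ns(n_sectors) {}

  // d = min-image displacement bin-center - leading pole, h = heading (unit)
  // returns true if the bin was inside the forward semicircle
  bool add(double dx, double dy, double h_x, double h_y, double r2,
           double count) {
    double d2 = dx * dx + dy * dy;
    if (d2 > r2 || d2 == 0.0) return false;
    double dot = dx * h_x + dy * h_y;
    if (dot <= 0.0) return false;  // acute-angle constraint
    double crs = h_x * dy - h_y * dx;
    double ang = std::atan2(crs, dot);  // in (-pi/2, pi/2) since dot > 0
    int s = (int)((ang + 1.5707963267948966) /
                  (3.141592653589793 / ns));
    if (s < 0) s = 0;
    if (s >= ns) s = ns - 1;
    cnt[s] += count;
    sx[s] += count * dx;
    sy[s] += count * dy;
    return true;
  }

  // pick winning sector; returns -1 if all empty or when the best sector
  // does not stand out against the rest (no "higher concentration"
  // direction exists in near-uniform slime, so the cell is not redirected)
  template <typename TieRng>
  int winner(TieRng &&tie, double contrast = 0.0) const {
    double best = 0.0, total = 0.0;
    for (int s = 0; s < ns; ++s) {
      if (cnt[s] > best) best = cnt[s];
      total += cnt[s];
    }
    if (best <= 0.0) return -1;
    if (contrast > 0.0 && ns > 1) {
      double mean_rest = (total - best) / (ns - 1);
      if (best < contrast * mean_rest) return -1;
    }
    std::vector<int> tied;
    for (int s = 0; s < ns; ++s)
      if (cnt[s] == best) tied.push_back(s);
    if (tied.size() == 1) return tied[0];
    // prefer the smaller turning angle (sector mid-angle closest to 0)
    double besta = 1e18;
    std::vector<int> tied2;
    for (int s : tied) {
      double mid = std::fabs(-90.0 + (s + 0.5) * 180.0 / ns);
      if (mid < besta - 1e-12) {
        besta = mid;
        tied2.clear();
        tied2.push_back(s);
      } else if (std::fabs(mid - besta) <= 1e-12) {
        tied2.push_back(s);
      }
    }
    if (tied2.size() == 1) return tied2[0];
    return tied2[tie((int)tied2.size())];
  }
};

// ---------------------------------------------------------------------------
// Node-chain body placement: nodes trail the leading pole along its recorded
// path at arc-length spacing L (track points oldest -> newest, newest point
// is the current leading pole; coordinates are unwrapped/continuous).
// out must hold n_nodes x 2 doubles; out[0] = leading pole.
// ---------------------------------------------------------------------------
inline void place_on_track(const std::vector<std::array<double, 2>> &track,
                           const std::vector<double> &cum, int n_nodes,
                           double L, double *outx, double *outy) {
  int m = (int)track.size();
  double end = cum[m - 1];
  int seg = m - 1;  // walk backwards through segments [seg-1, seg]
  for (int j = 0; j < n_nodes; ++j) {
    double target = end - j * L;  // arc position of node j from track start
    while (seg > 0 && cum[seg - 1] > target) --seg;
    if (seg == 0) {  // beyond the oldest point: clamp
      outx[j] = track[0][0];
      outy[j] = track[0][1];
      continue;
    }
    double c0 = cum[seg - 1], c1 = cum[seg];
    double f = (c1 > c0) ? (target - c0) / (c1 - c0) : 0.0;
    if (f < 0) f = 0;
    if (f > 1) f = 1;
    outx[j] = track[seg - 1][0] + f * (track[seg][0] - track[seg - 1][0]);
    outy[j] = track[seg - 1][1] + f * (track[seg][1] - track[seg - 1][1]);
  }
}

// ---------------------------------------------------------------------------
// Iterate nonzero slime bins inside the forward semicircle of radius r
// ahead of the wrapped leading pole (pxq, pyq) with unit heading (hx, hy).
// counts: column-major nbx x nby lattice covering [0,W) x [0,H); bins are
// W/nbx x H/nby.  excl: 0-based linear bin indices to skip (a cell's own
// freshly deposited trail).  fn(ix, iy, dx, dy, count) with d = min-image
// displacement from the pole to the bin center.
// ---------------------------------------------------------------------------
template <typename F>
inline void for_each_sensed(const int *counts, int nbx, int nby, double W,
                            double H, double pxq, double pyq, double hx,
                            double hy, double r, const int *excl, int nexcl,
                            F &&fn) {
  double bx = W / nbx, by = H / nby;
  int ix0 = (int)std::floor((pxq - r) / bx);
  int ix1 = (int)std::floor((pxq + r) / bx);
  int iy0 = (int)std::floor((pyq - r) / by);
  int iy1 = (int)std::floor((pyq + r) / by);
  if (ix1 - ix0 + 1 > nbx) { ix0 = 0; ix1 = nbx - 1; }
  if (iy1 - iy0 + 1 > nby) { iy0 = 0; iy1 = nby - 1; }
  double r2 = r * r;
  for (int iy = iy0; iy <= iy1; ++iy) {
    int wiy = ((iy % nby) + nby) % nby;
    double cy = (wiy + 0.5) * by;
    for (int ix = ix0; ix <= ix1; ++ix) {
      int wix = ((ix % nbx) + nbx) % nbx;
      int c = counts[(size_t)wiy * nbx + wix];
      if (c <= 0) continue;
      int lin = wiy * nbx + wix;
      bool skip = false;
      for (int t = 0; t < nexcl; ++t)
        if (excl[t] == lin) { skip = true; break; }
      if (skip) continue;
      double cx = (wix + 0.5) * bx;
      double dx = mimg1(cx - pxq, W);
      double dy = mimg1(cy - pyq, H);
      double d2 = dx * dx + dy * dy;
      if (d2 > r2 || d2 == 0.0) continue;
      if (dx * hx + dy * hy <= 0.0) continue;  // forward semicircle only
      fn(wix, wiy, dx, dy, c);
    }
  }
}

// ---------------------------------------------------------------------------
// Uniform-grid spatial index over wrapped node positions.
// ---------------------------------------------------------------------------
struct NodeGrid {
  int nx, ny;
  double gx, gy, W, H;
  std::vector<int> head;   // bucket -> first entry index, -1 terminated
  std::vector<int> nxt;    // entry -> next entry
  std::vector<int> cell_of, node_of;
  std::vector<double> px, py;

  void build(const double *nodes, int n, int stride, const int *nn,
             double W_, double H_, double target) {
    W = W_;
    H = H_;
    nx = std::max(1, (int)std::floor(W / target));
    ny = std::max(1, (int)std::floor(H / target));
    gx = W / nx;
    gy = H / ny;
    head.assign((size_t)nx * ny, -1);
    cell_of.clear();
    node_of.clear();
    px.clear();
    py.clear();
    int total = 0;
    for (int i = 0; i < n; ++i) total += nn[i];
    nxt.assign(total, -1);
    cell_of.reserve(total);
    node_of.reserve(total);
    px.reserve(total);
    py.reserve(total);
    int e = 0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < nn[i]; ++k) {
        double x = wrap1(nodes[(size_t)i * stride + 2 * k], W);
        double y = wrap1(nodes[(size_t)i * stride + 2 * k + 1], H);
        int bx = std::min(nx - 1, (int)(x / gx));
        int by = std::min(ny - 1, (int)(y / gy));
        int b = by * nx + bx;
        cell_of.push_back(i);
        node_of.push_back(k);
        px.push_back(x);
        py.push_back(y);
        nxt[e] = head[b];
        head[b] = e;
        ++e;
      }
    }
  }

  // visit all entries in buckets overlapping the square of half-side r
  // around wrapped point (x, y); fn(entry index)
  template <typename F>
  void query(double x, double y, double r, F &&fn) const {
    int bx0 = (int)std::floor((x - r) / gx);
    int bx1 = (int)std::floor((x + r) / gx);
    int by0 = (int)std::floor((y - r) / gy);
    int by1 = (int)std::floor((y + r) / gy);
    if (bx1 - bx0 + 1 > nx) { bx0 = 0; bx1 = nx - 1; }
    if (by1 - by0 + 1 > ny) { by0 = 0; by1 = ny - 1; }
    for (int by = by0; by <= by1; ++by) {
      int wby = ((by % ny) + ny) % ny;
      for (int bx = bx0; bx <= bx1; ++bx) {
        int wbx = ((bx % nx) + nx) % nx;
        for (int e = head[wby * nx + wbx]; e != -1; e = nxt[e]) fn(e);
      }
    }
  }
};

struct CollisionHit {
  int j = -1;     // partner cell (0-based), -1 = none
  int k = -1;     // partner node (0-based; 0 = its leading pole)
  double dist = 0.0;
};

// defined in ops.cpp, shared with the engine
int density_count(const double *nodes, const int *nn, int n, int stride,
                  int self, double cx, double cy, double half, double W,
                  double H);
CollisionHit collision_best(const NodeGrid &g, int self, double pxq,
                            double pyq, double wid);

}  // namespace myxo

#endif

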