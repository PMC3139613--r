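#include "core.h"

using namespace Rcpp;
using namespace myxo;

// ---- shared helpers also used by the engine -------------------------------

namespace myxo {

// brute-force count of other cells with >= 1 node inside the axis-aligned
// square of half-side `half` centered at (cx, cy); nodes row-major, wrapped
int density_count(const double *nodes, const int *nn, int n, int stride,
                  int self, double cx, double cy, double half, double W,
                  double H) {
  int cnt = 0;
  for (int j = 0; j < n; ++j) {
    if (j == self) continue;
    for (int k = 0; k < nn[j]; ++k) {
      double dx = mimg1(nodes[(size_t)j * stride + 2 * k] - cx, W);
      double dy = mimg1(nodes[(size_t)j * stride + 2 * k + 1] - cy, H);
      if (std::fabs(dx) <= half && std::fabs(dy) <= half) {
        ++cnt;
        break;
      }
    }
  }
  return cnt;
}

// nearest node of another cell strictly closer than `wid` to the wrapped
// leading pole (pxq, pyq); ties broken toward smaller (cell, node) index
CollisionHit collision_best(const NodeGrid &g, int self, double pxq,
                            double pyq, double wid) {
  CollisionHit best;
  g.query(pxq, pyq, wid, [&](int e) {
    int j = g.cell_of[e];
    if (j == self) return;
    double dx = mimg1(g.px[e] - pxq, g.W);
    double dy = mimg1(g.py[e] - pyq, g.H);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d >= wid) return;
    int k = g.node_of[e];
    if (best.j < 0 || d < best.dist - 1e-12) {
      best.j = j;
      best.k = k;
      best.dist = d;
    } else if (std::fabs(d - best.dist) <= 1e-12 &&
               (j < best.j || (j == best.j && k < best.k))) {
      best.j = j;
      best.k = k;
      best.dist = d;
    }
  });
  return best;
}

}  // namespace myxo

// ---- geometry -------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix wrap_points_cpp(NumericMatrix pts, double W, double H) {
  NumericMatrix out(pts.nrow(), 2);
  for (int i = 0; i < pts.nrow(); ++i) {
    out(i, 0) = wrap1(pts(i, 0), W);
    out(i, 1) = wrap1(pts(i, 1), H);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix min_image_cpp(NumericMatrix a, NumericMatrix b, double W,
                            double H) {
  NumericMatrix out(a.nrow(), 2);
  for (int i = 0; i < a.nrow(); ++i) {
    out(i, 0) = mimg1(b(i, 0) - a(i, 0), W);
    out(i, 1) = mimg1(b(i, 1) - a(i, 1), H);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rotate_cpp(NumericVector v, double deg) {
  double ox, oy;
  rotate2(v[0], v[1], deg, ox, oy);
  return NumericVector::create(ox, oy);
}

// orientation: unit min-image displacement lagging pole -> leading pole
// chain: m x 2 wrapped node positions, row 1 = leading pole
// [[Rcpp::export]]
NumericVector orientation_cpp(NumericMatrix chain, double W, double H) {
  int m = chain.nrow();
  double dx = mimg1(chain(0, 0) - chain(m - 1, 0), W);
  double dy = mimg1(chain(0, 1) - chain(m - 1, 1), H);
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm < 1e-12)
    stop("degenerate cell geometry: coincident leading and lagging poles");
  return NumericVector::create(dx / nrm, dy / nrm);
}

// nodes at arc-length spacing L behind the newest track point
// track: m x 2 (oldest -> newest, unwrapped); returns n_nodes x 2
// [[Rcpp::export]]
NumericMatrix place_on_track_cpp(NumericMatrix track, int n_nodes, double L) {
  int m = track.nrow();
  if (m < 2) stop("track needs at least two points");
  std::vector<std::array<double, 2>> tr(m);
  std::vector<double> cum(m);
  cum[0] = 0.0;
  for (int i = 0; i < m; ++i) {
    tr[i] = {track(i, 0), track(i, 1)};
    if (i > 0) {
      double dx = tr[i][0] - tr[i - 1][0], dy = tr[i][1] - tr[i - 1][1];
      cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy);
    }
  }
  std::vector<double> ox(n_nodes), oy(n_nodes);
  place_on_track(tr, cum, n_nodes, L, ox.data(), oy.data());
  NumericMatrix out(n_nodes, 2);
  for (int j = 0; j < n_nodes; ++j) {
    out(j, 0) = ox[j];
    out(j, 1) = oy[j];
  }
  return out;
}

// ---- slime field ----------------------------------------------------------

// all nonzero bins in the forward semicircle of radius r ahead of the pole;
// exclude: 1-based linear bin indices (column-major) to ignore
// returns matrix cols: ix, iy (1-based), cx, cy, count, dx, dy
// [[Rcpp::export]]
NumericMatrix slime_sense_cpp(IntegerMatrix counts, NumericVector pole,
                              NumericVector heading, double radius, double W,
                              double H, IntegerVector exclude) {
  int nbx = counts.nrow(), nby = counts.ncol();
  std::vector<int> excl(exclude.size());
  for (int i = 0; i < exclude.size(); ++i) excl[i] = exclude[i] - 1;
  std::vector<double> rows;
  double bx = W / nbx, by = H / nby;
  for_each_sensed(&counts[0], nbx, nby, W, H, pole[0], pole[1], heading[0],
                  heading[1], radius, excl.data(), (int)excl.size(),
                  [&](int ix, int iy, double dx, double dy, int c) {
                    rows.push_back(ix + 1);
                    rows.push_back(iy + 1);
                    rows.push_back((ix + 0.5) * bx);
                    rows.push_back((iy + 0.5) * by);
                    rows.push_back(c);
                    rows.push_back(dx);
                    rows.push_back(dy);
                  });
  int nr = (int)rows.size() / 7;
  NumericMatrix out(nr, 7);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = rows[(size_t)i * 7 + j];
  colnames(out) = CharacterVector::create("ix", "iy", "cx", "cy", "count",
                                          "dx", "dy");
  return out;
}

// trail-following direction: winning angular sector of the forward
// semicircle, count-weighted centroid; NULL when nothing qualifies
// [[Rcpp::export]]
SEXP eps_direction_cpp(IntegerMatrix counts, NumericVector pole,
                       NumericVector orientation, double radius, double W,
                       double H, IntegerVector exclude, int n_sectors,
                       double contrast, int tie_seed) {
  int nbx = counts.nrow(), nby = counts.ncol();
  std::vector<int> excl(exclude.size());
  for (int i = 0; i < exclude.size(); ++i) excl[i] = exclude[i] - 1;
  SectorAcc acc(n_sectors);
  double r2 = radius * radius;
  for_each_sensed(&counts[0], nbx, nby, W, H, pole[0], pole[1],
                  orientation[0], orientation[1], radius, excl.data(),
                  (int)excl.size(),
                  [&](int, int, double dx, double dy, int c) {
                    acc.add(dx, dy, orientation[0], orientation[1], r2,
                            (double)c);
                  });
  Rng tie;
  tie.seed((uint64_t)tie_seed, STREAM_TIEBREAK);
  int w = acc.winner([&](int k) { return tie.below(k); }, contrast);
  if (w < 0) return R_NilValue;
  double nrm = std::sqrt(acc.sx[w] * acc.sx[w] + acc.sy[w] * acc.sy[w]);
  return NumericVector::create(acc.sx[w] / nrm, acc.sy[w] / nrm);
}

// ---- neighborhood queries -------------------------------------------------

// local density for every cell: neighbors with >= 1 node in the square
// measuring domain of side = the focal cell's length, centered at its
// node centroid.  nodes: n x (2*max_nodes) wrapped, NA-padded.
// [[Rcpp::export]]
IntegerVector local_density_all_cpp(NumericMatrix nodes, IntegerVector nn,
                                    NumericVector len, double W, double H) {
  int n = nodes.nrow(), stride = nodes.ncol();
  std::vector<double> buf((size_t)n * stride);
  std::vector<int> nnv(n);
  for (int i = 0; i < n; ++i) {
    nnv[i] = nn[i];
    for (int j = 0; j < stride; ++j) buf[(size_t)i * stride + j] = nodes(i, j);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    // unwrap chain relative to the leading pole to get a consistent centroid
    double px = buf[(size_t)i * stride], py = buf[(size_t)i * stride + 1];
    double cx = px, cy = py, ux = px, uy = py;
    for (int k = 1; k < nnv[i]; ++k) {
      ux += mimg1(buf[(size_t)i * stride + 2 * k] - ux, W);
      uy += mimg1(buf[(size_t)i * stride + 2 * k + 1] - uy, H);
      cx += ux;
      cy += uy;
    }
    cx = wrap1(cx / nnv[i], W);
    cy = wrap1(cy / nnv[i], H);
    out[i] = density_count(buf.data(), nnv.data(), n, stride, i, cx, cy,
                           len[i] / 2.0, W, H);
  }
  return out;
}

// leading-pole collision partner for every cell (same grid query the
// engine uses). returns n x 3: partner (1-based, 0 = none), node, dist
// [[Rcpp::export]]
NumericMatrix detect_collision_cpp(NumericMatrix nodes, IntegerVector nn,
                                   NumericVector wid, double W, double H) {
  int n = nodes.nrow(), stride = nodes.ncol();
  std::vector<double> buf((size_t)n * stride);
  std::vector<int> nnv(n);
  for (int i = 0; i < n; ++i) {
    nnv[i] = nn[i];
    for (int j = 0; j < stride; ++j) buf[(size_t)i * stride + j] = nodes(i, j);
  }
  NodeGrid grid;
  grid.build(buf.data(), n, stride, nnv.data(), W, H, 2.5);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double pxq = wrap1(buf[(size_t)i * stride], W);
    double pyq = wrap1(buf[(size_t)i * stride + 1], H);
    CollisionHit hit = collision_best(grid, i, pxq, pyq, wid[i]);
    out(i, 0) = hit.j < 0 ? 0 : hit.j + 1;
    out(i, 1) = hit.j < 0 ? NA_REAL : hit.k + 1;
    out(i, 2) = hit.j < 0 ? NA_REAL : hit.dist;
  }
  colnames(out) = CharacterVector::create("partner", "node", "dist");
  return out;
}

// density-connected clustering under the min-image metric: core points have
// >= k other points within `radius`; clusters are connected components of
// core points linked at distance <= radius. labels: 0 = unclustered.
// [[Rcpp::export]]
IntegerVector density_cluster_cpp(NumericMatrix pos, double W, double H,
                                  double radius, int k) {
  int n = pos.nrow();
  std::vector<double> buf((size_t)n * 2);
  std::vector<int> one(n, 1);
  for (int i = 0; i < n; ++i) {
    buf[2 * i] = wrap1(pos(i, 0), W);
    buf[2 * i + 1] = wrap1(pos(i, 1), H);
  }
  NodeGrid grid;
  double target = std::max(radius, std::min(W, H) / 64.0);
  grid.build(buf.data(), n, 2, one.data(), W, H, target);
  double r2 = radius * radius;

  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    grid.query(buf[2 * i], buf[2 * i + 1], radius, [&](int e) {
      int j = grid.cell_of[e];
      if (j == i) return;
      double dx = mimg1(grid.px[e] - buf[2 * i], W);
      double dy = mimg1(grid.py[e] - buf[2 * i + 1], H);
      if (dx * dx + dy * dy <= r2) ++cnt;
    });
    core[i] = cnt >= k;
  }

  IntegerVector labels(n, 0);
  int lab = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != 0) continue;
    ++lab;
    labels[i] = lab;
    stack.push_back(i);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      grid.query(buf[2 * u], buf[2 * u + 1], radius, [&](int e) {
        int v = grid.cell_of[e];
        if (!core[v] || labels[v] != 0) return;
        double dx = mimg1(grid.px[e] - buf[2 * u], W);
        double dy = mimg1(grid.py[e] - buf[2 * u + 1], H);
        if (dx * dx + dy * dy <= r2) {
          labels[v] = lab;
          stack.push_back(v);
        }
      });
    }
  }
  return labels;
}
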