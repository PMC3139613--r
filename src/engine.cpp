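#include "core.h"

using namespace Rcpp;
using namespace myxo;

// decision modes (one-hot per cell per step)
enum Mode {
  M_REVERSED = 1,
  M_COLLISION_ALIGN = 2,
  M_COLLISION_POLE = 3,
  M_EPS_FOLLOW = 4,
  M_ACTIVE_TURN = 5,
  M_STRAIGHT = 6
};

// The per-step motility algorithm, strict priority:
//   (a) reversal clock (+ quorum modulation; no movement that step)
//   (b) collision: pole-to-side alignment or pole-to-pole pass/reverse
//   (c) EPS slime trail following (acute-angle sector rule)
//   (d) active turning when the turn timer has elapsed
//   else straight along the tail-to-head orientation.
// Decisions read the previous step's positions of all other cells
// (synchronous read); movement and slime deposition are applied after
// every cell has decided.
// [[Rcpp::export]]
List engine_run_cpp(List state, List cfg, List run) {
  // ---- unpack state ----
  NumericMatrix nodes0 = state["nodes"];
  IntegerVector n_nodes = state["n_nodes"];
  NumericVector cell_len = state["length"];
  NumericVector cell_wid = state["width"];
  NumericVector seg_len = state["seg_len"];
  NumericVector period_base = clone(as<NumericVector>(state["period_base"]));
  NumericVector period_cur = clone(as<NumericVector>(state["period_cur"]));
  NumericVector phase = clone(as<NumericVector>(state["phase"]));
  NumericVector turn_int = clone(as<NumericVector>(state["turn_interval"]));
  NumericVector last_turn = clone(as<NumericVector>(state["last_turn"]));
  IntegerMatrix slime = clone(as<IntegerMatrix>(state["slime"]));

  // ---- unpack config ----
  double speed = cfg["speed"], dt = cfg["dt"];
  double W = cfg["width"], H = cfg["height"];
  bool reversal_on = cfg["reversal_on"], quorum_on = cfg["quorum_on"];
  bool eps_on = cfg["eps_on"], turning_on = cfg["turning_on"];
  NumericMatrix qtab = cfg["quorum_table"];  // cols: dlo dhi plo phi
  int deposit_rate = cfg["deposit_rate"];
  int n_sectors = cfg["n_sectors"];
  double eps_contrast = cfg["eps_contrast"];
  double sense_radius = cfg["sense_radius"];  // <= 0: per-cell length
  double turn_mean = cfg["turn_mean"], turn_sd = cfg["turn_sd"];
  double turn_max = cfg["turn_max"];
  double turn_int_mean = cfg["turn_interval_mean"];
  double turn_int_sd = cfg["turn_interval_sd"];
  double pass_min = cfg["pass_min"], pass_max = cfg["pass_max"];

  // ---- unpack run options ----
  int n_steps = run["n_steps"];
  int step0 = run["step0"];
  double t0 = run["t0"];
  double rng_seed = run["seed"];
  int snap_every = run["snap_every"];  // steps; 0 = none
  int log_level = run["log_level"];    // 0 none, 1 sparse, 2 + EPS_FOLLOW
  bool store_path = run["store_path"];

  int n = nodes0.nrow();
  const int stride = nodes0.ncol();  // 2 * max nodes
  int nbx = slime.nrow(), nby = slime.ncol();

  Rng rng_rev, rng_turn, rng_coll, rng_tie;
  rng_rev.seed((uint64_t)rng_seed, STREAM_REVERSAL);
  rng_turn.seed((uint64_t)rng_seed, STREAM_TURNING);
  rng_coll.seed((uint64_t)rng_seed, STREAM_COLLISION);
  rng_tie.seed((uint64_t)rng_seed, STREAM_TIEBREAK);

  // unwrapped chains (row-major), from wrapped input via min-image steps
  std::vector<double> X((size_t)n * stride, 0.0);
  std::vector<int> nnv(n);
  for (int i = 0; i < n; ++i) {
    nnv[i] = n_nodes[i];
    X[(size_t)i * stride] = nodes0(i, 0);
    X[(size_t)i * stride + 1] = nodes0(i, 1);
    for (int k = 1; k < nnv[i]; ++k) {
      X[(size_t)i * stride + 2 * k] =
          X[(size_t)i * stride + 2 * (k - 1)] +
          mimg1(nodes0(i, 2 * k) - nodes0(i, 2 * (k - 1)), W);
      X[(size_t)i * stride + 2 * k + 1] =
          X[(size_t)i * stride + 2 * (k - 1) + 1] +
          mimg1(nodes0(i, 2 * k + 1) - nodes0(i, 2 * (k - 1) + 1), H);
    }
  }

  // leading-pole waypoint tracks (oldest -> newest; newest = current pole)
  std::vector<std::vector<std::array<double, 2>>> track(n);
  std::vector<std::vector<double>> tcum(n);
  auto rebuild_track_from_chain = [&](int i) {
    int m = nnv[i];
    track[i].resize(m);
    tcum[i].resize(m);
    for (int k = 0; k < m; ++k) {  // node m-1 (lagging) first, pole last
      track[i][k] = {X[(size_t)i * stride + 2 * (m - 1 - k)],
                     X[(size_t)i * stride + 2 * (m - 1 - k) + 1]};
      tcum[i][k] = k == 0 ? 0.0
                          : tcum[i][k - 1] +
                                std::hypot(track[i][k][0] - track[i][k - 1][0],
                                           track[i][k][1] - track[i][k - 1][1]);
    }
  };
  for (int i = 0; i < n; ++i) rebuild_track_from_chain(i);

  // per-cell ring of recently deposited bin ids (self-trail exclusion)
  std::vector<std::array<int, 8>> ring(n);
  std::vector<int> ring_len(n, 0), ring_pos(n, 0);
  for (int i = 0; i < n; ++i) ring[i].fill(-1);

  // wrapped copy for the spatial index
  std::vector<double> WN((size_t)n * stride, 0.0);
  NodeGrid grid;

  // outputs
  std::vector<double> events;  // 8 cols per event
  IntegerMatrix mode_counts(std::max(n_steps, 1), 6);
  IntegerVector n_moved(std::max(n_steps, 1));
  std::vector<double> snaps;
  std::vector<int> snap_steps;
  std::vector<double> path;  // per-step node dump when store_path
  double total_dep = 0.0;

  std::vector<int> mode(n);
  std::vector<double> dirx(n), diry(n);
  std::vector<char> do_rev(n);
  std::vector<double> orx(n), ory(n);

  auto log_event = [&](int step, int cell, int md, double angle, double dens,
                       double period, int moved) {
    double t = t0 + (step - step0) * dt;
    events.push_back(step);
    events.push_back(t);
    events.push_back(cell + 1);
    events.push_back(md);
    events.push_back(angle);
    events.push_back(dens);
    events.push_back(period);
    events.push_back(moved);
  };

  auto signed_angle = [](double ax, double ay, double bx, double by) {
    return rad2deg(std::atan2(ax * by - ay * bx, ax * bx + ay * by));
  };

  for (int s = 0; s < n_steps; ++s) {
    int gstep = step0 + s + 1;       // global step index after this step
    double t_now = t0 + (s + 1) * dt;

    // wrapped positions + spatial index (previous step's state)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < nnv[i]; ++k) {
        WN[(size_t)i * stride + 2 * k] = wrap1(X[(size_t)i * stride + 2 * k], W);
        WN[(size_t)i * stride + 2 * k + 1] =
            wrap1(X[(size_t)i * stride + 2 * k + 1], H);
      }
    grid.build(WN.data(), n, stride, nnv.data(), W, H, 2.5);

    for (int i = 0; i < n; ++i) {
      int m = nnv[i];
      double ox = X[(size_t)i * stride] - X[(size_t)i * stride + 2 * (m - 1)];
      double oy = X[(size_t)i * stride + 1] -
                  X[(size_t)i * stride + 2 * (m - 1) + 1];
      double nrm = std::hypot(ox, oy);
      orx[i] = ox / nrm;
      ory[i] = oy / nrm;
    }

    // ---- decide ----
    for (int i = 0; i < n; ++i) {
      do_rev[i] = 0;
      mode[i] = M_STRAIGHT;
      dirx[i] = orx[i];
      diry[i] = ory[i];

      // (a) reversal clock
      phase[i] += dt;
      if (reversal_on && phase[i] >= period_cur[i] - 1e-9) {
        mode[i] = M_REVERSED;
        do_rev[i] = 1;
        // centroid of own nodes for the measuring domain
        double cx = 0, cy = 0;
        int m = nnv[i];
        for (int k = 0; k < m; ++k) {
          cx += X[(size_t)i * stride + 2 * k];
          cy += X[(size_t)i * stride + 2 * k + 1];
        }
        cx = wrap1(cx / m, W);
        cy = wrap1(cy / m, H);
        int dens = density_count(WN.data(), nnv.data(), n, stride, i, cx, cy,
                                 cell_len[i] / 2.0, W, H);
        if (quorum_on) {
          bool matched = false;
          for (int r = 0; r < qtab.nrow(); ++r) {
            if (dens >= qtab(r, 0) && dens <= qtab(r, 1)) {
              period_cur[i] = rng_rev.unif(qtab(r, 2), qtab(r, 3));
              matched = true;
              break;
            }
          }
          if (!matched) period_cur[i] = period_base[i];
        }
        phase[i] = 0.0;
        if (log_level >= 1)
          log_event(gstep, i, M_REVERSED, NA_REAL, dens, period_cur[i], 0);
        continue;
      }

      // (b) collision of the leading pole with another cell's node
      double pxq = WN[(size_t)i * stride], pyq = WN[(size_t)i * stride + 1];
      CollisionHit hit = collision_best(grid, i, pxq, pyq, cell_wid[i]);
      if (hit.j >= 0) {
        if (hit.k == 0) {
          // pole-to-pole: pass by with a slight turn, or reverse (p = 1/2)
          if (rng_coll.coin()) {
            double delta = rng_coll.unif(pass_min, pass_max) *
                           (rng_coll.coin() ? 1.0 : -1.0);
            rotate2(orx[i], ory[i], delta, dirx[i], diry[i]);
            mode[i] = M_COLLISION_POLE;
            if (log_level >= 1)
              log_event(gstep, i, M_COLLISION_POLE, delta, NA_REAL, NA_REAL,
                        1);
          } else {
            mode[i] = M_COLLISION_POLE;
            do_rev[i] = 1;
            phase[i] = 0.0;
            if (log_level >= 1)
              log_event(gstep, i, M_COLLISION_POLE, NA_REAL, NA_REAL, NA_REAL,
                        0);
          }
        } else {
          // pole-to-side: align with the partner at an acute angle
          int j = hit.j, mj = nnv[j];
          double pjx = X[(size_t)j * stride] -
                       X[(size_t)j * stride + 2 * (mj - 1)];
          double pjy = X[(size_t)j * stride + 1] -
                       X[(size_t)j * stride + 2 * (mj - 1) + 1];
          double nj = std::hypot(pjx, pjy);
          pjx /= nj;
          pjy /= nj;
          double dot = orx[i] * pjx + ory[i] * pjy;
          double sgn = dot > 0 ? 1.0 : (dot < 0 ? -1.0 : (rng_tie.coin() ? 1.0 : -1.0));
          dirx[i] = sgn * pjx;
          diry[i] = sgn * pjy;
          mode[i] = M_COLLISION_ALIGN;
          if (log_level >= 1)
            log_event(gstep, i, M_COLLISION_ALIGN,
                      signed_angle(orx[i], ory[i], dirx[i], diry[i]), NA_REAL,
                      NA_REAL, 1);
        }
        continue;
      }

      // (c) EPS slime trail following
      if (eps_on) {
        double r = sense_radius > 0 ? sense_radius : cell_len[i];
        SectorAcc acc(n_sectors);
        double r2 = r * r;
        for_each_sensed(&slime[0], nbx, nby, W, H, pxq, pyq, orx[i], ory[i],
                        r, ring[i].data(), ring_len[i],
                        [&](int, int, double dx, double dy, int c) {
                          acc.add(dx, dy, orx[i], ory[i], r2, (double)c);
                        });
        int w = acc.winner([&](int k) { return rng_tie.below(k); },
                           eps_contrast);
        if (w >= 0) {
          double nrm = std::hypot(acc.sx[w], acc.sy[w]);
          dirx[i] = acc.sx[w] / nrm;
          diry[i] = acc.sy[w] / nrm;
          mode[i] = M_EPS_FOLLOW;
          if (log_level >= 2)
            log_event(gstep, i, M_EPS_FOLLOW,
                      signed_angle(orx[i], ory[i], dirx[i], diry[i]), NA_REAL,
                      NA_REAL, 1);
          continue;
        }
      }

      // (d) active turning
      if (turning_on && t_now - last_turn[i] >= turn_int[i] - 1e-9) {
        double mag = rng_turn.tnorm(turn_mean, turn_sd, 0.0, turn_max);
        double sgn = rng_turn.coin() ? 1.0 : -1.0;
        rotate2(orx[i], ory[i], sgn * mag, dirx[i], diry[i]);
        last_turn[i] = t_now;
        turn_int[i] = rng_turn.tnorm(turn_int_mean, turn_int_sd, 0.1, 1e9);
        mode[i] = M_ACTIVE_TURN;
        if (log_level >= 1)
          log_event(gstep, i, M_ACTIVE_TURN, sgn * mag, NA_REAL, NA_REAL, 1);
      }
    }

    // ---- apply ----
    int moved_cnt = 0;
    for (int i = 0; i < n; ++i) {
      int m = nnv[i];
      if (do_rev[i]) {
        // polarity reversal: flip node order; the body becomes the new track
        for (int k = 0; k < m / 2; ++k) {
          std::swap(X[(size_t)i * stride + 2 * k],
                    X[(size_t)i * stride + 2 * (m - 1 - k)]);
          std::swap(X[(size_t)i * stride + 2 * k + 1],
                    X[(size_t)i * stride + 2 * (m - 1 - k) + 1]);
        }
        rebuild_track_from_chain(i);
        continue;
      }
      ++moved_cnt;
      double step_len = speed * dt;
      double npx = X[(size_t)i * stride] + dirx[i] * step_len;
      double npy = X[(size_t)i * stride + 1] + diry[i] * step_len;
      track[i].push_back({npx, npy});
      tcum[i].push_back(tcum[i].back() + step_len);
      while (track[i].size() > 2 &&
             tcum[i].back() - tcum[i][1] > cell_len[i] + 1e-9) {
        track[i].erase(track[i].begin());
        tcum[i].erase(tcum[i].begin());
      }
      std::vector<double> oxv(m), oyv(m);
      place_on_track(track[i], tcum[i], m, seg_len[i], oxv.data(), oyv.data());
      for (int k = 0; k < m; ++k) {
        X[(size_t)i * stride + 2 * k] = oxv[k];
        X[(size_t)i * stride + 2 * k + 1] = oyv[k];
      }
      if (eps_on) {
        int bxi = std::min(nbx - 1, (int)(wrap1(oxv[m - 1], W) / (W / nbx)));
        int byi = std::min(nby - 1, (int)(wrap1(oyv[m - 1], H) / (H / nby)));
        slime(bxi, byi) += deposit_rate;
        total_dep += deposit_rate;
        int lin = byi * nbx + bxi;
        ring[i][ring_pos[i]] = lin;
        ring_pos[i] = (ring_pos[i] + 1) % m;  // keep last n_nodes deposits
        if (ring_len[i] < m) ++ring_len[i];
      }
    }
    for (int i = 0; i < n; ++i) ++mode_counts(s, mode[i] - 1);
    n_moved[s] = moved_cnt;

    if (snap_every > 0 && gstep % snap_every == 0) {
      snap_steps.push_back(gstep);
      for (int i = 0; i < n; ++i) {
        int m = nnv[i];
        double cx = 0, cy = 0;
        for (int k = 0; k < m; ++k) {
          cx += X[(size_t)i * stride + 2 * k];
          cy += X[(size_t)i * stride + 2 * k + 1];
        }
        double ox = X[(size_t)i * stride] - X[(size_t)i * stride + 2 * (m - 1)];
        double oy = X[(size_t)i * stride + 1] -
                    X[(size_t)i * stride + 2 * (m - 1) + 1];
        double nrm = std::hypot(ox, oy);
        snaps.push_back(wrap1(cx / m, W));
        snaps.push_back(wrap1(cy / m, H));
        snaps.push_back(ox / nrm);
        snaps.push_back(oy / nrm);
      }
    }
    if (store_path) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < stride / 2; ++k) {
          if (k < nnv[i]) {
            path.push_back(X[(size_t)i * stride + 2 * k]);
            path.push_back(X[(size_t)i * stride + 2 * k + 1]);
          } else {
            path.push_back(NA_REAL);
            path.push_back(NA_REAL);
          }
        }
    }
  }

  // wrapped final nodes
  NumericMatrix nodes_out(n, stride);
  std::fill(nodes_out.begin(), nodes_out.end(), NA_REAL);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < nnv[i]; ++k) {
      nodes_out(i, 2 * k) = wrap1(X[(size_t)i * stride + 2 * k], W);
      nodes_out(i, 2 * k + 1) = wrap1(X[(size_t)i * stride + 2 * k + 1], H);
    }

  int nev = (int)events.size() / 8;
  NumericMatrix ev(nev, 8);
  for (int i = 0; i < nev; ++i)
    for (int j = 0; j < 8; ++j) ev(i, j) = events[(size_t)i * 8 + j];
  colnames(ev) = CharacterVector::create("step", "time_min", "cell", "mode",
                                         "angle_deg", "density", "period_min",
                                         "moved");

  NumericMatrix snap_mat((int)snap_steps.size() * n, 4);
  {
    int r = 0;
    for (size_t i = 0; i + 3 < snaps.size(); i += 4, ++r) {
      snap_mat(r, 0) = snaps[i];
      snap_mat(r, 1) = snaps[i + 1];
      snap_mat(r, 2) = snaps[i + 2];
      snap_mat(r, 3) = snaps[i + 3];
    }
  }

  List out = List::create(
      _["nodes"] = nodes_out, _["period_cur"] = period_cur,
      _["phase"] = phase, _["turn_interval"] = turn_int,
      _["last_turn"] = last_turn, _["slime"] = slime, _["events"] = ev,
      _["mode_counts"] = mode_counts, _["n_moved"] = n_moved,
      _["snapshots"] = snap_mat,
      _["snap_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
      _["total_deposited"] = total_dep, _["steps_run"] = n_steps);
  if (store_path) {
    NumericVector pv(path.begin(), path.end());
    pv.attr("dim") =
        IntegerVector::create(stride, n, n_steps);  // (coords, cell, step)
    out["path"] = pv;
  }
  return out;
}
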