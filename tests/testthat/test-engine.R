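# Colony-engine invariants on small crowded scenes.

small_sim <- function(seed = 1, hours = 0.5, n = 40, width = 40, ...) {
  simulate_colony(myxo_config(n_cells = n, width = width, hours = hours,
                              ...),
                  seed = seed, log_level = 2, store_path = TRUE,
                  snapshot_every = 5)
}

test_that("a fixed seed reproduces the trajectory bit for bit", {
  s1 <- small_sim(seed = 42)
  s2 <- small_sim(seed = 42)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$state$nodes, s2$state$nodes)
  expect_identical(s1$state$slime, s2$state$slime)
  s3 <- small_sim(seed = 43)
  expect_false(identical(s1$state$nodes, s3$state$nodes))
})

test_that("exactly one decision mode is logged per cell per step", {
  s <- small_sim(seed = 7)
  expect_true(all(rowSums(s$mode_counts) == s$config$n_cells))
  # non-moving cells are reversals (clock or pole-to-pole reverse branch)
  rev_like <- s$mode_counts[, "REVERSED"]
  pole_rev <- table(factor(
    s$events$step[s$events$mode == "COLLISION_POLE" & s$events$moved == 0],
    levels = seq_len(nrow(s$mode_counts))))
  expect_equal(s$config$n_cells - s$n_moved,
               as.integer(rev_like + pole_rev))
})

test_that("slime totals exactly ledger the depositions of moving cells", {
  s <- small_sim(seed = 8)
  expect_equal(sum(s$state$slime), s$total_deposited)
  expect_equal(s$total_deposited, sum(s$n_moved))
  # EPS disabled: no slime, no EPS_FOLLOW decisions
  s0 <- small_sim(seed = 8, eps = FALSE)
  expect_equal(sum(s0$state$slime), 0)
  expect_equal(sum(s0$mode_counts[, "EPS_FOLLOW"]), 0)
  expect_equal(nrow(s0$events[s0$events$mode == "EPS_FOLLOW", ]), 0)
})

test_that("moving poles displace exactly v dt; reversing poles swap ends", {
  s <- small_sim(seed = 9, n = 15, hours = 0.2)
  path <- s$path  # coords x cell x step, unwrapped
  v_dt <- s$config$speed * s$config$dt
  n_steps <- dim(path)[3]
  for (i in seq_len(s$config$n_cells)) {
    m <- s$state$n_nodes[i]
    for (t in seq_len(n_steps - 1)) {
      dpole <- path[1:2, i, t + 1] - path[1:2, i, t]
      step_len <- sqrt(sum(dpole^2))
      if (abs(step_len - v_dt) > 1e-9) {
        # must be a polarity reversal: new pole = old lagging pole
        old_lag <- path[(2 * m - 1):(2 * m), i, t]
        expect_equal(path[1:2, i, t + 1], old_lag, tolerance = 1e-9)
      }
    }
  }
})

test_that("segment spacing survives crowded mixed-decision dynamics", {
  s <- small_sim(seed = 10, n = 30, hours = 0.6)  # ~3200 cell-steps
  # Euclidean inter-node spacing never exceeds L and equals L on straight
  # bodies; arc-length placement guarantees the upper bound exactly
  for (i in seq_len(s$config$n_cells)) {
    m <- s$state$n_nodes[i]
    ch <- matrix(s$state$nodes[i, seq_len(2 * m)], m, 2, byrow = TRUE)
    d <- sapply(seq_len(m - 1), function(k) {
      mi_dist_brute(ch[k, ], ch[k + 1, ], 40, 40)
    })
    expect_true(all(d <= s$state$seg_len[i] + 1e-9))
    expect_true(all(d > 0))
  }
})

test_that("quorum-off runs never modulate the reversal period", {
  s <- small_sim(seed = 11, quorum = FALSE)
  rev <- s$events[s$events$mode == "REVERSED", ]
  expect_gt(nrow(rev), 0)
  expect_equal(rev$period_min, s$state$period_base[rev$cell])
  # with quorum on, crowded scenes draw modulated periods in table ranges
  s2 <- small_sim(seed = 11, n = 80, width = 20)
  rev2 <- s2$events[s2$events$mode == "REVERSED" & s2$events$density >= 5, ]
  expect_gt(nrow(rev2), 0)
  expect_true(all(rev2$period_min >= 8 - 1e-9))
})

test_that("quorum draws land in the density class ranges", {
  s <- small_sim(seed = 12, n = 80, width = 20)  # crowded
  rev <- s$events[s$events$mode == "REVERSED", ]
  tab <- default_quorum_table()
  for (r in seq_len(nrow(tab))) {
    sel <- rev$density >= tab[r, "dlo"] & rev$density <= tab[r, "dhi"]
    if (any(sel)) {
      expect_true(all(rev$period_min[sel] >= tab[r, "plo"] - 1e-9))
      expect_true(all(rev$period_min[sel] <= min(tab[r, "phi"], 360) + 1e-9))
    }
  }
  below <- rev$density < 5
  if (any(below)) {
    expect_equal(rev$period_min[below], s$state$period_base[rev$cell[below]])
  }
})

test_that("logged EPS-follow directions are always acute", {
  s <- small_sim(seed = 13)
  eps <- s$events[s$events$mode == "EPS_FOLLOW", ]
  expect_gt(nrow(eps), 100)
  expect_true(all(abs(eps$angle_deg) < 90))
})

test_that("the engine matches the R reference rules on an RNG-free cell", {
  # single straight-gliding cell with a known period: pure clock + advance
  c0 <- myxo_config(n_cells = 1, width = 100, turning = FALSE, eps = FALSE,
                    quorum = FALSE)
  st <- initialize_colony(c0, seed = 21)
  sim <- run_colony(st, hours = 0.5, log_level = 1, snapshot_every = 0)

  cell <- make_cell(st$nodes[1, 1:2], 0, length = st$length[1], config = c0,
                    period = st$period_base[1], phase = st$phase[1])
  # orient the reference cell like the initialized one
  m <- cell$n_nodes
  cell$nodes_u <- t(vapply(seq_len(m) - 1L, function(k) {
    st$nodes[1, 1:2] - k * st$seg_len[1] *
      (mi_brute(st$nodes[1, 3:4], st$nodes[1, 1:2], 100, 100) /
         st$seg_len[1])
  }, numeric(2)))
  cell$track <- cell$nodes_u[m:1, , drop = FALSE]
  cell$nodes <- wrap_position(cell$nodes_u, c0)
  for (s in 1:90) {
    out <- check_reversal(cell, c0$dt)
    cell <- out$cell
    if (!out$reversed) {
      cell <- advance(cell, cell_orientation(cell), c0$dt)
    }
  }
  expect_equal(wrap_position(cell$nodes_u, c0),
               matrix(sim$state$nodes[1, seq_len(2 * m)], m, 2, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("snapshots appear at the configured cadence", {
  s <- simulate_colony(myxo_config(n_cells = 10, width = 30, hours = 1),
                       seed = 3, snapshot_every = 15)
  expect_equal(s$snapshot_times, c(0, 15, 30, 45, 60))
  expect_equal(nrow(s$snapshots[[2]]), 10)
})
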