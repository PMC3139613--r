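cfg <- myxo_config(n_cells = 5, width = 60)

test_that("the reversal clock fires at the threshold and flips polarity", {
  cell <- make_cell(c(30, 30), 0, length = 4, config = cfg, period = 6.24)
  cell$phase <- 6.24 - cfg$dt / 2
  o0 <- cell_orientation(cell)
  out <- check_reversal(cell, cfg$dt)
  expect_true(out$reversed)
  expect_equal(out$cell$phase, 0)
  expect_equal(cell_orientation(out$cell), -o0)
})

test_that("a fresh clock with T = 6.24 first fires on step 19", {
  # 19 steps of 1/3 min reach 6.33 >= 6.24; 18 reach 6.00
  cell <- make_cell(c(30, 30), 0, length = 4, config = cfg, period = 6.24)
  fired_at <- NA
  for (s in 1:25) {
    out <- check_reversal(cell, cfg$dt)
    cell <- out$cell
    if (out$reversed) {
      fired_at <- s
      break
    }
  }
  expect_equal(fired_at, 19)
  expect_equal(fired_at, ceiling(6.24 / (1 / 3)))  # integer-arithmetic oracle
})

test_that("an isolated reversing cell glides back and forth on one path", {
  c0 <- myxo_config(n_cells = 1, width = 200, turning = FALSE, eps = FALSE,
                    quorum = FALSE)
  st <- initialize_colony(c0, seed = 5)
  sim <- run_colony(st, hours = 1, log_level = 1, store_path = TRUE,
                    snapshot_every = 0)
  path <- sim$path  # dims: coords x cell x step (unwrapped)
  poles <- t(path[1:2, 1, ])
  rev_steps <- sim$events$step[sim$events$mode == "REVERSED"]
  expect_gte(length(rev_steps), 8)
  # the pole never leaves a single straight line...
  dir <- poles[2, ] - poles[1, ]
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(poles, 2, poles[1, ])
  perp <- rel[, 1] * dir[2] - rel[, 2] * dir[1]
  expect_lt(max(abs(perp)), 1e-6)
  # ...and oscillates on it: the visited extent is far below the total
  # distance traveled (here one reversal period's worth of gliding)
  proj <- rel %*% dir
  travel <- sum(abs(diff(proj)))
  expect_gt(travel, 200)
  expect_lt(diff(range(proj)), 40)
})

test_that("local density matches the measuring-domain definition", {
  # focal cell with 5 neighbors partly inside its square, 2 outside
  focal <- make_cell(c(32, 30), 0, length = 4, config = cfg)  # centroid (30, 30)
  inside <- lapply(1:5, function(i) {
    make_cell(c(30 + runif(1, -1, 1), 30 + runif(1, -1, 1)),
              runif(1, 0, 360), length = 4, config = cfg, id = i + 1)
  })
  outside <- lapply(6:7, function(i) {
    make_cell(c(45, 45) + i, 0, length = 4, config = cfg, id = i + 1)
  })
  set.seed(31)
  expect_equal(local_density(focal, c(list(focal), inside, outside)), 5)
  expect_equal(local_density(focal, list(focal)), 0)
})

test_that("density and collision detection match O(n^2) oracles", {
  set.seed(32)
  for (rep in 1:5) {
    sc <- random_scene(25, 40, 40)
    dens <- local_density_all_cpp(sc$nodes, sc$n_nodes, sc$length, 40, 40)
    expect_equal(dens, density_brute(sc, 40, 40))
    hits <- detect_collision_cpp(sc$nodes, sc$n_nodes, sc$width, 40, 40)
    oracle <- collision_brute(sc, 40, 40)
    expect_equal(unname(hits[, "partner"]), oracle[, 1])
    expect_equal(unname(hits[, "node"]), oracle[, 2])
  }
})

test_that("collision threshold is strictly less than one cell width", {
  # length-5 cells have width exactly 0.5 (representable in binary)
  a <- make_cell(c(20, 20), 0, length = 5, config = cfg, id = 1)
  # partner heading up (body extends down): its node 2 sits 0.3 um right
  # of a's pole
  b <- make_cell(c(20.3, 21.25), 90, length = 5, config = cfg, id = 2)
  hit <- detect_collision(a, list(a, b))
  expect_false(is.null(hit))
  expect_equal(hit$partner, 2L)
  expect_equal(hit$node, 2L)
  expect_equal(hit$dist, 0.3, tolerance = 1e-9)
  # exactly one width away: strict inequality, no collision
  b2 <- make_cell(c(20.5, 21.25), 90, length = 5, config = cfg, id = 2)
  expect_null(detect_collision(a, list(a, b2)))
})

test_that("pole-to-side alignment picks the acute-angle sign", {
  a <- make_cell(c(20, 20), 0, length = 4, config = cfg, id = 1)
  b <- make_cell(c(24, 23), 36.87, length = 4, config = cfg, id = 2)
  expect_equal(resolve_pole_to_side(a, b), cell_orientation(b),
               tolerance = 1e-9)
  b_opp <- make_cell(c(24, 20), 180, length = 4, config = cfg, id = 2)
  expect_equal(resolve_pole_to_side(a, b_opp), c(1, 0), tolerance = 1e-9)
  # orthogonal tie resolves to +/- partner orientation, deterministic seeded
  b_orth <- make_cell(c(24, 20), 90, length = 4, config = cfg, id = 2)
  set.seed(33)
  d1 <- resolve_pole_to_side(a, b_orth)
  set.seed(33)
  d2 <- resolve_pole_to_side(a, b_orth)
  expect_equal(d1, d2)
  expect_equal(abs(d1), c(0, 1), tolerance = 1e-9)
})

test_that("pole-to-pole collisions reverse half the time, else turn slightly", {
  set.seed(34)
  n <- 2000
  reversed <- 0
  for (i in seq_len(n)) {
    cell <- make_cell(c(20, 20), 0, length = 4, config = cfg)
    out <- resolve_pole_to_pole(cell, cfg)
    if (is.null(out$direction)) {
      reversed <- reversed + 1
      expect_equal(cell_orientation(out$cell), c(-1, 0))
      expect_equal(out$cell$phase, 0)
    } else {
      expect_gte(abs(out$angle), cfg$pass_range[1])
      expect_lte(abs(out$angle), cfg$pass_range[2])
    }
  }
  # binomial oracle: p = 0.5, 3 s.e. band
  expect_lt(abs(reversed / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("active turning honors the timer and its distributions", {
  cell <- make_cell(c(20, 20), 0, length = 4, config = cfg)
  cell$turn_interval <- 3
  expect_null(check_active_turn(cell, now = 2.9, config = cfg)$direction)
  set.seed(35)
  angs <- replicate(2000, {
    cl <- make_cell(c(20, 20), 0, length = 4, config = cfg)
    cl$turn_interval <- 0
    check_active_turn(cl, now = 1, config = cfg)$angle
  })
  expect_true(all(abs(angs) > 0 & abs(angs) <= 90))
  m_oracle <- tnorm_mean(30, 10, 0, 90)
  expect_lt(abs(mean(abs(angs)) - m_oracle),
            3 * sd(abs(angs)) / sqrt(length(angs)))
  expect_lt(abs(mean(angs > 0) - 0.5), 3 * sqrt(0.25 / length(angs)))
})

test_that("decide applies the strict mode priority", {
  set.seed(36)
  field <- slime_field(cfg, 0.5)
  # (a) beats (b): expiring clock with a collision present
  a <- make_cell(c(20, 20), 0, length = 4, config = cfg, id = 1)
  b <- make_cell(c(20.2, 22), 270, length = 4, config = cfg, id = 2)
  a$phase <- a$period_cur
  out <- decide(a, list(a, b), field, now = cfg$dt, config = cfg)
  expect_equal(out$mode, "REVERSED")
  expect_null(out$direction)
  # nothing around, timer not elapsed: straight along the orientation
  solo <- make_cell(c(40, 40), 0, length = 4, config = cfg, id = 3, phase = 0)
  solo$turn_interval <- 100
  out <- decide(solo, list(solo), field, now = cfg$dt, config = cfg)
  expect_equal(out$mode, "STRAIGHT")
  expect_equal(out$direction, c(1, 0))
  # (c) beats (d): slime ahead with the turn timer elapsed
  f2 <- slime_field(cfg, 0.5)
  for (i in 1:5) f2 <- slime_deposit(f2, c(42, 41.5))
  solo$turn_interval <- 0
  out <- decide(solo, list(solo), f2, now = 10, config = cfg)
  expect_equal(out$mode, "EPS_FOLLOW")
})

test_that("advance moves the pole by v dt and preserves arc spacing", {
  cell <- make_cell(c(0, 0), 0, length = 4, config = cfg)
  cell2 <- advance(cell, c(1, 0), cfg$dt)
  expect_equal(cell2$nodes_u[1, ], c(1.5, 0))
  # straight motion: collinear nodes at spacing L
  for (i in 1:10) cell2 <- advance(cell2, c(1, 0), cfg$dt)
  gaps <- sqrt(rowSums(diff(cell2$nodes_u)^2))
  expect_equal(gaps, rep(cell2$seg_len, cell2$n_nodes - 1), tolerance = 1e-9)
  expect_equal(max(abs(cell2$nodes_u[, 2])), 0)
})

test_that("body placement matches the arc-length oracle on curved tracks", {
  set.seed(37)
  # circular-arc track
  th <- seq(0, pi, length.out = 80)
  arc <- cbind(20 * cos(th), 20 * sin(th))
  for (m in 3:5) {
    got <- place_on_track_cpp(arc, m, 1.3)
    expect_equal(got, place_oracle(arc, m, 1.3), tolerance = 1e-9)
  }
  # random jagged tracks
  for (rep in 1:10) {
    steps <- matrix(rnorm(40), ncol = 2)
    track <- apply(steps, 2, cumsum)
    got <- place_on_track_cpp(track, 4, 0.9)
    expect_equal(got, place_oracle(track, 4, 0.9), tolerance = 1e-9)
  }
})
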