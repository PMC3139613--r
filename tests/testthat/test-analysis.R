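dom <- list(width = 200, height = 200)

blob <- function(n, center, spread = 2.5) {
  cbind(rnorm(n, center[1], spread) %% 200, rnorm(n, center[2], spread) %% 200)
}

test_that("two tight blobs plus scatter give two clusters at 90% recruitment", {
  set.seed(41)
  pos <- rbind(blob(45, c(50, 50)), blob(45, c(150, 120)),
               cbind(runif(10, 0, 200), runif(10, 0, 200)))
  det <- detect_aggregates(pos, dom)
  expect_equal(length(det$clusters), 2)
  expect_equal(det$recruitment_fraction, 0.90)
  expect_equal(sort(det$sizes), c(45, 45))
})

test_that("uniform sparse scatter yields no clusters", {
  set.seed(42)
  pos <- cbind(runif(100, 0, 200), runif(100, 0, 200))
  det <- detect_aggregates(pos, dom)
  expect_equal(length(det$clusters), 0)
  expect_equal(det$recruitment_fraction, 0)
})

test_that("a blob straddling the periodic boundary is one cluster", {
  set.seed(43)
  pos <- rbind(blob(30, c(1, 100)), blob(30, c(199, 100)))
  det <- detect_aggregates(pos, dom)
  expect_equal(length(det$clusters), 1)
  expect_equal(det$sizes, 60L)
})

test_that("density clustering matches the brute-force oracle", {
  set.seed(44)
  for (rep in 1:4) {
    n <- 120
    pos <- rbind(blob(40, runif(2, 30, 170), spread = 3),
                 cbind(runif(n - 40, 0, 200), runif(n - 40, 0, 200)))
    labs <- density_cluster_cpp(pos, 200, 200, 8, 10L)
    oracle <- cluster_brute(pos, 200, 200, 8, 10)
    # same partition up to label names
    expect_equal(labs > 0, oracle > 0)
    for (l in unique(labs[labs > 0])) {
      members <- which(labs == l)
      expect_equal(length(unique(oracle[members])), 1)
    }
  }
})

test_that("recruitment is invariant under global translation", {
  set.seed(45)
  pos <- rbind(blob(50, c(40, 60)), cbind(runif(50, 0, 200), runif(50, 0, 200)))
  d0 <- detect_aggregates(pos, dom)
  sh <- cbind((pos[, 1] + 123.4) %% 200, (pos[, 2] + 77.7) %% 200)
  d1 <- detect_aggregates(sh, dom)
  expect_equal(d1$recruitment_fraction, d0$recruitment_fraction)
  expect_equal(sort(d1$sizes), sort(d0$sizes))
})

test_that("the density-aware core threshold rejects dense uniform scatter", {
  set.seed(46)
  # at 0.25 cells/um^2 a uniform scatter has ~50 neighbors within 8 um;
  # the calibrated threshold (about 2x that) must not call it aggregated
  w <- 63.2
  pos <- cbind(runif(1000, 0, w), runif(1000, 0, w))
  det <- detect_aggregates(pos, list(width = w, height = w))
  expect_gt(det$k, 50)
  expect_lt(det$recruitment_fraction, 0.05)
})

disc_raster <- function(r_bins, bin = 1) {
  n <- 2 * r_bins + 9
  cen <- (n + 1) / 2
  idx <- expand.grid(x = 1:n, y = 1:n)
  mask <- matrix((idx$x - cen)^2 + (idx$y - cen)^2 <= r_bins^2, n, n)
  counts <- matrix(0L, n, n)
  counts[mask] <- 1L
  list(mask = mask, counts = counts, bin_size = bin)
}

test_that("shape classes are forced on constructed footprints", {
  # filled discs are ROUND at any resolution beyond ~8 bins across
  for (r in c(5, 10, 25)) {
    sh <- shape_classify(disc_raster(r))
    expect_equal(sh$class, "ROUND")
    expect_gt(sh$circularity, 0.8)
  }
  # annulus: the middle hole persists
  ann <- disc_raster(14)
  hole <- disc_raster(9)$mask
  pad <- (nrow(ann$mask) - nrow(hole)) / 2
  full <- matrix(FALSE, nrow(ann$mask), ncol(ann$mask))
  full[pad + seq_len(nrow(hole)), pad + seq_len(nrow(hole))] <- hole
  ann$mask <- ann$mask & !full
  ann$counts[!ann$mask] <- 0L
  expect_equal(shape_classify(ann)$class, "HOLED")
  # elongated bar
  bar <- list(mask = matrix(FALSE, 60, 20), counts = matrix(0L, 60, 20),
              bin_size = 1)
  bar$mask[8:52, 8:12] <- TRUE
  bar$counts[bar$mask] <- 1L
  expect_equal(shape_classify(bar)$class, "LONG_MULTI")
  # three touching discs in a line: multiple density peaks
  three <- list(mask = matrix(FALSE, 64, 28), counts = matrix(0L, 64, 28))
  three$bin_size <- 1
  cen <- cbind(c(14, 32, 50), 14)
  idx <- expand.grid(x = 1:64, y = 1:28)
  for (j in 1:3) {
    hit <- (idx$x - cen[j, 1])^2 + (idx$y - cen[j, 2])^2 <= 81
    three$mask[cbind(idx$x[hit], idx$y[hit])] <- TRUE
    three$counts[cbind(idx$x[hit], idx$y[hit])] <-
      three$counts[cbind(idx$x[hit], idx$y[hit])] + 5L
  }
  expect_equal(shape_classify(three)$class, "LONG_MULTI")
  # degenerate
  tiny <- list(mask = matrix(c(TRUE, TRUE, rep(FALSE, 23)), 5, 5),
               counts = matrix(0L, 5, 5), bin_size = 1)
  expect_equal(shape_classify(tiny)$class, "NONE")
  expect_equal(shape_classify(NULL)$class, "NONE")
})

test_that("torus-spanning clusters cannot be rasterized to a compact shape", {
  set.seed(47)
  band <- cbind(runif(200, 0, 200), rnorm(200, 100, 2) %% 200)
  expect_null(rasterize_cluster(band, dom))
  # a boundary-straddling but compact blob still works
  compact <- rbind(blob(30, c(2, 100)), blob(30, c(198, 100)))
  ras <- rasterize_cluster(compact, dom)
  expect_false(is.null(ras))
  expect_equal(shape_classify(ras)$class, "ROUND")
})

test_that("time to aggregation finds the first persistent round epoch", {
  set.seed(48)
  sparse <- function() cbind(runif(100, 0, 200), runif(100, 0, 200))
  round_epoch <- function() rbind(blob(85, c(100, 100), 4),
                                  cbind(runif(15, 0, 200), runif(15, 0, 200)))
  times <- seq(0, 1200, by = 60)
  snaps <- lapply(times, function(t) {
    if (t >= 720) round_epoch() else sparse()
  })
  out <- time_to_aggregation(snaps, times, dom)
  expect_true(out$reached)
  expect_equal(out$time_min, 720)
  # never aggregating series
  out2 <- time_to_aggregation(lapply(times, function(t) sparse()), times, dom)
  expect_false(out2$reached)
  expect_true(is.na(out2$time_min))
  # lowering the recruitment threshold can only find earlier (or equal) times
  out3 <- time_to_aggregation(snaps, times, dom,
                              recruitment_threshold = 0.5)
  expect_lte(out3$time_min, out$time_min)
})

test_that("behavior statistics handle sparse logs without inventing zeros", {
  ev <- data.frame(step = c(10L, 14L), time_min = c(10, 14) / 3,
                   cell = c(1L, 2L),
                   mode = factor(c("REVERSED", "REVERSED"),
                                 levels = c("REVERSED", "COLLISION_ALIGN",
                                            "COLLISION_POLE", "EPS_FOLLOW",
                                            "ACTIVE_TURN", "STRAIGHT")),
                   angle_deg = NA_real_, density = c(0, 0),
                   period_min = c(6, 6), moved = c(0, 0))
  bs <- behavior_stats(ev)
  expect_equal(bs$reversal$n_intervals, 0)
  expect_true(is.na(bs$reversal$interval_mean))
  expect_equal(bs$turning$n_turns, 0)
})
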