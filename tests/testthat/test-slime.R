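cfg <- myxo_config(n_cells = 1, width = 40)

test_that("deposition increments the containing bin and conserves totals", {
  f <- slime_field(cfg, bin_size = 0.5)
  f1 <- slime_deposit(f, c(10.2, 10.2))
  expect_equal(slime_total(f1), 1)
  expect_equal(f1$counts[21, 21], 1L)  # bin [10, 10.5)
  for (i in 1:7) f1 <- slime_deposit(f1, c(10.2, 10.2))
  expect_equal(f1$counts[21, 21], 8L)
  expect_equal(slime_total(f1), 8)
})

test_that("sensing returns exactly the nonzero forward-semicircle bins", {
  set.seed(21)
  f <- slime_field(cfg, bin_size = 0.5)
  for (i in 1:200) {
    f <- slime_deposit(f, runif(2, 0, 40))
  }
  pole <- c(20, 20)
  for (ang in c(0, 45, 133, 270)) {
    h <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    got <- slime_sense(f, pole, h, radius = 4)
    # brute-force scan of every bin
    exp_rows <- 0L
    for (ix in seq_len(nrow(f$counts))) {
      for (iy in seq_len(ncol(f$counts))) {
        if (f$counts[ix, iy] == 0) next
        ctr <- c((ix - 0.5) * f$bin_x, (iy - 0.5) * f$bin_y)
        d <- mi_brute(pole, ctr, 40, 40)
        if (sum(d^2) > 16 || sum(d^2) == 0) next
        if (sum(d * h) <= 0) next
        exp_rows <- exp_rows + 1L
        expect_true(any(got$ix == ix & got$iy == iy))
      }
    }
    expect_equal(nrow(got), exp_rows)
  }
})

test_that("sensing respects the forward semicircle and exclusion list", {
  f <- slime_field(cfg, bin_size = 0.5)
  f <- slime_deposit(f, c(22, 20))  # 2 um ahead
  f <- slime_deposit(f, c(18, 20))  # 2 um behind
  got <- slime_sense(f, c(20, 20), c(1, 0), radius = 4)
  expect_equal(nrow(got), 1)
  expect_true(got$dx > 0)
  # excluding the ahead bin leaves nothing
  lin <- got$ix + (got$iy - 1) * nrow(f$counts)
  got2 <- slime_sense(f, c(20, 20), c(1, 0), radius = 4, exclude = lin)
  expect_equal(nrow(got2), 0)
})

make_cell_at <- function(pole, ang, cfg) {
  make_cell(pole, ang, length = 4, config = cfg, period = 6.24)
}

test_that("the richer sector wins and the direction is acute", {
  f <- slime_field(cfg, bin_size = 0.5)
  cell <- make_cell_at(c(20, 20), 0, cfg)
  # five points up-ahead-left vs two down-ahead-right
  for (i in 1:5) f <- slime_deposit(f, c(21.5, 22.2))
  for (i in 1:2) f <- slime_deposit(f, c(21.5, 17.8))
  d <- eps_direction(f, cell)
  expect_false(is.null(d))
  expect_gt(d[2], 0)                       # toward the 5-point region
  expect_gt(sum(d * c(1, 0)), 0)           # acute to the orientation
  # reinforcing the winning region must not change the choice
  f2 <- slime_deposit(f, c(21.5, 22.2))
  d2 <- eps_direction(f2, cell)
  expect_gt(d2[2], 0)
})

test_that("no slime or saturated uniform slime gives no redirection", {
  f <- slime_field(cfg, bin_size = 0.5)
  cell <- make_cell_at(c(20, 20), 0, cfg)
  expect_null(eps_direction(f, cell))
  # uniform saturation: no direction of higher concentration exists
  f$counts[] <- 50L
  expect_null(eps_direction(f, cell))
  # but with the contrast condition disabled a direction is returned
  expect_false(is.null(eps_direction(f, cell, contrast = 0)))
})

test_that("slime straight ahead returns the heading itself", {
  f <- slime_field(cfg, bin_size = 0.5)
  cell <- make_cell_at(c(20.25, 20.25), 0, cfg)  # bin-centered pole
  f <- slime_deposit(f, c(22.3, 20.3))
  d <- eps_direction(f, cell)
  expect_equal(as.numeric(d), c(1, 0), tolerance = 1e-9)
})

test_that("acute-angle inequality holds on random fields", {
  set.seed(22)
  for (rep in 1:30) {
    f <- slime_field(cfg, bin_size = 0.5)
    for (i in 1:40) f <- slime_deposit(f, runif(2, 0, 40))
    ang <- runif(1, 0, 360)
    cell <- make_cell_at(runif(2, 0, 40), ang, cfg)
    d <- eps_direction(f, cell)
    if (!is.null(d)) {
      expect_gt(sum(d * cell_orientation(cell)), 0)
    }
  }
})

test_that("sector choice is stable across slime bin sizes", {
  for (bs in c(0.25, 0.5, 1.0)) {
    f <- slime_field(cfg, bin_size = bs)
    cell <- make_cell_at(c(20, 20), 0, cfg)
    for (i in 1:5) f <- slime_deposit(f, c(21.6, 22.1))
    for (i in 1:2) f <- slime_deposit(f, c(21.6, 17.9))
    d <- eps_direction(f, cell)
    expect_false(is.null(d))
    expect_gt(d[2], 0)
  }
})
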