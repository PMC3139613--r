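# Independent brute-force oracles and scene builders used across the suite.
# These deliberately avoid the package's spatial-index / clustering code
# paths so they can serve as references.

# minimum-image displacement by exhaustive search over the 9 periodic images
mi_brute <- function(a, b, W, H) {
  best <- c(NA_real_, NA_real_)
  bn <- Inf
  for (sx in -1:1) {
    for (sy in -1:1) {
      d <- c(b[1] + sx * W - a[1], b[2] + sy * H - a[2])
      if (sum(d^2) < bn) {
        bn <- sum(d^2)
        best <- d
      }
    }
  }
  best
}

mi_dist_brute <- function(a, b, W, H) sqrt(sum(mi_brute(a, b, W, H)^2))

# random padded node matrix for n cells (3-5 nodes each, ~straight bodies)
random_scene <- function(n, W, H, len_range = c(3, 5)) {
  len <- runif(n, len_range[1], len_range[2])
  nn <- pmin(5L, pmax(3L, as.integer(round(len))))
  nodes <- matrix(NA_real_, n, 10)
  for (i in seq_len(n)) {
    p <- c(runif(1, 0, W), runif(1, 0, H))
    a <- runif(1, 0, 2 * pi)
    L <- len[i] / (nn[i] - 1)
    for (k in seq_len(nn[i])) {
      q <- p - (k - 1) * L * c(cos(a), sin(a))
      nodes[i, 2 * k - 1] <- q[1] %% W
      nodes[i, 2 * k] <- q[2] %% H
    }
  }
  list(nodes = nodes, n_nodes = nn, length = len, width = 0.1 * len)
}

scene_chain <- function(scene, i) {
  m <- scene$n_nodes[i]
  matrix(scene$nodes[i, seq_len(2 * m)], m, 2, byrow = TRUE)
}

# O(n^2) local-density oracle: other cells with any node inside the square
# of side len[i] centered at cell i's (unwrapped) node centroid
density_brute <- function(scene, W, H) {
  n <- nrow(scene$nodes)
  out <- integer(n)
  for (i in seq_len(n)) {
    ch <- scene_chain(scene, i)
    u <- ch
    for (k in seq_len(nrow(ch))[-1]) {
      u[k, ] <- u[k - 1, ] + mi_brute(u[k - 1, ], ch[k, ], W, H)
    }
    cen <- colMeans(u) %% c(W, H)
    half <- scene$length[i] / 2
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      cj <- scene_chain(scene, j)
      hit <- FALSE
      for (k in seq_len(nrow(cj))) {
        d <- mi_brute(cen, cj[k, ], W, H)
        if (abs(d[1]) <= half && abs(d[2]) <= half) hit <- TRUE
      }
      if (hit) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

# O(n^2) collision oracle: nearest node of another cell strictly closer
# than cell i's width to its leading pole
collision_brute <- function(scene, W, H) {
  n <- nrow(scene$nodes)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    pole <- scene_chain(scene, i)[1, ]
    bj <- 0L
    bk <- NA_integer_
    bd <- scene$width[i]
    for (j in seq_len(n)) {
      if (j == i) next
      cj <- scene_chain(scene, j)
      for (k in seq_len(nrow(cj))) {
        d <- mi_dist_brute(pole, cj[k, ], W, H)
        if (d < bd - 1e-12 ||
            (bj != 0 && abs(d - bd) <= 1e-12 &&
               (j < bj || (j == bj && k < bk)))) {
          if (d < scene$width[i]) {
            bj <- j
            bk <- k
            bd <- d
          }
        }
      }
    }
    out[i, ] <- c(bj, if (bj == 0) NA else bk, if (bj == 0) NA else bd)
  }
  out
}

# brute-force density-connected clustering (core points with >= k neighbors
# within radius, linked at <= radius)
cluster_brute <- function(pos, W, H, radius, k) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- mi_dist_brute(pos[i, ], pos[j, ], W, H)
    }
  }
  adj <- d <= radius
  diag(adj) <- FALSE
  core <- rowSums(adj) >= k
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    lab <- lab + 1L
    q <- i
    labels[i] <- lab
    while (length(q)) {
      u <- q[1]
      q <- q[-1]
      nb <- which(adj[u, ] & core & labels == 0)
      labels[nb] <- lab
      q <- c(q, nb)
    }
  }
  labels
}

# arc-length body placement oracle: walk back from the track end and put
# node j at cumulative arc distance j * L (independent of the C++ path)
place_oracle <- function(track, n_nodes, L) {
  seg <- sqrt(rowSums(diff(track)^2))
  cum <- c(0, cumsum(seg))
  end <- cum[length(cum)]
  out <- matrix(NA_real_, n_nodes, 2)
  for (j in seq_len(n_nodes)) {
    target <- end - (j - 1) * L
    if (target <= 0) {
      out[j, ] <- track[1, ]
      next
    }
    s <- max(which(cum <= target + 1e-12))
    if (s == length(cum)) {
      out[j, ] <- track[nrow(track), ]
    } else {
      f <- (target - cum[s]) / (cum[s + 1] - cum[s])
      out[j, ] <- track[s, ] + f * (track[s + 1, ] - track[s, ])
    }
  }
  out
}

# mean of a normal truncated to (lo, hi] (numeric oracle)
tnorm_mean <- function(mean, sd, lo, hi) {
  f <- function(x) x * stats::dnorm(x, mean, sd)
  stats::integrate(f, lo, hi)$value /
    (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd))
}

# expected observed interval when a latent period X ~ truncN is realized on
# the dt grid as ceiling(X / dt) * dt
quantized_mean <- function(mean, sd, dt, lo = 0.1, hi = Inf) {
  kmax <- ceiling((mean + 8 * sd) / dt)
  k <- seq_len(kmax)
  p <- stats::pnorm(pmin(k * dt, hi), mean, sd) -
    stats::pnorm(pmax((k - 1) * dt, lo), mean, sd)
  p[p < 0] <- 0
  sum(k * dt * p) / sum(p)
}
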