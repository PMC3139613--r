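#' Plot a simulation snapshot
#'
#' Renders the slime field (log scale, light blue) with cells drawn as
#' segments through their nodes, in the style of the simulation snapshots
#' used to inspect gliding patterns and aggregation centers.
#'
#' @param x a `myxo_sim`.
#' @param show_slime draw the EPS slime raster underneath the cells.
#' @param cell_col cell color.
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @export
plot.myxo_sim <- function(x, show_slime = TRUE, cell_col = "grey20", ...) {
  cfg <- x$config
  graphics::plot.new()
  graphics::plot.window(c(0, cfg$width), c(0, cfg$height), asp = 1)
  if (show_slime && sum(x$state$slime) > 0) {
    z <- log1p(t(x$state$slime))
    pal <- grDevices::colorRampPalette(c("white", "lightblue",
                                         "steelblue"))(64)
    graphics::rasterImage(
      grDevices::as.raster(matrix(
        pal[pmin(64L, 1L + as.integer(63 * z / max(z)))],
        nrow(z), ncol(z)))[nrow(z):1, , drop = FALSE],
      0, 0, cfg$width, cfg$height, interpolate = FALSE)
  }
  nodes <- x$state$nodes
  for (i in seq_len(nrow(nodes))) {
    m <- x$state$n_nodes[i]
    ch <- matrix(nodes[i, seq_len(2 * m)], m, 2, byrow = TRUE)
    # split the polyline at periodic jumps
    jump <- c(FALSE, abs(diff(ch[, 1])) > cfg$width / 2 |
                abs(diff(ch[, 2])) > cfg$height / 2)
    grp <- cumsum(jump)
    for (g in unique(grp)) {
      seg <- ch[grp == g, , drop = FALSE]
      if (nrow(seg) > 1) graphics::lines(seg, col = cell_col, lwd = 1)
      else graphics::points(seg, col = cell_col, pch = 16, cex = 0.2)
    }
  }
  graphics::box()
  graphics::title(sprintf("%d cells at t = %.1f h", cfg$n_cells,
                          x$state$time / 60))
  invisible(x)
}
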