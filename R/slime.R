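#' Create an empty EPS slime field
#'
#' The slime field is a periodic lattice of deposition counts covering the
#' domain. Cells deposit EPS points from their lagging pole into the
#' containing bin; counts never decay, so the total count is an exact ledger
#' of depositions. The lattice is sized so that an integer number of bins
#' tiles each axis (the realized bin size can therefore differ slightly from
#' the request).
#'
#' @inheritParams wrap_position
#' @param bin_size target bin size (um).
#' @param deposit_rate EPS points added per deposition event.
#' @return A `slime_field` object: a list with the integer `counts` matrix
#'   (x bins in rows, y bins in columns), realized `bin_x`/`bin_y` sizes,
#'   the domain, and the deposit rate.
#' @export
slime_field <- function(domain, bin_size = 0.5, deposit_rate = 1L) {
  d <- as_domain(domain)
  nbx <- max(1L, as.integer(round(d$width / bin_size)))
  nby <- max(1L, as.integer(round(d$height / bin_size)))
  field <- list(
    counts = matrix(0L, nbx, nby),
    bin_x = d$width / nbx, bin_y = d$height / nby,
    width = d$width, height = d$height,
    deposit_rate = as.integer(deposit_rate)
  )
  class(field) <- "slime_field"
  field
}

#' Deposit EPS slime at a position
#'
#' Increments the count of the bin containing `pos` (typically a lagging
#' pole) by the field's deposit rate.
#'
#' @param field a [slime_field()].
#' @param pos a 2-vector (um), wrapped into the domain if necessary.
#' @return The updated field.
#' @export
slime_deposit <- function(field, pos) {
  p <- wrap_position(pos, field)
  ix <- min(nrow(field$counts), 1L + as.integer(p[1] %/% field$bin_x))
  iy <- min(ncol(field$counts), 1L + as.integer(p[2] %/% field$bin_y))
  field$counts[ix, iy] <- field$counts[ix, iy] + field$deposit_rate
  field
}

#' Total EPS count in a field
#' @param field a [slime_field()].
#' @return The sum of all bin counts.
#' @export
slime_total <- function(field) sum(field$counts)

#' Sense slime in the forward semicircle
#'
#' Returns every nonzero bin whose center lies strictly ahead of the leading
#' pole (positive dot product with the heading) within `radius`, under the
#' minimum-image metric. Bins listed in `exclude` (a cell's own freshly
#' deposited trail) are ignored.
#'
#' @param field a [slime_field()].
#' @param pole leading-pole position (2-vector, um).
#' @param heading unit heading vector.
#' @param radius sensing radius (um), approximately one cell length.
#' @param exclude integer vector of linear (column-major) bin indices to
#'   skip.
#' @return A data frame with bin indices (`ix`, `iy`), bin centers
#'   (`cx`, `cy`), the `count`, and the min-image displacement from the pole
#'   (`dx`, `dy`).
#' @export
slime_sense <- function(field, pole, heading, radius,
                        exclude = integer(0)) {
  m <- slime_sense_cpp(field$counts, as.numeric(pole), as.numeric(heading),
                       radius, field$width, field$height,
                       as.integer(exclude))
  as.data.frame(m)
}

#' EPS-driven direction of movement
#'
#' Implements acute-angle trail following: the forward semicircle ahead of
#' the leading pole is split into `n_sectors` equal angular sectors; slime
#' counts are summed per sector and the cell heads toward the count-weighted
#' centroid of the richest sector. Because only bins strictly ahead of the
#' pole qualify, the returned direction always makes an acute angle with the
#' current orientation. Sector ties go to the smaller turning angle and then
#' to a seeded tie-break draw.
#'
#' @param field a [slime_field()].
#' @param cell a cell object (see [make_cell()]); its leading pole,
#'   orientation and length define the sensing geometry.
#' @param radius sensing radius (um); defaults to the cell's length.
#' @param exclude linear bin indices to ignore (own fresh trail).
#' @param n_sectors number of angular sectors.
#' @param contrast minimum ratio of the winning sector's count to the mean
#'   of the other sectors; below it no higher-concentration direction
#'   exists and `NULL` is returned. `0` disables the condition.
#' @param tie_seed seed for the tie-break draw.
#' @return A unit 2-vector, or `NULL` when no qualifying slime is sensed
#'   (the cell then proceeds to the active-turning check).
#' @export
eps_direction <- function(field, cell, radius = NULL,
                          exclude = integer(0), n_sectors = 6L,
                          contrast = 2, tie_seed = 0L) {
  if (is.null(radius)) radius <- cell$length
  o <- cell_orientation(cell)
  eps_direction_cpp(field$counts, cell$nodes[1, ], o, radius,
                    field$width, field$height, as.integer(exclude),
                    as.integer(n_sectors), contrast,
                    as.integer(tie_seed))
}

#' @export
print.slime_field <- function(x, ...) {
  cat(sprintf("<slime_field> %d x %d bins (%.3g x %.3g um), total count %d\n",
              nrow(x$counts), ncol(x$counts), x$bin_x, x$bin_y,
              sum(x$counts)))
  invisible(x)
}
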