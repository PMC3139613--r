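#' Wrap positions into the periodic domain
#'
#' @param pos a 2-vector or n x 2 matrix of positions (um).
#' @param domain a `myxo_config`, a `list(width, height)`, or a length-2
#'   numeric vector.
#' @return Positions wrapped into `[0, width) x [0, height)`, congruent to
#'   the input modulo the domain size.
#' @export
wrap_position <- function(pos, domain) {
  d <- as_domain(domain)
  p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 2)
  out <- wrap_points_cpp(p, d$width, d$height)
  if (is.matrix(pos)) out else drop(out)
}

#' Minimum-image displacement between points
#'
#' Shortest displacement `b - a` under the periodic wrap; each component has
#' magnitude at most half the corresponding domain side.
#'
#' @param a,b 2-vectors or n x 2 matrices of (wrapped) positions.
#' @inheritParams wrap_position
#' @return The displacement(s), same shape as the input.
#' @export
min_image_displacement <- function(a, b, domain) {
  d <- as_domain(domain)
  am <- if (is.matrix(a)) a else matrix(a, ncol = 2)
  bm <- if (is.matrix(b)) b else matrix(b, ncol = 2)
  out <- min_image_cpp(am, bm, d$width, d$height)
  if (is.matrix(a) || is.matrix(b)) out else drop(out)
}

#' Rotate a vector by a signed angle
#'
#' @param v a 2-vector.
#' @param angle signed angle in degrees, positive = counterclockwise.
#' @return The rotated vector (norm preserved).
#' @export
rotate_vector <- function(v, angle) {
  rotate_cpp(as.numeric(v), angle)
}

#' Cell orientation
#'
#' The unit vector pointing from the lagging pole (last node) to the leading
#' pole (first node), computed as the minimum-image displacement so that
#' cells straddling the periodic boundary keep the correct heading.
#'
#' @param cell a cell object (see [make_cell()]) or an m x 2 matrix of node
#'   positions with the leading pole in row 1.
#' @param domain domain specification; taken from the cell if omitted.
#' @return A unit 2-vector.
#' @export
cell_orientation <- function(cell, domain = NULL) {
  if (is.matrix(cell)) {
    d <- as_domain(domain)
    return(orientation_cpp(cell, d$width, d$height))
  }
  d <- as_domain(if (is.null(domain)) cell$domain else domain)
  orientation_cpp(cell$nodes, d$width, d$height)
}
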