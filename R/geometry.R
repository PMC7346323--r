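#' Ellipse parameters
#'
#' Canonical parametrisation of a disc or cup boundary: centre in pixel
#' coordinates `(row, col)`, semi-axes with `semi_major >= semi_minor > 0`,
#' and the rotation of the major axis measured from the horizontal (column)
#' axis towards increasing row, normalised to `[0, pi)`.
#'
#' @param center numeric length-2, `(row, col)`.
#' @param semi_major,semi_minor semi-axis lengths in pixels.
#' @param rotation angle in radians.
#' @return an object of class `ellipse_params`.
#' @export
ellipse_params <- function(center, semi_major, semi_minor, rotation = 0) {
  if (semi_minor > semi_major) {
    tmp <- semi_major; semi_major <- semi_minor; semi_minor <- tmp
    rotation <- rotation + pi / 2
  }
  if (semi_minor <= 0) stop_fs("ellipse semi-axes must be positive")
  rotation <- rotation %% pi
  structure(
    list(center = as.numeric(center), semi_major = semi_major,
         semi_minor = semi_minor, rotation = rotation),
    class = "ellipse_params"
  )
}

# Ellipse with given vertical/horizontal semi-extents before tilt; `tilt` is
# an extra rotation applied to the whole figure (small in practice).
ellipse_from_axes <- function(center, semi_v, semi_h, tilt = 0) {
  if (semi_v >= semi_h) {
    ellipse_params(center, semi_v, semi_h, pi / 2 + tilt)
  } else {
    ellipse_params(center, semi_h, semi_v, tilt)
  }
}

#' Vertical and horizontal extents of an ellipse
#'
#' The full extent (diameter) of the ellipse along the image row (vertical)
#' and column (horizontal) axes.
#'
#' @param e an `ellipse_params` object.
#' @return named numeric vector with `vertical` and `horizontal` extents.
#' @export
ellipse_extents <- function(e) {
  a <- e$semi_major; b <- e$semi_minor; th <- e$rotation
  # major axis direction (drow, dcol) = (sin th, cos th)
  vert <- 2 * sqrt((a * sin(th))^2 + (b * cos(th))^2)
  horiz <- 2 * sqrt((a * cos(th))^2 + (b * sin(th))^2)
  c(vertical = vert, horizontal = horiz)
}

#' Area of an ellipse
#' @param e an `ellipse_params` object.
#' @return area in squared pixels, `pi * a * b`.
#' @export
ellipse_area <- function(e) pi * e$semi_major * e$semi_minor

#' Eccentricity of an ellipse
#' @param e an `ellipse_params` object.
#' @return eccentricity in `[0, 1)`.
#' @export
ellipse_eccentricity <- function(e) {
  sqrt(max(0, 1 - (e$semi_minor / e$semi_major)^2))
}

#' Rasterise a filled ellipse
#'
#' Pixel-centre inclusion test on the implicit equation; a pixel `(r, c)`
#' belongs to the mask iff its centre lies inside or on the ellipse.
#'
#' @param params an `ellipse_params` object.
#' @param dim integer length-2 grid size `(H, W)`.
#' @return 0/1 integer matrix of size `H x W`.
#' @export
render_ellipse_mask <- function(params, dim) {
  H <- dim[1]; W <- dim[2]
  e <- params
  dr <- matrix(seq_len(H) - e$center[1], H, W)
  dc <- matrix(seq_len(W) - e$center[2], H, W, byrow = TRUE)
  co <- cos(e$rotation); si <- sin(e$rotation)
  # coordinates in the ellipse frame: u along major axis, v along minor
  u <- dc * co + dr * si
  v <- -dc * si + dr * co
  m <- (u / e$semi_major)^2 + (v / e$semi_minor)^2 <= 1
  if (!any(m)) warning("ellipse does not intersect the grid; empty mask")
  matrix(as.integer(m), H, W)
}
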