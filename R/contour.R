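#' Capsule contour
#'
#' A user-traced closed polygon in image pixel coordinates, typically the edge
#' of the fibrotic capsule delineated on the alpha-SMA channel. Vertices are
#' (x, y) pairs, 0-based, x rightward and y downward, pixel centers at integer
#' coordinates; the polygon is closed implicitly.
#'
#' @param vertices numeric matrix or data.frame with two columns (x, y) in
#'   pixel coordinates; at least 3 rows.
#' @param pixel_size_um physical pixel size in micrometers per pixel.
#' @return an object of class \code{fbr_contour}: a list with elements
#'   \code{vertices} (n x 2 matrix) and \code{pixel_size_um}.
#' @examples
#' sq <- contour(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), pixel_size_um = 1)
#' @export
contour <- function(vertices, pixel_size_um = 1) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2) stop("contour vertices must have two columns (x, y)")
  storage.mode(v) <- "double"
  if (anyNA(v)) stop("contour vertices contain missing values")
  if (nrow(v) < 3) stop("a contour needs at least 3 vertices")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (polygon_self_intersects(v)) stop("contour polygon is self-intersecting")
  if (abs(polygon_area(v)) <= 0) stop("contour encloses zero area")
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, pixel_size_um = pixel_size_um),
            class = "fbr_contour")
}

#' @export
print.fbr_contour <- function(x, ...) {
  cat(sprintf("<fbr_contour> %d vertices, area %.1f um^2 (%.3g um/px)\n",
              nrow(x$vertices),
              abs(polygon_area(x$vertices)) * x$pixel_size_um^2,
              x$pixel_size_um))
  invisible(x)
}

is_contour <- function(x) inherits(x, "fbr_contour")

# Test whether points (pixel coords) lie inside the contour polygon.
# Boundary points count as inside.
contour_contains <- function(ct, px, py) {
  v <- ct$vertices
  pracma::inpolygon(px, py, v[, 1], v[, 2], boundary = TRUE)
}
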