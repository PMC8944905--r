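# Planar geometry primitives shared by the capsule and axon modules.
# Convention: pixel centers at integer coordinates, origin top-left,
# x rightward, y downward, 0-based. A pixel (x, y) maps to matrix[y + 1, x + 1].

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a y-down coordinate frame.
#'
#' @param v numeric matrix with two columns (x, y); the closing edge from the
#'   last vertex back to the first is implicit.
#' @return signed area in squared input units.
#' @keywords internal
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Proper-intersection test between segments p1-p2 and p3-p4.
# Shared endpoints (adjacent polygon edges) do not count.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# TRUE if any two non-adjacent edges of the closed polygon cross.
# Vectorized over all edge pairs; adjacent edges (sharing a vertex) and the
# wrap-around pair are excluded.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  j <- c(2:n, 1L)
  ax <- v[, 1]; ay <- v[, 2]; bx <- v[j, 1]; by <- v[j, 2]
  ex <- bx - ax; ey <- by - ay
  cr <- function(dx, dy, pxm, pym, ox, oy)
    dx * sweep(pym, 1, oy) - dy * sweep(pxm, 1, ox)
  Px <- matrix(ax, n, n, byrow = TRUE); Py <- matrix(ay, n, n, byrow = TRUE)
  Qx <- matrix(bx, n, n, byrow = TRUE); Qy <- matrix(by, n, n, byrow = TRUE)
  d3 <- cr(ex, ey, Px, Py, ax, ay)   # start of edge j vs edge i
  d4 <- cr(ex, ey, Qx, Qy, ax, ay)   # end of edge j vs edge i
  # straddle[i, j]: endpoints of edge j lie strictly on opposite sides of
  # edge i; a proper crossing needs this in both directions
  straddle <- (d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)
  cross <- straddle & t(straddle)
  # mask self and adjacent pairs
  idx <- seq_len(n)
  adj <- abs(outer(idx, idx, "-"))
  cross[adj <= 1 | adj == n - 1] <- FALSE
  any(cross)
}

#' Minimum distance from points to a closed polygon boundary
#'
#' Exact point-to-segment distances, minimized over all edges. Vectorized over
#' points; loops over edges.
#'
#' @param px,py point coordinates (pixels).
#' @param v polygon vertex matrix (x, y), closed implicitly.
#' @return numeric vector of distances in pixel units.
#' @keywords internal
dist_to_polygon <- function(px, py, v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    bx <- v[j[i], 1]; by <- v[j[i], 2]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- ((px - ax) * ex + (py - ay) * ey) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (ax + t * ex))^2 + (py - (ay + t * ey))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# Vectorized proper-crossing test between every edge of closed polygon A and
# every edge of closed polygon B. Returns TRUE if any pair crosses.
polygons_cross <- function(va, vb) {
  na_ <- nrow(va); nb_ <- nrow(vb)
  ja <- c(2:na_, 1L); jb <- c(2:nb_, 1L)
  a1x <- va[, 1]; a1y <- va[, 2]; a2x <- va[ja, 1]; a2y <- va[ja, 2]
  b1x <- vb[, 1]; b1y <- vb[, 2]; b2x <- vb[jb, 1]; b2y <- vb[jb, 2]
  ex <- a2x - a1x; ey <- a2y - a1y          # A edge directions (length na)
  fx <- b2x - b1x; fy <- b2y - b1y          # B edge directions (length nb)
  # cross(d, p - o) for all combinations; rows index A edges, cols B edges
  cr <- function(dx, dy, pxm, pym, ox, oy)
    dx * sweep(pym, 1, oy) - dy * sweep(pxm, 1, ox)
  B1x <- matrix(b1x, na_, nb_, byrow = TRUE); B1y <- matrix(b1y, na_, nb_, byrow = TRUE)
  B2x <- matrix(b2x, na_, nb_, byrow = TRUE); B2y <- matrix(b2y, na_, nb_, byrow = TRUE)
  d3 <- cr(ex, ey, B1x, B1y, a1x, a1y)      # B start vs A edge
  d4 <- cr(ex, ey, B2x, B2y, a1x, a1y)      # B end   vs A edge
  A1x <- matrix(a1x, nb_, na_, byrow = TRUE); A1y <- matrix(a1y, nb_, na_, byrow = TRUE)
  A2x <- matrix(a2x, nb_, na_, byrow = TRUE); A2y <- matrix(a2y, nb_, na_, byrow = TRUE)
  d1 <- t(cr(fx, fy, A1x, A1y, b1x, b1y))   # A start vs B edge
  d2 <- t(cr(fx, fy, A2x, A2y, b1x, b1y))   # A end   vs B edge
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Resample a closed polygon at n points uniformly spaced by arc length,
# starting at the first vertex. Returns an n x 2 matrix.
resample_closed_polygon <- function(v, n) {
  vv <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(diff(vv[, 1])^2 + diff(vv[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  x <- approx(cum, vv[, 1], xout = s)$y
  y <- approx(cum, vv[, 2], xout = s)$y
  cbind(x = x, y = y)
}

# Regular m-gon approximation of a circle; counter-clockwise in y-down frame.
circle_polygon <- function(center, radius, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}
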