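# Automated axon counting: random sampling boxes over a region mask,
# threshold + connected-component detection, densities per box / image / mouse.

#' Randomly sample square counting boxes inside a region mask
#'
#' Draws \code{n_boxes} axis-aligned square boxes (default side 100 um, three
#' boxes per image) whose pixels all lie inside the region mask. Top-left
#' positions are sampled uniformly and independently over all valid
#' placements, so boxes may overlap.
#'
#' @param region_mask logical matrix, TRUE where boxes are allowed (e.g. the
#'   inner nerve region).
#' @param side_um box side length in micrometers (default 100).
#' @param n_boxes number of boxes (default 3).
#' @param pixel_size_um micrometers per pixel.
#' @param seed integer seed.
#' @return data.frame with columns \code{box_id}, \code{x_px}, \code{y_px}
#'   (0-based top-left), \code{side_px}, \code{side_um}.
#' @export
sample_boxes <- function(region_mask, side_um = 100, n_boxes = 3L,
                         pixel_size_um = 1, seed = 1L) {
  stopifnot(is.matrix(region_mask), side_um > 0, n_boxes >= 1)
  side_px <- max(1L, round(side_um / pixel_size_um))
  nr <- nrow(region_mask); nc <- ncol(region_mask)
  if (side_px > nr || side_px > nc) stop("region too small for a single box")
  # integral image: number of TRUE pixels in each side_px x side_px window
  cs <- apply(apply(region_mask * 1, 2, cumsum), 1, cumsum)  # transposed csum
  cs <- t(cs)
  S <- rbind(0, cbind(0, cs))
  nr2 <- nr - side_px + 1L; nc2 <- nc - side_px + 1L
  win <- S[(1 + side_px):(nr + 1), (1 + side_px):(nc + 1), drop = FALSE] -
         S[1:nr2, (1 + side_px):(nc + 1), drop = FALSE] -
         S[(1 + side_px):(nr + 1), 1:nc2, drop = FALSE] +
         S[1:nr2, 1:nc2, drop = FALSE]
  valid <- which(win == side_px^2)           # linear indices in nr2 x nc2
  if (length(valid) < 1) stop("region mask admits no full box placement")
  with_seed(seed, {
    pick <- valid[sample.int(length(valid), n_boxes, replace = TRUE)]
    row0 <- (pick - 1L) %% nr2               # 0-based row of top-left
    col0 <- (pick - 1L) %/% nr2
    data.frame(box_id = seq_len(n_boxes), x_px = col0, y_px = row0,
               side_px = side_px, side_um = side_px * pixel_size_um)
  })
}

# Otsu threshold on a numeric vector (maximizes between-class variance over a
# 256-level histogram of the value range). Scale-invariant by construction.
otsu_threshold <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)  # constant input: nothing below threshold
  nb <- 256L
  h <- tabulate(pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb), nbins = nb)
  p <- h / sum(h)
  mids <- lo + (seq_len(nb) - 0.5) / nb * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Label connected components (8-connectivity) of a logical matrix.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[j] > 0L
    if (any(hit))
      edges <- c(edges, rbind(seq_along(idx)[ok][hit], pos[j][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Count axon puncta in one sampling box
#'
#' Thresholds the box sub-image (Otsu by default, or a fixed threshold),
#' labels connected components with 8-connectivity, and counts components of
#' at least \code{min_area_px} pixels whose centroid falls inside the box.
#' The sub-image is padded by a margin so components straddling a box edge
#' are measured whole before the centroid rule is applied; two puncta that
#' merge into one component under blur count as one.
#'
#' @param image intensity matrix.
#' @param box one row of \code{\link{sample_boxes}} output (or a list with
#'   \code{x_px}, \code{y_px}, \code{side_px}).
#' @param threshold_method "otsu" or "fixed".
#' @param threshold fixed threshold value (strictly exceeded = foreground)
#'   when \code{threshold_method = "fixed"}; with Otsu, the Otsu level plays
#'   the same role.
#' @param min_area_px minimum component area in pixels (default 4, suppresses
#'   single-pixel noise at ~1 um/px).
#' @param pad_px margin around the box used for whole-component labeling
#'   (default 8).
#' @return integer count.
#' @export
detect_axons <- function(image, box, threshold_method = c("otsu", "fixed"),
                         threshold = NULL, min_area_px = 4L, pad_px = 8L) {
  threshold_method <- match.arg(threshold_method)
  x0 <- box$x_px; y0 <- box$y_px; side <- box$side_px
  if (x0 < 0 || y0 < 0 || x0 + side > ncol(image) || y0 + side > nrow(image))
    stop("box extends outside the image")
  sub <- image[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), drop = FALSE]
  if (all(sub == 0)) return(0L)
  thr <- switch(threshold_method,
                otsu = otsu_threshold(as.numeric(sub)),
                fixed = { if (is.null(threshold)) stop("threshold required"); threshold })
  # padded crop so components crossing the box edge are labeled whole
  py0 <- max(0L, y0 - pad_px); py1 <- min(nrow(image), y0 + side + pad_px)
  px0 <- max(0L, x0 - pad_px); px1 <- min(ncol(image), x0 + side + pad_px)
  crop <- image[(py0 + 1):py1, (px0 + 1):px1, drop = FALSE]
  lab <- label_components(crop > thr)
  if (max(lab) == 0L) return(0L)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(comp)
  # centroids in 0-based full-image pixel coordinates
  cx <- tapply(cc, comp, mean) - 1 + px0
  cy <- tapply(r, comp, mean) - 1 + py0
  keep <- area >= min_area_px &
    cx >= x0 & cx < x0 + side & cy >= y0 & cy < y0 + side
  sum(keep)
}

#' Axon density per box and per image
#'
#' Counts puncta in each sampling box and converts to densities per square
#' millimeter; the per-image value is the mean over its boxes.
#'
#' @param image intensity matrix (axon channel).
#' @param boxes data.frame from \code{\link{sample_boxes}}.
#' @param pixel_size_um micrometers per pixel.
#' @param ... passed to \code{\link{detect_axons}}.
#' @return list with \code{per_box} (data.frame: box_id, count,
#'   density_per_mm2) and \code{per_image_mean} (mean density).
#' @export
axon_density <- function(image, boxes, pixel_size_um = 1, ...) {
  stopifnot(nrow(boxes) >= 1)
  counts <- vapply(seq_len(nrow(boxes)), function(i)
    detect_axons(image, boxes[i, ], ...), integer(1))
  area_mm2 <- (boxes$side_px * pixel_size_um / 1000)^2
  per_box <- data.frame(box_id = boxes$box_id, count = counts,
                        density_per_mm2 = counts / area_mm2)
  list(per_box = per_box, per_image_mean = mean(per_box$density_per_mm2))
}

#' Aggregate per-image axon densities to the mouse level
#'
#' @param per_image data.frame with columns \code{subject} and
#'   \code{density_per_mm2} (one row per image).
#' @return data.frame with one row per subject and the mean density.
#' @export
aggregate_axon_density <- function(per_image) {
  stopifnot(all(c("subject", "density_per_mm2") %in% names(per_image)))
  agg <- aggregate(density_per_mm2 ~ subject, data = per_image, FUN = mean)
  names(agg)[2] <- "mean_density_per_mm2"
  agg
}
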