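# Edge-aligned capsule quantification: depth maps from a traced contour,
# intensity-vs-depth profiles, near-edge means, and capsule thickness.

#' Per-pixel depth map inside a traced contour
#'
#' For every pixel whose center lies inside the contour polygon, the depth is
#' the exact Euclidean distance (in micrometers) to the nearest point of the
#' polygon boundary. Pixels outside the contour are \code{NA}. The depth map
#' is the alignment coordinate for intensity profiles: it reparameterizes an
#' irregular capsule by distance inward from the traced implant edge.
#'
#' @param image_shape integer pair \code{c(nrow, ncol)} of the image, or an
#'   image matrix (only its dimensions are used).
#' @param ct an \code{\link{contour}} object; must lie within the image.
#' @return an \code{fbr_depth_map}: a list with \code{depth_um} (matrix, NA
#'   outside the contour) and \code{pixel_size_um}.
#' @export
compute_depth_map <- function(image_shape, ct) {
  if (is.matrix(image_shape)) image_shape <- dim(image_shape)
  stopifnot(length(image_shape) == 2)
  if (!is_contour(ct)) stop("ct must be an fbr_contour")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  v <- ct$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > nc - 1) ||
      any(v[, 2] < 0) || any(v[, 2] > nr - 1))
    stop("contour extends outside the image bounds")

  depth <- matrix(NA_real_, nr, nc)
  # bounding box in pixel indices, clipped to the image
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(nc - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(nr - 1L, ceiling(max(v[, 2])))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- contour_contains(ct, px, py)
  if (!any(inside)) stop("contour contains no pixel centers")
  d <- dist_to_polygon(px[inside], py[inside], v) * ct$pixel_size_um
  depth[cbind(py[inside] + 1L, px[inside] + 1L)] <- d
  structure(list(depth_um = depth, pixel_size_um = ct$pixel_size_um),
            class = "fbr_depth_map")
}

#' @export
print.fbr_depth_map <- function(x, ...) {
  d <- x$depth_um
  cat(sprintf("<fbr_depth_map> %d x %d px, %d interior px, max depth %.1f um\n",
              nrow(d), ncol(d), sum(!is.na(d)), max(d, na.rm = TRUE)))
  invisible(x)
}

#' Stain intensity versus depth profile
#'
#' Bins interior pixels by depth and reports the mean intensity per bin. Bin b
#' covers depths \code{[b*w, (b+1)*w)}. Bins with no pixels have \code{NA}
#' mean, never zero.
#'
#' @param image numeric matrix of pixel intensities (arbitrary units).
#' @param depth_map an \code{fbr_depth_map} congruent with \code{image}.
#' @param bin_width_um bin width in micrometers (default 1).
#' @param max_depth_um profile extent; defaults to the maximum depth present.
#' @param stain,subject,group optional labels carried into the result.
#' @return data.frame of class \code{fbr_profile} with columns
#'   \code{depth_lo_um}, \code{depth_hi_um}, \code{mean_intensity},
#'   \code{pixel_count}, \code{stain}, \code{subject}, \code{group}.
#' @export
intensity_profile <- function(image, depth_map, bin_width_um = 1,
                              max_depth_um = NULL,
                              stain = NA_character_, subject = NA_character_,
                              group = NA_character_) {
  stopifnot(inherits(depth_map, "fbr_depth_map"))
  d <- depth_map$depth_um
  if (!identical(dim(image), dim(d)))
    stop("image and depth map have different shapes")
  if (bin_width_um <= 0) stop("bin_width_um must be positive")
  ok <- !is.na(d)
  dv <- d[ok]; iv <- image[ok]
  if (is.null(max_depth_um)) max_depth_um <- max(dv)
  n_bins <- ceiling(max_depth_um / bin_width_um)
  if (n_bins < 1) stop("max_depth_um too small for one bin")
  idx <- floor(dv / bin_width_um) + 1  # bin [b*w, (b+1)*w)
  keep <- idx <= n_bins
  idx <- idx[keep]; iv2 <- iv[keep]
  cnt <- tabulate(idx, nbins = n_bins)
  sums <- rep(0, n_bins)
  agg <- tapply(iv2, idx, sum)
  sums[as.integer(names(agg))] <- agg
  means <- ifelse(cnt > 0, sums / cnt, NA_real_)
  out <- data.frame(
    depth_lo_um = (seq_len(n_bins) - 1) * bin_width_um,
    depth_hi_um = seq_len(n_bins) * bin_width_um,
    mean_intensity = means,
    pixel_count = cnt,
    stain = stain, subject = subject, group = group,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fbr_profile", "data.frame")
  out
}

#' Mean intensity near the traced edge
#'
#' Unweighted (pixel-weighted) mean intensity over all pixels with depth at
#' most \code{window_um}. The default window is 25 um; CD68 (macrophage)
#' stains are conventionally profiled to 50 um because macrophages sit deeper
#' in the tissue, and a 15 um window is also in use for near-edge summaries.
#'
#' @param image intensity matrix.
#' @param depth_map an \code{fbr_depth_map}.
#' @param window_um depth window in micrometers (> 0), default 25.
#' @return scalar mean intensity.
#' @export
near_edge_mean <- function(image, depth_map, window_um = 25) {
  stopifnot(inherits(depth_map, "fbr_depth_map"))
  if (window_um <= 0) stop("window_um must be positive")
  d <- depth_map$depth_um
  if (!identical(dim(image), dim(d)))
    stop("image and depth map have different shapes")
  sel <- !is.na(d) & d <= window_um
  if (!any(sel)) stop("no pixels within the near-edge window (degenerate contour?)")
  mean(image[sel])
}

#' Normalize per-subject means to a control group
#'
#' Each subject's value is divided by the mean value of the control group, so
#' that the control group's ratios average to exactly 1.
#'
#' @param per_subject data.frame with columns \code{subject}, \code{group},
#'   \code{value}.
#' @param control_group label of the control group (e.g. the untreated
#'   implant condition).
#' @return the input data.frame with an added \code{ratio} column.
#' @export
normalize_to_control <- function(per_subject, control_group) {
  stopifnot(all(c("subject", "group", "value") %in% names(per_subject)))
  ctl <- per_subject$value[per_subject$group == control_group]
  if (length(ctl) < 1) stop("control group '", control_group, "' not present")
  m <- mean(ctl)
  if (m == 0) stop("control group mean is zero; ratios undefined")
  per_subject$ratio <- per_subject$value / m
  per_subject
}

#' Capsule thickness from outer and inner traced boundaries
#'
#' At \code{n_positions} points uniformly spaced by arc length along the outer
#' contour, thickness is the distance to the nearest point of the inner
#' contour. The per-sample value is the mean over positions (one value per
#' subject/mouse).
#'
#' @param outer,inner \code{\link{contour}} objects; the inner boundary must
#'   lie strictly inside the outer one and the two must not touch. Both must
#'   share \code{pixel_size_um}.
#' @param n_positions number of arc-length positions (default 360).
#' @param subject,group optional labels.
#' @return list of class \code{fbr_thickness} with
#'   \code{per_sample_mean_um}, \code{per_position_thickness_um},
#'   \code{subject}, \code{group}.
#' @export
capsule_thickness <- function(outer, inner, n_positions = 360L,
                              subject = NA_character_, group = NA_character_) {
  if (!is_contour(outer) || !is_contour(inner))
    stop("outer and inner must be fbr_contour objects")
  if (outer$pixel_size_um != inner$pixel_size_um)
    stop("outer and inner contours have different pixel sizes")
  vo <- outer$vertices; vi <- inner$vertices
  if (!all(contour_contains(outer, vi[, 1], vi[, 2])))
    stop("inner contour is not contained in the outer contour")
  # strict containment: boundaries must not touch or cross
  if (polygons_cross(vo, vi))
    stop("outer and inner contours intersect")
  d_edge <- dist_to_polygon(vi[, 1], vi[, 2], vo)
  if (min(d_edge) <= .Machine$double.eps^.5)
    stop("inner contour touches the outer contour (zero thickness)")

  pts <- resample_closed_polygon(vo, as.integer(n_positions))
  th <- dist_to_polygon(pts[, 1], pts[, 2], vi) * outer$pixel_size_um
  structure(list(per_sample_mean_um = mean(th),
                 per_position_thickness_um = th,
                 subject = subject, group = group),
            class = "fbr_thickness")
}

#' @export
print.fbr_thickness <- function(x, ...) {
  cat(sprintf("<fbr_thickness> mean %.2f um over %d positions (sd %.2f)\n",
              x$per_sample_mean_um, length(x$per_position_thickness_um),
              sd(x$per_position_thickness_um)))
  invisible(x)
}

#' Group summary of depth profiles
#'
#' Across-subject mean and sample SD of intensity per depth bin, per group.
#' Subjects are the unit: the SD is over subject profiles, not pixels.
#'
#' @param profiles list of \code{\link{intensity_profile}} results sharing
#'   identical bin edges; each must carry \code{subject} and \code{group}.
#' @return data.frame with columns \code{group}, \code{depth_lo_um},
#'   \code{depth_hi_um}, \code{mean_intensity}, \code{sd_intensity},
#'   \code{n_subjects}.
#' @export
profile_group_summary <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!isTRUE(all.equal(p$depth_lo_um, ref$depth_lo_um)) ||
        !isTRUE(all.equal(p$depth_hi_um, ref$depth_hi_um)))
      stop("profiles have mismatched depth bins")
  }
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(group = p$group, subject = p$subject, bin = seq_len(nrow(p)),
               depth_lo_um = p$depth_lo_um, depth_hi_um = p$depth_hi_um,
               mean_intensity = p$mean_intensity, stringsAsFactors = FALSE)))
  sp <- split(long, list(long$group, long$bin), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$mean_intensity[!is.na(d$mean_intensity)]
    data.frame(group = d$group[1], depth_lo_um = d$depth_lo_um[1],
               depth_hi_um = d$depth_hi_um[1],
               mean_intensity = if (length(v)) mean(v) else NA_real_,
               sd_intensity = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_,
               n_subjects = length(v), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$depth_lo_um), ]
  rownames(out) <- NULL
  out
}
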