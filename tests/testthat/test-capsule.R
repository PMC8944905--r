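# Capsule quantification: depth maps, profiles, near-edge means, thickness.

test_that("depth map matches brute-force boundary distance on random 12-gons", {
  set.seed(11)
  for (rep in 1:3) {
    verts <- random_star_polygon(12, c(60, 64), 20, 50)
    ct <- contour(verts, pixel_size_um = 1)
    dm <- compute_depth_map(c(128, 128), ct)
    inside <- which(!is.na(dm$depth_um), arr.ind = TRUE)
    pick <- inside[sample.int(nrow(inside), 50), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      y <- pick[i, 1] - 1; x <- pick[i, 2] - 1
      oracle <- brute_force_boundary_dist(x, y, verts)
      expect_lt(abs(dm$depth_um[pick[i, 1], pick[i, 2]] - oracle), 0.5)
    }
  }
})

test_that("depth map geometry: vertices at zero, circle center at radius", {
  sq <- contour(cbind(c(10, 50, 50, 10), c(10, 10, 50, 50)), 1)
  dm <- compute_depth_map(c(64, 64), sq)
  expect_equal(dm$depth_um[11, 11], 0)           # pixel on a vertex
  expect_equal(dm$depth_um[31, 31], 20)          # center of the square
  circ <- contour(circle_polygon <- {
    th <- seq(0, 2 * pi, length.out = 241)[-241]
    cbind(60 + 40 * cos(th), 60 + 40 * sin(th))
  }, 1)
  dmc <- compute_depth_map(c(121, 121), circ)
  expect_lt(abs(dmc$depth_um[61, 61] - 40), 0.5) # center depth = radius
})

test_that("depth map is masked outside and rejects bad contours", {
  sq <- contour(cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)), 1)
  dm <- compute_depth_map(c(40, 40), sq)
  expect_true(is.na(dm$depth_um[1, 1]))
  expect_true(all(dm$depth_um[!is.na(dm$depth_um)] >= 0))
  # bow-tie polygon self-intersects
  expect_error(contour(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)), 1),
               "self-intersecting")
  out_of_bounds <- contour(cbind(c(10, 60, 60, 10), c(10, 10, 60, 60)), 1)
  expect_error(compute_depth_map(c(40, 40), out_of_bounds), "outside")
})

test_that("intensity profile equals per-pixel brute-force binning", {
  sp <- phantom_spec(image_size_px = c(160L, 160L), nerve_radius_um = 60,
                     capsule_thickness_um = 25, seed = 13L)
  ph <- generate_nerve_phantom(sp)
  img <- ph$channels$asma
  dm <- compute_depth_map(dim(img), ph$outer)
  pr <- intensity_profile(img, dm, bin_width_um = 1, max_depth_um = 30)
  d <- dm$depth_um
  for (b in seq_len(nrow(pr))) {
    sel <- !is.na(d) & d >= pr$depth_lo_um[b] & d < pr$depth_hi_um[b]
    if (sum(sel) == 0) {
      expect_true(is.na(pr$mean_intensity[b]))
      expect_equal(pr$pixel_count[b], 0)
    } else {
      expect_equal(pr$mean_intensity[b], mean(img[sel]))
      expect_equal(pr$pixel_count[b], sum(sel))
    }
  }
  # full-depth profile conserves the interior pixel count
  pr_all <- intensity_profile(img, dm, bin_width_um = 1)
  expect_equal(sum(pr_all$pixel_count), sum(!is.na(d)))
  # constant image: every nonempty bin mean equals the constant
  cimg <- matrix(7.5, nrow(img), ncol(img))
  prc <- intensity_profile(cimg, dm, 1, 30)
  expect_true(all(prc$mean_intensity[prc$pixel_count > 0] == 7.5))
})

test_that("near-edge mean is a pixel-weighted region mean and is local", {
  sp <- phantom_spec(image_size_px = c(160L, 160L), nerve_radius_um = 60,
                     seed = 17L)
  ph <- generate_nerve_phantom(sp)
  img <- ph$channels$asma
  dm <- compute_depth_map(dim(img), ph$outer)
  sel <- !is.na(dm$depth_um) & dm$depth_um <= 25
  expect_equal(near_edge_mean(img, dm, 25), mean(img[sel]))
  # locality: content deeper than the window cannot change the value
  img2 <- img
  img2[!is.na(dm$depth_um) & dm$depth_um > 25] <- 1e6
  expect_equal(near_edge_mean(img2, dm, 25), near_edge_mean(img, dm, 25))
  # intensity scaling scales the mean exactly
  expect_equal(near_edge_mean(3 * img, dm, 25), 3 * near_edge_mean(img, dm, 25))
  expect_error(near_edge_mean(img, dm, -5), "positive")
})

test_that("normalization to the control group divides by its mean", {
  tab <- data.frame(subject = paste0("m", 1:6),
                    group = c("NI", "NI", "NI", "Dex", "Dex", "MCC"),
                    value = c(2, 4, 6, 2, 2, 8))
  out <- normalize_to_control(tab, "NI")
  expect_equal(out$ratio, c(0.5, 1, 1.5, 0.5, 0.5, 2))   # control mean is 4
  expect_equal(mean(out$ratio[out$group == "NI"]), 1)
  half <- normalize_to_control(
    data.frame(subject = 1:4, group = c("NI", "NI", "tx", "tx"),
               value = c(10, 10, 5, 5)), "NI")
  expect_equal(half$ratio[half$group == "tx"], c(0.5, 0.5))
  expect_error(normalize_to_control(tab, "absent"), "not present")
  zero <- data.frame(subject = 1:2, group = c("NI", "tx"), value = c(0, 1))
  expect_error(normalize_to_control(zero, "NI"), "zero")
})

test_that("capsule thickness: concentric circles and squares, degenerate cases", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  outer <- contour(cbind(80 + 50 * cos(th), 80 + 50 * sin(th)), 1)
  inner <- contour(cbind(80 + 40 * cos(th), 80 + 40 * sin(th)), 1)
  res <- capsule_thickness(outer, inner, n_positions = 180)
  expect_true(all(abs(res$per_position_thickness_um - 10) < 0.1))
  expect_equal(res$per_sample_mean_um, mean(res$per_position_thickness_um))

  sq_o <- contour(cbind(c(10, 90, 90, 10), c(10, 10, 90, 90)), 1)
  sq_i <- contour(cbind(c(30, 70, 70, 30), c(30, 30, 70, 70)), 1)
  res_sq <- capsule_thickness(sq_o, sq_i, n_positions = 64)
  pts <- fbrquant:::resample_closed_polygon(sq_o$vertices, 64L)
  oracle <- vapply(seq_len(64), function(i)
    brute_force_boundary_dist(pts[i, 1], pts[i, 2], sq_i$vertices),
    numeric(1))
  expect_equal(res_sq$per_position_thickness_um, oracle, tolerance = 1e-3)

  expect_error(capsule_thickness(sq_o, sq_o), "intersect|touches")
  crossing <- contour(cbind(c(50, 120, 120, 50), c(30, 30, 70, 70)), 1)
  expect_error(capsule_thickness(sq_o, crossing), "intersect|contained")
})

test_that("thickness recovery on phantoms across true values", {
  for (T in c(10, 25, 40)) {
    sp <- phantom_spec(image_size_px = c(224L, 224L), nerve_radius_um = 90,
                       capsule_thickness_um = T, seed = 100L + T)
    ph <- generate_nerve_phantom(sp)
    res <- capsule_thickness(ph$outer, ph$inner, n_positions = 180)
    expect_lt(abs(res$per_sample_mean_um - T), 1)     # within 1 px at 1 um/px
  }
})

test_that("profile group summary is subject-level mean and sample SD", {
  mk <- function(vals, subj, grp) {
    data.frame(depth_lo_um = 0:2, depth_hi_um = 1:3, mean_intensity = vals,
               pixel_count = 10L, stain = "asma", subject = subj, group = grp)
  }
  p1 <- mk(c(1, 1, 1), "m1", "NI"); p2 <- mk(c(3, 3, 3), "m2", "NI")
  s <- profile_group_summary(list(p1, p2))
  expect_equal(s$mean_intensity, rep(2, 3))
  expect_equal(s$sd_intensity, rep(sd(c(1, 3)), 3))
  single <- profile_group_summary(list(p1))
  expect_equal(single$sd_intensity, rep(0, 3))
  # 8 synthetic subjects vs direct recomputation
  set.seed(23)
  profs <- lapply(1:8, function(i)
    mk(rnorm(3, 10), paste0("m", i), if (i <= 4) "NI" else "Dex"))
  s8 <- profile_group_summary(profs)
  vals <- sapply(profs, function(p) p$mean_intensity[2])
  expect_equal(s8$mean_intensity[s8$group == "Dex" & s8$depth_lo_um == 1],
               mean(vals[5:8]))
  expect_equal(s8$sd_intensity[s8$group == "NI" & s8$depth_lo_um == 1],
               sd(vals[1:4]))
  bad <- mk(c(1, 1, 1), "m9", "NI"); bad$depth_lo_um <- c(0, 5, 10)
  bad$depth_hi_um <- c(5, 10, 15)
  expect_error(profile_group_summary(list(p1, bad)), "mismatched")
})

test_that("intensity scaling propagates linearly; control ratios are invariant", {
  sp <- phantom_spec(image_size_px = c(128L, 128L), nerve_radius_um = 50,
                     capsule_thickness_um = 20, seed = 29L)
  ph <- generate_nerve_phantom(sp)
  img <- ph$channels$asma
  dm <- compute_depth_map(dim(img), ph$outer)
  pr1 <- intensity_profile(img, dm, 2, 30)
  prk <- intensity_profile(4.5 * img, dm, 2, 30)
  expect_equal(prk$mean_intensity, 4.5 * pr1$mean_intensity)
  tab <- data.frame(subject = 1:4, group = c("NI", "NI", "tx", "tx"),
                    value = c(3, 5, 1, 7))
  k <- 42
  tab_k <- tab; tab_k$value <- k * tab_k$value
  expect_equal(normalize_to_control(tab_k, "NI")$ratio,
               normalize_to_control(tab, "NI")$ratio)
})
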