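# Independent oracles used across the suite. These deliberately use naive
# brute-force formulations, not the package's own code paths.

# Minimum distance from a point to a closed polygon boundary, by dense
# resampling of every edge (pts_per_edge points per segment).
brute_force_boundary_dist <- function(px, py, verts, pts_per_edge = 400L) {
  n <- nrow(verts)
  j <- c(2:n, 1L)
  best <- Inf
  for (i in seq_len(n)) {
    t <- seq(0, 1, length.out = pts_per_edge)
    bx <- verts[i, 1] + t * (verts[j[i], 1] - verts[i, 1])
    by <- verts[i, 2] + t * (verts[j[i], 2] - verts[i, 2])
    best <- min(best, sqrt(min((bx - px)^2 + (by - py)^2)))
  }
  best
}

# Random star-shaped (non-self-intersecting) polygon around a center.
random_star_polygon <- function(n_vertices, center, r_min, r_max) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Exhaustive simplex grid search for the 3-type deconvolution problem at the
# given resolution; returns the best fraction vector.
grid_search_simplex3 <- function(S, x, res = 0.001) {
  f1 <- seq(0, 1, by = res)
  grid <- expand.grid(f1 = f1, f2 = f1)
  grid <- grid[grid$f1 + grid$f2 <= 1 + 1e-12, ]
  F3 <- rbind(grid$f1, grid$f2, 1 - grid$f1 - grid$f2)
  R <- S %*% F3 - as.numeric(x)        # genes x candidates
  ss <- colSums(R^2)
  F3[, which.min(ss)]
}

# Two-sided Dunnett family-wise p for k=2 balanced comparisons by direct
# 2D quadrature: P(max(|T1|,|T2|) >= t0) with T_i = Z_i / s,
# Z_i = sqrt(rho) Z0 + sqrt(1-rho) e_i, s^2 ~ chi^2_df / df.
dunnett_k2_integration_p <- function(t0, df, rho) {
  gz <- pracma::gaussLegendre(120, -8, 8)
  # integrate over u = chi2 quantile scale via substitution s = sqrt(q/df),
  # using Gauss-Legendre on the chi density over a wide support
  gs <- pracma::gaussLegendre(160, 1e-6, 6)   # s support
  fs <- function(s) 2 * df * s * dchisq(df * s^2, df)  # density of s
  inner <- function(s) {
    # P(|Z1| < t0 s and |Z2| < t0 s) via conditioning on Z0
    c0 <- t0 * s
    vapply(c0, function(cc) {
      pz <- pnorm((cc - sqrt(rho) * gz$x) / sqrt(1 - rho)) -
            pnorm((-cc - sqrt(rho) * gz$x) / sqrt(1 - rho))
      sum(gz$w * dnorm(gz$x) * pz^2)
    }, numeric(1))
  }
  1 - sum(gs$w * fs(gs$x) * inner(gs$x))
}

# Rebuild a fractions data.frame column into a named vector for one sample.
fraction_vector <- function(fr, sample_id) {
  d <- fr[fr$sample == sample_id, ]
  setNames(d$fraction, d$cell_type)
}
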