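# Synthetic ground-truth generators: nerve cross-section phantoms, cell-type
# signature/mixture matrices, negative-binomial count matrices, and qPCR Ct
# tables. Every generator is deterministic under its seed and records the
# truth it embedded, so downstream quantification can be tested by recovery.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom specification for a synthetic nerve cross-section
#'
#' Describes a circular nerve disk with an annular myofibroblast capsule at
#' its edge, scattered nuclei, and disjoint axon puncta, from which per-stain
#' channels are rendered. The capsule stain decays exponentially with depth
#' inward from the nerve edge.
#'
#' @param image_size_px integer pair (rows, cols); default c(256, 256).
#' @param pixel_size_um micrometers per pixel (default 1).
#' @param nerve_center_px (x, y) center in pixel coordinates; defaults to the
#'   image center.
#' @param nerve_radius_um nerve disk radius (default 100).
#' @param capsule_thickness_um radial extent of the capsule ring; must be
#'   smaller than the nerve radius (default 40).
#' @param capsule_peak_intensity stain intensity at the nerve edge, arbitrary
#'   units (default 1000).
#' @param intensity_decay_um exponential length constant of the capsule stain
#'   decay with depth (default 15).
#' @param axon_density_per_mm2 true axon puncta density inside the inner
#'   boundary (default 800).
#' @param axon_spot_radius_um radius of one axon punctum (default 1.5).
#' @param nuclei_density_per_mm2 nuclei speckle density (default 2000).
#' @param noise_sd additive Gaussian noise SD on every channel (default 0).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_size_px = c(256L, 256L),
                         pixel_size_um = 1,
                         nerve_center_px = NULL,
                         nerve_radius_um = 100,
                         capsule_thickness_um = 40,
                         capsule_peak_intensity = 1000,
                         intensity_decay_um = 15,
                         axon_density_per_mm2 = 800,
                         axon_spot_radius_um = 1.5,
                         nuclei_density_per_mm2 = 2000,
                         noise_sd = 0,
                         seed = 1L) {
  if (is.null(nerve_center_px))
    nerve_center_px <- c((image_size_px[2] - 1) / 2, (image_size_px[1] - 1) / 2)
  s <- list(image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            nerve_center_px = as.numeric(nerve_center_px),
            nerve_radius_um = nerve_radius_um,
            capsule_thickness_um = capsule_thickness_um,
            capsule_peak_intensity = capsule_peak_intensity,
            intensity_decay_um = intensity_decay_um,
            axon_density_per_mm2 = axon_density_per_mm2,
            axon_spot_radius_um = axon_spot_radius_um,
            nuclei_density_per_mm2 = nuclei_density_per_mm2,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  with(s, {
    if (any(image_size_px < 8)) stop("image too small")
    if (pixel_size_um <= 0 || nerve_radius_um <= 0 || capsule_thickness_um <= 0 ||
        intensity_decay_um <= 0 || axon_spot_radius_um <= 0)
      stop("all lengths must be positive")
    if (capsule_thickness_um >= nerve_radius_um)
      stop("capsule_thickness_um must be smaller than nerve_radius_um")
    if (axon_density_per_mm2 < 0 || nuclei_density_per_mm2 < 0)
      stop("densities must be non-negative")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
  })
  class(s) <- "phantom_spec"
  s
}

# Place n disk centers uniformly in a disk of radius r_um around center,
# pairwise separated by >= 2*spot_r (disjoint puncta), by rejection sampling.
# Centers are uniform over the FULL disk so that their density equals the
# nominal count/area; spots near the rim may straddle the boundary.
place_disjoint_spots <- function(n, center_px, r_um, spot_r_um, pixel_size_um,
                                 max_tries = 10000L) {
  pts <- matrix(numeric(0), 0, 2)
  r_px <- r_um / pixel_size_um
  min_sep <- 2 * spot_r_um / pixel_size_um
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1L
    th <- runif(1, 0, 2 * pi)
    rr <- sqrt(runif(1)) * r_px
    p <- center_px + rr * c(cos(th), sin(th))
    if (nrow(pts) == 0 ||
        all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= min_sep^2))
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " disjoint spots; density too high for the region")
  pts
}

# Render filled disks of radius r_px at the given centers into a zero matrix.
render_spots <- function(size_px, centers, r_px, intensity) {
  img <- matrix(0, size_px[1], size_px[2])
  if (nrow(centers) == 0) return(img)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(0, floor(cx - r_px)):min(size_px[2] - 1, ceiling(cx + r_px))
    ys <- max(0, floor(cy - r_px)):min(size_px[1] - 1, ceiling(cy + r_px))
    for (x in xs) {
      dy2 <- r_px^2 - (x - cx)^2
      if (dy2 < 0) next
      yy <- ys[(ys - cy)^2 <= dy2]
      img[cbind(yy + 1L, rep(x + 1L, length(yy)))] <- intensity
    }
  }
  img
}

#' Generate a synthetic nerve cross-section phantom
#'
#' Renders one channel per stain: \code{asma} (capsule ring, intensity
#' \code{peak * exp(-depth / decay)} for depth within the capsule thickness
#' and zero deeper), \code{tubb3} (disjoint axon puncta placed uniformly
#' inside the inner boundary at the requested density), and \code{dapi}
#' (nuclei speckle, likewise). Returns the exact outer (nerve edge) and inner
#' (capsule inner boundary) contours and the full ground truth. Identical
#' spec and seed give bitwise-identical output.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param contour_vertices number of vertices for the circular contours
#'   (default 180).
#' @return list with \code{channels} (named list of matrices), \code{outer},
#'   \code{inner} (\code{\link{contour}} objects), \code{truth} (the spec plus
#'   derived counts: \code{n_axons}, \code{n_nuclei}, \code{axon_centers_px}),
#'   and \code{pixel_size_um}.
#' @export
generate_nerve_phantom <- function(spec, contour_vertices = 180L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sz <- spec$image_size_px
  ps <- spec$pixel_size_um
  ctr <- spec$nerve_center_px
  r_px <- spec$nerve_radius_um / ps
  inner_r_um <- spec$nerve_radius_um - spec$capsule_thickness_um

  # radial depth from the nerve edge, analytic (no polygon needed here)
  xs <- 0:(sz[2] - 1); ys <- 0:(sz[1] - 1)
  rx <- matrix(xs, sz[1], sz[2], byrow = TRUE) - ctr[1]
  ry <- matrix(ys, sz[1], sz[2]) - ctr[2]
  r_um <- sqrt(rx^2 + ry^2) * ps
  depth_um <- spec$nerve_radius_um - r_um      # >0 inside the nerve

  asma <- matrix(0, sz[1], sz[2])
  in_capsule <- depth_um >= 0 & depth_um <= spec$capsule_thickness_um
  asma[in_capsule] <- spec$capsule_peak_intensity *
    exp(-depth_um[in_capsule] / spec$intensity_decay_um)

  inner_area_mm2 <- pi * (inner_r_um / 1000)^2
  n_axons <- round(spec$axon_density_per_mm2 * inner_area_mm2)
  n_nuclei <- round(spec$nuclei_density_per_mm2 * pi * (spec$nerve_radius_um / 1000)^2)

  out <- with_seed(spec$seed, {
    axon_centers <- place_disjoint_spots(n_axons, ctr, inner_r_um,
                                         spec$axon_spot_radius_um, ps)
    tubb3 <- render_spots(sz, axon_centers, spec$axon_spot_radius_um / ps,
                          spec$capsule_peak_intensity)
    nuc_centers <- if (n_nuclei > 0)
      cbind(ctr[1] + (sqrt(runif(n_nuclei)) * r_px) * cos(runif(n_nuclei, 0, 2 * pi)),
            ctr[2] + (sqrt(runif(n_nuclei)) * r_px) * sin(runif(n_nuclei, 0, 2 * pi)))
    else matrix(numeric(0), 0, 2)
    dapi <- render_spots(sz, nuc_centers, 2 / ps, spec$capsule_peak_intensity * 0.6)
    chans <- list(asma = asma, tubb3 = tubb3, dapi = dapi)
    if (spec$noise_sd > 0)
      chans <- lapply(chans, function(m)
        pmax(m + matrix(rnorm(length(m), 0, spec$noise_sd), nrow(m)), 0))
    list(channels = chans, axon_centers = axon_centers)
  })

  truth <- c(unclass(spec),
             list(n_axons = n_axons, n_nuclei = n_nuclei,
                  axon_centers_px = out$axon_centers,
                  inner_radius_um = inner_r_um))
  list(channels = out$channels,
       outer = contour(circle_polygon(ctr, r_px, contour_vertices), ps),
       inner = contour(circle_polygon(ctr, inner_r_um / ps, contour_vertices), ps),
       truth = truth,
       pixel_size_um = ps)
}

#' Default 25-to-6 immune cell-type grouping
#'
#' A grouping table mapping 25 fine hematopoietic cell types onto the six
#' major types: granulocytes, B cells, T cells, natural killer cells,
#' dendritic cells, and mono/macrophages. This synthetic taxonomy stands in
#' for published mouse hematopoietic references; each fine type maps to
#' exactly one major type.
#'
#' @return data.frame with columns \code{fine_type}, \code{major_type}.
#' @export
default_cell_grouping <- function() {
  data.frame(
    fine_type = c("neutrophil", "eosinophil", "basophil", "mast_cell",
                  "pro_b", "pre_b", "naive_b", "memory_b", "plasma_cell",
                  "cd4_naive_t", "cd4_memory_t", "cd8_naive_t", "cd8_memory_t",
                  "regulatory_t", "gamma_delta_t",
                  "nk_resting", "nk_activated",
                  "cdc1", "cdc2", "plasmacytoid_dc", "migratory_dc",
                  "classical_monocyte", "nonclassical_monocyte",
                  "m1_macrophage", "m2_macrophage"),
    major_type = c(rep("granulocytes", 4), rep("b_cells", 5), rep("t_cells", 6),
                   rep("nk_cells", 2), rep("dendritic_cells", 4),
                   rep("mono_macrophages", 4)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic signature matrix and mixed bulk samples
#'
#' Builds a non-negative genes x cell-types signature with per-type marker
#' structure (so columns are well separated), draws per-sample fractions from
#' a flat Dirichlet on the simplex, and mixes \code{signature %*% fractions}
#' plus additive Gaussian noise clipped at zero.
#'
#' @param n_genes number of genes (>= n_types).
#' @param n_types number of fine cell types (default 25; with the default
#'   grouping of \code{\link{default_cell_grouping}}).
#' @param n_samples number of bulk samples.
#' @param noise_sd additive Gaussian noise SD on the mixtures.
#' @param seed integer seed.
#' @return list with \code{signature} (genes x types), \code{mixtures}
#'   (genes x samples), \code{fractions_true} (types x samples, columns on the
#'   simplex), and \code{grouping} (only when \code{n_types == 25}).
#' @export
generate_signature_and_mixtures <- function(n_genes = 200L, n_types = 25L,
                                            n_samples = 8L, noise_sd = 0,
                                            seed = 1L) {
  if (n_genes < n_types)
    stop("n_genes must be at least n_types (system otherwise underdetermined)")
  grouping <- if (n_types == 25L) default_cell_grouping() else NULL
  with_seed(seed, {
    type_names <- if (!is.null(grouping)) grouping$fine_type
                  else paste0("type_", seq_len(n_types))
    sig <- matrix(rlnorm(n_genes * n_types, meanlog = 1, sdlog = 0.6),
                  n_genes, n_types,
                  dimnames = list(paste0("gene_", seq_len(n_genes)), type_names))
    # marker genes: each type gets a block of strongly enriched genes
    for (k in seq_len(n_types)) {
      idx <- seq.int(from = 1 + (k - 1) %% n_genes,
                     by = n_types, length.out = max(1, n_genes %/% (2 * n_types)))
      idx <- ((idx - 1) %% n_genes) + 1
      sig[idx, k] <- sig[idx, k] * 50
    }
    # flat Dirichlet via normalized Gamma(1) draws
    fr <- matrix(rexp(n_types * n_samples), n_types, n_samples)
    fr <- sweep(fr, 2, colSums(fr), "/")
    dimnames(fr) <- list(type_names, paste0("sample_", seq_len(n_samples)))
    mix <- sig %*% fr
    if (noise_sd > 0)
      mix <- pmax(mix + matrix(rnorm(length(mix), 0, noise_sd), nrow(mix)), 0)
    list(signature = sig, mixtures = mix, fractions_true = fr,
         grouping = grouping)
  })
}

#' Generate a negative-binomial count matrix with known truth
#'
#' Counts follow NB(mu, dispersion) with per-sample multiplicative size
#' factors and per-gene group effects: a fraction of genes carries a true
#' log2 fold change between the first (reference) group and the others.
#'
#' @param n_genes number of genes.
#' @param groups named integer vector of samples per group (>= 2 groups,
#'   >= 3 samples each), e.g. \code{c(NI = 6, Dex = 6)}; the first group is
#'   the reference.
#' @param de_fraction fraction of genes with a true effect.
#' @param lfc_sd SD of the true log2 fold changes (normal, mean 0); ignored
#'   when \code{lfc_fixed} is given.
#' @param lfc_fixed optional fixed magnitude of the true |log2FC| (random
#'   sign per gene).
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion * mu^2.
#' @param size_factor_range range of the uniform true size factors.
#' @param base_mean_range range of per-gene base means (log-uniform).
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{meta} (data.frame: sample, group), and \code{truth} (list:
#'   \code{log2fc_true}, \code{de_genes}, \code{size_factors_true}).
#' @export
generate_count_matrix <- function(n_genes = 2000L,
                                  groups = c(NI = 6L, Dex = 6L),
                                  de_fraction = 0.1, lfc_sd = 1,
                                  lfc_fixed = NULL,
                                  dispersion = 0.05,
                                  size_factor_range = c(0.7, 1.4),
                                  base_mean_range = c(5, 500),
                                  seed = 1L) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(groups < 3)) stop("need at least 3 samples per group")
  if (dispersion <= 0) stop("dispersion must be positive")
  group_lab <- rep(names(groups), groups)
  n_samples <- sum(groups)
  sample_ids <- paste0(group_lab, "_", unlist(lapply(groups, seq_len)))
  with_seed(seed, {
    sf <- runif(n_samples, size_factor_range[1], size_factor_range[2])
    base <- exp(runif(n_genes, log(base_mean_range[1]), log(base_mean_range[2])))
    lfc <- numeric(n_genes)
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    if (n_de > 0) {
      lfc[de_idx] <- if (is.null(lfc_fixed)) rnorm(n_de, 0, lfc_sd)
                     else sample(c(-1, 1), n_de, replace = TRUE) * lfc_fixed
    }
    is_ref <- group_lab == names(groups)[1]
    mu <- outer(base, sf)                      # genes x samples
    mu[, !is_ref] <- mu[, !is_ref] * 2^lfc     # effect in non-reference groups
    counts <- matrix(as.integer(rnbinom(n_genes * n_samples, mu = mu,
                                        size = 1 / dispersion)),
                     n_genes, n_samples,
                     dimnames = list(paste0("gene_", seq_len(n_genes)), sample_ids))
    list(counts = counts,
         meta = data.frame(sample = sample_ids, group = group_lab,
                           stringsAsFactors = FALSE),
         truth = list(log2fc_true = setNames(lfc, rownames(counts)),
                      de_genes = rownames(counts)[sort(de_idx)],
                      size_factors_true = setNames(sf, sample_ids)))
  })
}

#' Generate a qPCR Ct table with known relative quantification
#'
#' Builds per-well Ct values such that, in the noiseless case, the
#' delta-delta-Ct relative quantification recovered downstream equals
#' \code{2^(-ddct_true)} for every gene and non-reference group. The
#' housekeeping gene has zero delta-delta-Ct by construction.
#'
#' @param genes character vector of target gene names (housekeeping excluded).
#' @param groups named integer vector of replicates per group; first group is
#'   the reference.
#' @param housekeeping_gene name of the endogenous control gene.
#' @param ddct_true genes x non-reference-groups numeric matrix (or a single
#'   number recycled) of true delta-delta-Ct values.
#' @param noise_sd Gaussian noise SD added to every Ct value.
#' @param seed integer seed.
#' @return list with \code{ct} (long data.frame: gene, sample, group, ct) and
#'   \code{truth} (\code{rq_true}: genes x non-reference-groups matrix of
#'   \code{2^(-ddct_true)}).
#' @export
generate_ct_table <- function(genes, groups = c(WT = 3L, KO = 3L),
                              housekeeping_gene = "Gapdh",
                              ddct_true = 0, noise_sd = 0, seed = 1L) {
  stopifnot(length(genes) >= 1, length(groups) >= 2)
  if (housekeeping_gene %in% genes)
    stop("housekeeping gene must not be among the target genes")
  other <- names(groups)[-1]
  dd <- matrix(ddct_true, length(genes), length(other),
               dimnames = list(genes, other))
  with_seed(seed, {
    rows <- list()
    dct_base <- setNames(runif(length(genes), 2, 8), genes)  # gene-specific dCt
    for (g in names(groups)) {
      for (r in seq_len(groups[[g]])) {
        samp <- paste0(g, "_", r)
        offset <- runif(1, -1, 1)                 # per-sample machine offset
        ct_hk <- 20 + offset + rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          gene = housekeeping_gene, sample = samp, group = g, ct = ct_hk,
          stringsAsFactors = FALSE)
        for (gene in genes) {
          shift <- if (g %in% other) dd[gene, g] else 0
          rows[[length(rows) + 1]] <- data.frame(
            gene = gene, sample = samp, group = g,
            ct = 20 + offset + dct_base[gene] + shift + rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = do.call(rbind, rows), truth = list(rq_true = 2^(-dd)))
  })
}
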