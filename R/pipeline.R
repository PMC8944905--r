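# Pipeline orchestration: a config-driven run over a manifest of images and
# expression tables, emitting tidy CSVs and one JSON summary per run.
# Identical config and seeds give identical outputs.

#' Read / write a pipeline configuration
#'
#' Configurations are YAML mappings of the stage parameters; they round-trip
#' losslessly through the file form.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list of parameters.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

default_config <- function() {
  list(stages = c("capsule", "axons", "deconv", "expr", "rq", "stats"),
       window_um = 25, window_um_cd68 = 50, bin_um = 1, profile_depth_um = 50,
       boxes = 3L, side_um = 100, seed = 1L,
       rin_threshold = 3, fc_min = 2, base_min = 3, padj_max = 0.01,
       control_group = "NI", housekeeping_gene = "Gapdh",
       reference_group = "NI")
}

stage_window <- function(stain, config) {
  if (tolower(stain) == "cd68") config$window_um_cd68 else config$window_um
}

run_capsule_stage <- function(manifest, config, out_dir) {
  profs <- list(); nem <- list(); thick <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- read_image(row$image_path)
    ct <- read_contour(row$contour_path, row$pixel_size_um)
    dm <- compute_depth_map(dim(img), ct)
    profs[[i]] <- intensity_profile(img, dm, bin_width_um = config$bin_um,
                                    max_depth_um = config$profile_depth_um,
                                    stain = row$stain, subject = row$subject,
                                    group = row$group)
    nem[[i]] <- data.frame(subject = row$subject, group = row$group,
                           stain = row$stain,
                           window_um = stage_window(row$stain, config),
                           value = near_edge_mean(img, dm,
                                                  stage_window(row$stain, config)),
                           stringsAsFactors = FALSE)
    inner_path <- row[["inner_contour_path"]]
    if (!is.null(inner_path) && !is.na(inner_path) && nzchar(inner_path)) {
      th <- capsule_thickness(ct, read_contour(inner_path, row$pixel_size_um),
                              subject = row$subject, group = row$group)
      thick[[length(thick) + 1]] <-
        data.frame(subject = row$subject, group = row$group,
                   thickness_um = th$per_sample_mean_um,
                   stringsAsFactors = FALSE)
    }
  }
  near <- do.call(rbind, nem)
  ratios <- do.call(rbind, lapply(split(near, near$stain), function(d)
    normalize_to_control(d, config$control_group)))
  prof_long <- do.call(rbind, profs)
  write.csv(prof_long, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  write.csv(ratios, file.path(out_dir, "near_edge_means.csv"), row.names = FALSE)
  summ <- profile_group_summary(profs)
  write.csv(summ, file.path(out_dir, "profile_group_summary.csv"),
            row.names = FALSE)
  thick_df <- if (length(thick)) do.call(rbind, thick) else NULL
  if (!is.null(thick_df))
    write.csv(thick_df, file.path(out_dir, "capsule_thickness.csv"),
              row.names = FALSE)
  list(near_edge = ratios, thickness = thick_df,
       mean_thickness_by_group =
         if (!is.null(thick_df))
           as.list(tapply(thick_df$thickness_um, thick_df$group, mean)))
}

run_axon_stage <- function(manifest, config, out_dir) {
  rows <- manifest[tolower(manifest$stain) %in% c("tubb3", "b3tubulin"), ]
  if (nrow(rows) == 0) return(NULL)
  per_image <- list()
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    img <- read_image(row$image_path)
    region_path <- row[["inner_contour_path"]]
    if (is.null(region_path) || is.na(region_path) || !nzchar(region_path))
      region_path <- row$contour_path
    ct <- read_contour(region_path, row$pixel_size_um)
    xs <- 0:(ncol(img) - 1); ys <- 0:(nrow(img) - 1)
    mask <- matrix(contour_contains(ct, rep(xs, each = length(ys)),
                                    rep(ys, times = length(xs))),
                   nrow(img), ncol(img))
    boxes <- sample_boxes(mask, side_um = config$side_um,
                          n_boxes = config$boxes,
                          pixel_size_um = row$pixel_size_um,
                          seed = config$seed + i)
    dens <- axon_density(img, boxes, pixel_size_um = row$pixel_size_um)
    per_image[[i]] <- data.frame(subject = row$subject, group = row$group,
                                 image = row$image_path,
                                 density_per_mm2 = dens$per_image_mean,
                                 stringsAsFactors = FALSE)
  }
  per_image <- do.call(rbind, per_image)
  per_mouse <- aggregate_axon_density(per_image)
  per_mouse$group <- per_image$group[match(per_mouse$subject,
                                           per_image$subject)]
  write.csv(per_image, file.path(out_dir, "axon_density_per_image.csv"),
            row.names = FALSE)
  write.csv(per_mouse, file.path(out_dir, "axon_density_per_mouse.csv"),
            row.names = FALSE)
  list(per_mouse = per_mouse,
       mean_density_by_group =
         as.list(tapply(per_mouse$mean_density_per_mm2, per_mouse$group, mean)))
}

run_deconv_stage <- function(config, out_dir) {
  if (is.null(config$signature_path) || is.null(config$mixtures_path))
    return(NULL)
  sig <- read_counts(config$signature_path)
  mix <- read_counts(config$mixtures_path)
  fr <- deconvolve(mix, sig)
  write.csv(fr, file.path(out_dir, "cell_fractions.csv"), row.names = FALSE)
  major <- NULL
  if (ncol(sig) == 25 &&
      all(colnames(sig) %in% default_cell_grouping()$fine_type)) {
    major <- aggregate_fractions(fr)
    write.csv(major, file.path(out_dir, "cell_fractions_major.csv"),
              row.names = FALSE)
  }
  list(n_samples = length(unique(fr$sample)),
       mean_residual = mean(attr(fr, "residual_norm")))
}

run_expr_stage <- function(config, out_dir) {
  if (is.null(config$counts_path)) return(NULL)
  counts <- read_counts(config$counts_path)
  meta <- read.delim(config$meta_path, stringsAsFactors = FALSE)
  keep <- filter_samples_by_rin(meta, config$rin_threshold)
  counts <- counts[, colnames(counts) %in% keep, drop = FALSE]
  meta <- meta[meta$sample %in% keep, ]
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  res <- list(n_samples_retained = ncol(counts),
              size_factor_range = range(sf))
  if (length(unique(meta$group)) == 2) {
    de <- de_test(norm, meta$group[match(colnames(counts), meta$sample)])
    degs <- deg_filter(de, config$fc_min, config$base_min, config$padj_max)
    write.csv(de, file.path(out_dir, "de_table.csv"), row.names = FALSE)
    writeLines(degs, file.path(out_dir, "deg_list.txt"))
    res$n_deg <- length(degs)
  }
  k <- min(500L, nrow(norm))
  top <- top_k_variable_genes(norm, k)
  pca <- pca_scores(norm[top, , drop = FALSE], 2)
  write.csv(data.frame(sample = rownames(pca$scores), pca$scores),
            file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  res$pc1_explained <- pca$explained[1]
  res
}

run_rq_stage <- function(config, out_dir) {
  if (is.null(config$ct_path)) return(NULL)
  ct <- read_ct(config$ct_path)
  rq <- compute_rq(ct, config$housekeeping_gene, config$reference_group)
  write.csv(rq, file.path(out_dir, "rq_table.csv"), row.names = FALSE)
  list(n_significant = sum(rq$significant))
}

run_stats_stage <- function(capsule_res, axon_res, config, out_dir) {
  out <- list()
  thick <- capsule_res$thickness
  if (!is.null(thick) && length(unique(thick$group)) >= 2 &&
      all(table(thick$group) >= 2)) {
    if (length(unique(thick$group)) == 2) {
      tt <- tryCatch(t_test_groups(thick$thickness_um, thick$group),
                     error = function(e) list(p = NA_real_))
      out$thickness_t_p <- tt$p
    } else {
      out$thickness_anova_p <-
        one_way_anova(thick$thickness_um, thick$group)$p
      dn <- dunnett_test(thick$thickness_um, thick$group,
                         control = config$control_group,
                         seed = config$seed)
      out$thickness_dunnett <- setNames(as.list(dn$p_adjusted), dn$comparison)
    }
  }
  pm <- axon_res$per_mouse
  if (!is.null(pm) && length(unique(pm$group)) == 2 &&
      all(table(pm$group) >= 2)) {
    out$axon_t_p <- t_test_groups(pm$mean_density_per_mm2, pm$group)$p
  }
  if (length(out))
    jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  out
}

#' Run the quantification pipeline
#'
#' Executes the selected stages in dependency order over the inputs named in
#' the configuration, writes per-stage CSVs and a JSON summary into
#' \code{out_dir}, and returns the summary. Identical configuration and
#' seeds give identical summaries.
#'
#' @param config named list (see \code{\link{read_config}}); recognised keys
#'   include \code{manifest_path}, \code{stages}, \code{window_um},
#'   \code{bin_um}, \code{boxes}, \code{side_um}, \code{seed},
#'   \code{rin_threshold}, \code{counts_path}, \code{meta_path},
#'   \code{signature_path}, \code{mixtures_path}, \code{ct_path},
#'   \code{control_group}, \code{housekeeping_gene}, \code{reference_group}.
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly also written to
#'   \code{summary.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = config[setdiff(names(config),
                                              c("stages"))],
                  stages = list())
  manifest <- if (!is.null(config$manifest_path))
    read_manifest(config$manifest_path) else NULL
  capsule_res <- NULL; axon_res <- NULL
  stages <- config$stages
  if ("capsule" %in% stages && !is.null(manifest)) {
    capsule_res <- run_capsule_stage(
      manifest[tolower(manifest$stain) != "tubb3", ], config, out_dir)
    summary$stages$capsule <-
      capsule_res[c("mean_thickness_by_group")]
  }
  if ("axons" %in% stages && !is.null(manifest)) {
    axon_res <- run_axon_stage(manifest, config, out_dir)
    if (!is.null(axon_res))
      summary$stages$axons <- axon_res["mean_density_by_group"]
  }
  if ("deconv" %in% stages) {
    r <- run_deconv_stage(config, out_dir)
    if (!is.null(r)) summary$stages$deconv <- r
  }
  if ("expr" %in% stages) {
    r <- run_expr_stage(config, out_dir)
    if (!is.null(r)) summary$stages$expr <- r
  }
  if ("rq" %in% stages) {
    r <- run_rq_stage(config, out_dir)
    if (!is.null(r)) summary$stages$rq <- r
  }
  if ("stats" %in% stages) {
    r <- run_stats_stage(capsule_res, axon_res, config, out_dir)
    if (length(r)) summary$stages$stats <- r
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate demo fixtures and run the full pipeline on them
#'
#' Builds a small synthetic study (two treatment groups of mice with
#' different capsule thicknesses, axon channels, a count matrix, signature /
#' mixture matrices, and a Ct table), writes the fixtures and a config to
#' \code{out_dir/fixtures}, runs every stage, and returns the summary. Runs
#' in well under a minute and is deterministic for a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_per_group mice per group (default 3).
#' @return pipeline summary list.
#' @export
run_demo <- function(out_dir, seed = 1L, n_per_group = 3L) {
  fix <- file.path(out_dir, "fixtures")
  dir.create(fix, recursive = TRUE, showWarnings = FALSE)
  groups <- c(NI = 40, MCC950 = 18)  # mean capsule thickness per group, um
  man <- list()
  for (g in names(groups)) {
    # biological spread: each mouse gets its own thickness around the mean
    spread <- seq(-3, 3, length.out = n_per_group)
    for (m in seq_len(n_per_group)) {
      sid <- paste0(g, "_m", m)
      sp <- phantom_spec(image_size_px = c(192L, 192L), nerve_radius_um = 80,
                         capsule_thickness_um = groups[[g]] + spread[m],
                         axon_density_per_mm2 = 800,
                         nuclei_density_per_mm2 = 1000,
                         seed = seed + 97L * match(g, names(groups)) + m)
      ph <- generate_nerve_phantom(sp, contour_vertices = 120L)
      ip <- file.path(fix, paste0(sid, "_asma.tif"))
      ap <- file.path(fix, paste0(sid, "_tubb3.tif"))
      oc <- file.path(fix, paste0(sid, "_outer.csv"))
      ic <- file.path(fix, paste0(sid, "_inner.csv"))
      write_image(ph$channels$asma, ip)
      write_image(ph$channels$tubb3, ap)
      write_contour(ph$outer, oc)
      write_contour(ph$inner, ic)
      man[[length(man) + 1]] <- data.frame(
        subject = sid, group = g, stain = c("asma", "tubb3"),
        image_path = c(ip, ap), contour_path = oc, inner_contour_path = ic,
        pixel_size_um = 1, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  man_path <- file.path(fix, "manifest.tsv")
  write.table(manifest, man_path, sep = "\t", quote = FALSE, row.names = FALSE)

  cm <- generate_count_matrix(n_genes = 600L,
                              groups = setNames(c(4L, 4L), names(groups)),
                              de_fraction = 0.1, lfc_fixed = 2,
                              seed = seed + 11L)
  counts_path <- file.path(fix, "counts.tsv")
  write_counts(cm$counts, counts_path)
  meta <- cm$meta
  meta$rin <- 7
  meta_path <- file.path(fix, "meta.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gsm <- generate_signature_and_mixtures(n_genes = 150L, n_types = 25L,
                                         n_samples = 4L, noise_sd = 0.5,
                                         seed = seed + 13L)
  sig_path <- file.path(fix, "signature.tsv")
  mix_path <- file.path(fix, "mixtures.tsv")
  write_counts(gsm$signature, sig_path)
  write_counts(gsm$mixtures, mix_path)

  ctt <- generate_ct_table(genes = c("Il1b", "Nlrp3"),
                           groups = setNames(c(4L, 4L), names(groups)),
                           ddct_true = cbind(MCC950 = c(-1.5, 0.3)),
                           noise_sd = 0.1, seed = seed + 17L)
  ct_path <- file.path(fix, "ct.csv")
  write.csv(ctt$ct, ct_path, row.names = FALSE)

  config <- list(manifest_path = man_path, counts_path = counts_path,
                 meta_path = meta_path, signature_path = sig_path,
                 mixtures_path = mix_path, ct_path = ct_path,
                 control_group = "NI", reference_group = "NI",
                 housekeeping_gene = "Gapdh", seed = seed,
                 side_um = 50)  # boxes must fit the demo's inner region

  write_config(config, file.path(fix, "config.yaml"))
  run_pipeline(config, out_dir)
}
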