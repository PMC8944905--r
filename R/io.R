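# File formats: 16-bit grayscale TIFF images, contour CSVs, count-matrix and
# Ct tables, and the per-subject manifest. Plain text everywhere but images;
# write-then-read round trips reproduce values exactly.

#' Write a grayscale image as 16-bit TIFF
#'
#' Intensities are stored as integers in [0, 65535]; values are rounded and
#' clipped into that range.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF image
#'
#' @param path TIFF file.
#' @return numeric matrix with intensities on the stored integer scale
#'   (0..65535 for 16-bit files).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]   # take first channel if multi
  round(m * 65535)
}

#' Write a contour to CSV
#'
#' Columns \code{x_px}, \code{y_px}, 0-based pixel coordinates, polygon
#' closed implicitly.
#'
#' @param ct an \code{\link{contour}}.
#' @param path output CSV path.
#' @export
write_contour <- function(ct, path) {
  stopifnot(is_contour(ct))
  write.csv(data.frame(x_px = ct$vertices[, 1], y_px = ct$vertices[, 2]),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a contour CSV
#'
#' @param path CSV with columns \code{x_px}, \code{y_px}.
#' @param pixel_size_um physical pixel size to attach.
#' @return an \code{\link{contour}}.
#' @export
read_contour <- function(path, pixel_size_um = 1) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  d <- read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(d)))
    stop("contour file ", path, " must have columns x_px, y_px")
  if (nrow(d) < 3)
    stop("contour file ", path, " has fewer than 3 vertices")
  contour(cbind(d$x_px, d$y_px), pixel_size_um = pixel_size_um)
}

#' Write a count matrix as TSV
#'
#' Genes in rows; first column \code{gene}, then one column per sample.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path output TSV path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV
#'
#' @param path TSV with a \code{gene} column followed by sample columns.
#' @return numeric matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  d <- read.delim(path, check.names = FALSE)
  if (names(d)[1] != "gene") stop("counts file ", path,
                                  " must start with a 'gene' column")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyDuplicated(d$gene)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts file %s: invalid value at gene '%s', sample '%s'",
                 path, d$gene[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(m) <- d$gene
  m
}

#' Read a qPCR Ct table CSV
#'
#' @param path CSV with columns \code{gene}, \code{sample}, \code{group},
#'   \code{ct}.
#' @return data.frame in the long format used by \code{\link{compute_rq}}.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("Ct file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "group", "ct")
  if (!all(need %in% names(d)))
    stop("Ct file ", path, " must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(d$ct)))
    stop("Ct file ", path, ": non-numeric Ct at line ",
         which(!is.finite(d$ct))[1] + 1L)
  d
}

#' Read a per-subject image manifest
#'
#' One row per image: which subject and group it belongs to, which stain it
#' shows, where the image and contour files live, and the pixel size.
#'
#' @param path TSV with columns \code{subject}, \code{group}, \code{stain},
#'   \code{image_path}, \code{contour_path} (optionally
#'   \code{inner_contour_path}), \code{pixel_size_um}.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "stain", "image_path", "contour_path",
            "pixel_size_um")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("manifest ", path, " lacks columns: ", paste(miss, collapse = ", "))
  d
}
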