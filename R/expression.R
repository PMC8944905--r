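# Expression-side arithmetic: RIN sample QC, median-of-ratios size factors,
# a per-gene stand-in DE test, DEG filtering, top-variance gene selection,
# PCA, and qPCR relative quantification with the two-fold rule.

#' Filter samples by RNA integrity number
#'
#' Keeps samples whose RIN is strictly above the threshold (default 3);
#' samples with missing RIN are excluded with a warning.
#'
#' @param metadata data.frame with columns \code{sample} and \code{rin}.
#' @param threshold RIN threshold; retained samples satisfy
#'   \code{rin > threshold}.
#' @return character vector of retained sample ids.
#' @export
filter_samples_by_rin <- function(metadata, threshold = 3) {
  stopifnot(all(c("sample", "rin") %in% names(metadata)))
  miss <- is.na(metadata$rin)
  if (any(miss))
    warning("samples without RIN excluded: ",
            paste(metadata$sample[miss], collapse = ", "))
  metadata$sample[!miss & metadata$rin > threshold]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: for each sample,
#' the median over genes (restricted to genes with a positive geometric mean
#' across samples) of the ratio of that gene's count to its geometric mean.
#' No rescaling is applied beyond the median.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has nonzero counts in every sample; ",
         "size factors undefined (filter samples or genes first)")
  logc <- log(counts[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(lc) exp(median(lc - loggeo)))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples matrix.
#' @param sf size factors; computed with \code{\link{size_factors}} when
#'   omitted.
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Per-gene two-group differential test (stand-in)
#'
#' A deliberately simple per-gene test on \code{log2(normalized + 1)}: Welch
#' two-sample t with Benjamini-Hochberg adjustment across genes. The log2
#' fold change is the difference of group means on the log scale. This is a
#' stand-in for a full negative-binomial analysis; its contract is calibrated
#' type-I error on null data, which is what the downstream DEG filter needs.
#' Genes with zero variance in both groups get p = 1.
#'
#' @param norm_counts normalized count matrix (genes x samples).
#' @param groups character/factor vector of length \code{ncol(norm_counts)}
#'   with exactly two levels; the first level is the reference.
#' @return data.frame with columns \code{gene}, \code{base_mean},
#'   \code{log2_fold_change}, \code{p_value}, \code{adjusted_p}.
#' @export
de_test <- function(norm_counts, groups) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("de_test expects exactly two groups")
  if (any(table(groups) < 2)) stop("need at least 2 samples per group")
  a <- groups == levels(groups)[1]
  b <- !a
  lg <- log2(norm_counts + 1)
  m1 <- rowMeans(lg[, a, drop = FALSE]); m2 <- rowMeans(lg[, b, drop = FALSE])
  v1 <- apply(lg[, a, drop = FALSE], 1, var)
  v2 <- apply(lg[, b, drop = FALSE], 1, var)
  n1 <- sum(a); n2 <- sum(b)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # zero variance in both groups: p undefined, recorded as 1
  data.frame(gene = rownames(norm_counts),
             base_mean = rowMeans(norm_counts),
             log2_fold_change = m2 - m1,
             p_value = p,
             adjusted_p = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Differentially-expressed-gene filter
#'
#' Retains genes with at least a two-fold change (\code{|log2FC| >= 1},
#' inclusive), a base expression above \code{base_min} normalized counts
#' (strict), and an adjusted p value below \code{padj_max} (strict).
#'
#' @param records data.frame from \code{\link{de_test}} (columns \code{gene},
#'   \code{base_mean}, \code{log2_fold_change}, \code{adjusted_p}).
#' @param fc_min minimum fold change (default 2; applied as
#'   \code{|log2FC| >= log2(fc_min)}).
#' @param base_min strict lower bound on base mean (default 3).
#' @param padj_max strict upper bound on adjusted p (default 0.01).
#' @param fc_inclusive whether the fold-change bound is inclusive
#'   (default TRUE).
#' @return character vector of retained gene ids.
#' @export
deg_filter <- function(records, fc_min = 2, base_min = 3, padj_max = 0.01,
                       fc_inclusive = TRUE) {
  lfc <- abs(records$log2_fold_change)
  cut <- log2(fc_min)
  keep <- (if (fc_inclusive) lfc >= cut else lfc > cut) &
    records$base_mean > base_min &
    records$adjusted_p < padj_max
  records$gene[keep & !is.na(keep)]
}

#' Top-k most variable genes
#'
#' Ranks genes by across-sample variance of \code{log2(normalized + 1)} and
#' returns the top k (default 500, the usual input size for expression PCA).
#' Ties are broken by gene id order.
#'
#' @param norm_counts normalized count matrix with gene rownames.
#' @param k number of genes to keep.
#' @return character vector of k gene ids.
#' @export
top_k_variable_genes <- function(norm_counts, k = 500L) {
  norm_counts <- as.matrix(norm_counts)
  if (k > nrow(norm_counts)) stop("k exceeds the number of genes")
  v <- apply(log2(norm_counts + 1), 1, var)
  ord <- order(-v, rownames(norm_counts))
  rownames(norm_counts)[ord[seq_len(k)]]
}

#' PCA scores of samples
#'
#' Centered principal component analysis with samples as observations and
#' genes as variables.
#'
#' @param mat genes x samples matrix (samples become rows internally).
#' @param n_components number of components to return.
#' @return list with \code{scores} (samples x components) and
#'   \code{explained} (variance fractions, non-increasing, summing to <= 1).
#' @export
pca_scores <- function(mat, n_components = 2L) {
  X <- t(as.matrix(mat))                      # samples x genes
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  if (all(apply(X, 2, var) == 0)) stop("matrix has zero variance")
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = (ev / sum(ev))[seq_len(n_components)])
}

#' qPCR relative quantification (delta-delta-Ct)
#'
#' For each target gene and group: \code{dCt = Ct_gene - Ct_housekeeping} per
#' sample, averaged within group; \code{ddCt = dCt_group - dCt_reference};
#' \code{RQ = 2^(-ddCt)}. RQ is flagged significant under the two-fold rule,
#' strictly: RQ greater than 2 or less than 0.5 (an RQ of exactly 2 is not
#' flagged). Samples without a housekeeping Ct are dropped with a warning.
#'
#' @param ct_table long data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{ct}.
#' @param housekeeping_gene endogenous control gene name.
#' @param reference_group group against which ddCt is taken.
#' @return data.frame with columns \code{gene}, \code{group}, \code{rq},
#'   \code{significant} (one row per gene x non-reference group).
#' @export
compute_rq <- function(ct_table, housekeeping_gene, reference_group) {
  stopifnot(all(c("gene", "sample", "group", "ct") %in% names(ct_table)))
  hk <- ct_table[ct_table$gene == housekeeping_gene, ]
  if (nrow(hk) == 0) stop("housekeeping gene '", housekeeping_gene,
                          "' not found in the Ct table")
  if (!reference_group %in% ct_table$group)
    stop("reference group '", reference_group, "' not present")
  hk_ct <- setNames(hk$ct, hk$sample)
  tg <- ct_table[ct_table$gene != housekeeping_gene, ]
  no_hk <- !(tg$sample %in% names(hk_ct))
  if (any(no_hk)) {
    warning("samples without housekeeping Ct dropped: ",
            paste(unique(tg$sample[no_hk]), collapse = ", "))
    tg <- tg[!no_hk, ]
  }
  tg$dct <- tg$ct - hk_ct[tg$sample]
  dct_mean <- aggregate(dct ~ gene + group, data = tg, FUN = mean)
  ref <- dct_mean[dct_mean$group == reference_group, c("gene", "dct")]
  names(ref)[2] <- "dct_ref"
  other <- dct_mean[dct_mean$group != reference_group, ]
  out <- merge(other, ref, by = "gene")
  out$rq <- 2^(-(out$dct - out$dct_ref))
  out$significant <- out$rq > 2 | out$rq < 0.5
  out <- out[order(out$gene, out$group), c("gene", "group", "rq", "significant")]
  rownames(out) <- NULL
  out
}
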