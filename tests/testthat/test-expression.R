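# Expression arithmetic: QC, normalization, DE stand-in, filters, PCA, RQ.

test_that("RIN filter is strictly greater-than and warns on missing values", {
  meta <- data.frame(sample = paste0("s", 1:4), rin = c(2.9, 3.0, 3.1, 7))
  expect_equal(filter_samples_by_rin(meta), c("s3", "s4"))
  all8 <- data.frame(sample = paste0("s", 1:3), rin = c(8, 8, 8))
  expect_equal(filter_samples_by_rin(all8), paste0("s", 1:3))
  withna <- data.frame(sample = c("a", "b"), rin = c(NA, 9))
  expect_warning(keep <- filter_samples_by_rin(withna), "without RIN")
  expect_equal(keep, "b")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50), 5, 3)
  colnames(m) <- paste0("s", 1:3); rownames(m) <- paste0("g", 1:5)
  expect_equal(unname(size_factors(m)), rep(1, 3))   # identical columns

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  # 5x3 toy matrix against hand-computed medians of ratios
  toy <- matrix(c(2, 4, 8, 16, 32,
                  4, 4, 8, 8, 32,
                  2, 8, 8, 32, 32), 5, 3,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  geo <- exp(rowMeans(log(toy)))
  hand <- apply(toy / geo, 2, median)
  expect_equal(size_factors(toy), hand)

  # agrees with the standard Bioconductor implementation
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(toy)
  expect_equal(size_factors(toy), sf_ref, tolerance = 1e-12)

  zero_row <- rbind(toy, g6 = c(0, 5, 5))
  expect_equal(size_factors(zero_row), size_factors(toy))  # gene dropped
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "no gene")
})

test_that("size factors are idempotent after normalization", {
  # pure depth-scaled matrix: normalization removes all scale differences
  base <- c(10, 25, 60, 120, 300, 40)
  sf_true <- c(0.5, 1, 2, 1.6)
  m <- outer(base, sf_true)
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:4))
  sf1 <- size_factors(m)
  norm <- normalize_counts(m, sf1)
  sf2 <- size_factors(norm)
  expect_equal(unname(sf2), rep(1, 4), tolerance = 1e-9)
  # and on noisy data the recomputed factors are all equal
  g <- generate_count_matrix(n_genes = 500, groups = c(A = 3, B = 3),
                             de_fraction = 0, seed = 3)
  nrm <- normalize_counts(g$counts)
  sfr <- size_factors(nrm)
  expect_lt(diff(range(sfr)) / mean(sfr), 1e-9)
})

test_that("DE stand-in: closed-form log2FC, zero-variance handling, BH", {
  m <- matrix(c(1, 1, 1, 4, 4, 4), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  de <- de_test(m, rep(c("ctl", "trt"), each = 3))
  expect_equal(abs(de$log2_fold_change), log2(5) - log2(2))
  expect_equal(de$p_value, 1)        # zero variance in both groups
  # identical groups: log2FC exactly zero
  m2 <- matrix(rpois(60, 20), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m2 <- cbind(m2[, 1:3], m2[, 1:3])
  colnames(m2) <- paste0("s", 1:6)
  de2 <- de_test(m2, rep(c("a", "b"), each = 3))
  expect_true(all(de2$log2_fold_change == 0))
  # BH adjustment matches p.adjust and adjusted >= raw
  set.seed(6)
  m3 <- matrix(rnbinom(1200, mu = 50, size = 10), 200, 6,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  de3 <- de_test(m3, rep(c("a", "b"), each = 3))
  expect_equal(de3$adjusted_p, p.adjust(de3$p_value, "BH"))
  expect_true(all(de3$adjusted_p >= de3$p_value - 1e-12))
})

test_that("DEG filter equals the brute-force predicate", {
  rec <- data.frame(gene = "g", log2_fold_change = 1.5, base_mean = 10,
                    adjusted_p = 0.001)
  expect_equal(deg_filter(rec), "g")
  rec0 <- data.frame(gene = "g", log2_fold_change = 0, base_mean = 1e6,
                     adjusted_p = 1e-30)
  expect_equal(length(deg_filter(rec0)), 0L)
  set.seed(12)
  tab <- data.frame(gene = paste0("g", 1:1000),
                    log2_fold_change = rnorm(1000, 0, 1.2),
                    base_mean = exp(runif(1000, 0, 6)),
                    adjusted_p = runif(1000))
  # plant boundary cases
  tab$log2_fold_change[1:4] <- c(1, -1, 0.999, 1.001)
  tab$base_mean[5:6] <- c(3, 3.0001)
  tab$adjusted_p[7:8] <- c(0.01, 0.00999)
  got <- deg_filter(tab)
  brute <- tab$gene[abs(tab$log2_fold_change) >= 1 &
                    tab$base_mean > 3 & tab$adjusted_p < 0.01]
  expect_identical(got, brute)
  # exclusive fold-change variant flips only the |lfc| == 1 boundary
  got_ex <- deg_filter(tab, fc_inclusive = FALSE)
  brute_ex <- tab$gene[abs(tab$log2_fold_change) > 1 &
                       tab$base_mean > 3 & tab$adjusted_p < 0.01]
  expect_identical(got_ex, brute_ex)
})

test_that("top-variance gene selection matches a brute-force sort", {
  set.seed(14)
  m <- matrix(rnbinom(50 * 8, mu = 40, size = 5), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  top <- top_k_variable_genes(m, 10)
  v <- apply(log2(m + 1), 1, var)
  brute <- names(sort(v, decreasing = TRUE))[1:10]
  expect_setequal(top, brute)
  expect_equal(sort(top_k_variable_genes(m, 50)), sort(rownames(m)))
  one_var <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10),
                                              paste0("s", 1:4)))
  one_var[3, ] <- c(1, 10, 1, 10)
  expect_equal(top_k_variable_genes(one_var, 1), "g3")
})

test_that("PCA scores match a direct eigendecomposition", {
  set.seed(16)
  m <- matrix(rnorm(8 * 20), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  pc <- pca_scores(m, 5)
  X <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(cov(X))$values
  got_var <- apply(pc$scores, 2, var)
  expect_equal(unname(got_var), ev[1:5], tolerance = 1e-9)
  expect_equal(unname(pc$explained), (ev / sum(ev))[1:5], tolerance = 1e-9)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # samples on a line: PC1 explains everything
  line <- outer(rnorm(10), seq_len(4))
  rownames(line) <- paste0("g", 1:10); colnames(line) <- paste0("s", 1:4)
  pl <- pca_scores(line, 2)
  expect_equal(unname(pl$explained[1]), 1, tolerance = 1e-9)
  # duplicated samples get identical scores
  dup <- cbind(m, s9 = m[, 1])
  pd <- pca_scores(dup, 2)
  expect_equal(pd$scores["s9", ], pd$scores["s1", ], ignore_attr = TRUE)
  expect_error(pca_scores(matrix(3, 5, 3,
                                 dimnames = list(paste0("g", 1:5),
                                                 paste0("s", 1:3))), 2),
               "zero variance")
})

test_that("RQ follows 2^(-ddCt) with strict two-fold flagging", {
  # hand-built 2-gene, 2-group table
  ct <- rbind(
    data.frame(gene = "Gapdh", sample = c("w1", "w2", "k1", "k2"),
               group = c("WT", "WT", "KO", "KO"), ct = c(20, 21, 20, 22)),
    data.frame(gene = "Il1b", sample = c("w1", "w2", "k1", "k2"),
               group = c("WT", "WT", "KO", "KO"),
               ct = c(25, 26, 23, 25)),    # dCt: WT 5,5 -> 5; KO 3,3 -> 3
    data.frame(gene = "Tnf", sample = c("w1", "w2", "k1", "k2"),
               group = c("WT", "WT", "KO", "KO"),
               ct = c(24, 25, 23, 25)))    # dCt: WT 4,4 -> 4; KO 3,3 -> 3
  rq <- compute_rq(ct, "Gapdh", "WT")
  expect_equal(rq$rq[rq$gene == "Il1b"], 4)      # ddCt -2
  expect_true(rq$significant[rq$gene == "Il1b"])
  expect_equal(rq$rq[rq$gene == "Tnf"], 2)       # ddCt -1
  expect_false(rq$significant[rq$gene == "Tnf"]) # RQ exactly 2: not flagged
  # gene behaving like the housekeeping gene gives RQ 1
  ct_id <- rbind(
    data.frame(gene = "Gapdh", sample = c("a1", "b1", "a2", "b2"),
               group = c("A", "B", "A", "B"), ct = c(20, 22, 21, 19)),
    data.frame(gene = "X", sample = c("a1", "b1", "a2", "b2"),
               group = c("A", "B", "A", "B"), ct = c(20, 22, 21, 19)))
  rq_id <- compute_rq(ct_id, "Gapdh", "A")
  expect_equal(rq_id$rq, 1)
  expect_false(rq_id$significant)
  # invariance to a per-sample constant Ct offset
  ct_off <- ct
  ct_off$ct[ct_off$sample == "k1"] <- ct_off$ct[ct_off$sample == "k1"] + 3.7
  expect_equal(compute_rq(ct_off, "Gapdh", "WT")$rq, rq$rq)
  # missing housekeeping well drops the sample with a warning
  ct_miss <- ct[!(ct$gene == "Gapdh" & ct$sample == "k2"), ]
  expect_warning(rq_m <- compute_rq(ct_miss, "Gapdh", "WT"), "dropped")
  expect_equal(rq_m$rq[rq_m$gene == "Il1b"], 2^-(3 - 5))
})
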