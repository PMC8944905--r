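# Group-comparison statistics: one-way ANOVA, Dunnett and Tukey post hoc
# tests, two-way ANOVA (Type II for unbalanced layouts), Student's t and
# Mann-Whitney U. Observations are subject-level values (one per mouse).

check_design <- function(values, groups, min_per_group = 2L) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < min_per_group))
    stop("every group needs at least ", min_per_group, " observations; ",
         "short: ", paste(names(tab)[tab < min_per_group], collapse = ", "))
  list(values = as.numeric(values), groups = groups)
}

#' One-way fixed-effects ANOVA
#'
#' @param values numeric vector of subject-level observations.
#' @param groups group labels, same length.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
one_way_anova <- function(values, groups) {
  d <- check_design(values, groups)
  gm <- tapply(d$values, d$groups, mean)
  n <- table(d$groups)
  ssb <- sum(n * (gm - mean(d$values))^2)
  ssw <- sum((d$values - gm[d$groups])^2)
  df1 <- nlevels(d$groups) - 1L
  df2 <- length(d$values) - nlevels(d$groups)
  if (ssw == 0 && ssb == 0) {          # all observations identical
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df1 = df1, df2 = df2, p = p)
}

#' Dunnett many-to-one comparisons
#'
#' Compares every treatment group with a named control, controlling the
#' family-wise error rate over the set of comparisons. Adjusted p values are
#' computed from the null distribution of the maximum absolute component of
#' the equicorrelated multivariate t (correlations
#' \code{sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))}), evaluated by seeded Monte
#' Carlo; they are monotone in |t| by construction. With a single treatment
#' group this reduces to the two-sided pooled t test.
#'
#' @param values,groups observations and labels.
#' @param control control group label.
#' @param mc_draws Monte Carlo draws (default 1e5).
#' @param seed RNG seed for the draws.
#' @return data.frame with one row per treatment group: \code{comparison},
#'   \code{estimate}, \code{t}, \code{p_adjusted}.
#' @export
dunnett_test <- function(values, groups, control, mc_draws = 1e5, seed = 1L) {
  d <- check_design(values, groups)
  lev <- levels(d$groups)
  if (!control %in% lev) stop("control group '", control, "' not present")
  trt <- setdiff(lev, control)
  n <- table(d$groups)
  means <- tapply(d$values, d$groups, mean)
  ss <- sum(tapply(d$values, d$groups, function(v) sum((v - mean(v))^2)))
  df <- length(d$values) - length(lev)
  if (df < 1) stop("no residual degrees of freedom")
  s2 <- ss / df
  tstat <- (means[trt] - means[control]) /
    sqrt(s2 * (1 / n[trt] + 1 / n[control]))
  k <- length(trt)
  maxT <- with_seed(seed, {
    z0 <- rnorm(mc_draws)
    Tmat <- vapply(trt, function(g) {
      zi <- rnorm(mc_draws)
      (zi / sqrt(n[g]) - z0 / sqrt(n[control])) /
        sqrt(1 / n[g] + 1 / n[control])
    }, numeric(mc_draws))
    s <- sqrt(rchisq(mc_draws, df) / df)
    m <- abs(Tmat[, 1])
    for (j in seq_len(ncol(Tmat))[-1]) m <- pmax(m, abs(Tmat[, j]))
    m / s
  })
  padj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
  data.frame(comparison = paste(trt, "-", control),
             estimate = as.numeric(means[trt] - means[control]),
             t = as.numeric(tstat),
             p_adjusted = padj,
             stringsAsFactors = FALSE)
}

#' Tukey honest-significant-difference comparisons
#'
#' All pairwise comparisons with family-wise adjustment from the studentized
#' range distribution (pooled variance).
#'
#' @param values,groups observations and labels.
#' @return data.frame with columns \code{comparison}, \code{estimate},
#'   \code{t}, \code{p_adjusted}.
#' @export
tukey_hsd <- function(values, groups) {
  d <- check_design(values, groups)
  lev <- levels(d$groups)
  k <- length(lev)
  n <- table(d$groups)
  means <- tapply(d$values, d$groups, mean)
  ss <- sum(tapply(d$values, d$groups, function(v) sum((v - mean(v))^2)))
  df <- length(d$values) - k
  s2 <- ss / df
  pairs <- combn(lev, 2)
  est <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(s2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  tstat <- est / se
  padj <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
  data.frame(comparison = paste(pairs[2, ], "-", pairs[1, ]),
             estimate = as.numeric(est), t = as.numeric(tstat),
             p_adjusted = as.numeric(padj), stringsAsFactors = FALSE)
}

#' Two-way fixed-effects ANOVA (Type II)
#'
#' Fits \code{value ~ factor1 * factor2} and reports marginal (Type II) sums
#' of squares, appropriate for the unbalanced layouts that arise with unequal
#' mice per group. Typical use: treatment group crossed with depth bin for
#' intensity profiles.
#'
#' @param values numeric observations.
#' @param factor1,factor2 factor labels (e.g. group and depth bin).
#' @return data.frame with one row per effect (\code{factor1},
#'   \code{factor2}, \code{interaction}): \code{df}, \code{F}, \code{p}.
#' @export
two_way_anova <- function(values, factor1, factor2) {
  stopifnot(length(values) == length(factor1), length(values) == length(factor2))
  f1 <- as.factor(as.character(factor1)); f2 <- as.factor(as.character(factor2))
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("both factors need at least 2 levels")
  cells <- table(f1, f2)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  # Type II (marginal) sums of squares from nested model comparisons:
  # each main effect is adjusted for the other, the interaction for both.
  rss <- function(form) sum(lm(form)$residuals^2)
  full <- lm(values ~ f1 * f2)
  rss_full <- sum(full$residuals^2)
  df_res <- full$df.residual
  ss1 <- rss(values ~ f2) - rss(values ~ f1 + f2)
  ss2 <- rss(values ~ f1) - rss(values ~ f1 + f2)
  ss12 <- rss(values ~ f1 + f2) - rss_full
  df1 <- nlevels(f1) - 1L
  df2 <- nlevels(f2) - 1L
  df12 <- df1 * df2
  ss <- pmax(c(ss1, ss2, ss12), 0)
  dfe <- c(df1, df2, df12)
  if (rss_full <= 1e-12 * max(1, var(values) * length(values))) {
    # saturated/noiseless fit: effects with zero marginal SS get F = 0,
    # effects with positive SS are infinitely significant
    F <- ifelse(ss <= 1e-12, 0, Inf)
    p <- ifelse(ss <= 1e-12, 1, 0)
  } else {
    F <- (ss / dfe) / (rss_full / df_res)
    p <- pf(F, dfe, df_res, lower.tail = FALSE)
  }
  data.frame(effect = c("factor1", "factor2", "interaction"),
             df = dfe, F = F, p = p, stringsAsFactors = FALSE)
}

#' Two-group Student's t test
#'
#' Two-sided, pooled-variance by default (set \code{var_equal = FALSE} for
#' Welch).
#'
#' @param values,groups observations and labels (exactly 2 groups).
#' @param var_equal pool the variances (default TRUE).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
t_test_groups <- function(values, groups, var_equal = TRUE) {
  d <- check_design(values, groups)
  if (nlevels(d$groups) != 2) stop("t test expects exactly 2 groups")
  ht <- t.test(d$values[d$groups == levels(d$groups)[2]],
               d$values[d$groups == levels(d$groups)[1]],
               var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-group Mann-Whitney U test
#'
#' Two-sided; exact null when both groups have at most 8 observations and
#' there are no ties, normal approximation with continuity and tie correction
#' otherwise.
#'
#' @param values,groups observations and labels (exactly 2 groups).
#' @return list with \code{U}, \code{p}, \code{exact}.
#' @export
mann_whitney <- function(values, groups) {
  d <- check_design(values, groups)
  if (nlevels(d$groups) != 2) stop("Mann-Whitney expects exactly 2 groups")
  x <- d$values[d$groups == levels(d$groups)[1]]
  y <- d$values[d$groups == levels(d$groups)[2]]
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= 8 && length(y) <= 8
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}
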