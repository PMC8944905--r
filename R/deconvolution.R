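# Immune cell-type deconvolution of bulk expression: simplex-constrained
# least squares against a signature matrix, plus fine-to-major aggregation.

# Solve min ||S f - x||^2  s.t.  sum(f) = 1, f >= 0, by a primal active-set
# method. Each equality-constrained subproblem is solved through its KKT
# system; variables are clamped to zero when they would go negative and
# released when their Lagrange multiplier indicates a descent direction.
solve_simplex_ls <- function(S, x, tol = 1e-9, max_iter = NULL) {
  p <- ncol(S)
  if (is.null(max_iter)) max_iter <- 50L * p
  StS <- crossprod(S)
  Stx <- crossprod(S, x)
  free <- rep(TRUE, p)
  f <- rep(1 / p, p)
  rank_warn <- FALSE

  solve_kkt <- function(free) {
    k <- sum(free)
    K <- rbind(cbind(2 * StS[free, free, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(2 * Stx[free], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) {  # rank-deficient subproblem: minimum-norm solution
      rank_warn <<- TRUE
      sol <- as.numeric(MASS::ginv(K) %*% rhs)
    }
    list(f = sol[seq_len(k)], lambda = sol[k + 1])
  }

  lambda <- 0
  for (it in seq_len(max_iter)) {
    sol <- solve_kkt(free)
    f_new <- rep(0, p)
    f_new[free] <- sol$f
    lambda <- sol$lambda
    if (all(f_new[free] >= -tol)) {
      f <- pmax(f_new, 0)
      # KKT multipliers for clamped variables must be non-negative
      grad <- 2 * (StS %*% f - Stx) + lambda
      mu <- grad[!free]
      if (!any(!free) || all(mu >= -max(tol, 1e-7 * max(abs(grad))))) break
      release <- which(!free)[which.min(mu)]
      free[release] <- TRUE
    } else {
      # step from f toward f_new until the first free variable hits zero
      d <- f_new - f
      blocking <- free & (f_new < -tol) & (d < 0)
      alpha <- min(-f[blocking] / d[blocking])
      f <- pmax(f + alpha * d, 0)
      hit <- which(blocking)[which.min(-f[blocking] / d[blocking])]
      # clamp every free variable driven (numerically) to zero
      clamp <- free & f <= tol & d < 0
      clamp[hit] <- TRUE
      free[clamp] <- FALSE
      f[clamp] <- 0
      if (!any(free)) { free[which.max(Stx)] <- TRUE }
    }
  }
  f <- pmax(f, 0)
  f <- f / sum(f)
  list(f = f, rank_deficient = rank_warn)
}

#' Deconvolve a bulk sample into cell-type fractions
#'
#' Estimates the cell-type composition of bulk expression profiles under the
#' linear mixing model \code{x = S f}: fractions minimize the least-squares
#' residual subject to non-negativity and sum-to-one (the probability
#' simplex), solved exactly by an active-set quadratic program. Genes are
#' matched case-insensitively between mixture and signature; a warning is
#' given when fewer than half of the mixture genes are found in the
#' signature.
#'
#' @param mixtures numeric matrix (genes x samples) or vector (one sample) of
#'   bulk expression, rownames = gene symbols.
#' @param signature numeric matrix (genes x cell types), non-negative, no
#'   all-zero column, rownames = gene symbols.
#' @return data.frame of class \code{fbr_fractions}: one row per sample x
#'   type with columns \code{sample}, \code{cell_type}, \code{fraction}, plus
#'   attributes \code{residual_norm} (per sample) and
#'   \code{rank_deficient} (logical flag per sample).
#' @examples
#' gen <- generate_signature_and_mixtures(60, 3, 2, noise_sd = 0, seed = 1)
#' deconvolve(gen$mixtures, gen$signature)
#' @export
deconvolve <- function(mixtures, signature) {
  if (is.null(dim(mixtures))) mixtures <- cbind(sample_1 = mixtures)
  if (is.null(rownames(signature)) || is.null(rownames(mixtures)))
    stop("mixtures and signature need gene rownames")
  if (any(signature < 0)) stop("signature must be non-negative")
  if (any(colSums(signature) == 0)) stop("signature has an all-zero column")
  gm <- tolower(rownames(mixtures)); gs <- tolower(rownames(signature))
  common <- intersect(gm, gs)
  if (length(common) < ncol(signature))
    stop("fewer shared genes than cell types; system underdetermined")
  if (length(common) < 0.5 * length(gm))
    warning(sprintf("only %d/%d mixture genes found in the signature",
                    length(common), length(gm)))
  S <- signature[match(common, gs), , drop = FALSE]
  X <- mixtures[match(common, gm), , drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("sample_", seq_len(ncol(X)))
  types <- colnames(signature)
  if (is.null(types)) types <- paste0("type_", seq_len(ncol(signature)))

  res <- lapply(seq_len(ncol(X)), function(j) solve_simplex_ls(S, X[, j]))
  fr <- vapply(res, `[[`, numeric(ncol(S)), "f")
  if (is.null(dim(fr))) fr <- matrix(fr, ncol = length(res))
  resid <- vapply(seq_len(ncol(X)), function(j)
    sqrt(sum((S %*% fr[, j] - X[, j])^2)), numeric(1))
  rk <- vapply(res, `[[`, logical(1), "rank_deficient")
  if (any(rk))
    warning("signature rank-deficient after gene intersection; ",
            "fractions may be non-unique")
  out <- data.frame(sample = rep(colnames(X), each = length(types)),
                    cell_type = rep(types, ncol(X)),
                    fraction = as.numeric(fr),
                    stringsAsFactors = FALSE)
  attr(out, "residual_norm") <- setNames(resid, colnames(X))
  attr(out, "rank_deficient") <- setNames(rk, colnames(X))
  class(out) <- c("fbr_fractions", "data.frame")
  out
}

#' Aggregate fine cell-type fractions into major types
#'
#' Sums the fractions of the fine types belonging to each major group (for
#' the default taxonomy: granulocytes, B cells, T cells, NK cells, dendritic
#' cells, mono/macrophages). The result stays on the probability simplex.
#'
#' @param fractions output of \code{\link{deconvolve}} (or any data.frame
#'   with \code{sample}, \code{cell_type}, \code{fraction}).
#' @param grouping data.frame with columns \code{fine_type},
#'   \code{major_type}; defaults to \code{\link{default_cell_grouping}}.
#' @return data.frame with columns \code{sample}, \code{major_type},
#'   \code{fraction}.
#' @export
aggregate_fractions <- function(fractions, grouping = default_cell_grouping()) {
  stopifnot(all(c("sample", "cell_type", "fraction") %in% names(fractions)))
  unmapped <- setdiff(unique(fractions$cell_type), grouping$fine_type)
  if (length(unmapped))
    stop("cell types not covered by the grouping: ",
         paste(unmapped, collapse = ", "))
  fractions$major_type <-
    grouping$major_type[match(fractions$cell_type, grouping$fine_type)]
  agg <- aggregate(fraction ~ sample + major_type, data = fractions, FUN = sum)
  agg[order(agg$sample, agg$major_type), c("sample", "major_type", "fraction")]
}
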