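# subset a qtlx_prep to a set of individuals (e.g. complete phenotypes)
subset_prep <- function(prep, keep) {
  prep$X0 <- prep$X0[keep, , drop = FALSE]
  prep$strat <- prep$strat[keep, , drop = FALSE]
  prep$cols <- lapply(prep$cols, function(m) m[keep, , drop = FALSE])
  prep$cross$pheno <- prep$cross$pheno[keep]
  prep$cross$sex <- prep$cross$sex[keep]
  prep$cross$direction <- prep$cross$direction[keep]
  prep
}

# resolve phenotype and drop missing values from prep + y together
.scan_inputs <- function(prep, pheno) {
  y <- if (is.null(pheno)) prep$cross$pheno else pheno
  if (length(y) != nrow(prep$X0)) stop("phenotype length does not match cross")
  keep <- !is.na(y)
  if (!all(keep)) prep <- subset_prep(prep, keep)
  list(prep = prep, y = y[keep])
}

# assemble the design columns of a QTL model beyond the null covariates
model_columns <- function(prep, model) {
  if (n_qtl(model) == 0L) return(matrix(0, nrow(prep$X0), 0L))
  idx <- model_grid_index(model, prep$grid)
  mains <- lapply(idx, function(i) prep$cols[[i]])
  ints <- if (nrow(model$edges) > 0)
    lapply(seq_len(nrow(model$edges)), function(e)
      pair_int_columns(prep, idx[model$edges[e, 1L]], idx[model$edges[e, 2L]]))
  else list()
  nm <- paste0(model$chr, "@", round(model$pos, 4))
  for (k in seq_along(mains))
    colnames(mains[[k]]) <- paste0(nm[k], ".", colnames(mains[[k]]))
  do.call(cbind, c(mains, ints))
}

lod_from_rss <- function(rss0, rss1, n) {
  pmax((n / 2) * log10(rss0 / pmax(rss1, 1e-300)), 0)
}

#' Fit a multiple-QTL model by Haley-Knott regression
#'
#' Least-squares fit of intercept + null covariates + per-QTL main-effect
#' columns + per-edge interaction columns, with the LOD score taken against
#' the null model (intercept + null covariates only).  Individuals with
#' missing phenotype are dropped from both fits.
#'
#' @param prep A [scan_prep()] object.
#' @param model A [qtl_model()]; the empty model gives LOD 0.
#' @param pheno Optional phenotype vector (default: the cross phenotype).
#' @return Object of class `qtlx_modelfit`: `lod`, `rss_null`, `rss_model`,
#'   `n`, `coef`, `fitted`, `residuals`, `rank_deficient`.
#' @export
fit_model <- function(prep, model, pheno = NULL) {
  si <- .scan_inputs(prep, pheno)
  prep <- si$prep; y <- si$y
  n <- length(y)
  X <- cbind(prep$X0, model_columns(prep, model))
  f0 <- stats::lm.fit(prep$X0, y)
  f1 <- stats::lm.fit(X, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  structure(list(model = model,
                 lod = lod_from_rss(rss0, rss1, n),
                 rss_null = rss0, rss_model = rss1, n = n,
                 coef = f1$coefficients,
                 fitted = f1$fitted.values, residuals = f1$residuals,
                 rank_deficient = f1$rank < ncol(X)),
            class = "qtlx_modelfit")
}

#' @export
print.qtlx_modelfit <- function(x, ...) {
  cat("Haley-Knott fit:", n_qtl(x$model), "QTL,",
      nrow(x$model$edges), "interactions; LOD =", round(x$lod, 3),
      "(n =", x$n, ")\n")
  if (x$rank_deficient) cat("  note: rank-deficient design (pseudoinverse fit)\n")
  invisible(x)
}

#' Single-QTL genome scan
#'
#' At every grid position, the LOD score of context + position versus the
#' context model (by default the null model).  The null covariates of the
#' design are present in both models at every position; X-chromosome
#' positions use the sex/direction-specific column scheme.
#'
#' @param prep A [scan_prep()] object.
#' @param pheno Optional phenotype vector.
#' @param context Optional `qtlx_model` whose columns are included in both
#'   the null and the alternative at every position (used during forward
#'   selection).
#' @return A data.frame of class `qtlx_scan1` with columns `chr`, `pos`,
#'   `is_X`, `label`, `lod`; attributes `n` and `rss0`.
#' @export
scanone <- function(prep, pheno = NULL, context = NULL) {
  si <- .scan_inputs(prep, pheno)
  prep <- si$prep; y <- matrix(si$y)
  n <- nrow(y)
  Xbase <- if (is.null(context) || n_qtl(context) == 0L) prep$X0
           else cbind(prep$X0, model_columns(prep, context))
  rss0 <- cpp_rss(Xbase, y)
  rss <- cpp_rss_scan(prep$cols, Xbase, y, list())
  out <- prep$grid[, c("chr", "pos", "is_X", "label")]
  out$lod <- lod_from_rss(rss0, rss[, 1L], n)
  attr(out, "n") <- n
  attr(out, "rss0") <- rss0
  class(out) <- c("qtlx_scan1", "data.frame")
  out
}

#' @export
summary.qtlx_scan1 <- function(object, threshold = 0, ...) {
  # per-chromosome maxima above threshold
  sp <- split(seq_len(nrow(object)), object$chr)
  rows <- vapply(sp, function(i) i[which.max(object$lod[i])], 0L)
  res <- object[sort(rows), , drop = FALSE]
  res[res$lod >= threshold, c("chr", "pos", "label", "lod")]
}

#' @export
plot.qtlx_scan1 <- function(x, ...) {
  chrs <- unique(x$chr)
  off <- 0; xs <- numeric(nrow(x)); ticks <- numeric(length(chrs))
  for (k in seq_along(chrs)) {
    i <- x$chr == chrs[k]
    xs[i] <- x$pos[i] + off
    ticks[k] <- off + mean(range(x$pos[i]))
    off <- max(xs[i]) + 10
  }
  graphics::plot(xs, x$lod, type = "n", xaxt = "n", xlab = "Chromosome",
                 ylab = "LOD", ...)
  for (k in seq_along(chrs)) {
    i <- x$chr == chrs[k]
    graphics::lines(xs[i], x$lod[i])
  }
  graphics::axis(1, at = ticks, labels = chrs)
  invisible(x)
}

# pair table for a 2d scan: unordered position pairs (grid row indices,
# i < j), self-pairs excluded, labelled by region AA/AX/XX
pair_table <- function(grid, regions = c("AA", "AX", "XX")) {
  idx <- seq_len(nrow(grid))
  pairs <- utils::combn(idx, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  nx <- grid$is_X[i] + grid$is_X[j]
  region <- c("AA", "AX", "XX")[nx + 1L]
  keep <- region %in% regions
  data.frame(i = i[keep], j = j[keep], region = region[keep])
}

#' Two-dimensional, two-QTL genome scan
#'
#' For every pair of grid positions: the LOD of the full two-QTL model
#' (both main effects plus their interaction), of the additive two-QTL
#' model, their difference (the interaction LOD), and the full LOD minus
#' the better of the pair's two single-QTL LODs (`lod_fv1`, the
#' full-versus-one comparison used for the light interaction penalty).
#' Pairs are labelled by region (`AA`, `AX`, `XX`) according to which of
#' the two positions are on the X chromosome.
#'
#' @param prep A [scan_prep()] object.
#' @param pheno Optional phenotype vector.
#' @param regions Subset of `c("AA","AX","XX")` to scan (region-restricted
#'   scans are used for far-tail penalty replicates).
#' @return A data.frame of class `qtlx_scan2` with pair positions, region,
#'   `lod_full`, `lod_add`, `lod_int`, `lod_fv1`; attribute `scanone_max`.
#' @export
scantwo <- function(prep, pheno = NULL, regions = c("AA", "AX", "XX")) {
  regions <- match.arg(regions, several.ok = TRUE)
  si <- .scan_inputs(prep, pheno)
  prep <- si$prep; y <- matrix(si$y)
  n <- nrow(y)
  s1 <- scanone(prep, si$y)
  pt <- pair_table(prep$grid, regions)
  if (nrow(pt) == 0L) stop("no position pairs in the requested regions")
  rss0 <- cpp_rss(prep$X0, y)
  res <- cpp_rss_pairs(prep$cols, prep$X0, y, pt$i - 1L, pt$j - 1L,
                       as.integer(prep$grid$is_X), prep$strat)
  out <- data.frame(chr1 = prep$grid$chr[pt$i], pos1 = prep$grid$pos[pt$i],
                    chr2 = prep$grid$chr[pt$j], pos2 = prep$grid$pos[pt$j],
                    region = pt$region,
                    lod_full = lod_from_rss(rss0, res$rss_full[, 1L], n),
                    lod_add = lod_from_rss(rss0, res$rss_add[, 1L], n))
  out$lod_int <- pmax(out$lod_full - out$lod_add, 0)
  out$lod_fv1 <- out$lod_full - pmax(s1$lod[pt$i], s1$lod[pt$j])
  attr(out, "scanone_max") <- max(s1$lod)
  attr(out, "scanone_chr_max") <- tapply(s1$lod, s1$chr, max)
  attr(out, "n") <- n
  class(out) <- c("qtlx_scan2", "data.frame")
  out
}

#' Condensed chromosome-pair summary of a two-QTL scan
#'
#' For each chromosome pair: the maximum full and additive LODs over the
#' pair's 2D grid (maximized separately), the interaction LOD as their
#' difference, and the full-versus-one LOD (max full minus the larger
#' single-QTL maximum of the two chromosomes).  This condensed convention
#' is the one the penalty thresholds are derived under.
#'
#' @param object A [scantwo()] result.
#' @param ... Unused.
#' @return A data.frame with one row per chromosome pair.
#' @export
summary.qtlx_scan2 <- function(object, ...) {
  s1max <- attr(object, "scanone_chr_max")
  key <- paste(object$chr1, object$chr2)
  out <- NULL
  for (k in unique(key)) {
    rows <- object[key == k, , drop = FALSE]
    bf <- rows[which.max(rows$lod_full), ]
    mf <- max(rows$lod_full); ma <- max(rows$lod_add)
    out <- rbind(out, data.frame(
      chr1 = bf$chr1, chr2 = bf$chr2, pos1 = bf$pos1, pos2 = bf$pos2,
      region = bf$region, lod_full = mf, lod_add = ma, lod_int = mf - ma,
      lod_fv1 = mf - max(s1max[[bf$chr1]], s1max[[bf$chr2]])))
  }
  rownames(out) <- NULL
  out
}

#' Maximum LOD within a region
#'
#' @param x A `qtlx_scan1` or `qtlx_scan2` result.
#' @param region For single-QTL scans `"A"`, `"X"` or `"all"`; for two-QTL
#'   scans `"AA"`, `"AX"`, `"XX"` or `"all"`.
#' @param statistic For two-QTL scans, which surface to maximize:
#'   `"int"`, `"full"`, `"add"` or `"fv1"`.
#' @return The maximum LOD (error if the region is empty).
#' @export
region_max <- function(x, region = "all", statistic = "int") {
  UseMethod("region_max")
}

#' @rdname region_max
#' @export
region_max.qtlx_scan1 <- function(x, region = "all", statistic = NULL) {
  keep <- switch(region, all = rep(TRUE, nrow(x)), A = !x$is_X, X = x$is_X,
                 stop("region must be 'A', 'X' or 'all'"))
  if (!any(keep)) stop("empty region: ", region)
  max(x$lod[keep])
}

#' @rdname region_max
#' @export
region_max.qtlx_scan2 <- function(x, region = "all", statistic = "int") {
  stat <- switch(statistic, int = x$lod_int, full = x$lod_full,
                 add = x$lod_add, fv1 = x$lod_fv1,
                 stop("unknown statistic: ", statistic))
  keep <- if (region == "all") rep(TRUE, nrow(x)) else x$region == region
  if (!any(keep)) stop("empty region: ", region)
  max(stat[keep])
}
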