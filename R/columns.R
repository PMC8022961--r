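#' Null-model covariates for a cross design
#'
#' The covariates that must be present under the null model (and therefore
#' under every model) to avoid spurious X-chromosome linkage: a sex
#' indicator when both sexes are present, a cross-direction indicator when
#' both directions are present, and with both sexes and both directions two
#' columns spanning the three strata (female-dir0, female-dir1, male).
#'
#' @param cross A `qtlx_cross`.
#' @return Numeric matrix with `n_ind(cross)` rows and 0+ named columns
#'   (intercept not included).
#' @export
null_covariates <- function(cross) {
  n <- n_ind(cross)
  d <- cross$design
  cols <- NULL
  if (d$sexes == "both" && d$directions == "both") {
    cols <- cbind(male = as.numeric(cross$sex == 1L),
                  fdir1 = as.numeric(cross$sex == 0L & cross$direction == 1L))
  } else if (d$sexes == "both") {
    cols <- cbind(sex = as.numeric(cross$sex == 1L))
  } else if (d$directions == "both") {
    cols <- cbind(dir = as.numeric(cross$direction == 1L))
  } else {
    cols <- matrix(0, n, 0)
  }
  cols
}

#' QTL main-effect design columns at one position
#'
#' The Haley-Knott regressors for a QTL at a position: expected-genotype
#' indicator columns on an autosome (one for a backcross, two for an
#' intercross), and sex/direction-stratified genotype columns on the X
#' chromosome (zeroed outside the relevant stratum), e.g. one female plus
#' one male column in a backcross with both sexes, or two female columns
#' plus one male column in an intercross with both sexes and directions.
#'
#' @param cross A `qtlx_cross`.
#' @param pr Matrix (individuals x states) of genotype-state probabilities
#'   at the position (a slice of [calc_genoprob()]).
#' @param is_X Is the position on the X chromosome?
#' @return Numeric matrix of named design columns.
#' @export
qtl_columns <- function(cross, pr, is_X) {
  d <- cross$design
  if (!is_X) {
    if (d$type == "bc") {
      cbind(g = pr[, 2L])
    } else {
      cbind(gAB = pr[, 2L], gBB = pr[, 3L])
    }
  } else {
    p2 <- pr[, 2L]                      # P(recombinant X carries allele B)
    both_sexes <- d$sexes == "both"
    both_dir <- d$directions == "both"
    female <- cross$sex == 0L
    if (both_sexes && both_dir) {
      # female genotype classes across directions: AA (dir0,state1),
      # AB (reference), BB (dir1,state2); plus one male column
      cbind(fAA = (1 - p2) * (female & cross$direction == 0L),
            fBB = p2 * (female & cross$direction == 1L),
            m = p2 * !female)
    } else if (both_sexes) {
      cbind(f = p2 * female, m = p2 * !female)
    } else if (both_dir) {              # females only, both directions
      cbind(fAA = (1 - p2) * (cross$direction == 0L),
            fBB = p2 * (cross$direction == 1L))
    } else {
      cbind(g = p2)
    }
  }
}

#' Pairwise-interaction columns
#'
#' All elementwise products of two sets of main-effect columns.  Requires
#' both main effects (hierarchy); the number of columns, and hence the
#' degrees of freedom of the interaction test, differs by region
#' (A:A vs A:X vs X:X).
#'
#' @param colsA,colsB Numeric matrices with equal row counts.
#' @return Matrix with `ncol(colsA) * ncol(colsB)` columns.
#' @export
interaction_columns <- function(colsA, colsB) {
  if (is.null(colsA) || is.null(colsB) || ncol(colsA) == 0L || ncol(colsB) == 0L)
    stop("interaction requires both main effects (model hierarchy)")
  out <- matrix(0, nrow(colsA), ncol(colsA) * ncol(colsB))
  k <- 0L
  for (i in seq_len(ncol(colsA))) for (j in seq_len(ncol(colsB))) {
    k <- k + 1L
    out[, k] <- colsA[, i] * colsB[, j]
  }
  colnames(out) <- as.vector(outer(colnames(colsA), colnames(colsB), paste, sep = ":"))
  out
}

# Epistasis columns for a pair of grid positions.  A mixed autosome-X
# pair gets, beyond the products of the two main-effect column sets,
# products of the autosomal columns with the sex/direction stratum
# indicators: the X main effect is sex-stratified, so the full model must
# allow the autosomal effect to differ between strata (joint cell means).
pair_int_columns <- function(prep, i, j) {
  out <- interaction_columns(prep$cols[[i]], prep$cols[[j]])
  xi <- prep$grid$is_X[i]; xj <- prep$grid$is_X[j]
  if (xor(xi, xj) && ncol(prep$strat) > 0L) {
    A <- if (xi) prep$cols[[j]] else prep$cols[[i]]
    out <- cbind(out, interaction_columns(A, prep$strat))
  }
  out
}

#' Precompute scan inputs
#'
#' Bundles, for a cross and its genotype probabilities, everything the scan
#' kernels need: the base design matrix (intercept + null covariates), and
#' the QTL main-effect column matrix at every grid position.
#'
#' @param cross A `qtlx_cross`.
#' @param probs A [calc_genoprob()] result (computed with `step = 0`,
#'   `error_prob = 0` if omitted).
#' @return Object of class `qtlx_prep`: list with `cross`, `grid`, `X0`,
#'   `cols` (list of per-position matrices).
#' @export
scan_prep <- function(cross, probs = NULL) {
  if (is.null(probs)) probs <- calc_genoprob(cross)
  grid <- probs$grid
  strat <- null_covariates(cross)
  X0 <- cbind(intercept = rep(1, n_ind(cross)), strat)
  cols <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ch <- grid$chr[i]
    pr <- probs$chroms[[ch]][, grid$index[i], , drop = FALSE][, 1L, ]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
    cols[[i]] <- qtl_columns(cross, pr, grid$is_X[i])
  }
  structure(list(cross = cross, grid = grid, X0 = X0, strat = strat,
                 cols = cols),
            class = "qtlx_prep")
}
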