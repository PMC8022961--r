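#' Apportion a genome-wide significance level across regions
#'
#' Splits an overall level `alpha` into per-region levels proportional to
#' genetic length (main effects) or search area (interaction regions):
#' `alpha_i = 1 - (1 - alpha)^(L_i/L)` for the autosomes and X chromosome,
#' and `alpha_i = 1 - (1 - alpha)^(S_i/S)` for the pair regions, where
#' `S_AA = L_A^2/2`, `S_AX = L_A L_X`, `S_XX = L_X^2/2` and
#' `S = S_AA + S_AX + S_XX = L^2/2`.  These satisfy
#' `(1-alpha_A)(1-alpha_X) = 1-alpha` and
#' `(1-alpha_AA)(1-alpha_AX)(1-alpha_XX) = 1-alpha` exactly.
#'
#' @param alpha Overall significance level (default 0.05).
#' @param map A `qtlx_map`.
#' @return Object of class `qtlx_alpha`: `alpha`, `alpha_A`, `alpha_X`,
#'   `alpha_AA`, `alpha_AX`, `alpha_XX`, the areas `S_AA`, `S_AX`, `S_XX`,
#'   `S`, and the lengths `L_A`, `L_X`, `L`.  X-dependent entries are `NA`
#'   when the map has no X chromosome.
#' @export
apportion_alpha <- function(alpha = 0.05, map) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  len <- map_length(map)
  LA <- len[["L_A"]]; LX <- len[["L_X"]]; L <- len[["L"]]
  if (LA <= 0) stop("map has no autosomal length")
  SAA <- LA^2 / 2; SAX <- LA * LX; SXX <- LX^2 / 2
  S <- SAA + SAX + SXX
  a <- function(frac) 1 - (1 - alpha)^frac
  out <- list(alpha = alpha,
              alpha_A = a(LA / L),
              alpha_X = if (LX > 0) a(LX / L) else NA_real_,
              alpha_AA = a(SAA / S),
              alpha_AX = if (LX > 0) a(SAX / S) else NA_real_,
              alpha_XX = if (LX > 0) a(SXX / S) else NA_real_,
              S_AA = SAA, S_AX = SAX, S_XX = SXX, S = S,
              L_A = LA, L_X = LX, L = L)
  class(out) <- "qtlx_alpha"
  out
}

#' @export
print.qtlx_alpha <- function(x, ...) {
  cat("alpha =", x$alpha, " (L_A =", x$L_A, ", L_X =", x$L_X, ")\n")
  cat(sprintf("  mains: alpha_A = %.5g, alpha_X = %.5g\n", x$alpha_A, x$alpha_X))
  cat(sprintf("  pairs: alpha_AA = %.5g, alpha_AX = %.5g, alpha_XX = %.5g\n",
              x$alpha_AA, x$alpha_AX, x$alpha_XX))
  invisible(x)
}

#' Replicate counts per interaction region
#'
#' The A:X and X:X interaction quantiles lie much farther out in the tail
#' than the A:A quantile, so replicates are allocated inversely to region
#' area: `reps_AX = base * S_AA/S_AX` (that is, `base * L_A/(2 L_X)`) and
#' `reps_XX = base * S_AA/S_XX = base * (L_A/L_X)^2`.
#'
#' @param base Replicates for the A:A region.
#' @param alloc An [apportion_alpha()] object.
#' @return Named integer vector `c(AA, AX, XX)`.
#' @export
allocate_replicates <- function(base, alloc) {
  stopifnot(base >= 1)
  if (is.na(alloc$alpha_X)) stop("no X chromosome: only the A:A region exists")
  c(AA = as.integer(base),
    AX = as.integer(round(base * alloc$S_AA / alloc$S_AX)),
    XX = as.integer(round(base * alloc$S_AA / alloc$S_XX)))
}

#' Construct a penalty set
#'
#' Holds the penalties of one method: `XneA` (X treated separately) uses
#' `T_mA`, `T_mX`, `T_iAAH`, `T_iAAL`, `T_iAX`, `T_iXX`; `XeqA` (X treated
#' like an autosome) uses `T_m`, `T_iH`, `T_iL`.
#'
#' @param method `"XneA"` or `"XeqA"`.
#' @param T_m,T_iH,T_iL XeqA penalties (LOD units).
#' @param T_mA,T_mX,T_iAAH,T_iAAL,T_iAX,T_iXX XneA penalties (LOD units).
#' @param alpha Significance level the penalties were derived at.
#' @param provenance Optional list (replicate counts, seed, map hash).
#' @return Object of class `qtlx_penalties`.
#' @export
penalties <- function(method = c("XneA", "XeqA"),
                      T_m = NA, T_iH = NA, T_iL = NA,
                      T_mA = NA, T_mX = NA, T_iAAH = NA, T_iAAL = NA,
                      T_iAX = NA, T_iXX = NA,
                      alpha = NA, provenance = NULL) {
  method <- match.arg(method)
  need <- if (method == "XneA") c(T_mA = T_mA, T_iAAH = T_iAAH, T_iAAL = T_iAAL)
          else c(T_m = T_m, T_iH = T_iH, T_iL = T_iL)
  if (anyNA(need))
    stop("missing required penalties for method ", method, ": ",
         paste(names(need)[is.na(need)], collapse = ", "))
  vals <- c(T_m, T_iH, T_iL, T_mA, T_mX, T_iAAH, T_iAAL, T_iAX, T_iXX)
  if (any(!is.na(vals) & vals <= 0)) stop("penalties must be positive")
  if (method == "XneA" && !is.na(T_iAAL) && T_iAAL >= T_iAAH)
    warning("light penalty is not below the heavy penalty; ",
            "light/heavy logic is degenerate")
  if (method == "XeqA" && !is.na(T_iL) && T_iL >= T_iH)
    warning("light penalty is not below the heavy penalty; ",
            "light/heavy logic is degenerate")
  structure(list(method = method, T_m = T_m, T_iH = T_iH, T_iL = T_iL,
                 T_mA = T_mA, T_mX = T_mX, T_iAAH = T_iAAH, T_iAAL = T_iAAL,
                 T_iAX = T_iAX, T_iXX = T_iXX,
                 alpha = alpha, provenance = provenance),
            class = "qtlx_penalties")
}

#' @export
print.qtlx_penalties <- function(x, ...) {
  cat("Penalties (", x$method, ", alpha = ", x$alpha, "):\n", sep = "")
  flds <- if (x$method == "XneA")
    c("T_mA", "T_mX", "T_iAAH", "T_iAAL", "T_iAX", "T_iXX")
  else c("T_m", "T_iH", "T_iL")
  for (f in flds) cat(sprintf("  %-7s %.3f\n", f, x[[f]]))
  invisible(x)
}

# far-tail empirical quantile (type 7), warning when the expected number
# of exceedances is too small for a stable estimate
tail_quantile <- function(x, p, what = "") {
  ex <- length(x) * (1 - p)
  if (ex < 5)
    warning(sprintf(paste0("quantile %s estimated with only %.1f expected ",
                           "exceedances (n=%d); estimate is unstable"),
                    what, ex, length(x)))
  unname(stats::quantile(x, p, type = 7))
}

# default phenotypes-per-genome for each null-scan batch; far-tail
# batches reuse each simulated genome for more null phenotypes (kept
# small so that quantile estimates average over many genomes)
.batch_B <- c(scan1 = 4, scan1X = 40, AA = 8, AX = 24, XX = 200)

# default evaluation-grid pseudomarker step (cM) per batch: dense grids
# where the scan is small; 5 cM for the genome-wide 2D batch, whose cost
# grows with the fourth power of grid density
.batch_step <- c(scan1 = 2.5, scan1X = 2.5, AA = 5, AX = 5, XX = 2.5)

# simulate (or permute) a block of null phenotypes
.null_pheno <- function(n, B, pheno = NULL, strata = NULL) {
  if (is.null(pheno)) return(matrix(rnorm(n * B), n, B))
  Y <- matrix(0, n, B)
  for (b in seq_len(B)) {
    perm <- seq_len(n)
    for (s in unique(strata)) {
      i <- which(strata == s)
      perm[i] <- i[sample.int(length(i))]
    }
    Y[, b] <- pheno[perm]
  }
  Y
}

# restrict a prep to the grid rows of the given chromosomes
.prep_filter_chr <- function(prep, chrs) {
  keep <- prep$grid$chr %in% chrs
  prep$grid <- prep$grid[keep, , drop = FALSE]
  prep$cols <- prep$cols[keep]
  prep
}

# one batch of null single-QTL scans; returns per-replicate maxima
# (columns maxA, maxX, maxG) over the chromosomes present in `map`
.batch_scan1 <- function(map, design, n, reps, B, seed0,
                         cross = NULL, pheno = NULL, step = 0) {
  nset <- ceiling(reps / B)
  maxA <- maxX <- maxG <- numeric(0)
  fixed_prep <- if (!is.null(cross))
    .prep_filter_chr(scan_prep(cross, calc_genoprob(cross, step = step,
                                                    error_prob = 1e-4)),
                     names(map))
  strata <- if (!is.null(cross)) cross$sex * 2L + cross$direction
  for (g in seq_len(nset)) {
    set.seed(seed0 + g)
    if (is.null(cross)) {
      cr <- sim_cross(n, map, design)
      prep <- scan_prep(cr, calc_genoprob(cr, step = step))
    } else prep <- fixed_prep
    Bg <- min(B, reps - (g - 1L) * B)
    Y <- .null_pheno(nrow(prep$X0), Bg, pheno, strata)
    rss0 <- cpp_rss(prep$X0, Y)
    rss <- cpp_rss_scan(prep$cols, prep$X0, Y, list())
    lod <- (nrow(Y) / 2) * log10(outer(rep(1, nrow(rss)), rss0) / rss)
    isx <- prep$grid$is_X
    if (any(!isx)) maxA <- c(maxA, apply(lod[!isx, , drop = FALSE], 2, max))
    if (any(isx)) maxX <- c(maxX, apply(lod[isx, , drop = FALSE], 2, max))
    maxG <- c(maxG, apply(lod, 2, max))
  }
  list(maxA = maxA, maxX = maxX, maxG = maxG)
}

# chromosome-pair bookkeeping for the condensed two-QTL summaries
.chrpair_info <- function(grid, pt) {
  chrs <- unique(grid$chr)
  c1 <- match(grid$chr[pt$i], chrs)
  c2 <- match(grid$chr[pt$j], chrs)
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  key <- paste(lo, hi)
  ukey <- unique(key)
  first <- match(ukey, key)
  list(chr_of_pos = match(grid$chr, chrs) - 1L, nchr = length(chrs),
       id = match(key, ukey) - 1L, n = length(ukey),
       region = pt$region[first], c1 = lo[first], c2 = hi[first])
}

# One batch of null two-QTL scans over the given pair regions.  Uses the
# condensed convention: for each chromosome pair, the interaction LOD is
# max(full) - max(add) over its 2D grid (each maximized separately), and
# the full-versus-one LOD is max(full) minus the larger single-QTL
# maximum of the two chromosomes.  Returns per-replicate region maxima.
.batch_scan2 <- function(map, design, n, reps, B, seed0, regions,
                         cross = NULL, pheno = NULL, step = 0) {
  nset <- ceiling(reps / B)
  out <- list()
  fixed_prep <- if (!is.null(cross))
    .prep_filter_chr(scan_prep(cross, calc_genoprob(cross, step = step,
                                                    error_prob = 1e-4)),
                     names(map))
  strata <- if (!is.null(cross)) cross$sex * 2L + cross$direction
  pt <- cp <- NULL
  for (g in seq_len(nset)) {
    set.seed(seed0 + g)
    if (is.null(cross)) {
      cr <- sim_cross(n, map, design)
      prep <- scan_prep(cr, calc_genoprob(cr, step = step))
    } else prep <- fixed_prep
    if (is.null(pt) || is.null(cross)) {
      pt <- pair_table(prep$grid, regions)
      cp <- .chrpair_info(prep$grid, pt)
    }
    Bg <- min(B, reps - (g - 1L) * B)
    Y <- .null_pheno(nrow(prep$X0), Bg, pheno, strata)
    mm <- cpp_pairs_chrpair_max(prep$cols, prep$X0, Y, pt$i - 1L, pt$j - 1L,
                                cp$id, cp$n, cp$chr_of_pos, cp$nchr,
                                as.integer(prep$grid$is_X), prep$strat)
    int_cp <- mm$max_full - mm$max_add
    fv1_cp <- mm$max_full - pmax(mm$max1[cp$c1, , drop = FALSE],
                                 mm$max1[cp$c2, , drop = FALSE])
    max_int <- max_fv1 <- matrix(-Inf, 3L, Bg)
    for (r in seq_along(c("AA", "AX", "XX"))) {
      rows <- cp$region == c("AA", "AX", "XX")[r]
      if (any(rows)) {
        max_int[r, ] <- apply(int_cp[rows, , drop = FALSE], 2L, max)
        max_fv1[r, ] <- apply(fv1_cp[rows, , drop = FALSE], 2L, max)
      }
    }
    out[[g]] <- list(max_int = max_int, max_fv1 = max_fv1)
  }
  list(max_int = do.call(cbind, lapply(out, `[[`, "max_int")),
       max_fv1 = do.call(cbind, lapply(out, `[[`, "max_fv1")))
}

#' Estimate all penalty classes from null genome scans
#'
#' Monte-Carlo derivation of the penalties of both methods from single-QTL
#' and two-dimensional two-QTL scans under the null hypothesis of no QTL.
#' In `simulate_null` mode, crosses are simulated on `map` and phenotypes
#' drawn i.i.d. `N(0,1)`; in `permute` mode the supplied cross's genotypes
#' are fixed and its phenotype permuted within sex-by-direction strata.
#'
#' Each main-effect penalty is the `1 - alpha_i` quantile of the maximum
#' LOD over its region; each heavy interaction penalty is the
#' `1 - alpha_i` quantile of the maximum interaction LOD over its pair
#' region; the light penalties use the maximum over pairs of the
#' full-versus-one LOD (full two-locus LOD minus the better of the pair's
#' two single-QTL LODs), minus the corresponding main-effect penalty.
#' Far-tail regions (A:X, X:X) use
#' inflated replicate counts from [allocate_replicates()] and
#' region-restricted scans; the X:X batch simulates and scans only the X
#' chromosome.
#'
#' @param map A `qtlx_map` (must include an X chromosome).
#' @param design A [cross_design()].
#' @param n Individuals per simulated cross (default 250).
#' @param alpha Overall significance level (default 0.05).
#' @param base_reps Replicates for the A:A region and the autosomal
#'   single-QTL batch (default 1056); other batches are scaled by region.
#' @param reps2d Optional separate base for the two-dimensional batches
#'   (the A:X and X:X batches scale from it); defaults to `base_reps`.
#'   Lets the costly 2D scans run at reduced replication while the cheap
#'   single-QTL batches keep full replication.
#' @param mode `"simulate_null"` or `"permute"`.
#' @param cross,pheno For `permute` mode: the observed cross and phenotype.
#' @param seed Integer seed; batch `b`, genome-set `g` uses seed
#'   `seed + b*10^7 + g` so every batch is individually reproducible.
#' @param step Evaluation-grid pseudomarker spacing in cM for the null
#'   scans: a scalar, or a named vector over batches (default
#'   `c(scan1=2.5, scan1X=2.5, AA=5, AX=5, XX=2.5)`).  Finer grids raise
#'   the maxima, and hence the penalties, slightly; 0 scans markers only.
#' @param phenos_per_geno Null phenotypes per simulated genome, either a
#'   scalar or a named vector over batches
#'   (default `c(scan1=4, scan1X=40, AA=8, AX=24, XX=200)`).
#' @param keep_samples If `TRUE`, attach the per-replicate maxima.
#' @return List of class `qtlx_penalty_set` with elements `XneA` and
#'   `XeqA` (each a [penalties()] object), `alloc`, `reps`, `seed`.
#' @export
estimate_penalties <- function(map, design = cross_design("bc"), n = 250,
                               alpha = 0.05, base_reps = 1056,
                               reps2d = NULL,
                               mode = c("simulate_null", "permute"),
                               cross = NULL, pheno = NULL, seed = 1,
                               step = NULL, phenos_per_geno = NULL,
                               keep_samples = FALSE) {
  mode <- match.arg(mode)
  if (mode == "permute") {
    if (is.null(cross) || is.null(pheno))
      stop("permute mode requires a cross and a phenotype")
    map <- cross$map; design <- cross$design; n <- n_ind(cross)
  } else cross <- NULL
  alloc <- apportion_alpha(alpha, map)
  if (is.na(alloc$alpha_X))
    stop("map has no X chromosome; X-region penalties are undefined")
  reps2 <- allocate_replicates(reps2d %||% base_reps, alloc)
  LA_LX <- alloc$L_A / alloc$L_X
  reps <- c(scan1 = as.integer(base_reps),
            scan1X = as.integer(round(base_reps * LA_LX)), reps2)
  B <- .batch_B
  if (!is.null(phenos_per_geno)) {
    if (is.null(names(phenos_per_geno))) B[] <- phenos_per_geno
    else B[names(phenos_per_geno)] <- phenos_per_geno
  }
  st <- .batch_step
  if (!is.null(step)) {
    if (is.null(names(step))) st[] <- step
    else st[names(step)] <- step
  }

  xchr <- names(map)[vapply(map, function(ch) ch$is_X, FALSE)]
  xmap <- map_subset(map, xchr)

  s1 <- .batch_scan1(map, design, n, reps["scan1"], B["scan1"],
                     seed + 1e7, cross, pheno, st[["scan1"]])
  s1x <- .batch_scan1(xmap, design, n, reps["scan1X"], B["scan1X"],
                      seed + 2e7, cross, pheno, st[["scan1X"]])
  aa <- .batch_scan2(map, design, n, reps["AA"], B["AA"],
                     seed + 3e7, c("AA", "AX", "XX"), cross, pheno, st[["AA"]])
  ax <- .batch_scan2(map, design, n, reps["AX"], B["AX"],
                     seed + 4e7, "AX", cross, pheno, st[["AX"]])
  xx <- .batch_scan2(xmap, design, n, reps["XX"], B["XX"],
                     seed + 5e7, "XX", cross, pheno, st[["XX"]])

  q <- tail_quantile
  # XeqA: one threshold per statistic, genome-wide, at level alpha
  T_m <- q(s1$maxG, 1 - alpha, "T_m")
  genome_int <- apply(aa$max_int, 2, max)
  genome_fv1 <- apply(aa$max_fv1, 2, max)
  T_iH <- q(genome_int, 1 - alpha, "T_iH")
  T_iL <- q(genome_fv1, 1 - alpha, "T_iL") - T_m
  # estimated light penalties can fall to zero at very small replicate
  # counts; floor them so the penalty set stays usable
  floor_pen <- function(x, what) {
    if (x <= 0) {
      warning("estimated ", what, " was non-positive (too few replicates); ",
              "floored at 0.001")
      0.001
    } else x
  }
  T_iL <- floor_pen(T_iL, "T_iL")

  # XneA: region-apportioned levels
  T_mA <- q(s1$maxA, 1 - alloc$alpha_A, "T_mA")
  T_mX <- q(s1x$maxX, 1 - alloc$alpha_X, "T_mX")
  T_iAAH <- q(aa$max_int[1L, ], 1 - alloc$alpha_AA, "T_iAAH")
  fv1_AA <- aa$max_fv1[1L, ]
  T_iAAL <- floor_pen(q(fv1_AA, 1 - alloc$alpha_AA, "T_iAAL") - T_mA, "T_iAAL")
  T_iAX <- q(ax$max_int[2L, ], 1 - alloc$alpha_AX, "T_iAX")
  T_iXX <- q(xx$max_int[3L, ], 1 - alloc$alpha_XX, "T_iXX")

  prov <- list(mode = mode, n = n, reps = reps, seed = seed, alpha = alpha,
               step = st, phenos_per_geno = B,
               L_A = alloc$L_A, L_X = alloc$L_X)
  out <- list(XneA = penalties("XneA", T_mA = T_mA, T_mX = T_mX,
                               T_iAAH = T_iAAH, T_iAAL = T_iAAL,
                               T_iAX = T_iAX, T_iXX = T_iXX,
                               alpha = alpha, provenance = prov),
              XeqA = penalties("XeqA", T_m = T_m, T_iH = T_iH, T_iL = T_iL,
                               alpha = alpha, provenance = prov),
              alloc = alloc, reps = reps, seed = seed)
  if (keep_samples)
    out$samples <- list(maxA = s1$maxA, maxX = s1x$maxX, maxG = s1$maxG,
                        int_AA = aa$max_int[1L, ], int_genome = genome_int,
                        fv1_AA = fv1_AA, fv1_genome = genome_fv1,
                        int_AX = ax$max_int[2L, ], int_XX = xx$max_int[3L, ])
  class(out) <- "qtlx_penalty_set"
  out
}

#' @export
print.qtlx_penalty_set <- function(x, ...) {
  print(x$XneA); print(x$XeqA)
  cat("replicates:", paste(names(x$reps), x$reps, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
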