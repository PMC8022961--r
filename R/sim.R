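# variance of the raw genotype score used when simulating a QTL effect,
# with residual SD fixed at 1: backcross / X-linked loci are 0/1 with
# variance 1/4; intercross autosomal loci use the additive dose 0/1/2 with
# variance 1/2.  Interaction terms use centered products of the two scores,
# so their variance factor is the product of the per-locus factors.
.geno_varfac <- function(design, is_X) {
  if (is_X || design$type == "bc") 0.25 else 0.5
}

#' Effect size yielding a target phenotypic variance fraction
#'
#' Solves for the coefficient `a` such that a QTL (or epistatic product
#' term) contributes a fraction `pve` of the total phenotypic variance when
#' the residual SD is 1: `a^2 v / (a^2 v + 1) = pve`, where `v` is the
#' variance of the genotype score (1/4 for a backcross or X-linked locus,
#' 1/2 for an intercross additive locus, and the product of the per-locus
#' factors for an interaction term).
#'
#' @param pve Target variance fraction, in \[0, 1).
#' @param design A [cross_design()].
#' @param is_X Logical flag (per locus).  For `what = "interaction"`, a
#'   length-2 logical for the two loci.
#' @param what `"main"` or `"interaction"`.
#' @return The coefficient `a >= 0`.
#' @examples
#' effect_for_pve(0.08, cross_design("bc"))  # 0.5898
#' @export
effect_for_pve <- function(pve, design, is_X = FALSE, what = c("main", "interaction")) {
  what <- match.arg(what)
  if (pve < 0 || pve >= 1) stop("pve must be in [0, 1)")
  if (pve == 0) return(0)
  v <- if (what == "main") .geno_varfac(design, is_X[1L])
       else .geno_varfac(design, is_X[1L]) * .geno_varfac(design, is_X[2L])
  sqrt(pve / ((1 - pve) * v))
}

# genotype score (raw dose: 0/1 or 0/1/2) at a marker position
.geno_score <- function(cross, chr, pos) {
  ch <- cross$map[[as.character(chr)]]
  if (is.null(ch)) stop("no chromosome ", chr, " on the map")
  idx <- which(abs(ch$pos - pos) < 1e-8)
  if (length(idx) != 1L)
    stop("QTL position ", chr, "@", pos, " is not a marker on the map")
  geno <- if (!is.null(cross$true_geno)) cross$true_geno else cross$geno
  g <- as.numeric(geno[[ch$name]][, idx]) - 1
  if (anyNA(g)) stop("missing true genotypes at a simulated QTL")
  g
}

#' Simulate a phenotype on a cross
#'
#' Adds QTL main effects and (optionally) pairwise epistatic effects to
#' i.i.d. standard normal residuals:
#' `y = sum a_k g_k + sum c_e (g_i - mu_i)(g_j - mu_j) + N(0,1)`.
#' With an empty QTL list this is the null phenotype generator (pure
#' `N(0,1)`, independent of genotype) used for penalty estimation.
#'
#' @param cross A [sim_cross()] object (true genotypes are used if the
#'   cross was simulated with observation error).
#' @param qtl `NULL`, or a data.frame with columns `chr`, `pos`, `pve`
#'   (variance fraction per QTL, e.g. 0.08).
#' @param interactions `NULL`, or a data.frame with columns `q1`, `q2`
#'   (row indices into `qtl`) and `pve` for the epistatic term.
#' @return The cross with `pheno` filled in.  The phenotype-generating
#'   coefficients are attached as `attr(cross$pheno, "effects")`.
#' @export
sim_phenotype <- function(cross, qtl = NULL, interactions = NULL) {
  n <- n_ind(cross)
  y <- rnorm(n)
  eff <- list()
  if (!is.null(qtl) && nrow(qtl) > 0) {
    scores <- vector("list", nrow(qtl))
    isx <- logical(nrow(qtl))
    for (k in seq_len(nrow(qtl))) {
      ch <- cross$map[[as.character(qtl$chr[k])]]
      if (is.null(ch)) stop("no chromosome ", qtl$chr[k], " on the map")
      isx[k] <- ch$is_X
      scores[[k]] <- .geno_score(cross, qtl$chr[k], qtl$pos[k])
      a <- effect_for_pve(qtl$pve[k], cross$design, isx[k])
      y <- y + a * scores[[k]]
      eff[[paste0(qtl$chr[k], "@", qtl$pos[k])]] <- a
    }
    if (!is.null(interactions) && nrow(interactions) > 0) {
      for (e in seq_len(nrow(interactions))) {
        i <- interactions$q1[e]; j <- interactions$q2[e]
        ci <- effect_for_pve(interactions$pve[e], cross$design,
                             is_X = isx[c(i, j)], what = "interaction")
        gi <- scores[[i]] - mean(scores[[i]])
        gj <- scores[[j]] - mean(scores[[j]])
        y <- y + ci * gi * gj
        eff[[paste0("int:", i, ":", j)]] <- ci
      }
    }
  }
  attr(y, "effects") <- eff
  cross$pheno <- y
  cross
}

# the eight simulation scenarios: a mouse-like backcross of 250 (both
# sexes), each QTL explaining about 8% of the phenotypic variance
SCENARIOS <- list(
  "null"        = list(qtl = NULL, int = NULL),
  "1-auto"      = list(qtl = data.frame(chr = "1", pos = 50, pve = 0.08), int = NULL),
  "2-auto-add"  = list(qtl = data.frame(chr = c("1", "2"), pos = c(50, 50), pve = 0.08), int = NULL),
  "3-auto-add"  = list(qtl = data.frame(chr = c("1", "2", "3"), pos = c(50, 50, 40), pve = 0.08), int = NULL),
  "1-X"         = list(qtl = data.frame(chr = "X", pos = 40, pve = 0.08), int = NULL),
  "2-X-add"     = list(qtl = data.frame(chr = c("X", "X"), pos = c(10, 60), pve = 0.08), int = NULL),
  "2-auto-int"  = list(qtl = data.frame(chr = c("1", "2"), pos = c(50, 50), pve = 0.08),
                       int = data.frame(q1 = 1L, q2 = 2L, pve = 0.08)),
  "auto-X-int"  = list(qtl = data.frame(chr = c("1", "X"), pos = c(50, 40), pve = 0.08),
                       int = data.frame(q1 = 1L, q2 = 2L, pve = 0.08)))

#' Named simulation scenarios
#'
#' The eight study conditions: a null model; one, two or three additive
#' autosomal QTL; one or two additive X-linked QTL; two interacting
#' autosomal QTL; and an autosome-by-X interacting pair.  All use a
#' backcross of `n` individuals (both sexes, split evenly) on the
#' mouse-like 10 cM map, with each QTL (and each epistatic term)
#' explaining approximately 8% of the phenotypic variance.
#'
#' @param name One of `names(qtlx_scenarios())`.
#' @param n Number of individuals (default 250).
#' @return A list with `name`, `n`, `map`, `design`, `qtl`, `interactions`.
#' @export
scenario <- function(name, n = 250) {
  if (!name %in% names(SCENARIOS)) stop("unknown scenario: ", name)
  sc <- SCENARIOS[[name]]
  list(name = name, n = n, map = mouse_map(10), design = cross_design("bc"),
       qtl = sc$qtl, interactions = sc$int)
}

#' @rdname scenario
#' @export
qtlx_scenarios <- function() names(SCENARIOS)

#' Simulate a full scenario (genotypes + phenotype)
#' @inheritParams scenario
#' @return A `qtlx_cross` with phenotype.
#' @export
sim_scenario <- function(name, n = 250) {
  sc <- scenario(name, n)
  cr <- sim_cross(sc$n, sc$map, sc$design)
  sim_phenotype(cr, sc$qtl, sc$interactions)
}
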