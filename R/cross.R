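#' Describe an experimental cross design
#'
#' @param type `"bc"` (backcross) or `"f2"` (intercross).
#' @param sexes Which sexes are present: `"both"`, `"female"` or `"male"`.
#' @param directions Cross directions present (`"one"` or `"both"`).  The
#'   direction is defined by the strain of the paternal grandmother, which
#'   constrains female X genotypes in an intercross; backcrosses always have
#'   a single direction.
#'
#' @return A list of class `qtlx_design`.
#' @export
cross_design <- function(type = c("bc", "f2"),
                         sexes = c("both", "female", "male"),
                         directions = c("one", "both")) {
  type <- match.arg(type)
  sexes <- match.arg(sexes)
  directions <- match.arg(directions)
  if (type == "bc" && directions == "both")
    stop("a backcross has a single cross direction")
  if (sexes == "male" && directions == "both")
    stop("cross direction only stratifies females; males-only implies one direction")
  structure(list(type = type, sexes = sexes, directions = directions),
            class = "qtlx_design")
}

#' @export
print.qtlx_design <- function(x, ...) {
  cat(if (x$type == "bc") "Backcross" else "F2 intercross",
      "| sexes:", x$sexes, "| directions:", x$directions, "\n")
  invisible(x)
}

# number of autosomal genotype states for a design
n_auto_states <- function(design) if (design$type == "bc") 2L else 3L

# Sample n haplotype chains (0/1 allele at each marker) along one chromosome:
# a Markov chain with switch probability = Haldane recombination fraction
# between adjacent markers (equivalent to a Poisson crossover process with
# uniform locations, observed at the markers).
sim_haplotypes <- function(n, pos) {
  m <- length(pos)
  h <- matrix(0L, n, m)
  h[, 1L] <- rbinom(n, 1L, 0.5)
  if (m > 1L) {
    r <- haldane(diff(pos))
    for (j in 2L:m)
      h[, j] <- bitwXor(h[, j - 1L], rbinom(n, 1L, r[j - 1L]))
  }
  h
}

#' Simulate an experimental cross
#'
#' Simulates marker genotypes for a backcross or F2 intercross on a genetic
#' map, with the X chromosome transmitted according to the design rules:
#' males are hemizygous, and female intercross X genotypes are constrained
#' by the cross direction (paternal grandmother's strain).  Autosomal
#' genotypes are formed from one (backcross) or two (intercross) independent
#' meiotic products per individual, each a no-interference (Haldane)
#' crossover process.
#'
#' Genotype codes: autosomes 1=AA, 2=AB (backcross) or 1=AA, 2=AB, 3=BB
#' (intercross).  X-chromosome genotypes are stored as the allele carried by
#' the single recombinant X (1=A, 2=B); the corresponding diploid female
#' genotype follows from the direction (see [x_female_geno()]).
#'
#' @param n Number of individuals.
#' @param map A [make_map()] genetic map.
#' @param design A [cross_design()].
#' @param error_prob Probability that an observed genotype is replaced by a
#'   uniformly chosen different valid code (default 0).
#' @param missing_prob Probability a genotype is missing (default 0).
#'
#' @return An object of class `qtlx_cross`: list with `design`, `map`,
#'   `geno` (per-chromosome integer matrices, individuals x markers),
#'   `pheno` (numeric, `NA` until simulated or assigned), `sex` (0=female,
#'   1=male) and `direction` (0/1 by paternal grandmother strain A/B).
#'
#' Uses the current R random number generator; call `set.seed()` first for
#' reproducibility.
#' @examples
#' set.seed(1)
#' cr <- sim_cross(100, mouse_map(10), cross_design("bc"))
#' table(cr$sex)
#' @export
sim_cross <- function(n, map, design = cross_design("bc"),
                      error_prob = 0, missing_prob = 0) {
  stopifnot(inherits(map, "qtlx_map"), inherits(design, "qtlx_design"), n >= 1)
  sex <- switch(design$sexes,
                both   = as.integer(seq_len(n) > ceiling(n / 2)),
                female = integer(n),
                male   = rep(1L, n))
  direction <- if (design$directions == "both")
    as.integer(seq_len(n) %% 2L == 0L) else integer(n)

  true_geno <- lapply(map, function(ch) {
    g <- if (ch$is_X || design$type == "bc")
      1L + sim_haplotypes(n, ch$pos)        # single meiotic product
    else
      1L + sim_haplotypes(n, ch$pos) + sim_haplotypes(n, ch$pos)
    colnames(g) <- names(ch$pos)
    g
  })

  corrupt <- error_prob > 0 || missing_prob > 0
  geno <- if (!corrupt) true_geno else lapply(map, function(ch) {
    g <- true_geno[[ch$name]]
    nstates <- if (ch$is_X) 2L else n_auto_states(design)
    if (error_prob > 0) {
      err <- matrix(runif(length(g)) < error_prob, nrow(g), ncol(g))
      if (any(err)) {
        shift <- 1L + as.integer(floor(runif(sum(err)) * (nstates - 1L)))
        g[err] <- 1L + (g[err] - 1L + shift) %% nstates
      }
    }
    if (missing_prob > 0)
      g[matrix(runif(length(g)) < missing_prob, nrow(g), ncol(g))] <- NA_integer_
    g
  })

  out <- list(design = design, map = map, geno = geno,
              pheno = rep(NA_real_, n), sex = sex, direction = direction)
  if (corrupt) out$true_geno <- true_geno
  structure(out, class = "qtlx_cross")
}

#' Number of individuals in a cross
#' @param cross A `qtlx_cross`.
#' @export
n_ind <- function(cross) length(cross$sex)

#' @export
print.qtlx_cross <- function(x, ...) {
  cat("Cross:", if (x$design$type == "bc") "backcross" else "F2 intercross",
      "with", n_ind(x), "individuals\n")
  cat("  sexes:", x$design$sexes, "| directions:", x$design$directions, "\n")
  cat("  ", length(x$map), " chromosomes, ",
      sum(vapply(x$geno, ncol, 0L)), " markers; phenotype ",
      if (all(is.na(x$pheno))) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Female diploid X genotype implied by the recombinant-X allele
#'
#' The single recombinant X product carries allele A (state 1) or B
#' (state 2); the other female X is the intact grandparental chromosome
#' determined by the cross direction.  Returns 1=AA, 2=AB, 3=BB.
#'
#' @param state Integer vector of X states (1/2).
#' @param direction 0 if the paternal grandmother was strain A (female
#'   genotypes AA/AB), 1 if strain B (AB/BB).
#' @export
x_female_geno <- function(state, direction) {
  ifelse(direction == 0L, state, state + 1L)
}

# validity check used by the CSV reader and tests
validate_cross <- function(cross) {
  n <- n_ind(cross)
  stopifnot(length(cross$pheno) == n, length(cross$direction) == n)
  if (anyNA(cross$sex)) stop("missing sex labels are not allowed")
  if (anyNA(cross$direction)) stop("missing direction labels are not allowed")
  for (ch in cross$map) {
    g <- cross$geno[[ch$name]]
    stopifnot(nrow(g) == n, ncol(g) == length(ch$pos))
    nstates <- if (ch$is_X) 2L else n_auto_states(cross$design)
    bad <- !is.na(g) & (g < 1L | g > nstates)
    if (any(bad))
      stop("invalid genotype code on chromosome ", ch$name)
  }
  invisible(cross)
}
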