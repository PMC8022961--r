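#' Evaluation grid for genome scans
#'
#' Marker positions plus (optionally) pseudomarkers every `step` cM,
#' labelled `"chr@pos"` (e.g. `"7@18.6"`).
#'
#' @param map A `qtlx_map`.
#' @param step Pseudomarker spacing in cM; 0 means markers only.
#' @return A data.frame with columns `chr`, `pos`, `is_X`, `is_marker`,
#'   `label`, plus `chr_index` and `index` (position index within
#'   chromosome).
#' @export
grid_positions <- function(map, step = 0) {
  stopifnot(inherits(map, "qtlx_map"), step >= 0)
  out <- lapply(seq_along(map), function(i) {
    ch <- map[[i]]
    pos <- ch$pos
    if (step > 0) {
      extra <- seq(min(pos), max(pos), by = step)
      extra <- extra[vapply(extra, function(p) all(abs(p - pos) > 1e-6), TRUE)]
      allpos <- sort(c(pos, extra))
      ismar <- vapply(allpos, function(p) any(abs(p - pos) < 1e-6), TRUE)
    } else {
      allpos <- unname(pos); ismar <- rep(TRUE, length(pos))
    }
    data.frame(chr = ch$name, pos = allpos, is_X = ch$is_X, is_marker = ismar,
               label = paste0(ch$name, "@", round(allpos, 4)),
               chr_index = i, index = seq_along(allpos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# transition matrix between adjacent grid positions at recombination r
.trans_matrix <- function(r, nstates) {
  if (nstates == 2L) {
    matrix(c(1 - r, r, r, 1 - r), 2, 2)
  } else {
    a <- 1 - r
    matrix(c(a^2, a * r, r^2,
             2 * a * r, a^2 + r^2, 2 * a * r,
             r^2, a * r, a^2), 3, 3)  # rows=from, cols=to; states AA,AB,BB
  }
}

#' Conditional QTL genotype probabilities
#'
#' Computes, for every individual and every grid position, the probability
#' of each genotype state given the observed multipoint marker data, by the
#' forward-backward algorithm on a per-chromosome hidden Markov model with
#' Haldane transition probabilities.  These are the Haley-Knott regressors.
#'
#' States: 2 for a backcross autosome (AA, AB), 3 for an intercross
#' autosome (AA, AB, BB), and always 2 on the X chromosome -- the allele
#' carried by the single recombinant X (the diploid female genotype follows
#' from the cross direction).
#'
#' @param cross A `qtlx_cross`.
#' @param step Pseudomarker spacing in cM (0 = markers only).
#' @param error_prob Genotyping error rate used in the emission model
#'   (default 0; use ~1e-4 for real data).
#' @return Object of class `qtlx_probs`: list with `chroms` (per
#'   chromosome, an array individuals x positions x states), `grid` (the
#'   [grid_positions()] table), `step`, `error_prob`.
#' @export
calc_genoprob <- function(cross, step = 0, error_prob = 0) {
  stopifnot(inherits(cross, "qtlx_cross"), step >= 0,
            error_prob >= 0, error_prob < 1)
  n <- n_ind(cross)
  grid <- grid_positions(cross$map, step)
  chroms <- lapply(cross$map, function(ch) {
    g <- grid[grid$chr == ch$name, ]
    npos <- nrow(g)
    K <- if (ch$is_X || cross$design$type == "bc") 2L else 3L
    obs <- cross$geno[[ch$name]]          # n x nmarkers
    mar_at <- match(round(g$pos, 6), round(ch$pos, 6))  # NA at pseudomarkers

    # emission probabilities at each grid position: n x K
    emis <- function(j) {
      e <- matrix(1, n, K)
      mj <- mar_at[j]
      if (!is.na(mj)) {
        o <- obs[, mj]
        seen <- !is.na(o)
        if (any(seen)) {
          for (k in seq_len(K)) {
            ek <- ifelse(o[seen] == k, 1 - error_prob, error_prob / (K - 1))
            e[seen, k] <- ek
          }
        }
      }
      e
    }

    init <- if (K == 2L) c(0.5, 0.5) else c(0.25, 0.5, 0.25)
    r <- if (npos > 1L) haldane(diff(g$pos)) else numeric(0)

    alpha <- array(0, c(n, npos, K))
    a <- sweep(emis(1L), 2, init, `*`)
    s <- rowSums(a)
    if (any(s <= 0)) stop("impossible genotype data on chromosome ", ch$name,
                          "; use a positive error_prob")
    alpha[, 1L, ] <- a / s
    if (npos > 1L) for (j in 2L:npos) {
      Tm <- .trans_matrix(r[j - 1L], K)
      a <- (alpha[, j - 1L, , drop = FALSE][, 1L, ] %*% Tm) * emis(j)
      s <- rowSums(a)
      if (any(s <= 0)) stop("impossible genotype data on chromosome ", ch$name,
                            "; use a positive error_prob")
      alpha[, j, ] <- a / s
    }

    beta <- array(0, c(n, npos, K))
    beta[, npos, ] <- 1
    if (npos > 1L) for (j in (npos - 1L):1L) {
      Tm <- .trans_matrix(r[j], K)
      b <- (beta[, j + 1L, , drop = FALSE][, 1L, ] * emis(j + 1L)) %*% t(Tm)
      beta[, j, ] <- b / rowSums(b)
    }

    pr <- alpha * beta
    pr <- pr / array(rep(rowSums(pr, dims = 2), K), dim(pr))
    dimnames(pr) <- list(NULL, g$label, NULL)
    pr
  })
  structure(list(chroms = chroms, grid = grid, step = step,
                 error_prob = error_prob),
            class = "qtlx_probs")
}

#' @export
print.qtlx_probs <- function(x, ...) {
  cat("Genotype probabilities:", nrow(x$grid), "positions on",
      length(x$chroms), "chromosomes (step =", x$step,
      "cM, error_prob =", x$error_prob, ")\n")
  invisible(x)
}
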