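# Hand-built crosses, toy genomes, and brute-force oracles used across the
# test files.  The oracles use base R linear models and exhaustive
# enumeration only -- never the package's scan kernels.

# assemble a cross object directly from its pieces
make_cross <- function(map, design, geno, pheno = NULL, sex = NULL,
                       direction = NULL) {
  n <- nrow(geno[[1L]])
  structure(list(design = design, map = map, geno = geno,
                 pheno = pheno %||% rep(NA_real_, n),
                 sex = sex %||% integer(n),
                 direction = direction %||% integer(n)),
            class = "qtlx_cross")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# toy genome: one 3-marker autosome + a 3-marker X chromosome
toy_map <- function() make_map(list("1" = c(0, 10, 20), "X" = c(0, 10, 20)),
                               x_chr = "X")

# simulate a small backcross on the toy genome with both sexes
toy_cross <- function(n = 60) {
  cr <- sim_cross(n, toy_map(), cross_design("bc"))
  sim_phenotype(cr)
}

# brute-force RSS via base R least squares
bf_rss <- function(X, y) sum(stats::lm.fit(X, y)$residuals^2)

# brute-force main-effect columns for a complete-data backcross, built
# straight from the stored genotype codes
bf_cols_bc <- function(cross, chr, idx) {
  g <- cross$geno[[chr]][, idx]
  if (cross$map[[chr]]$is_X) {
    if (cross$design$sexes == "both")
      cbind((g == 2) * (cross$sex == 0L), (g == 2) * (cross$sex == 1L))
    else cbind(g == 2)
  } else cbind(g == 2)
}

bf_null_cols <- function(cross) {
  if (cross$design$sexes == "both") cbind(1, cross$sex) else cbind(rep(1, n_ind(cross)))
}

# brute-force scanone for a complete-data backcross toy
bf_scanone_bc <- function(cross, y) {
  X0 <- bf_null_cols(cross)
  rss0 <- bf_rss(X0, y)
  out <- NULL
  for (ch in cross$map) for (j in seq_along(ch$pos)) {
    rss1 <- bf_rss(cbind(X0, bf_cols_bc(cross, ch$name, j)), y)
    out <- rbind(out, data.frame(chr = ch$name, pos = ch$pos[j],
                                 lod = length(y) / 2 * log10(rss0 / rss1)))
  }
  out
}

# brute-force two-QTL scan (full/additive/interaction) over all pairs
bf_scantwo_bc <- function(cross, y) {
  X0 <- bf_null_cols(cross)
  rss0 <- bf_rss(X0, y)
  loci <- do.call(rbind, lapply(cross$map, function(ch)
    data.frame(chr = ch$name, idx = seq_along(ch$pos), pos = ch$pos)))
  out <- NULL
  for (a in seq_len(nrow(loci) - 1L)) for (b in (a + 1L):nrow(loci)) {
    Ca <- bf_cols_bc(cross, loci$chr[a], loci$idx[a])
    Cb <- bf_cols_bc(cross, loci$chr[b], loci$idx[b])
    prods <- NULL
    for (i in seq_len(ncol(Ca))) for (j in seq_len(ncol(Cb)))
      prods <- cbind(prods, Ca[, i] * Cb[, j])
    lf <- length(y) / 2 * log10(rss0 / bf_rss(cbind(X0, Ca, Cb, prods), y))
    la <- length(y) / 2 * log10(rss0 / bf_rss(cbind(X0, Ca, Cb), y))
    out <- rbind(out, data.frame(chr1 = loci$chr[a], pos1 = loci$pos[a],
                                 chr2 = loci$chr[b], pos2 = loci$pos[b],
                                 lod_full = lf, lod_add = la))
  }
  out
}

# brute-force genotype probabilities by enumerating every hidden-state
# sequence on one chromosome (complete or missing observations)
bf_genoprob_chr <- function(obs, pos, K, error_prob, init, trans_fun) {
  m <- length(pos)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  r <- haldane(diff(pos))
  post <- matrix(0, m, K)
  total <- 0
  for (s in seq_len(nrow(seqs))) {
    g <- seqs[s, ]
    p <- init[g[1L]]
    if (m > 1L) for (j in 2L:m) p <- p * trans_fun(r[j - 1L])[g[j - 1L], g[j]]
    for (j in seq_len(m)) {
      if (!is.na(obs[j]))
        p <- p * if (obs[j] == g[j]) 1 - error_prob else error_prob / (K - 1)
    }
    for (j in seq_len(m)) post[j, g[j]] <- post[j, g[j]] + p
    total <- total + p
  }
  post / total
}

# exhaustive best model (max pLOD) on a toy genome: all models with up to
# 2 QTL and at most one interaction, honouring the minimum-separation rule
bf_best_model <- function(prep, y, pen) {
  grid <- prep$grid
  best <- list(model = qtl_model(), plod = 0)
  consider <- function(m) {
    lod <- fit_model(prep, m, y)$lod
    pl <- plod(lod, m, pen, grid)
    if (pl > best$plod + 1e-9) best <<- list(model = m, plod = pl)
  }
  for (i in seq_len(nrow(grid)))
    consider(qtl_model(grid$chr[i], grid$pos[i]))
  for (i in seq_len(nrow(grid) - 1L)) for (j in (i + 1L):nrow(grid)) {
    if (grid$chr[i] == grid$chr[j] && abs(grid$index[i] - grid$index[j]) <= 1L)
      next
    consider(qtl_model(grid$chr[c(i, j)], grid$pos[c(i, j)]))
    consider(qtl_model(grid$chr[c(i, j)], grid$pos[c(i, j)],
                       matrix(c(1L, 2L), 1L)))
  }
  best
}
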