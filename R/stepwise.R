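# LOD of a model versus the null model, via the RSS kernel
.model_lod <- function(prep, y, model, rss0 = NULL) {
  Y <- matrix(y)
  if (is.null(rss0)) rss0 <- cpp_rss(prep$X0, Y)
  if (n_qtl(model) == 0L) return(0)
  X <- cbind(prep$X0, model_columns(prep, model))
  lod_from_rss(rss0, cpp_rss(X, Y), length(y))
}

# sum of main-effect penalties of a model
.main_pen <- function(model, pen, grid) {
  if (n_qtl(model) == 0L) return(0)
  isx <- model_is_X(model, grid)
  if (pen$method == "XneA") {
    if (any(isx) && is.na(pen$T_mX))
      stop("model has X-linked QTL but no X main-effect penalty")
    sum(isx) * pen$T_mX + sum(!isx) * pen$T_mA
  } else n_qtl(model) * pen$T_m
}

# Scan setup for moving (or profiling) one QTL of a model: the fixed
# design columns (null covariates, other QTL, edges not involving q, and
# any fixed stratified-epistasis extras) plus the partner column sets
# whose products with the moving QTL's columns complete its edges.
.move_setup <- function(prep, model, q) {
  grid <- prep$grid
  idx <- model_grid_index(model, grid)
  isx <- model_is_X(model, grid)
  strat <- prep$strat
  Xbase <- prep$X0
  for (k in setdiff(seq_len(n_qtl(model)), q))
    Xbase <- cbind(Xbase, prep$cols[[idx[k]]])
  touches <- model$edges[, 1L] == q | model$edges[, 2L] == q
  eo <- model$edges[!touches, , drop = FALSE]
  for (e in seq_len(nrow(eo)))
    Xbase <- cbind(Xbase, pair_int_columns(prep, idx[eo[e, 1L]], idx[eo[e, 2L]]))
  partner_nodes <- c(model$edges[model$edges[, 2L] == q, 1L],
                     model$edges[model$edges[, 1L] == q, 2L])
  partners <- list()
  for (k in partner_nodes) {
    partners <- c(partners, list(prep$cols[[idx[k]]]))
    if (xor(isx[q], isx[k]) && ncol(strat) > 0L) {
      if (isx[k]) partners <- c(partners, list(strat))
      else Xbase <- cbind(Xbase, interaction_columns(prep$cols[[idx[k]]], strat))
    }
  }
  list(Xbase = Xbase, partners = partners)
}

# positions where a new QTL may be placed: everything except positions
# within one grid step of an existing QTL on the same chromosome
.allowed_positions <- function(grid, model) {
  ok <- rep(TRUE, nrow(grid))
  if (n_qtl(model) == 0L) return(ok)
  idx <- model_grid_index(model, grid)
  for (i in idx) {
    near <- grid$chr == grid$chr[i] & abs(grid$index - grid$index[i]) <= 1L
    ok[near] <- FALSE
  }
  ok
}

#' One step of forward selection
#'
#' Evaluates (a) adding one additive QTL anywhere on the allowed grid and
#' (b) for each QTL in the current model, adding a QTL that interacts with
#' it, and returns the candidate with the largest penalized LOD.  The best
#' candidate is returned even if its pLOD is below the current model's.
#' Ties go to the earliest candidate: the additive scan first, then the
#' interaction scans in node order, each in (chromosome, position) order.
#'
#' @param prep A [scan_prep()] object.
#' @param y Phenotype vector (no missing values).
#' @param model Current `qtlx_model`.
#' @param pen A [penalties()] object.
#' @return List with `model`, `lod`, `plod` of the chosen candidate.
#' @export
forward_step <- function(prep, y, model, pen) {
  grid <- prep$grid
  n <- length(y)
  Y <- matrix(y)
  rss0 <- cpp_rss(prep$X0, Y)
  Xbase <- if (n_qtl(model) == 0L) prep$X0
           else cbind(prep$X0, model_columns(prep, model))
  allowed <- which(.allowed_positions(grid, model))
  if (length(allowed) == 0L) stop("no allowed positions remain")
  pen_cur <- .main_pen(model, pen, grid) + interaction_penalty(model, pen, grid)
  new_main_pen <- if (pen$method == "XneA")
    ifelse(grid$is_X[allowed], pen$T_mX, pen$T_mA) else rep(pen$T_m, length(allowed))

  cand_plod <- numeric(0); cand_lod <- numeric(0)
  cand_pos <- integer(0); cand_partner <- integer(0)

  # (a) one more additive QTL
  rss <- cpp_rss_scan(prep$cols[allowed], Xbase, Y, list())
  lod_a <- lod_from_rss(rss0, rss[, 1L], n)
  cand_plod <- lod_a - pen_cur - new_main_pen
  cand_lod <- lod_a
  cand_pos <- allowed
  cand_partner <- rep(0L, length(allowed))

  # (b) a QTL interacting with each current QTL
  if (n_qtl(model) > 0L) {
    idx <- model_grid_index(model, grid)
    isx <- model_is_X(model, grid)
    regs <- edge_regions(model, grid)
    for (q in seq_len(n_qtl(model))) {
      edges2 <- rbind(model$edges, c(q, n_qtl(model) + 1L))
      # interaction penalty of the candidate graph, for a new autosomal
      # QTL and for a new X-linked QTL (topology is position-free)
      reg_new <- function(newx) c("AA", "AX", "XX")[isx[q] + newx + 1L]
      ipen_A <- .int_penalty_core(n_qtl(model) + 1L, edges2,
                                  c(regs, reg_new(FALSE)), pen)
      ipen_X <- .int_penalty_core(n_qtl(model) + 1L, edges2,
                                  c(regs, reg_new(TRUE)), pen)
      # candidate scans split by chromosome type: a mixed A:X pair adds
      # stratified epistasis columns (see pair_int_columns)
      Cq <- prep$cols[[idx[q]]]
      strat <- prep$strat
      pa <- allowed[!grid$is_X[allowed]]
      px <- allowed[grid$is_X[allowed]]
      lod_q <- numeric(length(allowed))
      if (length(pa)) {
        partners <- if (isx[q] && ncol(strat) > 0L) list(Cq, strat) else list(Cq)
        rss_q <- cpp_rss_scan(prep$cols[pa], Xbase, Y, partners)
        lod_q[match(pa, allowed)] <- lod_from_rss(rss0, rss_q[, 1L], n)
      }
      if (length(px)) {
        Xb2 <- if (!isx[q] && ncol(strat) > 0L)
          cbind(Xbase, interaction_columns(Cq, strat)) else Xbase
        rss_q <- cpp_rss_scan(prep$cols[px], Xb2, Y, list(Cq))
        lod_q[match(px, allowed)] <- lod_from_rss(rss0, rss_q[, 1L], n)
      }
      ipen <- ifelse(grid$is_X[allowed], ipen_X, ipen_A)
      plod_q <- lod_q - .main_pen(model, pen, grid) - new_main_pen - ipen
      cand_plod <- c(cand_plod, plod_q)
      cand_lod <- c(cand_lod, lod_q)
      cand_pos <- c(cand_pos, allowed)
      cand_partner <- c(cand_partner, rep(q, length(allowed)))
    }
  }

  b <- which.max(cand_plod)
  p <- cand_pos[b]
  new_model <- qtl_model(c(model$chr, grid$chr[p]), c(model$pos, grid$pos[p]),
                         if (cand_partner[b] == 0L) model$edges
                         else rbind(model$edges,
                                    c(cand_partner[b], n_qtl(model) + 1L)))
  list(model = new_model, lod = cand_lod[b], plod = cand_plod[b])
}

#' One step of backward elimination
#'
#' Evaluates dropping each interaction edge and dropping each QTL (with its
#' incident edges) and returns the candidate with the largest penalized
#' LOD; the step is taken even if pLOD decreases.  Ties go to the earliest
#' candidate (edge drops in edge order, then node drops in node order).
#'
#' @inheritParams forward_step
#' @return List with `model`, `lod`, `plod`.
#' @export
backward_step <- function(prep, y, model, pen) {
  if (n_qtl(model) == 0L) stop("cannot step back from the null model")
  grid <- prep$grid
  cands <- list()
  if (nrow(model$edges) > 0L)
    for (e in seq_len(nrow(model$edges)))
      cands[[length(cands) + 1L]] <-
        qtl_model(model$chr, model$pos, model$edges[-e, , drop = FALSE])
  for (k in seq_len(n_qtl(model))) {
    keep_e <- model$edges[, 1L] != k & model$edges[, 2L] != k
    e2 <- model$edges[keep_e, , drop = FALSE]
    e2[e2 > k] <- e2[e2 > k] - 1L
    cands[[length(cands) + 1L]] <- qtl_model(model$chr[-k], model$pos[-k], e2)
  }
  Y <- matrix(y)
  rss0 <- cpp_rss(prep$X0, Y)
  lods <- vapply(cands, function(m) .model_lod(prep, y, m, rss0), 0)
  plods <- vapply(seq_along(cands), function(i)
    plod(lods[i], cands[[i]], pen, grid), 0)
  b <- which.max(plods)
  list(model = cands[[b]], lod = lods[b], plod = plods[b])
}

#' Refine QTL positions by cyclic hill climbing
#'
#' One QTL at a time (in chromosome, then position order), the QTL is moved
#' to the grid position on its chromosome that maximizes the model LOD,
#' keeping all other QTL fixed; cycles repeat until no move improves the
#' LOD.  The model LOD never decreases.
#'
#' @inheritParams forward_step
#' @param maxit Maximum number of full cycles.
#' @return The refined `qtlx_model`.
#' @export
refine_positions <- function(prep, y, model, maxit = 10) {
  if (n_qtl(model) == 0L) return(model)
  grid <- prep$grid
  Y <- matrix(y)
  rss0 <- cpp_rss(prep$X0, Y)
  for (it in seq_len(maxit)) {
    moved <- FALSE
    ord <- order(match(model$chr, unique(grid$chr)), model$pos)
    for (q in ord) {
      idx <- model_grid_index(model, grid)
      ms <- .move_setup(prep, model, q)
      # candidate positions: q's chromosome, away from the other QTL
      model_wo_q <- qtl_model(model$chr[-q], model$pos[-q],
                              matrix(0L, 0L, 2L))
      ok <- .allowed_positions(grid, model_wo_q) & grid$chr == model$chr[q]
      cand <- which(ok)
      if (length(cand) == 0L) next
      rss <- cpp_rss_scan(prep$cols[cand], ms$Xbase, Y, ms$partners)[, 1L]
      cur <- which(cand == idx[q])
      b <- which.min(rss)
      if (length(cur) == 1L && rss[b] >= rss[cur] - 1e-12) next
      if (length(cur) == 0L || rss[b] < rss[cur] - 1e-12) {
        model$pos[q] <- grid$pos[cand[b]]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  model
}

#' Penalized-LOD stepwise search for a multiple-QTL model
#'
#' Forward selection up to `max_qtl` QTL (at each step: the best additional
#' additive QTL, or the best new QTL interacting with a QTL already in the
#' model), followed by backward elimination to the null model; among all
#' models visited, the one with maximum penalized LOD is selected.
#' Positions are refined by [refine_positions()] after every accepted step
#' (switchable).
#'
#' @param cross A `qtlx_cross` with a phenotype (or supply `pheno`).
#' @param pen A [penalties()] object; its `method` (`XneA` or `XeqA`)
#'   determines the penalty scheme.
#' @param pheno Optional phenotype vector overriding `cross$pheno`.
#' @param probs Optional [calc_genoprob()] result.
#' @param max_qtl Maximum model size during forward selection (default 10).
#' @param refine Refine positions after each step (default `TRUE`).
#' @return Object of class `qtlx_fit`: the selected `model`, its
#'   [fit_model()] `fit`, `lod`, `plod`, per-QTL and per-edge drop-one LOD
#'   scores, the search `trace`, and the inputs needed by
#'   [profile_lod()] and the plot method.
#' @seealso [estimate_penalties()], [profile_lod()]
#' @export
stepwise_qtl <- function(cross, pen, pheno = NULL, probs = NULL,
                         max_qtl = 10, refine = TRUE) {
  stopifnot(inherits(cross, "qtlx_cross"), inherits(pen, "qtlx_penalties"))
  prep <- scan_prep(cross, probs)
  si <- .scan_inputs(prep, pheno)
  prep <- si$prep; y <- si$y
  grid <- prep$grid

  model <- qtl_model()
  trace <- list(list(dir = "start", n_qtl = 0L, n_int = 0L, lod = 0, plod = 0))
  best <- list(model = model, lod = 0, plod = 0)
  note <- function(dir, model, lod, plod) {
    trace[[length(trace) + 1L]] <<- list(dir = dir, n_qtl = n_qtl(model),
                                         n_int = nrow(model$edges),
                                         lod = lod, plod = plod)
    if (plod > best$plod + 1e-12)
      best <<- list(model = model, lod = lod, plod = plod)
  }

  while (n_qtl(model) < max_qtl) {
    st <- forward_step(prep, y, model, pen)
    model <- st$model; lod <- st$lod
    if (refine) {
      model <- refine_positions(prep, y, model)
      lod <- .model_lod(prep, y, model)
    }
    note("forward", model, lod, plod(lod, model, pen, grid))
  }
  while (n_qtl(model) > 0L) {
    st <- backward_step(prep, y, model, pen)
    model <- st$model
    if (refine) model <- refine_positions(prep, y, model)
    lod <- .model_lod(prep, y, model)
    note("backward", model, lod, plod(lod, model, pen, grid))
  }

  fit <- fit_model(prep, best$model)
  out <- list(model = best$model, fit = fit, lod = best$lod,
              plod = best$plod, penalties = pen,
              drop = drop_one(prep, y, best$model),
              trace = do.call(rbind, lapply(trace, as.data.frame)),
              prep = prep, pheno = y, call = match.call())
  class(out) <- "qtlx_fit"
  out
}

#' Drop-one LOD scores
#'
#' For each QTL: the LOD of the full model versus the model with that QTL
#' (and any interactions involving it) omitted.  For each interaction
#' edge: the full model versus the model without that edge.
#'
#' @inheritParams forward_step
#' @return List with `qtl` (vector) and `edges` (vector, possibly empty).
#' @export
drop_one <- function(prep, y, model) {
  full <- .model_lod(prep, y, model)
  dq <- vapply(seq_len(n_qtl(model)), function(k) {
    keep_e <- model$edges[, 1L] != k & model$edges[, 2L] != k
    e2 <- model$edges[keep_e, , drop = FALSE]
    e2[e2 > k] <- e2[e2 > k] - 1L
    full - .model_lod(prep, y, qtl_model(model$chr[-k], model$pos[-k], e2))
  }, 0)
  de <- vapply(seq_len(nrow(model$edges)), function(e)
    full - .model_lod(prep, y,
                      qtl_model(model$chr, model$pos,
                                model$edges[-e, , drop = FALSE])), 0)
  list(qtl = dq, edges = de)
}

#' @export
print.qtlx_fit <- function(x, ...) {
  m <- x$model
  cat("Selected QTL model (", x$penalties$method, "): pLOD = ",
      round(x$plod, 3), ", LOD = ", round(x$lod, 3), "\n", sep = "")
  if (n_qtl(m) == 0L) { cat("  (null model: no QTL)\n"); return(invisible(x)) }
  nm <- paste0(m$chr, "@", round(m$pos, 4))
  df <- data.frame(name = nm, chr = m$chr, pos = m$pos,
                   LOD = round(x$drop$qtl, 2))
  rownames(df) <- paste0("Q", seq_len(n_qtl(m)))
  if (nrow(m$edges) > 0L) {
    edf <- data.frame(name = paste(nm[m$edges[, 1L]], nm[m$edges[, 2L]], sep = ":"),
                      chr = paste(m$chr[m$edges[, 1L]], m$chr[m$edges[, 2L]], sep = ":"),
                      pos = NA, LOD = round(x$drop$edges, 2))
    rownames(edf) <- paste0("Q", m$edges[, 1L], ":Q", m$edges[, 2L])
    df <- rbind(df, edf)
  }
  print(df)
  invisible(x)
}

#' @export
summary.qtlx_fit <- function(object, ...) {
  print(object)
  cat("\nSearch trace (", nrow(object$trace), " models visited):\n", sep = "")
  print(utils::head(object$trace, 25))
  invisible(object)
}

#' @export
coef.qtlx_fit <- function(object, ...) object$fit$coef

#' @export
fitted.qtlx_fit <- function(object, ...) object$fit$fitted

#' @export
residuals.qtlx_fit <- function(object, ...) object$fit$residuals

#' @export
simulate.qtlx_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$fit$rss_model / object$fit$n)
  mu <- object$fit$fitted
  matrix(rnorm(length(mu) * nsim, mean = mu, sd = sigma), ncol = nsim)
}

#' Profile LOD curves of a fitted model
#'
#' For each QTL, the LOD comparing the model with that QTL moved along its
#' chromosome (all other QTL fixed at their estimated positions) to the
#' model with the QTL omitted, along with any interactions it is involved
#' in.  The curve's value at the fitted position equals the drop-one LOD.
#'
#' @param x A `qtlx_fit` from [stepwise_qtl()].
#' @return Object of class `qtlx_profile`: list of per-QTL data.frames
#'   (`chr`, `pos`, `lod`) plus a summary `table` (name, chr, pos, LOD).
#' @export
profile_lod <- function(x) {
  stopifnot(inherits(x, "qtlx_fit"))
  prep <- x$prep; y <- x$pheno; model <- x$model
  grid <- prep$grid
  Y <- matrix(y)
  rss0 <- cpp_rss(prep$X0, Y)
  n <- length(y)
  curves <- vector("list", n_qtl(model))
  for (q in seq_len(n_qtl(model))) {
    ms <- .move_setup(prep, model, q)
    cand <- which(grid$chr == model$chr[q])
    rss_at <- cpp_rss_scan(prep$cols[cand], ms$Xbase, Y, ms$partners)[, 1L]
    lod_at <- lod_from_rss(rss0, rss_at, n)          # model with q at p
    keep_e <- model$edges[, 1L] != q & model$edges[, 2L] != q
    e2 <- model$edges[keep_e, , drop = FALSE]
    e2[e2 > q] <- e2[e2 > q] - 1L
    lod_wo <- .model_lod(prep, y,                    # model without q and
                         qtl_model(model$chr[-q], model$pos[-q], e2))  # its edges
    curves[[q]] <- data.frame(chr = grid$chr[cand], pos = grid$pos[cand],
                              lod = lod_at - lod_wo)
  }
  names(curves) <- paste0(model$chr, "@", round(model$pos, 4))
  tab <- data.frame(name = names(curves), chr = model$chr, pos = model$pos,
                    LOD = x$drop$qtl)
  rownames(tab) <- paste0("Q", seq_len(n_qtl(model)))
  structure(list(curves = curves, table = tab), class = "qtlx_profile")
}

#' @export
print.qtlx_profile <- function(x, ...) {
  cat("Profile LOD of", nrow(x$table), "QTL\n")
  print(x$table)
  invisible(x)
}

#' @export
plot.qtlx_profile <- function(x, ...) {
  chrs <- unique(unlist(lapply(x$curves, function(cv) cv$chr[1L])))
  allpos <- do.call(rbind, x$curves)
  off <- stats::setNames(numeric(length(chrs)), chrs)
  run <- 0
  for (ch in chrs) {
    off[ch] <- run
    run <- run + max(allpos$pos[allpos$chr == ch]) + 10
  }
  graphics::plot(NULL, xlim = c(0, run), ylim = c(0, max(allpos$lod) * 1.05),
                 xlab = "Chromosome", ylab = "Profile LOD", xaxt = "n", ...)
  graphics::axis(1, at = off + vapply(chrs, function(ch)
    mean(range(allpos$pos[allpos$chr == ch])), 0), labels = chrs)
  for (cv in x$curves)
    graphics::lines(cv$pos + off[cv$chr[1L]], cv$lod)
  invisible(x)
}

#' @export
plot.qtlx_fit <- function(x, ...) {
  if (n_qtl(x$model) == 0L) stop("null model: nothing to plot")
  plot(profile_lod(x), ...)
}
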