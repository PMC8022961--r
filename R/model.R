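#' Multiple-QTL model graph
#'
#' A QTL model is a graph: nodes are QTL (chromosome + position in cM) and
#' edges are pairwise epistatic interactions.  The model hierarchy requires
#' both endpoints of every edge to be nodes of the model, which holds by
#' construction since edges are stored as node-index pairs.
#'
#' @param chr Character vector of chromosome names (one per QTL).
#' @param pos Numeric vector of positions (cM).
#' @param edges Two-column integer matrix of node indices (may have 0 rows).
#' @return Object of class `qtlx_model` with elements `chr`, `pos`,
#'   `edges`.
#' @export
qtl_model <- function(chr = character(), pos = numeric(),
                      edges = matrix(0L, 0L, 2L)) {
  chr <- as.character(chr)
  if (length(chr) != length(pos)) stop("chr and pos lengths differ")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > length(chr)))
      stop("edge endpoint is not a model node (hierarchy violation)")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-interaction edge")
    edges <- t(apply(edges, 1L, sort))
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) stop("duplicate edge")
  }
  if (anyDuplicated(paste(chr, pos))) stop("duplicate QTL position")
  structure(list(chr = chr, pos = pos, edges = edges), class = "qtlx_model")
}

#' Number of QTL in a model
#' @param model A `qtlx_model`.
#' @export
n_qtl <- function(model) length(model$chr)

# locate model nodes on a scan grid; error if a position is off-grid
model_grid_index <- function(model, grid) {
  idx <- integer(n_qtl(model))
  for (k in seq_len(n_qtl(model))) {
    hit <- which(grid$chr == model$chr[k] & abs(grid$pos - model$pos[k]) < 1e-6)
    if (length(hit) != 1L)
      stop("QTL ", model$chr[k], "@", model$pos[k], " is not on the scan grid")
    idx[k] <- hit
  }
  idx
}

# TRUE for each node on the X chromosome (by grid lookup)
model_is_X <- function(model, grid) {
  xchr <- unique(grid$chr[grid$is_X])
  model$chr %in% xchr
}

# region label ("AA","AX","XX") of each edge
edge_regions <- function(model, grid) {
  if (nrow(model$edges) == 0L) return(character(0))
  isx <- model_is_X(model, grid)
  nx <- isx[model$edges[, 1L]] + isx[model$edges[, 2L]]
  c("AA", "AX", "XX")[nx + 1L]
}

#' @export
print.qtlx_model <- function(x, ...) {
  if (n_qtl(x) == 0L) { cat("Null QTL model (no QTL)\n"); return(invisible(x)) }
  cat("QTL model:", n_qtl(x), "QTL,", nrow(x$edges), "interactions\n")
  df <- data.frame(name = paste0(x$chr, "@", round(x$pos, 4)),
                   chr = x$chr, pos = x$pos)
  print(df, row.names = paste0("Q", seq_len(n_qtl(x))))
  if (nrow(x$edges) > 0)
    cat("interactions:",
        paste(paste0("Q", x$edges[, 1L], ":Q", x$edges[, 2L]), collapse = ", "),
        "\n")
  invisible(x)
}

# connected components of the interaction graph (nodes with >=1 edge);
# returns component id per node (NA for isolated nodes)
.components <- function(nnode, edges) {
  comp <- seq_len(nnode)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- comp[edges[e, 1L]]; b <- comp[edges[e, 2L]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

#' Total interaction penalty of a QTL model
#'
#' Heavy penalties are applied to every interaction edge by region, except
#' that within each connected component of the interaction graph one
#' autosome-autosome edge (if present) may take the light penalty instead.
#' Under the X-aware method (`XneA`) light penalties are allowed only for
#' autosome-autosome interactions; any interaction involving the X
#' chromosome is penalized heavily.  Under `XeqA` one edge per component
#' (of any kind) takes the light penalty.
#'
#' @param model A `qtlx_model`.
#' @param pen A [penalties] object (see [estimate_penalties()]).
#' @param grid A scan grid ([grid_positions()]) to resolve X flags.
#' @return Total interaction penalty (0 for a model without edges).
#' @export
interaction_penalty <- function(model, pen, grid) {
  .int_penalty_core(n_qtl(model), model$edges, edge_regions(model, grid), pen)
}

# core of the interaction penalty, on an explicit edge-region labelling
# (lets the search price hypothetical moves without grid lookups)
.int_penalty_core <- function(nnode, edges, regions, pen) {
  ne <- nrow(edges)
  if (ne == 0L) return(0)
  if (pen$method == "XneA") {
    heavy <- c(AA = pen$T_iAAH, AX = pen$T_iAX, XX = pen$T_iXX)[regions]
    if (anyNA(heavy)) stop("missing interaction penalty for region(s) ",
                           paste(unique(regions[is.na(heavy)]), collapse = ", "))
    light_gain <- pen$T_iAAH - pen$T_iAAL
    light_ok <- regions == "AA"
  } else {
    heavy <- rep(pen$T_iH, ne)
    light_gain <- pen$T_iH - pen$T_iL
    light_ok <- rep(TRUE, ne)
  }
  comp <- .components(nnode, edges)
  ecomp <- comp[edges[, 1L]]
  total <- sum(heavy)
  for (cc in unique(ecomp))
    if (any(light_ok[ecomp == cc])) total <- total - light_gain
  total
}

#' Penalized LOD score
#'
#' `pLOD = LOD - (main-effect penalties) - (interaction penalty)`.  Under
#' `XneA` the main-effect penalty is `T_mA` per autosomal QTL and `T_mX`
#' per X-linked QTL; under `XeqA` it is `T_m` per QTL.
#'
#' @param lod LOD score of the fitted model versus the null model.
#' @param model A `qtlx_model`.
#' @param pen A [penalties] object.
#' @param grid Scan grid used to resolve X flags.
#' @return The penalized LOD score (0 for the null model).
#' @export
plod <- function(lod, model, pen, grid) {
  if (n_qtl(model) == 0L) return(0)
  isx <- model_is_X(model, grid)
  main_pen <- if (pen$method == "XneA") {
    if (any(isx) && is.na(pen$T_mX))
      stop("model has X-linked QTL but no X main-effect penalty")
    sum(isx) * pen$T_mX + sum(!isx) * pen$T_mA
  } else {
    n_qtl(model) * pen$T_m
  }
  lod - main_pen - interaction_penalty(model, pen, grid)
}
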