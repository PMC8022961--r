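#' Haldane map function
#'
#' Convert a genetic distance in centiMorgans to a recombination fraction
#' under the Haldane (no-interference) map function, or back.
#'
#' @param d Genetic distance in cM (non-negative).
#' @param r Recombination fraction in \[0, 0.5).
#'
#' @return `haldane()` returns the recombination fraction
#'   \eqn{r = (1 - e^{-2d/100})/2}; `haldane_inv()` returns the distance
#'   \eqn{d = -50 \log(1 - 2r)} in cM.
#'
#' @examples
#' haldane(10)          # 0.0906
#' haldane_inv(0.25)    # 34.66 cM
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane
#' @export
haldane_inv <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Construct a genetic map
#'
#' A map is an ordered set of chromosomes, each with strictly increasing
#' marker positions in cM and a flag marking the (at most one) X chromosome.
#'
#' @param positions Named list of numeric vectors of marker positions (cM),
#'   one element per chromosome, in chromosome order.  Vectors may carry
#'   marker names; unnamed markers are named `"<chr>_m<i>"`.
#' @param x_chr Name of the X chromosome, or `NULL` if all autosomal.
#'
#' @return An object of class `qtlx_map`: a list with one element per
#'   chromosome, each a list with `name`, `is_X`, and `pos`.
#'
#' @seealso [mouse_map()] for the built-in mouse-like map.
#' @export
make_map <- function(positions, x_chr = NULL) {
  if (is.null(names(positions)) || any(!nzchar(names(positions))))
    stop("'positions' must be a fully named list")
  if (!is.null(x_chr)) {
    if (length(x_chr) != 1L || !x_chr %in% names(positions))
      stop("'x_chr' must name exactly one chromosome in 'positions'")
  }
  map <- lapply(names(positions), function(nm) {
    p <- positions[[nm]]
    if (length(p) < 1L) stop("chromosome ", nm, " has no markers")
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing on chromosome ", nm)
    if (is.null(names(p)))
      names(p) <- paste0(nm, "_m", seq_along(p))
    list(name = nm, is_X = identical(nm, x_chr), pos = p)
  })
  names(map) <- names(positions)
  class(map) <- "qtlx_map"
  map
}

# cM lengths of the default mouse-like autosomes (chr 1-19); X is 80 cM.
# Fixed package constants for a genome "modeled after the mouse":
# autosomes total 1400 cM, so L_A/L_X = 17.5.
MOUSE_CHR_LEN <- c(100, 100, 90, 90, 90, 80, 80, 80, 80, 80,
                   70, 70, 70, 60, 60, 60, 50, 50, 40)
MOUSE_X_LEN <- 80

#' Mouse-like genetic map with equally spaced markers
#'
#' Nineteen autosomes (total 1400 cM) plus an 80 cM X chromosome, with
#' markers every `spacing` cM from 0 to the chromosome end.  The chromosome
#' lengths are fixed package constants (see `qtlx:::MOUSE_CHR_LEN`).
#'
#' @param spacing Marker spacing in cM (default 10).
#' @return A [make_map()] object with chromosomes `"1"`..`"19"` and `"X"`.
#' @examples
#' m <- mouse_map(10)
#' map_length(m)   # L_A = 1400, L_X = 80
#' @export
mouse_map <- function(spacing = 10) {
  if (spacing <= 0) stop("spacing must be positive")
  lens <- c(MOUSE_CHR_LEN, MOUSE_X_LEN)
  names(lens) <- c(as.character(seq_along(MOUSE_CHR_LEN)), "X")
  pos <- lapply(lens, function(L) seq(0, L, by = spacing))
  make_map(pos, x_chr = "X")
}

#' Map lengths by region
#'
#' @param map A `qtlx_map`.
#' @return Named vector with `L_A` (total autosomal length), `L_X`
#'   (X length, 0 if no X chromosome) and `L = L_A + L_X`, in cM.
#' @export
map_length <- function(map) {
  stopifnot(inherits(map, "qtlx_map"))
  len <- vapply(map, function(ch) diff(range(ch$pos)), 0)
  isx <- vapply(map, function(ch) ch$is_X, FALSE)
  LA <- sum(len[!isx])
  LX <- if (any(isx)) sum(len[isx]) else 0
  c(L_A = LA, L_X = LX, L = LA + LX)
}

#' @export
print.qtlx_map <- function(x, ...) {
  nm <- vapply(x, function(ch) ch$name, "")
  nmar <- vapply(x, function(ch) length(ch$pos), 0L)
  len <- vapply(x, function(ch) diff(range(ch$pos)), 0)
  cat("Genetic map:", length(x), "chromosomes,", sum(nmar), "markers\n")
  print(data.frame(chr = nm, n_markers = nmar, length_cM = len,
                   X = vapply(x, function(ch) ch$is_X, FALSE),
                   row.names = NULL))
  invisible(x)
}

#' Restrict a map to a subset of chromosomes
#' @param map A `qtlx_map`.
#' @param chrs Character vector of chromosome names to keep.
#' @return A `qtlx_map` with only the named chromosomes, in map order.
#' @export
map_subset <- function(map, chrs) {
  stopifnot(inherits(map, "qtlx_map"))
  keep <- names(map) %in% chrs
  if (!any(keep)) stop("no matching chromosomes")
  out <- map[keep]
  class(out) <- "qtlx_map"
  out
}
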