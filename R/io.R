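# genotype letter codes; X-chromosome states are encoded through the
# implied observable genotype (males by their hemizygous allele)
.GENO_CODES <- c("A", "H", "B")

.encode_geno <- function(cross) {
  n <- n_ind(cross)
  cols <- list()
  for (ch in cross$map) {
    g <- cross$geno[[ch$name]]
    enc <- matrix("-", n, ncol(g))
    if (!ch$is_X) {
      seen <- !is.na(g)
      enc[seen] <- .GENO_CODES[g[seen]]
    } else {
      male <- cross$sex == 1L
      for (j in seq_len(ncol(g))) {
        ok <- !is.na(g[, j])
        mi <- ok & male
        enc[mi, j] <- c("A", "B")[g[mi, j]]
        fi <- ok & !male
        enc[fi, j] <- .GENO_CODES[x_female_geno(g[fi, j], cross$direction[fi])]
      }
    }
    colnames(enc) <- names(ch$pos)
    cols[[ch$name]] <- enc
  }
  cols
}

#' Write a cross to a CSV cross file
#'
#' The comma-delimited cross format of the reference QTL-mapping ecosystem:
#' row 1 holds phenotype and marker names, row 2 chromosome ids (blank over
#' phenotype columns), row 3 marker positions in cM, and subsequent rows
#' one individual each.  Phenotype columns written: `pheno`, `sex`
#' (`f`/`m`) and `pgm` (paternal grandmother, 0/1, the cross direction).
#' Genotypes are `A`/`H`/`B` with `-` for missing; X-chromosome males are
#' coded by their hemizygous allele.
#'
#' @param cross A `qtlx_cross`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cross <- function(cross, path) {
  enc <- .encode_geno(cross)
  gmat <- do.call(cbind, enc)
  chrow <- unlist(lapply(cross$map, function(ch) rep(ch$name, length(ch$pos))))
  posrow <- unlist(lapply(cross$map, function(ch) unname(ch$pos)))
  ph <- cbind(pheno = ifelse(is.na(cross$pheno), "-", as.character(cross$pheno)),
              sex = c("f", "m")[cross$sex + 1L],
              pgm = as.character(cross$direction))
  lines <- c(paste(c(colnames(ph), colnames(gmat)), collapse = ","),
             paste(c("", "", "", chrow), collapse = ","),
             paste(c("", "", "", posrow), collapse = ","),
             apply(cbind(ph, gmat), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

.parse_x_geno <- function(code, sex, dir, ind, marker) {
  if (sex == 1L) {
    v <- match(code, c("A", "B"))
    if (is.na(v))
      stop("illegal X genotype '", code, "' for male individual ", ind,
           " at marker ", marker)
  } else {
    valid <- if (dir == 0L) c("A", "H") else c("H", "B")
    v <- match(code, valid)
    if (is.na(v))
      stop("illegal X genotype '", code, "' for female individual ", ind,
           " (direction ", dir, ") at marker ", marker)
  }
  v
}

#' Read a CSV cross file
#'
#' Inverse of [write_cross()]; the cross design is inferred from the data
#' (genotype codes observed on autosomes give backcross vs intercross, and
#' the `sex`/`pgm` columns give the sexes and directions present).  X
#' chromosome ids are recognized case-insensitively.  Illegal X genotypes
#' (e.g. a heterozygous male) are reported with individual and marker.
#'
#' @param path Path to the file.
#' @param na.string Missing-genotype code (default `"-"`).
#' @return A `qtlx_cross`.
#' @export
read_cross <- function(path, na.string = "-") {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4L) stop("malformed cross file: fewer than 4 rows")
  header <- unlist(raw[1L, ], use.names = FALSE)
  chrow <- unlist(raw[2L, ], use.names = FALSE)
  posrow <- unlist(raw[3L, ], use.names = FALSE)
  is_pheno <- !nzchar(trimws(chrow))
  if (!any(is_pheno)) stop("no phenotype columns (blank row-2 cells) found")
  if (is_pheno[length(is_pheno)]) stop("no marker columns found")
  dat <- raw[-(1:3), , drop = FALSE]
  n <- nrow(dat)

  phn <- header[is_pheno]
  sex <- if ("sex" %in% phn) {
    s <- tolower(dat[[which(is_pheno)[match("sex", phn)]]])
    if (!all(s %in% c("f", "m", "female", "male")))
      stop("sex column must be f/m")
    as.integer(substr(s, 1L, 1L) == "m")
  } else integer(n)
  dir <- if ("pgm" %in% phn)
    as.integer(dat[[which(is_pheno)[match("pgm", phn)]]]) else integer(n)
  if (anyNA(sex) || anyNA(dir)) stop("missing sex/pgm labels are not allowed")
  pheno_col <- setdiff(phn, c("sex", "pgm"))[1L]
  pheno <- if (!is.na(pheno_col)) {
    v <- dat[[which(is_pheno)[match(pheno_col, phn)]]]
    suppressWarnings(as.numeric(ifelse(v == na.string, NA, v)))
  } else rep(NA_real_, n)

  mcol <- which(!is_pheno)
  chr <- chrow[mcol]
  chr[toupper(chr) == "X"] <- "X"
  pos <- as.numeric(posrow[mcol])
  if (anyNA(pos)) stop("non-numeric marker position in row 3")
  uchr <- unique(chr)
  posl <- lapply(uchr, function(cc) {
    p <- pos[chr == cc]
    names(p) <- header[mcol][chr == cc]
    p
  })
  names(posl) <- uchr
  map <- make_map(posl, x_chr = if ("X" %in% uchr) "X" else NULL)

  # design inference from observed codes and labels
  gm <- as.matrix(dat[, mcol, drop = FALSE])
  colnames(gm) <- header[mcol]
  gm[gm == na.string] <- NA
  auto_codes <- unique(stats::na.omit(as.vector(gm[, chr != "X", drop = FALSE])))
  bad <- setdiff(auto_codes, .GENO_CODES)
  if (length(bad))
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  type <- if ("B" %in% auto_codes) "f2" else "bc"
  design <- cross_design(type,
                         sexes = if (all(sex == 0L)) "female"
                                 else if (all(sex == 1L)) "male" else "both",
                         directions = if (length(unique(dir)) > 1L) "both" else "one")

  geno <- lapply(map, function(ch) {
    sub <- gm[, chr == ch$name, drop = FALSE]
    out <- matrix(NA_integer_, n, ncol(sub))
    for (j in seq_len(ncol(sub))) for (i in seq_len(n)) {
      code <- sub[i, j]
      if (is.na(code)) next
      out[i, j] <- if (ch$is_X)
        .parse_x_geno(code, sex[i], dir[i], i, colnames(sub)[j] %||% j)
      else {
        v <- match(code, .GENO_CODES[seq_len(n_auto_states(design))])
        if (is.na(v)) stop("illegal genotype '", code, "' for individual ",
                           i, " on chromosome ", ch$name)
        v
      }
    }
    colnames(out) <- names(ch$pos)
    out
  })

  validate_cross(structure(list(design = design, map = map, geno = geno,
                                pheno = pheno, sex = sex, direction = dir),
                           class = "qtlx_cross"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a penalty set
#'
#' Plain-text key-value serialization with provenance comments.
#'
#' @param pen A `qtlx_penalties` or `qtlx_penalty_set`.
#' @param path File path.
#' @export
write_penalties <- function(pen, path) {
  lines <- c("# qtlx penalties")
  emit <- function(p, prefix) {
    flds <- c("T_m", "T_iH", "T_iL", "T_mA", "T_mX", "T_iAAH", "T_iAAL",
              "T_iAX", "T_iXX", "alpha")
    vals <- unlist(p[flds])
    vals <- vals[!is.na(vals)]
    paste(paste0(prefix, names(vals)), format(vals, digits = 15))
  }
  if (inherits(pen, "qtlx_penalty_set")) {
    prov <- pen$XneA$provenance
    lines <- c(lines,
               paste("#", names(prov$reps), "reps:", prov$reps),
               paste("# seed:", pen$seed),
               emit(pen$XneA, "XneA."), emit(pen$XeqA, "XeqA."))
  } else {
    lines <- c(lines, paste("# method:", pen$method), emit(pen, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_penalties
#' @export
read_penalties <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2L]), kv[, 1L])
  mk <- function(method, prefix) {
    v <- vals[startsWith(names(vals), prefix)]
    if (nzchar(prefix))
      names(v) <- substring(names(v), nchar(prefix) + 1L)
    args <- as.list(v[setdiff(names(v), "alpha")])
    args$alpha <- unname(v["alpha"])
    args$method <- method
    do.call(penalties, args)
  }
  if (any(startsWith(names(vals), "XneA."))) {
    out <- list(XneA = mk("XneA", "XneA."), XeqA = mk("XeqA", "XeqA."))
    class(out) <- "qtlx_penalty_set"
    out
  } else {
    method <- if (!is.na(vals["T_mA"]) || "T_mA" %in% names(vals)) "XneA" else "XeqA"
    mk(method, "")
  }
}

# tab-delimited result tables with '# ' provenance header
write_result_table <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste("#", p), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
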