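# Greedy one-to-one matching of selected QTL to true QTL: a selected QTL
# is a true positive if it lies within `window` cM of an unmatched true
# QTL on the same chromosome (closest assignments first); all other
# selected QTL are false positives.
match_qtl <- function(model, truth, window = 15) {
  ns <- n_qtl(model)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  match_of <- rep(NA_integer_, ns)
  if (ns == 0L || nt == 0L)
    return(list(match_of = match_of, detected = rep(FALSE, nt)))
  d <- matrix(Inf, ns, nt)
  for (s in seq_len(ns)) for (t in seq_len(nt))
    if (model$chr[s] == as.character(truth$chr[t]))
      d[s, t] <- abs(model$pos[s] - truth$pos[t])
  d[d > window] <- Inf
  repeat {
    if (!any(is.finite(d))) break
    b <- arrayInd(which.min(d), dim(d))
    match_of[b[1L]] <- b[2L]
    d[b[1L], ] <- Inf
    d[, b[2L]] <- Inf
  }
  list(match_of = match_of, detected = seq_len(nt) %in% match_of)
}

#' Type-I error and power of model selection methods by simulation
#'
#' Repeatedly simulates a scenario, runs the stepwise search under each
#' supplied penalty set on the same data, and tallies false-positive and
#' detection events.  A selected QTL counts as correct if it falls within
#' `window` cM of a distinct true QTL on the same chromosome; a selected
#' interaction is correct only if its two QTL match a truly interacting
#' pair.
#'
#' @param name Scenario name (see [scenario()]).
#' @param pens Named list of [penalties()] objects (e.g.
#'   `list(XneA = ..., XeqA = ...)`).
#' @param n_reps Number of simulation replicates.
#' @param n Individuals per replicate (default 250).
#' @param window Matching window in cM (default 15).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param max_qtl Forward-selection cap (default 10).
#' @return List with `counts` (per method: replicates with any false main
#'   QTL, any false autosomal / X-linked main, any false interaction) and
#'   `detect` (per method x true QTL: detections), plus `n_reps` and the
#'   truth tables.
#' @export
evaluate_scenario <- function(name, pens, n_reps, n = 250, window = 15,
                              seed = 1, max_qtl = 10) {
  sc <- scenario(name, n)
  truth <- sc$qtl
  tint <- sc$interactions
  xchr <- "X"
  methods <- names(pens)
  counts <- array(0L, c(length(methods), 4L),
                  dimnames = list(methods,
                                  c("fp_main", "fp_A", "fp_X", "fp_int")))
  nt <- if (is.null(truth)) 0L else nrow(truth)
  detect <- matrix(0L, length(methods), nt,
                   dimnames = list(methods, if (nt) paste0(truth$chr, "@", truth$pos)))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cr <- sim_scenario(name, n)
    probs <- calc_genoprob(cr)
    for (m in methods) {
      fit <- stepwise_qtl(cr, pens[[m]], probs = probs, max_qtl = max_qtl)
      mt <- match_qtl(fit$model, truth, window)
      fp <- is.na(mt$match_of)
      if (any(fp)) counts[m, "fp_main"] <- counts[m, "fp_main"] + 1L
      if (any(fp & fit$model$chr != xchr)) counts[m, "fp_A"] <- counts[m, "fp_A"] + 1L
      if (any(fp & fit$model$chr == xchr)) counts[m, "fp_X"] <- counts[m, "fp_X"] + 1L
      if (nt) detect[m, ] <- detect[m, ] + mt$detected
      if (nrow(fit$model$edges) > 0L) {
        ok_edge <- apply(fit$model$edges, 1L, function(e) {
          a <- mt$match_of[e[1L]]; b <- mt$match_of[e[2L]]
          !is.na(a) && !is.na(b) && !is.null(tint) &&
            any((tint$q1 == a & tint$q2 == b) | (tint$q1 == b & tint$q2 == a))
        })
        if (any(!ok_edge)) counts[m, "fp_int"] <- counts[m, "fp_int"] + 1L
      }
    }
  }
  list(scenario = name, n_reps = n_reps, truth = truth,
       interactions = tint, counts = counts, detect = detect)
}
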