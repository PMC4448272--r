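#' Generate a multinomial random genome
#'
#' Draws each position independently from the given nucleotide
#' frequencies — the null model used to calibrate the energy threshold:
#' in such a genome base pairs arise by chance only, so a robust energy
#' model should separate its hairpins from genuine pre-miRNAs.
#'
#' @param base_frequencies named numeric over A, C, G and U (or T),
#'   non-negative, summing to 1 (tolerance 1e-9).
#' @param length sequence length, >= 1.
#' @param seed optional integer; when given, the draw is made under a
#'   local RNG state and is reproducible.
#' @return character scalar in the alphabet of `names(base_frequencies)`.
#' @export
random_genome <- function(base_frequencies, length, seed = NULL) {
  ab <- names(base_frequencies)
  if (is.null(ab) || !setequal(toupper(ab), c("A", "C", "G", "U")) &&
      !setequal(toupper(ab), c("A", "C", "G", "T")))
    stop("base_frequencies must be named over A, C, G and U (or T)")
  if (any(base_frequencies < 0) || abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base_frequencies must be non-negative and sum to 1")
  stopifnot(length >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  paste(sample(toupper(ab), length, replace = TRUE, prob = base_frequencies),
        collapse = "")
}

#' Match predictions against a control miRNA set
#'
#' A prediction is a true positive when one of its two stem-arms fully
#' covers a control (mature miRNA) interval on the same strand. A
#' prediction covering several controls is credited once — processing is
#' greedy in ascending energy, so the best-scoring prediction claims a
#' control first and each control is credited at most once. Controls
#' covered by no prediction are false negatives; predictions covering no
#' (unclaimed) control are false positives.
#'
#' @param predictions candidate `GRanges` with `l` and `energy` metadata
#'   columns (as from [scan_sequence()]).
#' @param controls control `GRanges` (mature miRNA intervals); strand `*`
#'   matches either strand.
#' @return list with counts `TP`, `FP`, `FN`, logical vectors `is_tp`
#'   (per prediction) and `matched` (per control), and the TP loci as a
#'   `GRanges`.
#' @export
match_predictions <- function(predictions, controls) {
  np <- length(predictions); nc <- length(controls)
  is_tp <- logical(np); matched <- logical(nc)
  if (np > 0 && nc > 0) {
    l <- mcols(predictions)$l
    arm1 <- GenomicRanges::resize(predictions, width = l, fix = "start")
    arm2 <- GenomicRanges::resize(predictions, width = l, fix = "end")
    cov1 <- GenomicRanges::findOverlaps(controls, arm1, type = "within")
    cov2 <- GenomicRanges::findOverlaps(controls, arm2, type = "within")
    covers <- unique(rbind(
      data.frame(ctrl = queryHits(cov1), pred = subjectHits(cov1)),
      data.frame(ctrl = queryHits(cov2), pred = subjectHits(cov2))))
    ord <- order(mcols(predictions)$energy, start(predictions))
    for (pk in ord) {
      cands <- covers$ctrl[covers$pred == pk & !matched[covers$ctrl]]
      if (length(cands)) {          # claim one control; others stay available
        matched[cands[1]] <- TRUE
        is_tp[pk] <- TRUE
      }
    }
  }
  list(TP = sum(is_tp), FP = sum(!is_tp), FN = sum(!matched),
       is_tp = is_tp, matched = matched,
       tp_loci = predictions[is_tp])
}

#' Sensitivity, precision and specificity
#'
#' The three standard ratios as percentages: sensitivity
#' `100 TP/(TP+FN)`, precision `100 TP/(TP+FP)`, and — only when a true
#' negative count is supplied, i.e. when an explicit negative set exists —
#' specificity `100 TN/(TN+FP)`. A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param x either a [match_predictions()] result or the TP count.
#' @param fp,fn,tn counts when `x` is given as a number; `tn` is optional.
#' @return list of class `prediction_metrics` with the counts and the
#'   three percentages.
#' @export
compute_metrics <- function(x, fp = NULL, fn = NULL, tn = NA_real_) {
  if (is.list(x)) {
    tp <- x$TP; fp <- x$FP; fn <- x$FN
  } else {
    tp <- x
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 sensitivity = ratio(tp, tp + fn),
                 precision = ratio(tp, tp + fp),
                 specificity = if (is.na(tn)) NA_real_ else ratio(tn, tn + fp)),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("TP=%d FP=%d FN=%d%s\n", x$TP, x$FP, x$FN,
              if (!is.na(x$TN)) paste0(" TN=", x$TN) else ""))
  cat("  sensitivity:", fmt(x$sensitivity),
      " precision:", fmt(x$precision),
      " specificity:", fmt(x$specificity), "\n")
  invisible(x)
}

#' Calibrate the energy threshold against a random genome
#'
#' Implements the random-genome procedure: predictions are made both on
#' the original genome and on a shuffled (multinomial) genome of the same
#' composition; a random-genome candidate counts as a "true" hit only
#' when its coordinates coincide exactly with a true-miRNA locus of the
#' original genome (a TP prediction there). The returned threshold is the
#' largest candidate energy in the random genome at or below which no
#' such coordinate-matching hit occurs.
#'
#' @param real_predictions candidate `GRanges` from the original genome
#'   (with `l`, `energy`).
#' @param random_predictions candidate `GRanges` from the random genome.
#' @param controls control miRNA `GRanges` for the original genome.
#' @param ceiling threshold returned when the vacuous condition holds
#'   (no coordinate-matching random hit at all), kcal/mol.
#' @return threshold e in kcal/mol.
#' @export
calibrate_threshold <- function(real_predictions, random_predictions,
                                controls, ceiling = 0) {
  if (length(random_predictions) == 0) {
    warning("no candidate in the random genome; returning the ceiling")
    return(ceiling)
  }
  tp_loci <- match_predictions(real_predictions, controls)$tp_loci
  key <- function(gr) paste(seqnames(gr), start(gr), end(gr), strand(gr))
  hit <- key(random_predictions) %in% key(tp_loci)
  e <- mcols(random_predictions)$energy
  if (!any(hit)) return(ceiling)
  ok <- e[e < min(e[hit])]
  if (length(ok) == 0) {
    warning("every random-genome energy level contains a coordinate-matching ",
            "hit; no usable threshold")
    return(-Inf)
  }
  max(ok)
}
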