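#' Align two candidate stem-arms
#'
#' Runs a global Needleman-Wunsch alignment of the 5' arm against the 3'
#' arm (the latter supplied 3'->5' so that a Match is an antiparallel
#' canonical base pair), with incremental scores derived from the
#' Nearest-Neighbour model: consecutive matches credit the pair-step
#' stacking energy, mismatch steps charge half the 2-nt internal-loop
#' initiation, and gap steps charge the 1-nt bulge initiation. The search
#' may be restricted to a diagonal band of half-width `dw`, which bounds
#' the bulge lengths an alignment can contain; `full_matrix = TRUE`
#' explores every cell (equivalent to `dw` equal to the arm length).
#'
#' The DP score is a search heuristic; the energy reported for a candidate
#' is always the exact motif re-scoring, see [score_alignment()].
#'
#' @param st1 5' arm sequence (5'->3'), character.
#' @param st2 3' arm sequence given 3'->5', character, same length as
#'   `st1`.
#' @param params an [nn_params()] object.
#' @param dw diagonal half-width in cells; defaults to 5, clipped to the
#'   arm length for very short arms.
#' @param full_matrix explore the full DP matrix.
#' @return an object of class `hairpin_alignment`: list with `ops` (string
#'   over M/S/I/D), `st1`, `st2`, `score` (DP objective, negated energy
#'   surrogate) and `cells` (number of DP cells visited, for scaling
#'   diagnostics).
#' @examples
#' p <- nn_params()
#' a <- align_arms("GGCAGC", "CCGUCG", p)
#' a$ops               # all matches: "MMMMMM"
#' score_alignment(a, p)
#' @export
align_arms <- function(st1, st2, params = nn_params(), dw = NULL,
                       full_matrix = FALSE) {
  st1 <- rna_normalize(st1); st2 <- rna_normalize(st2)
  if (nchar(st1) != nchar(st2)) stop("stem-arms must have equal length")
  if (nchar(st1) == 0) stop("empty stem-arms")
  if (is.null(dw)) dw <- min(5L, nchar(st1))
  e1 <- .encode_seq(st1); e2 <- .encode_seq(st2)
  if (any(e1 < 0) || any(e2 < 0))
    stop("stem-arms must contain only A, C, G, U (or T)")
  if (!full_matrix && (dw < 1 || dw > nchar(st1)))
    stop("dw must be in 1..arm length")
  r <- cpp_align(e1, e2, as.integer(dw), isTRUE(full_matrix), unclass(params))
  structure(list(ops = r$ops, st1 = st1, st2 = st2, score = r$score,
                 cells = r$cells, dw = if (full_matrix) nchar(st1) else dw,
                 full_matrix = isTRUE(full_matrix)),
            class = "hairpin_alignment")
}

#' Build an alignment object from an explicit operation string
#'
#' Mostly for tests and programmatic construction: validates that the
#' M/S/I/D operations project back onto both arm sequences.
#'
#' @param ops string over the alphabet M, S, I, D.
#' @param st1,st2 the arm sequences (st2 in 3'->5' orientation).
#' @return a `hairpin_alignment`.
#' @export
hairpin_alignment <- function(ops, st1, st2) {
  st1 <- rna_normalize(st1); st2 <- rna_normalize(st2)
  o <- .chars(ops)
  if (!all(o %in% c("M", "S", "I", "D"))) stop("ops must be over M/S/I/D")
  if (sum(o %in% c("M", "S", "D")) != nchar(st1) ||
      sum(o %in% c("M", "S", "I")) != nchar(st2))
    stop("ops do not project onto the arm sequences")
  x <- .chars(st1); y <- .chars(st2)
  xs <- x[pmax(cumsum(o %in% c("M", "S", "D")), 1)]
  ys <- y[pmax(cumsum(o %in% c("M", "S", "I")), 1)]
  isM <- o == "M"
  if (any(isM & !is_canonical_pair(xs, ys)))
    stop("M symbols must correspond to canonical base pairs")
  if (any(o == "S" & is_canonical_pair(xs, ys)))
    stop("S symbols must correspond to non-canonical pairs")
  structure(list(ops = ops, st1 = st1, st2 = st2, score = NA_real_,
                 cells = NA_real_, dw = NA_integer_, full_matrix = NA),
            class = "hairpin_alignment")
}

#' @export
print.hairpin_alignment <- function(x, ...) {
  cat("hairpin arm alignment (", nchar(x$st1), "nt arms )\n", sep = "")
  cat(" ", x$ops, "\n", sep = "")
  if (!is.na(x$score)) cat(sprintf("  DP score %.3f, %d cells\n", x$score,
                                   as.integer(x$cells)))
  invisible(x)
}

# per-symbol table: op, consumed arm1 base (or NA), consumed arm2 base
.sym_table <- function(v) {
  o <- .chars(v$ops)
  x <- .chars(v$st1); y <- .chars(v$st2)
  cx <- cumsum(o %in% c("M", "S", "D"))
  cy <- cumsum(o %in% c("M", "S", "I"))
  data.frame(op = o,
             x = ifelse(o %in% c("M", "S", "D"), x[pmax(cx, 1)], NA),
             y = ifelse(o %in% c("M", "S", "I"), y[pmax(cy, 1)], NA),
             xi = ifelse(o %in% c("M", "S", "D"), cx, NA),
             yi = ifelse(o %in% c("M", "S", "I"), cy, NA),
             stringsAsFactors = FALSE)
}

# maximal run of identical bases containing position pos (1-based)
.run_length_at <- function(seq_chars, pos) {
  b <- seq_chars[pos]
  n <- 1L
  k <- pos - 1L
  while (k >= 1 && seq_chars[k] == b) { n <- n + 1L; k <- k - 1L }
  k <- pos + 1L
  while (k <= length(seq_chars) && seq_chars[k] == b) { n <- n + 1L; k <- k + 1L }
  n
}

#' Decompose an arm alignment into structural motifs
#'
#' Maximal runs of M become helices; interior runs with unpaired bases on
#' both strands become internal loops (`n1`/`n2` from the per-strand base
#' counts, closing pairs taken from the adjacent matches); runs unpaired
#' on one strand only become bulges. A terminal (leading or trailing)
#' unpaired run contributes a dangling end for each strand carrying
#' exactly one base there; longer terminal runs are unscored and raise a
#' warning.
#'
#' @param v a `hairpin_alignment`.
#' @return list of `hairpin_motif` objects, outermost first.
#' @export
decompose_motifs <- function(v) {
  stopifnot(inherits(v, "hairpin_alignment"))
  tab <- .sym_table(v)
  L <- nrow(tab)
  isM <- tab$op == "M"
  if (!any(isM)) {
    warning("alignment contains no canonical pair; no motifs")
    return(list())
  }
  r <- rle(isM)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  x1c <- .chars(v$st1); y2c <- .chars(v$st2)
  motifs <- list()
  midx <- which(r$values)             # helix runs
  first_h <- midx[1]; last_h <- midx[length(midx)]

  pair_at <- function(k) paste0(tab$x[k], tab$y[k])

  # a dangling end is a single unpaired base: scored only when the whole
  # terminal run carries exactly one base (a lone I or D symbol)
  terminal_dangles <- function(from, to, helix_k, leading) {
    xb <- tab$x[from:to]; yb <- tab$y[from:to]
    xb <- xb[!is.na(xb)]; yb <- yb[!is.na(yb)]
    P <- pair_at(helix_k)
    if (length(xb) + length(yb) == 1) {
      if (leading) {
        if (length(xb) == 1) return(list(dangle_motif(xb, P, "5p")))
        return(list(dangle_motif(yb, P, "3p")))
      }
      Pr <- .rev_pair(P)
      if (length(xb) == 1) return(list(dangle_motif(xb, Pr, "3p")))
      return(list(dangle_motif(yb, Pr, "5p")))
    }
    warning("terminal unpaired run with more than one base is not scored")
    list()
  }

  for (k in seq_along(r$lengths)) {
    from <- starts[k]; to <- ends[k]
    if (r$values[k]) {                # helix
      motifs <- c(motifs, list(helix_motif(vapply(from:to, pair_at, ""))))
    } else if (k < first_h) {         # leading terminal run
      motifs <- c(motifs, terminal_dangles(from, to, ends[first_h] - r$lengths[first_h] + 1L,
                                           leading = TRUE))
    } else if (k > last_h) {          # trailing terminal run
      motifs <- c(motifs, terminal_dangles(from, to, ends[last_h], leading = FALSE))
    } else {                          # interior loop run
      closing5 <- pair_at(from - 1L)
      closing3 <- pair_at(to + 1L)
      xb <- tab$x[from:to]; yb <- tab$y[from:to]
      xidx <- tab$xi[from:to][!is.na(xb)]; yidx <- tab$yi[from:to][!is.na(yb)]
      xb <- xb[!is.na(xb)]; yb <- yb[!is.na(yb)]
      if (length(xb) > 0 && length(yb) > 0) {
        motifs <- c(motifs, list(internal_loop_motif(xb, yb, closing5, closing3)))
      } else if (length(xb) > 0) {
        tconf <- if (length(xb) == 1) .run_length_at(x1c, xidx[1]) else 1L
        motifs <- c(motifs, list(bulge_motif(xb, 1L, closing5, closing3, tconf)))
      } else {
        tconf <- if (length(yb) == 1) .run_length_at(y2c, yidx[1]) else 1L
        motifs <- c(motifs, list(bulge_motif(yb, 2L, closing5, closing3, tconf)))
      }
    }
  }
  motifs
}

#' Exact free energy of an arm alignment
#'
#' Decomposes the alignment into motifs and sums their Nearest-Neighbour
#' increments. This re-scoring — not the DP objective — is the energy
#' reported for every candidate.
#'
#' @param v a `hairpin_alignment`.
#' @param params an [nn_params()] object.
#' @return energy E in kcal/mol.
#' @export
score_alignment <- function(v, params = nn_params()) {
  motifs <- decompose_motifs(v)
  if (length(motifs) == 0) return(0)
  total_energy(params, motifs)
}

#' Dot-bracket structure of a candidate hairpin
#'
#' Arm-1 bases in matches become `(`, arm-2 bases in matches `)`, and
#' everything else — mismatches, bulged bases and the whole terminal loop —
#' a dot. The string covers arm1 + loop + arm2 in genomic order and its
#' parentheses are balanced by construction.
#'
#' @param v a `hairpin_alignment`.
#' @param loop_length terminal-loop length n (>= 0).
#' @return character scalar of length `2l' + n` where `l'` counts the
#'   bases of each arm (equal to the arm length).
#' @export
to_dot_bracket <- function(v, loop_length) {
  stopifnot(inherits(v, "hairpin_alignment"), loop_length >= 0)
  o <- .chars(v$ops)
  arm1 <- ifelse(o[o %in% c("M", "S", "D")] == "M", "(", ".")
  # arm2 is stored 3'->5'; genomic order is the reverse
  arm2 <- rev(ifelse(o[o %in% c("M", "S", "I")] == "M", ")", "."))
  paste0(paste(arm1, collapse = ""),
         strrep(".", loop_length),
         paste(arm2, collapse = ""))
}
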