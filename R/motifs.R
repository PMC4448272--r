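#' Structural motifs of a stem-loop
#'
#' A hairpin stem decomposes into helices (runs of stacked canonical base
#' pairs), bulge loops (unpaired bases on one strand) and internal loops
#' (unpaired bases on both strands); single unpaired bases at a stem
#' terminus are dangling ends. These constructors build the motif objects
#' consumed by the energy functions. Pairs are written as two-character
#' strings, first base on the 5' arm, second the partner on the 3' arm
#' (stored 3'->5', so a pair string like `"GC"` is an antiparallel G-C
#' pair).
#'
#' @param pairs character vector of canonical pairs, outermost first.
#' @param n1,n2 unpaired-base counts on strand 1 (5' arm) / strand 2.
#' @param closing5,closing3 the canonical pairs closing the loop on its
#'   5'-arm side and its loop-proximal side.
#' @param x_bases,y_bases unpaired bases of an internal loop on strand 1 /
#'   strand 2, in strand order.
#' @param strand which strand carries a bulge's unpaired bases (1 or 2).
#' @param bases unpaired bases of a bulge, in strand order.
#' @param t_conformations number of sequence-identical conformations of a
#'   single-base bulge (run length of the bulged base across the site).
#' @param base,side a dangling end's base and the side (`"5p"`/`"3p"`) of
#'   `closing5` it stacks on.
#' @return a list of class `hairpin_motif`.
#' @name motif-constructors
NULL

.check_bases <- function(b) {
  bad <- setdiff(b, .BASES)
  if (length(bad)) stop("unknown nucleotide symbol(s): ", paste(bad, collapse = ", "))
}
.check_pairs <- function(p) {
  bad <- setdiff(p, .PAIRS)
  if (length(bad)) stop("non-canonical base pair(s): ", paste(bad, collapse = ", "))
}

#' @rdname motif-constructors
#' @export
helix_motif <- function(pairs) {
  .check_pairs(pairs)
  if (length(pairs) < 1) stop("a helix needs at least one base pair")
  structure(list(kind = "HELIX", n1 = 0L, n2 = 0L, pairs = pairs),
            class = "hairpin_motif")
}

#' @rdname motif-constructors
#' @export
internal_loop_motif <- function(x_bases, y_bases, closing5, closing3) {
  .check_bases(c(x_bases, y_bases))
  .check_pairs(c(closing5, closing3))
  if (length(x_bases) < 1 || length(y_bases) < 1)
    stop("an internal loop needs unpaired bases on both strands (a bulge otherwise)")
  structure(list(kind = "INTERNAL_LOOP",
                 n1 = length(x_bases), n2 = length(y_bases),
                 x_bases = x_bases, y_bases = y_bases,
                 closing5 = closing5, closing3 = closing3),
            class = "hairpin_motif")
}

#' @rdname motif-constructors
#' @export
bulge_motif <- function(bases, strand, closing5, closing3, t_conformations = 1L) {
  .check_bases(bases)
  .check_pairs(c(closing5, closing3))
  if (length(bases) < 1) stop("a bulge needs at least one unpaired base")
  if (!strand %in% c(1L, 2L)) stop("strand must be 1 or 2")
  if (t_conformations < 1) stop("t_conformations must be >= 1")
  structure(list(kind = "BULGE",
                 n1 = if (strand == 1) length(bases) else 0L,
                 n2 = if (strand == 2) length(bases) else 0L,
                 bases = bases, strand = as.integer(strand),
                 closing5 = closing5, closing3 = closing3,
                 t_conformations = as.integer(t_conformations)),
            class = "hairpin_motif")
}

#' @rdname motif-constructors
#' @export
dangle_motif <- function(base, closing5, side = c("5p", "3p")) {
  side <- match.arg(side)
  .check_bases(base)
  .check_pairs(closing5)
  structure(list(kind = "DANGLE", n1 = 0L, n2 = 0L, base = base,
                 closing5 = closing5, side = side),
            class = "hairpin_motif")
}

#' @export
print.hairpin_motif <- function(x, ...) {
  cat(sprintf("<%s n1=%d n2=%d>\n", x$kind, x$n1, x$n2))
  invisible(x)
}

# count of RU (A-U or G-U in either orientation) pairs among those given
.ru_count <- function(pairs) sum(pairs %in% .RU_PAIRS)

#' Free energy of an internal loop
#'
#' Initiation for the total loop size `n = n1 + n2` (tabulated up to 30,
#' Jacobson-Stockmayer extrapolated beyond), plus the asymmetry penalty
#' (0.6 kcal/mol per unit of `|n1 - n2|`), the first and last loop
#' mismatches against their closing pairs, and 0.7 kcal/mol per RU closing
#' pair (U paired with a purine).
#'
#' @param params an [nn_params()] object.
#' @param m an internal-loop motif from [internal_loop_motif()].
#' @return energy in kcal/mol.
#' @export
internal_loop_energy <- function(params, m) {
  stopifnot(inherits(m, "hairpin_motif"))
  if (m$kind != "INTERNAL_LOOP") stop("not an internal loop (n1 or n2 is 0?)")
  n <- m$n1 + m$n2
  init <- .loop_init(params, "internal", n)
  asym <- params$asym_penalty * abs(m$n1 - m$n2)
  # first mismatch: bases adjacent to the 5'-side closure, looked up with
  # that closure; last mismatch: adjacent to the far closure, looked up with
  # the far closure read in the direction entering the loop (reversed)
  m1 <- params$terminal_mismatch[m$closing5, m$x_bases[1], m$y_bases[1]]
  m2 <- params$terminal_mismatch[.rev_pair(m$closing3),
                                 m$y_bases[m$n2], m$x_bases[m$n1]]
  ru <- params$ru_closure * .ru_count(c(m$closing5, m$closing3))
  init + asym + m1 + m2 + ru
}

#' Free energy of a bulge loop
#'
#' A single-base bulge keeps the flanking helix stacked: initiation plus
#' the stacking of the two closing pairs, the C-bulge bonus (-0.9 kcal/mol
#' when a C is bulged next to a paired C), a `-RT log(t)` correction for
#' the `t` sequence-identical conformations, and 0.45 kcal/mol per RU
#' closing pair. Bulges of 2..30 bases cost the initiation alone; larger
#' ones are extrapolated.
#'
#' @param params an [nn_params()] object.
#' @param m a bulge motif from [bulge_motif()].
#' @return energy in kcal/mol.
#' @export
bulge_energy <- function(params, m) {
  stopifnot(inherits(m, "hairpin_motif"))
  if (m$kind != "BULGE") stop("not a bulge")
  n <- length(m$bases)
  if (n == 0) stop("empty bulge")
  if (n > 1) return(.loop_init(params, "bulge", n))
  # n = 1
  init <- params$bulge_init[1]
  stck <- params$stacking[m$closing5, m$closing3]
  b <- m$bases[1]
  flank <- if (m$strand == 1)
    c(substring(m$closing5, 1, 1), substring(m$closing3, 1, 1))
  else
    c(substring(m$closing5, 2, 2), substring(m$closing3, 2, 2))
  cb <- if (b == "C" && any(flank == "C")) params$c_bulge else 0
  ru <- params$ru_end * .ru_count(c(m$closing5, m$closing3))
  init + cb + stck - params$RT * log(m$t_conformations) + ru
}

#' Free energy of a helix
#'
#' Sum of the stacking increments of consecutive base pairs, the
#' self-complementary duplex correction when the two strands read
#' identically 5'->3', and 0.45 kcal/mol per RU terminal pair.
#'
#' @param params an [nn_params()] object.
#' @param m a helix motif from [helix_motif()].
#' @return energy in kcal/mol.
#' @export
helix_energy <- function(params, m) {
  stopifnot(inherits(m, "hairpin_motif"))
  if (m$kind != "HELIX") stop("not a helix")
  .check_pairs(m$pairs)
  k <- length(m$pairs)
  stck <- if (k > 1)
    sum(params$stacking[cbind(m$pairs[-k], m$pairs[-1])])
  else 0
  s1 <- substring(m$pairs, 1, 1)                 # 5' arm, 5'->3'
  s2 <- substring(m$pairs, 2, 2)                 # 3' arm, 3'->5'
  selfc <- identical(s1, rev(s2))                # both strands identical 5'->3'
  sym <- if (selfc) params$sym_correction else 0
  ru <- params$ru_end * .ru_count(c(m$pairs[1], m$pairs[k]))
  stck + sym + ru
}

#' Free energy of a single motif
#'
#' Dispatches to [helix_energy()], [bulge_energy()],
#' [internal_loop_energy()] or [dangling_end_energy()] by motif kind.
#'
#' @param params an [nn_params()] object.
#' @param m a `hairpin_motif`.
#' @return energy in kcal/mol.
#' @export
motif_energy <- function(params, m) {
  stopifnot(inherits(m, "hairpin_motif"))
  switch(m$kind,
         HELIX = helix_energy(params, m),
         BULGE = bulge_energy(params, m),
         INTERNAL_LOOP = internal_loop_energy(params, m),
         DANGLE = dangling_end_energy(params, m$closing5, m$base, m$side),
         stop("unknown motif kind: ", m$kind))
}

#' Total free energy of a motif decomposition
#'
#' The stem-loop energy is the plain sum of its motif increments; the
#' terminal loop contributes nothing (only the stem-arms are scored).
#'
#' @param params an [nn_params()] object.
#' @param motifs list of `hairpin_motif` objects from one decomposition.
#' @return total energy E in kcal/mol.
#' @export
total_energy <- function(params, motifs) {
  if (length(motifs) == 0) {
    warning("empty motif list; total energy is 0")
    return(0)
  }
  sum(vapply(motifs, function(m) motif_energy(params, m), numeric(1)))
}
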