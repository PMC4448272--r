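#' Configuration of a genome scan
#'
#' Window geometry and scoring options of the sliding-window hairpin
#' screen. Defaults are the genome-scale settings for metazoan pre-miRNAs:
#' stem-arm length 25 nt (mean mature miRNA length 22 nt plus a 3 nt
#' offset), terminal-loop lengths 5..20 nt, energy threshold -20.6
#' kcal/mol and a diagonal band of half-width 5. Plant scans typically use
#' longer arms and loops (e.g. `l = 48`, `n_max = 70`) and a lower
#' threshold.
#'
#' @param l stem-arm length in nt.
#' @param n_min,n_max terminal-loop length bounds in nt.
#' @param energy_threshold keep candidates with exact energy at or below
#'   this value (kcal/mol).
#' @param dw diagonal half-width of the alignment band; defaults to 5,
#'   clipped to the arm length for very short arms.
#' @param full_matrix explore the full DP matrix instead of the band.
#' @param both_strands scan the reverse complement too.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(l = 25, n_min = 5, n_max = 20,
                        energy_threshold = -20.6, dw = NULL,
                        full_matrix = FALSE, both_strands = TRUE) {
  stopifnot(l >= 1, n_min >= 1, n_min <= n_max, is.finite(energy_threshold))
  if (is.null(dw)) dw <- min(5L, l)
  if (!full_matrix && (dw < 1 || dw > l)) stop("dw must be in 1..l")
  structure(list(l = as.integer(l), n_min = as.integer(n_min),
                 n_max = as.integer(n_max),
                 energy_threshold = energy_threshold,
                 dw = as.integer(if (full_matrix) l else dw),
                 full_matrix = isTRUE(full_matrix),
                 both_strands = isTRUE(both_strands)),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("scan_config: l=%d loop=[%d,%d] threshold=%.2f kcal/mol %s both_strands=%s\n",
              x$l, x$n_min, x$n_max, x$energy_threshold,
              if (x$full_matrix) "full matrix" else paste0("dw=", x$dw),
              x$both_strands))
  invisible(x)
}

#' Enumerate candidate stem-arm pairs over a sequence
#'
#' Yields every window: for each start `i` in `[0, N - 2l - n]` and loop
#' length `n` in `[n_min, n_max]`, the 5' arm is `W[i, i+l)`, the loop
#' `W[i+l, i+l+n)` and the 3' arm the `l` bases after the loop,
#' returned reversed (3'->5') so a Match in the alignment is an
#' antiparallel base pair. Enumeration is exhaustive over positions.
#'
#' @param W sequence (character scalar, DNA or RNA alphabet).
#' @param config a [scan_config()].
#' @return data.frame with columns `i` (0-based window start), `n`, `st1`,
#'   `loop`, `st2` (3'->5').
#' @export
enumerate_windows <- function(W, config = scan_config()) {
  W <- rna_normalize(as.character(W))
  N <- nchar(W)
  l <- config$l
  if (N < 2 * l + config$n_min) {
    warning("sequence shorter than the smallest window (2l + n_min)")
    return(data.frame(i = integer(), n = integer(), st1 = character(),
                      loop = character(), st2 = character()))
  }
  revstr <- function(s) paste(rev(.chars(s)), collapse = "")
  out <- do.call(rbind, lapply(config$n_min:config$n_max, function(n) {
    imax <- N - 2L * l - n
    if (imax < 0) return(NULL)
    i <- 0:imax
    data.frame(i = i, n = n,
               st1 = substring(W, i + 1, i + l),
               loop = substring(W, i + l + 1, i + l + n),
               st2 = vapply(substring(W, i + l + n + 1, i + 2 * l + n),
                            revstr, "", USE.NAMES = FALSE))
  }))
  out[order(out$i, out$n), , drop = FALSE]
}

#' Scan one sequence for stable hairpin candidates
#'
#' Every enumerated stem-arm pair is aligned with the banded DP and
#' re-scored exactly; windows whose energy is at or below the threshold
#' are reported. With `both_strands`, the reverse complement is scanned
#' too and its hits are mapped back to forward coordinates on the minus
#' strand. Windows whose arms contain non-ACGU characters (assembly gaps,
#' masked bases) are skipped with a warning summarising how many.
#'
#' @param W sequence (character scalar, or `Biostrings::DNAString`-like).
#' @param config a [scan_config()].
#' @param params an [nn_params()] object.
#' @param seqname name used for the output seqlevel.
#' @return a `GRanges` of candidates (1-based, inclusive) with metadata
#'   columns `l`, `n`, `energy` (kcal/mol), `structure` (dot-bracket) and
#'   `ops` (alignment operations).
#' @export
scan_sequence <- function(W, config = scan_config(), params = nn_params(),
                          seqname = "seq") {
  W <- rna_normalize(as.character(W))
  N <- nchar(W)
  enc <- .encode_seq(W)
  run <- function(e) cpp_scan(e, config$l, config$n_min, config$n_max,
                              config$dw, config$full_matrix,
                              config$energy_threshold, unclass(params))
  hits <- list()
  r <- run(enc)
  skipped <- r$skipped
  if (length(r$start))
    hits[["+"]] <- data.frame(start = r$start, n = r$n, energy = r$energy,
                              ops = r$ops, strand = "+",
                              stringsAsFactors = FALSE)
  if (config$both_strands) {
    rc <- .revcomp_chars(W)
    r2 <- run(.encode_seq(rc))
    skipped <- skipped + r2$skipped
    if (length(r2$start)) {
      width <- 2L * config$l + r2$n
      hits[["-"]] <- data.frame(start = N - (r2$start + width), n = r2$n,
                                energy = r2$energy, ops = r2$ops,
                                strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " window(s) skipped: stem-arm contains non-ACGU characters")
  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), n = integer(), energy = numeric(),
               ops = character(), strand = character())
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(df)) seqname else character(),
    ranges = IRanges::IRanges(start = df$start + 1L,
                              width = 2L * config$l + df$n),
    strand = df$strand)
  seqlevels(gr) <- seqname
  mcols(gr)$l <- rep(config$l, nrow(df))
  mcols(gr)$n <- df$n
  mcols(gr)$energy <- df$energy
  mcols(gr)$ops <- df$ops
  mcols(gr)$structure <- if (nrow(df))
    mapply(function(ops, n) {
      to_dot_bracket(structure(list(ops = ops), class = "hairpin_alignment"), n)
    }, df$ops, df$n, USE.NAMES = FALSE)
  else character()
  seqlengths(gr) <- setNames(N, seqname)
  sort(gr, ignore.strand = TRUE)
}

# reverse complement on the internal RNA character representation
.revcomp_chars <- function(W) {
  paste(rev(.chars(chartr("ACGUN", "UGCAN", W))), collapse = "")
}

#' Scan a set of sequences
#'
#' Applies [scan_sequence()] to each element of a named sequence set and
#' concatenates the results.
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet`.
#' @param config a [scan_config()].
#' @param params an [nn_params()] object.
#' @return a `GRanges` of candidates across all sequences.
#' @export
scan_genome <- function(seqs, config = scan_config(), params = nn_params()) {
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  grl <- mapply(function(s, nm) scan_sequence(s, config, params, seqname = nm),
                seqs, names(seqs), SIMPLIFY = FALSE)
  out <- suppressWarnings(do.call(c, unname(grl)))
  out
}

#' Resolve overlapping candidates to one hit per locus
#'
#' Greedy selection by ascending energy (best first): a candidate is kept
#' only if its interval does not overlap an already kept candidate on the
#' same strand. Ties in energy are broken by start position, then loop
#' length, making the result deterministic.
#'
#' @param candidates a candidate `GRanges` from [scan_sequence()].
#' @return the kept subset, in genomic order.
#' @export
resolve_overlaps <- function(candidates) {
  if (length(candidates) <= 1) return(candidates)
  o <- order(mcols(candidates)$energy, start(candidates), mcols(candidates)$n)
  cand <- candidates[o]
  hits <- GenomicRanges::findOverlaps(cand, cand)   # strand-aware
  hits <- hits[queryHits(hits) != subjectHits(hits)]
  nb <- split(subjectHits(hits), factor(queryHits(hits), levels = seq_along(cand)))
  kept <- logical(length(cand))
  blocked <- logical(length(cand))
  for (k in seq_along(cand)) {
    if (!blocked[k]) {
      kept[k] <- TRUE
      blocked[nb[[k]]] <- TRUE
    }
  }
  sort(cand[kept], ignore.strand = TRUE)
}

#' Mask intervals of a sequence
#'
#' Replaces the masked positions with `N` so that no candidate stem-arm
#' can pair through them — the recommended treatment for annotated rRNA
#' and tRNA loci before a scan. Masking is idempotent.
#'
#' @param W sequence (character scalar).
#' @param mask_intervals `IRanges`/`GRanges` (1-based, inclusive) or a
#'   data.frame with `start`/`end` columns in the same convention.
#' @return the masked sequence, character scalar.
#' @export
apply_mask <- function(W, mask_intervals) {
  W <- rna_normalize(as.character(W))
  if (is.data.frame(mask_intervals)) {
    s <- mask_intervals$start; e <- mask_intervals$end
  } else {
    s <- start(mask_intervals)
    e <- end(mask_intervals)
  }
  if (length(s) == 0) return(W)
  if (any(s < 1) || any(e > nchar(W)) || any(s > e))
    stop("mask interval out of range")
  ch <- .chars(W)
  for (k in seq_along(s)) ch[s[k]:e[k]] <- "N"
  paste(ch, collapse = "")
}
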