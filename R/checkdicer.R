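#' Tolerances of the Dicer-signature read filter
#'
#' Two percentages control how tolerant the a-posteriori check is to reads
#' crossing the mature/loop/star boundaries: the fraction of a read's
#' length allowed outside its primary region, and the fraction of reads
#' allowed to exceed that. `dicer_config(0, 0)` is the strict mode: any
#' boundary-crossing read fails the candidate.
#'
#' @param max_read_overlap_pct per-read tolerance, percent of read length.
#' @param max_overlapping_reads_pct population tolerance, percent of reads.
#' @return an object of class `dicer_config`.
#' @export
dicer_config <- function(max_read_overlap_pct = 0,
                         max_overlapping_reads_pct = 0) {
  stopifnot(max_read_overlap_pct >= 0, max_read_overlap_pct <= 100,
            max_overlapping_reads_pct >= 0, max_overlapping_reads_pct <= 100)
  structure(list(max_read_overlap_pct = max_read_overlap_pct,
                 max_overlapping_reads_pct = max_overlapping_reads_pct),
            class = "dicer_config")
}

#' Assign reads to the mature / loop / star regions of a hairpin
#'
#' The candidate interval splits into the 5' arm (`MATURE`), the terminal
#' loop (`LOOP`) and the 3' arm (`STAR`). Each overlapping read is
#' assigned to the region containing most of its bases, ties resolved
#' toward an arm (never the loop); its overlap percentage is the share of
#' its bases falling outside that primary region. Reads not overlapping
#' the candidate are ignored.
#'
#' @param candidate a single-range candidate `GRanges` with metadata
#'   columns `l` and `n` (as produced by [scan_sequence()]).
#' @param reads read `GRanges`.
#' @return list of class `hairpin_read_partition`: per-region counts and a
#'   per-read data.frame with `region` and `overlap_pct`.
#' @export
partition_reads <- function(candidate, reads) {
  stopifnot(length(candidate) == 1)
  l <- mcols(candidate)$l; n <- mcols(candidate)$n
  s <- start(candidate)
  segs <- IRanges::IRanges(start = c(s, s + l, s + l + n),
                           width = c(l, n, l),
                           names = c("MATURE", "LOOP", "STAR"))
  keep <- IRanges::overlapsAny(reads, candidate, ignore.strand = TRUE)
  reads <- reads[keep]
  if (length(reads) == 0) {
    return(structure(list(counts = c(MATURE = 0L, LOOP = 0L, STAR = 0L),
                          reads = data.frame(region = character(),
                                             overlap_pct = numeric())),
                     class = "hairpin_read_partition"))
  }
  ov <- sapply(seq_along(segs), function(k) {
    IRanges::width(IRanges::pintersect(
      rep(segs[k], length(reads)), ranges(reads), resolve.empty = "start.x"))
  })
  if (is.null(dim(ov))) ov <- matrix(ov, nrow = 1)
  # primary region: most bases; ties favour the arms (MATURE, then STAR)
  pref <- c(1L, 3L, 2L)                      # MATURE, STAR, LOOP
  primary <- apply(ov, 1, function(x) pref[which.max(x[pref])])
  inpct <- ov[cbind(seq_along(primary), primary)]
  overlap_pct <- 100 * (width(reads) - inpct) / width(reads)
  region <- names(segs)[primary]
  counts <- table(factor(region, levels = names(segs)))
  structure(list(counts = setNames(as.integer(counts), names(segs)),
                 reads = data.frame(region = region,
                                    overlap_pct = overlap_pct)),
            class = "hairpin_read_partition")
}

#' Dicer-processing signature check
#'
#' A candidate fails when the fraction of boundary-crossing reads — reads
#' whose overlap percentage exceeds the per-read tolerance — is larger
#' than the population tolerance. With zero reads the check passes with a
#' `no_evidence` flag. The filter is advisory: it does not alter the scan
#' output unless applied explicitly.
#'
#' @param partition a [partition_reads()] result.
#' @param config a [dicer_config()].
#' @return list with `pass`, `n_reads`, `n_overlapping`,
#'   `pct_overlapping`, `no_evidence` and the offending reads.
#' @export
check_dicer <- function(partition, config = dicer_config()) {
  stopifnot(inherits(partition, "hairpin_read_partition"),
            inherits(config, "dicer_config"))
  nr <- nrow(partition$reads)
  if (nr == 0) {
    return(list(pass = TRUE, n_reads = 0L, n_overlapping = 0L,
                pct_overlapping = 0, no_evidence = TRUE,
                offending = partition$reads))
  }
  crossing <- partition$reads$overlap_pct > config$max_read_overlap_pct
  pct <- 100 * sum(crossing) / nr
  list(pass = pct <= config$max_overlapping_reads_pct,
       n_reads = nr, n_overlapping = sum(crossing),
       pct_overlapping = pct, no_evidence = FALSE,
       offending = partition$reads[crossing, , drop = FALSE])
}
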