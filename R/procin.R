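#' Read small-RNA alignments from a SAM file
#'
#' Converts the SAM text to BAM in a temporary location and loads the
#' mapped records (Rsamtools/GenomicAlignments); unmapped, secondary and
#' supplementary records are skipped by default. Reference spans are
#' derived from the CIGAR strings.
#'
#' @param path path to a SAM file with a header.
#' @param keep_secondary also keep secondary/supplementary alignments.
#' @return a `GRanges` of read alignments (1-based, inclusive) with a
#'   `qname` metadata column; seqlengths are taken from the SAM header.
#' @export
read_sam <- function(path, keep_secondary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (keep_secondary) NA else FALSE,
    isSupplementaryAlignment = if (keep_secondary) NA else FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags, what = "qname"))
  gr <- GenomicRanges::granges(ga)
  mcols(gr)$qname <- mcols(ga)$qname
  gr
}

#' Extract expressed regions from mapped reads
#'
#' Maximal runs of positions covered by at least `min_reads` reads become
#' regions. Regions shorter than `min_len` (the approximate length of a
#' pre-miRNA, 70 nt by default) are extended by `min_len` both up- and
#' downstream, clipped at the sequence ends, so the whole precursor is
#' covered. Both cutoffs are parameters.
#'
#' @param reads read `GRanges` (e.g. from [read_sam()]).
#' @param seqlens named integer vector of reference lengths; defaults to
#'   the seqlengths carried by `reads`.
#' @param min_reads minimum coverage defining an expressed position.
#' @param min_len minimum region length; shorter regions are extended.
#' @return a `GRanges` of regions with a logical `extended` column.
#' @export
extract_expressed_regions <- function(reads, seqlens = seqlengths(reads),
                                      min_reads = 1, min_len = 70) {
  if (length(reads) == 0) return(GenomicRanges::GRanges())
  known <- names(seqlens)[!is.na(seqlens)]
  drop <- !(as.character(seqnames(reads)) %in% known)
  if (any(drop)) {
    warning(sum(drop), " read(s) on sequences of unknown length skipped")
    reads <- reads[!drop]
  }
  if (length(reads) == 0) return(GenomicRanges::GRanges())
  cov <- GenomicRanges::coverage(reads)[known]
  core <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_reads,
                                                rangesOnly = TRUE))
  if (length(core) == 0) return(core)
  short <- width(core) < min_len
  ext <- core
  if (any(short)) {
    ext[short] <- ext[short] + min_len       # min_len both up- and downstream
  }
  # extension may poke past the sequence ends; clip right after
  suppressWarnings(seqlengths(ext) <- seqlens[seqlevels(ext)])
  ext <- trim(ext)
  mcols(ext)$extended <- short
  ext
}

#' Infer stem-arm and terminal-loop lengths from a read stack
#'
#' Reads covering the middle coordinate of the putative precursor are
#' discarded (they likely arise from the terminal loop and would mislead
#' the inference). The highest remaining read stack — reads whose start
#' positions agree within one nucleotide — is located. If it sits on the
#' 5' half, the stem-arm length is `l = i + 1` where `i` is the 0-based
#' region-local end of the stack's right-most read; on the 3' half,
#' `l = p - j + 1` with `p` the region length and `j` the 1-based start of
#' the stack's left-most read. The arm is mirrored to the opposite side
#' and the remaining distance `t = p - 2l` is the maximum terminal-loop
#' length, so `2l + t = p` exactly.
#'
#' @param region a single-range `GRanges` (or anything with start/end).
#' @param reads read `GRanges` overlapping the region.
#' @return list of class `arm_loop_estimate`: `l`, `t`, `dominant_arm`
#'   (`"5p"` or `"3p"`).
#' @export
infer_arm_and_loop <- function(region, reads) {
  stopifnot(length(region) == 1)
  p <- width(region)
  hit <- IRanges::overlapsAny(reads, region, ignore.strand = TRUE)
  reads <- reads[hit]
  if (length(reads) == 0) stop("region has no overlapping reads")
  ls <- start(reads) - start(region)          # 0-based local start
  le <- end(reads) - start(region) + 1L       # 0-based local end, exclusive
  mid <- p %/% 2L                              # region-local middle coordinate
  keep <- !(ls <= mid & mid < le)              # read covers mid -> excluded
  if (!any(keep))
    stop("all reads align to the middle coordinate; cannot infer arm length")
  ls <- ls[keep]; le <- le[keep]
  # stacks: reads whose starts agree within +/- 1 nt; height = member count
  starts <- sort(unique(ls))
  height <- vapply(starts, function(s) sum(abs(ls - s) <= 1), integer(1))
  anchor <- starts[which.max(height)]          # ties -> 5'-most stack
  members <- abs(ls - anchor) <= 1
  on5 <- le[members][1] <= mid                 # excluded-mid reads fall on one side
  if (on5) {
    i <- max(le[members]) - 1L                 # right-most read end, 0-based
    l <- i + 1L
    arm <- "5p"
  } else {
    j <- min(ls[members]) + 1L                 # left-most read start, 1-based
    l <- p - j + 1L
    arm <- "3p"
  }
  structure(list(l = as.integer(l), t = as.integer(p - 2L * l),
                 dominant_arm = arm), class = "arm_loop_estimate")
}

#' @export
print.arm_loop_estimate <- function(x, ...) {
  cat(sprintf("arm/loop estimate: l=%d t=%d dominant arm %s\n",
              x$l, x$t, x$dominant_arm))
  invisible(x)
}

#' Turn expressed regions into per-region scan inputs
#'
#' Maps each region's arm/loop estimate onto a scan configuration (arm
#' length `l`, loop range `[n_min, t]`) and extracts the region sequence
#' from the genome. Regions whose estimate cannot host a single window
#' (`2l + n_min` exceeding the region length) or whose maximum loop is
#' below `n_min` are skipped with a warning.
#'
#' @param genome named character vector of reference sequences.
#' @param regions region `GRanges` from [extract_expressed_regions()].
#' @param estimates list of [infer_arm_and_loop()] results, one per region.
#' @param base_config a [scan_config()] providing the remaining options.
#' @return list of `list(seqname, offset, sequence, config)` entries;
#'   `offset` is the 0-based genomic start of the region.
#' @export
regions_to_scan_inputs <- function(genome, regions, estimates,
                                   base_config = scan_config()) {
  stopifnot(length(regions) == length(estimates))
  out <- list()
  for (k in seq_along(regions)) {
    est <- estimates[[k]]
    p <- width(regions)[k]
    if (est$t < base_config$n_min || 2 * est$l + base_config$n_min > p) {
      warning("region ", k, " skipped: estimate (l=", est$l, ", t=", est$t,
              ") cannot host a window")
      next
    }
    cfg <- scan_config(l = est$l, n_min = base_config$n_min, n_max = est$t,
                       energy_threshold = base_config$energy_threshold,
                       dw = min(base_config$dw, est$l),
                       full_matrix = base_config$full_matrix,
                       both_strands = base_config$both_strands)
    sq <- substring(genome[[as.character(seqnames(regions)[k])]],
                    start(regions)[k], end(regions)[k])
    out[[length(out) + 1]] <- list(seqname = as.character(seqnames(regions)[k]),
                                   offset = start(regions)[k] - 1L,
                                   sequence = sq, config = cfg)
  }
  out
}
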