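#' Specification of a synthetic test fixture
#'
#' Describes a random genome with planted stem-loops and fabricated read
#' stacks, the stand-in for real genomes plus sRNA-seq libraries in tests
#' and examples. Each planted hairpin is a random 5' arm (optionally
#' GC-biased), a random terminal loop, and the reverse complement of the
#' arm carrying a configurable number of substitutions (creating
#' mismatches) and single-base insertions (creating bulges). A designated
#' 22-nt mature interval at the start of each 5' arm serves as the control
#' set for evaluation.
#'
#' @param genome_length total genome length in nt.
#' @param base_frequencies named background nucleotide frequencies
#'   (DNA alphabet), summing to 1.
#' @param n_hairpins number of planted stem-loops.
#' @param arm_length,loop_length geometry of the planted hairpins.
#' @param arm_gc GC fraction used when drawing arm sequences.
#' @param substitutions_per_arm substitutions applied to each planted 3'
#'   arm (each breaks one base pair).
#' @param indels_per_arm single-base insertions applied to each planted 3'
#'   arm (each creates a bulge).
#' @param reads_per_arm,read_length,loop_spanning_reads read-stack layout
#'   for the fabricated sRNA-seq library.
#' @param seed RNG seed; a fixed seed makes all outputs identical.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 50000,
                         base_frequencies = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                         n_hairpins = 10, arm_length = 25, loop_length = 8,
                         arm_gc = 0.7, substitutions_per_arm = 0,
                         indels_per_arm = 0, reads_per_arm = 10,
                         read_length = 21, loop_spanning_reads = 0,
                         seed = 1) {
  stopifnot(genome_length >= 1, n_hairpins >= 0, arm_length >= 1,
            loop_length >= 0, arm_gc >= 0, arm_gc <= 1,
            substitutions_per_arm >= 0, indels_per_arm >= 0,
            abs(sum(base_frequencies) - 1) < 1e-9)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic genome, truth set and read library
#'
#' Builds a multinomial random genome, plants the specified stem-loops at
#' non-overlapping positions, records their loci and 22-nt mature control
#' intervals, and fabricates read stacks (one stack per arm, plus optional
#' loop-spanning reads). When `dir` is given, the genome is written as
#' FASTA, the truth intervals as BED-like TSV and the reads as SAM.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return list with `genome` (named character), `hairpins` (truth
#'   `GRanges` of planted loci), `controls` (`GRanges` of mature
#'   intervals, names shared with `hairpins`), `reads` (`GRanges`), and
#'   when `dir` is given the written `files`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  ab <- toupper(names(spec$base_frequencies))
  genome <- .chars(random_genome(spec$base_frequencies, spec$genome_length))
  l <- spec$arm_length; n <- spec$loop_length
  span <- 2L * l + n
  if (spec$n_hairpins * span > spec$genome_length)
    stop("hairpins cannot be placed without overlap: genome too short")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  # non-overlapping placement, uniform random starts with rejection
  starts <- integer(0)
  tries <- 0
  while (length(starts) < spec$n_hairpins) {
    s <- sample.int(spec$genome_length - span + 1L, 1L)
    if (!any(abs(starts - s) < span)) starts <- c(starts, s)
    tries <- tries + 1
    if (tries > 1000 * max(1, spec$n_hairpins))
      stop("hairpins cannot be placed without overlap after many attempts")
  }
  starts <- sort(starts)

  draw_arm <- function() {
    sample(c("G", "C", "A", "T"), l, replace = TRUE,
           prob = c(spec$arm_gc / 2, spec$arm_gc / 2,
                    (1 - spec$arm_gc) / 2, (1 - spec$arm_gc) / 2))
  }
  for (s in starts) {
    arm1 <- draw_arm()
    loop <- sample(ab, n, replace = TRUE, prob = spec$base_frequencies)
    arm2 <- rev(comp[arm1])                       # genomic reverse complement
    if (spec$substitutions_per_arm > 0) {
      at <- sample.int(l, min(spec$substitutions_per_arm, l))
      arm2[at] <- vapply(arm2[at],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         "")
    }
    if (spec$indels_per_arm > 0) {
      for (k in seq_len(spec$indels_per_arm)) {    # insert one base, trim end
        at <- sample.int(l - 1L, 1L)
        arm2 <- c(arm2[seq_len(at)], sample(c("A", "C", "G", "T"), 1),
                  arm2[(at + 1L):l])[seq_len(l)]
      }
    }
    genome[s:(s + span - 1L)] <- c(arm1, loop, arm2)
  }
  genome <- paste(genome, collapse = "")
  gname <- "synthetic_chr"
  gseq <- setNames(genome, gname)

  hairpins <- GenomicRanges::GRanges(gname,
                                     IRanges::IRanges(start = starts, width = span),
                                     strand = "+")
  names(hairpins) <- sprintf("planted_%02d", seq_along(hairpins))
  # mature interval centered in the 5' arm: the arm is the mature length
  # plus an offset, so the designated miRNA sits inside the arm with slack
  mat_w <- min(22L, l)
  controls <- GenomicRanges::GRanges(
    gname,
    IRanges::IRanges(start = starts + (l - mat_w) %/% 2L, width = mat_w),
    strand = "+")
  names(controls) <- names(hairpins)
  seqlengths(hairpins) <- seqlengths(controls) <- setNames(spec$genome_length, gname)

  # read stacks: one per arm anchored at the arm boundary (+/- 1 nt jitter),
  # optional loop-spanning reads covering the hairpin middle
  rl <- spec$read_length
  rs <- integer(0)
  for (s in starts) {
    if (spec$reads_per_arm > 0) {
      rs <- c(rs, s + sample(0:1, spec$reads_per_arm, replace = TRUE))
      a2end <- s + span - 1L
      rs <- c(rs, a2end - rl + 1L - sample(0:1, spec$reads_per_arm, replace = TRUE))
    }
    if (spec$loop_spanning_reads > 0) {
      mid <- s + span %/% 2L
      rs <- c(rs, rep(mid - rl %/% 2L, spec$loop_spanning_reads))
    }
  }
  reads <- GenomicRanges::GRanges(gname,
                                  IRanges::IRanges(start = rs, width = rl),
                                  strand = "+")
  if (length(reads)) names(reads) <- NULL
  seqlengths(reads) <- setNames(spec$genome_length, gname)
  mcols(reads)$qname <- sprintf("read_%05d", seq_along(reads))

  out <- list(genome = gseq, hairpins = hairpins, controls = controls,
              reads = reads, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    bed <- file.path(dir, "truth.bed")
    sam <- file.path(dir, "reads.sam")
    write_fasta(gseq, fa)
    # BED: 0-based half-open, name, score 0, strand
    df <- data.frame(chrom = as.character(seqnames(hairpins)),
                     start = start(hairpins) - 1L, end = end(hairpins),
                     name = names(hairpins), score = 0L,
                     strand = as.character(strand(hairpins)))
    write.table(df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    .write_sam(reads, gseq, sam)
    out$files <- c(genome = fa, truth = bed, reads = sam)
  }
  out
}
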