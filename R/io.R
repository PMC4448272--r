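#' Read and write multi-FASTA files
#'
#' Thin wrappers over Biostrings. Sequences are uppercased on input;
#' the DNA/RNA alphabet is preserved (normalization to RNA happens inside
#' the scanning functions).
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: a named character vector (empty, with a warning,
#'   for an empty file). `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(), character()))
  }
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write candidates to TSV or GFF3
#'
#' TSV columns: `seq_id`, `start`, `end` (1-based, inclusive), `strand`,
#' `l`, `n`, `energy_kcal_mol` (2 decimals), `dot_bracket`,
#' `alignment_string`. GFF3 records use type `pre_miRNA` with the energy
#' as score. Output is ordered by (seq_id, start).
#'
#' @param candidates candidate `GRanges` from [scan_sequence()].
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  o <- order(as.character(seqnames(candidates)), start(candidates))
  cand <- candidates[o]
  if (format == "tsv") {
    df <- data.frame(seq_id = as.character(seqnames(cand)),
                     start = start(cand), end = end(cand),
                     strand = as.character(strand(cand)),
                     l = mcols(cand)$l, n = mcols(cand)$n,
                     energy_kcal_mol = sprintf("%.2f", mcols(cand)$energy),
                     dot_bracket = mcols(cand)$structure,
                     alignment_string = mcols(cand)$ops)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 output needs the rtracklayer package")
    gr <- cand
    mcols(gr) <- NULL
    mcols(gr)$source <- "premirscan"
    mcols(gr)$type <- "pre_miRNA"
    mcols(gr)$score <- round(mcols(cand)$energy, 2)
    mcols(gr)$ID <- sprintf("hairpin_%05d", seq_along(gr))
    mcols(gr)$arm_length <- mcols(cand)$l
    mcols(gr)$loop_length <- mcols(cand)$n
    mcols(gr)$structure <- mcols(cand)$structure
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

# minimal SAM text writer for the fixture generator (header + 11 mandatory
# columns); sequences are echoed from the reference slice
.write_sam <- function(reads, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(seqs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(seqs[[nm]])), con)
  if (length(reads)) {
    o <- order(as.character(seqnames(reads)), start(reads))
    reads <- reads[o]
    sq <- substring(seqs[as.character(seqnames(reads))],
                    start(reads), end(reads))
    sq <- chartr("U", "T", sq)
    flag <- ifelse(as.character(strand(reads)) == "-", 16L, 0L)
    qname <- if (!is.null(mcols(reads)$qname)) mcols(reads)$qname
             else sprintf("read_%05d", seq_along(reads))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       qname, flag, as.character(seqnames(reads)),
                       start(reads), width(reads), sq), con)
  }
  invisible(path)
}
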