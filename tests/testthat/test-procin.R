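# write a small SAM file in code
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           refs = c(ref = 1000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, records), path)
  path
}
samrec <- function(qname, flag, rname, pos, cigar, seq = "*") {
  if (seq == "*" && grepl("^(\\d+)M$", cigar))
    seq <- strrep("A", as.integer(sub("M", "", cigar)))
  sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, cigar, seq)
}

test_that("SAM reading honours flags and CIGAR reference spans", {
  p <- write_test_sam(c(
    samrec("r1", 0L, "ref", 101L, "22M"),
    samrec("r2", 4L, "ref", 1L, "22M"),              # unmapped: skipped
    samrec("r3", 0L, "ref", 301L, "10M2D10M",
           seq = strrep("A", 20)),                    # spans 22 on the reference
    samrec("r4", 256L, "ref", 401L, "22M")))          # secondary: skipped
  reads <- read_sam(p)
  expect_identical(length(reads), 2L)
  expect_identical(GenomicRanges::start(reads), c(101L, 301L))
  expect_identical(GenomicRanges::end(reads), c(122L, 322L))
  expect_identical(GenomicRanges::width(reads)[2], 22L)
  reads2 <- read_sam(p, keep_secondary = TRUE)
  expect_identical(length(reads2), 3L)
  expect_error(read_sam(tempfile()), "no such file")
})

test_that("expressed regions are coverage runs, extended when short", {
  # one 22-nt read at 0-based position 100 on a 1000-nt reference:
  # core [101,122] 1-based, extended by 70 both ways -> [31,192]
  p <- write_test_sam(samrec("r1", 0L, "ref", 101L, "22M"))
  reads <- read_sam(p)
  reg <- extract_expressed_regions(reads)
  expect_identical(length(reg), 1L)
  expect_identical(GenomicRanges::start(reg), 31L)
  expect_identical(GenomicRanges::end(reg), 192L)
  expect_true(mcols(reg)$extended)
  # extension clips at the sequence start
  p2 <- write_test_sam(samrec("r1", 0L, "ref", 10L, "22M"))
  reg2 <- extract_expressed_regions(read_sam(p2))
  expect_identical(GenomicRanges::start(reg2), 1L)
  # distant reads are never merged
  p3 <- write_test_sam(c(samrec("a", 0L, "ref", 101L, "22M"),
                         samrec("b", 0L, "ref", 601L, "22M")))
  expect_identical(length(extract_expressed_regions(read_sam(p3))), 2L)
  # no reads
  expect_length(extract_expressed_regions(GenomicRanges::GRanges()), 0)
  # min_reads cutoff
  reg4 <- extract_expressed_regions(read_sam(p3), min_reads = 2)
  expect_length(reg4, 0)
})

# reads placed at 0-based offsets within a region starting at `region_start`
local_reads <- function(region_start, local_starts, len = 22L) {
  GenomicRanges::GRanges("ref",
    IRanges::IRanges(start = region_start + local_starts, width = len))
}
REGION_START <- 201L

test_that("arm length follows l = i + 1 and l = p - j + 1 exactly", {
  region <- GenomicRanges::GRanges("ref", IRanges::IRanges(201, 320)) # p = 120
  # 3' stack: left-most read starts at region-local 1-based j = 100
  reads3 <- local_reads(REGION_START, c(99L, 99L, 100L), len = 20L)
  est3 <- infer_arm_and_loop(region, reads3)
  expect_identical(est3$l, 21L)                  # 120 - 100 + 1
  expect_identical(est3$dominant_arm, "3p")
  expect_identical(2L * est3$l + est3$t, 120L)   # mirror consistency
  # 5' stack: right-most member ends at region-local 0-based i = 24
  reads5 <- local_reads(REGION_START, c(2L, 3L, 3L), len = 22L) # ends 23,24,24
  est5 <- infer_arm_and_loop(region, reads5)
  expect_identical(est5$l, 25L)                  # i + 1
  expect_identical(est5$dominant_arm, "5p")
  expect_identical(2L * est5$l + est5$t, 120L)
})

test_that("reads over the middle coordinate never affect the estimate", {
  region <- GenomicRanges::GRanges("ref", IRanges::IRanges(201, 320))
  base <- local_reads(REGION_START, c(2L, 3L, 3L), len = 22L)
  with_loop <- c(base, local_reads(REGION_START, c(50L, 55L), len = 22L)) # cover mid=60
  e1 <- infer_arm_and_loop(region, base)
  e2 <- infer_arm_and_loop(region, with_loop)
  expect_identical(e1, e2)
  # symmetric stacks on both arms plus a loop read: still unchanged
  both <- c(local_reads(REGION_START, c(0L, 0L, 0L), 22L),
            local_reads(REGION_START, c(98L, 98L, 98L), 22L))
  e3 <- infer_arm_and_loop(region, both)
  e4 <- infer_arm_and_loop(region, c(both, local_reads(REGION_START, 49L, 22L)))
  expect_identical(e3, e4)
  # ties between equal stacks go to the 5' arm
  expect_identical(e3$dominant_arm, "5p")
  # all reads on the middle: impossible to infer
  expect_error(infer_arm_and_loop(region, local_reads(REGION_START, c(50L, 51L), 22L)),
               "middle coordinate")
})

test_that("estimates map onto per-region scan configurations", {
  genome <- c(ref = strrep("ACGT", 300))
  regions <- GenomicRanges::GRanges("ref", IRanges::IRanges(c(1, 501),
                                                            c(120, 560)))
  est <- list(structure(list(l = 21L, t = 10L, dominant_arm = "5p"),
                        class = "arm_loop_estimate"),
              structure(list(l = 28L, t = 4L, dominant_arm = "3p"),
                        class = "arm_loop_estimate"))
  # second region: 2l + n_min = 61 > 60 -> skipped
  expect_warning(inp <- regions_to_scan_inputs(genome, regions, est,
                                               scan_config()),
                 "skipped")
  expect_length(inp, 1)
  expect_identical(inp[[1]]$config$l, 21L)
  expect_identical(inp[[1]]$config$n_max, 10L)
  expect_identical(inp[[1]]$config$n_min, 5L)
  expect_identical(nchar(inp[[1]]$sequence), 120L)
  # plant-style geometry is expressible
  cfg <- scan_config(l = 48, n_min = 5, n_max = 70,
                     energy_threshold = -42.8)
  expect_identical(cfg$l, 48L)
  expect_identical(cfg$n_max, 70L)
  # empty input
  expect_length(regions_to_scan_inputs(genome, GenomicRanges::GRanges(),
                                       list(), scan_config()), 0)
})

test_that("fixture reads recover the planted arm geometry end to end", {
  fx <- generate_fixture(fixture_spec(genome_length = 4000, n_hairpins = 2,
                                      reads_per_arm = 8, loop_spanning_reads = 2,
                                      seed = 13))
  regs <- extract_expressed_regions(fx$reads, seqlengths(fx$reads))
  expect_gte(length(regs), 2)
  regs <- IRanges::subsetByOverlaps(regs, fx$hairpins)
  for (k in seq_along(regs)) {
    e <- infer_arm_and_loop(regs[k], fx$reads)
    expect_gte(e$l, 15L)
    expect_identical(2L * e$l + e$t, GenomicRanges::width(regs)[k])
  }
})
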