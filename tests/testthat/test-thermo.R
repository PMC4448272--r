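test_that("parameter tables are complete, finite and internally consistent", {
  p <- PARAMS
  expect_false(anyNA(p$stacking))
  expect_false(anyNA(p$terminal_mismatch))
  expect_false(anyNA(p$dangle))
  expect_length(p$internal_init, 30)
  expect_length(p$bulge_init, 30)
  expect_true(all(is.finite(c(p$stacking, p$internal_init, p$bulge_init,
                              p$terminal_mismatch, p$dangle))))
  # initiation non-decreasing from n = 3 on
  expect_true(all(diff(p$internal_init[3:30]) >= 0))
  expect_true(all(diff(p$bulge_init[3:30]) >= 0))
  # duplex-reversal symmetry of stacking
  pairs <- rownames(p$stacking)
  revp <- function(x) paste0(substring(x, 2, 2), substring(x, 1, 1))
  for (a in pairs) for (b in pairs)
    expect_identical(p$stacking[a, b], p$stacking[revp(b), revp(a)])
  # RT derived from the bundled R and T in kcal/mol
  expect_equal(p$RT, RT_KCAL, tolerance = 1e-12)
})

test_that("bundled tables match their frozen checksums", {
  dir <- system.file("extdata", "nn_params", package = "premirscan")
  sums <- tools::md5sum(file.path(dir, c("stacking.tsv", "loop_init.tsv",
                                         "mismatch_internal.tsv",
                                         "dangles.tsv", "scalars.tsv")))
  expect_identical(unname(sums),
                   c("091493996492426268c4fd10efdf3bc2",
                     "edb30c6919f1ea07db91f556e34c875c",
                     "248cdda44b7ee73857a0d61d8921010a",
                     "a65a15007203e4983b3dbd26223c1bbb",
                     "5b4f58dd68d445dc6689095c3fe6c7f7"))
})

test_that("internal loop energy follows initiation + asymmetry + mismatches + RU closures", {
  p <- PARAMS
  # symmetric 2x2 loop: asymmetry contributes nothing
  m22 <- internal_loop_motif(c("A", "A"), c("A", "A"), "GC", "GC")
  m31 <- internal_loop_motif(c("A", "A", "A"), c("A"), "GC", "GC")
  e22 <- internal_loop_energy(p, m22)
  e31 <- internal_loop_energy(p, m31)
  # same n = 4, same closings, same adjacent bases: only asymmetry differs
  expect_equal(e31 - e22, 0.6 * 2, tolerance = 1e-12)
  # explicit decomposition of the symmetric case
  expect_equal(e22,
               p$internal_init[4] +
                 p$terminal_mismatch["GC", "A", "A"] +
                 p$terminal_mismatch["CG", "A", "A"],
               tolerance = 1e-12)
  # RU closures: swapping a GC closure for AU adds 0.7 on top of the
  # mismatch-table difference
  mAU <- internal_loop_motif(c("A", "A"), c("A", "A"), "AU", "GC")
  shift <- p$terminal_mismatch["AU", "A", "A"] - p$terminal_mismatch["GC", "A", "A"]
  expect_equal(internal_loop_energy(p, mAU) - e22 - shift, 0.7,
               tolerance = 1e-12)
  mAUUA <- internal_loop_motif(c("A", "A"), c("A", "A"), "AU", "UA")
  shift2 <- (p$terminal_mismatch["AU", "A", "A"] +
               p$terminal_mismatch["AU", "A", "A"]) -
    (p$terminal_mismatch["GC", "A", "A"] + p$terminal_mismatch["CG", "A", "A"])
  expect_equal(internal_loop_energy(p, mAUUA) - e22 - shift2, 2 * 0.7,
               tolerance = 1e-12)
  # degenerate inputs are rejected
  expect_error(internal_loop_motif(character(), c("A"), "GC", "GC"))
  expect_error(internal_loop_motif(c("X"), c("A"), "GC", "GC"), "unknown")
})

test_that("bulge energy: n>1 is pure initiation; n=1 adds stacking, C-bulge and RT ln t", {
  p <- PARAMS
  m3 <- bulge_motif(c("A", "A", "A"), 1, "GC", "GC")
  expect_identical(bulge_energy(p, m3), p$bulge_init[3])
  # single C bulge next to a paired C: the -0.9 bonus appears
  mc <- bulge_motif("C", 1, "CG", "GC", t_conformations = 1)
  ma <- bulge_motif("A", 1, "CG", "GC", t_conformations = 1)
  expect_equal(bulge_energy(p, mc) - bulge_energy(p, ma), -0.9,
               tolerance = 1e-12)
  # t = 1 contributes nothing; t = 2 subtracts RT ln 2
  m1 <- bulge_motif("A", 1, "GC", "GC", t_conformations = 1)
  m2 <- bulge_motif("A", 1, "GC", "GC", t_conformations = 2)
  expect_equal(bulge_energy(p, m2) - bulge_energy(p, m1), -RT_KCAL * log(2),
               tolerance = 1e-12)
  # n=1 explicit value: init + flanking stack (+ no C bonus, no RU)
  expect_equal(bulge_energy(p, m1),
               p$bulge_init[1] + p$stacking["GC", "GC"], tolerance = 1e-12)
  expect_error(bulge_motif(character(), 1, "GC", "GC"))
  expect_error(bulge_motif("A", 1, "GC", "GC", t_conformations = 0), "t_conf")
})

test_that("loops beyond the tables extrapolate continuously and monotonically", {
  p <- PARAMS
  # continuity at the table boundary
  expect_lt(abs(long_loop_extension(p, "internal", 30 + 1e-9) -
                  p$internal_init[30]), 1e-9)
  expect_lt(abs(long_loop_extension(p, "bulge", 30 + 1e-9) -
                  p$bulge_init[30]), 1e-9)
  # closed form at n = 60, recomputed from first principles
  expect_equal(long_loop_extension(p, "internal", 60),
               p$internal_init[30] + 1.75 * RT_KCAL * log(2),
               tolerance = 1e-12)
  # strictly increasing over (30, 300]
  ns <- 31:300
  expect_true(all(diff(vapply(ns, function(n)
    long_loop_extension(p, "internal", n), numeric(1))) > 0))
  expect_error(long_loop_extension(p, "internal", 30), "n > 30")
})

test_that("helix energy sums the stacking table and charges RU ends", {
  p <- PARAMS
  # independent hand summation straight from the shipped table file
  tab <- read.delim(system.file("extdata", "nn_params", "stacking.tsv",
                                package = "premirscan"))
  lookup <- function(a, b) tab$dG[tab$bp1 == a & tab$bp2 == b]
  pairs <- c("GC", "CG", "GC", "GC", "CG", "GC") # not self-complementary
  byhand <- sum(mapply(lookup, pairs[-6], pairs[-1]))
  expect_equal(helix_energy(p, helix_motif(pairs)), byhand, tolerance = 1e-12)
  # a single pair has no stack; GC ends carry no RU penalty
  expect_identical(helix_energy(p, helix_motif("GC")), 0)
  # each RU (here AU) terminal pair costs exactly +0.45 beyond its stacks
  set.seed(101)
  for (k in 1:20) {
    pr <- sample(rownames(p$stacking), sample(2:8, 1), replace = TRUE)
    stacks <- sum(mapply(lookup, pr[-length(pr)], pr[-1]))
    ru <- 0.45 * sum(c(pr[1], pr[length(pr)]) %in% c("AU", "UA", "GU", "UG"))
    s1 <- substring(pr, 1, 1); s2 <- substring(pr, 2, 2)
    sym <- if (identical(s1, rev(s2))) p$sym_correction else 0
    expect_equal(helix_energy(p, helix_motif(pr)), stacks + ru + sym,
                 tolerance = 1e-12)
  }
  # self-complementary duplex correction triggers
  expect_equal(helix_energy(p, helix_motif(c("GC", "CG"))),
               lookup("GC", "CG") + p$sym_correction, tolerance = 1e-12)
  expect_error(helix_motif(c("GC", "AA")), "non-canonical")
})

test_that("GC-rich helices are more stable than AU helices of the same length", {
  p <- PARAMS
  for (k in 2:10) {
    expect_lt(helix_energy(p, helix_motif(rep("GC", k))) - p$sym_correction,
              helix_energy(p, helix_motif(rep("AU", k))))
  }
})

test_that("dangling ends are pure, complete table lookups", {
  p <- PARAMS
  combos <- expand.grid(pair = rownames(p$stacking),
                        base = c("A", "C", "G", "U"),
                        side = c("5p", "3p"), stringsAsFactors = FALSE)
  vals <- mapply(function(a, b, s) dangling_end_energy(p, a, b, s),
                 combos$pair, combos$base, combos$side)
  expect_length(vals, 6 * 4 * 2)
  expect_true(all(is.finite(vals)))
  # determinism
  expect_identical(dangling_end_energy(p, "GC", "A", "5p"),
                   dangling_end_energy(p, "GC", "A", "5p"))
  expect_error(dangling_end_energy(p, "GC", "X"), "invalid base")
  expect_error(dangling_end_energy(p, "AA", "A"), "non-canonical")
  # removing a dangling base from an alignment changes the total by its value
  v_d <- hairpin_alignment("IMMMM", "GGCC", "UCCGG")
  v_0 <- hairpin_alignment("MMMM", "GGCC", "CCGG")
  d <- suppressWarnings(score_alignment(v_d, p) - score_alignment(v_0, p))
  expect_equal(d, dangling_end_energy(p, "GC", "U", "3p"), tolerance = 1e-12)
})

test_that("motif_energy dispatches by kind and total_energy is additive", {
  p <- PARAMS
  h <- helix_motif(c("GC", "AU", "UA"))
  il <- internal_loop_motif(c("A"), c("C"), "GC", "AU")
  bg <- bulge_motif(c("A", "A"), 2, "GC", "GC")
  expect_identical(motif_energy(p, h), helix_energy(p, h))
  expect_identical(motif_energy(p, il), internal_loop_energy(p, il))
  expect_identical(motif_energy(p, bg), bulge_energy(p, bg))
  motifs <- list(h, il, bg)
  expect_equal(total_energy(p, motifs),
               sum(vapply(motifs, function(m) motif_energy(p, m), numeric(1))),
               tolerance = 1e-12)
  # disjoint-set additivity
  expect_equal(total_energy(p, motifs),
               total_energy(p, motifs[1]) + total_energy(p, motifs[2:3]),
               tolerance = 1e-12)
  expect_warning(e0 <- total_energy(p, list()), "empty")
  expect_identical(e0, 0)
})
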