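---
title: "The stem-arm alignment energy model behind premirscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stem-arm alignment energy model behind premirscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premirscan)
```

## Model and assumptions

`premirscan` treats a pre-miRNA as two stem-arms of equal length `l`
separated by a terminal loop of length `n`, and asks a single question of
every window of the genome: *can these two arms form a stable duplex?*
The duplex free energy is computed with the Nearest-Neighbour (NN) model —
the energy of a structure is the sum of increments of its local motifs,
each parameterized by the identity of adjacent base pairs. Canonical
pairs are AU, GC and the GU wobble.

The assumptions this buys and their costs:

- **Only the stem is scored.** The terminal loop separates the arms but
  contributes no energy, and any multibranch structure inside a long loop
  (common in plant precursors) is invisible. A hairpin with an elaborate
  loop is found only if its stem alone is stable enough.
- **The structure is the alignment.** Pairing is whatever the global
  alignment of the two arms says; pseudoknots and exterior loops cannot
  occur, and alternative foldings of the same window are not enumerated.
- **Alignment search is heuristic, scoring is exact.** The dynamic
  program needs cell-local increments, but several NN terms (loop
  initiation, asymmetry, mismatch context, conformation multiplicity)
  are only defined for a complete motif. We therefore drive the DP with
  locally additive surrogates — consecutive matches credit the pair-step
  stacking, a mismatch step charges half the 2-nt internal-loop
  initiation, a gap step charges the 1-nt bulge initiation — and then
  re-score the returned alignment exactly by motif decomposition. Every
  energy the package reports comes from the exact re-scoring; the DP
  objective is only a search ranking. The residual risk is that the
  surrogate optimum is not the exact-energy optimum; on short arms,
  where exhaustive enumeration is feasible, the tests measure this gap
  rather than assume it away.

## The motif energies

For an internal loop with `n1` and `n2` unpaired bases on the two
strands (`n = n1 + n2`):

`dG = dG_i(n) + 0.6 |n1 - n2| + dG_m1 + dG_m2 + 0.7 * lambda`

where `dG_i` is the tabulated initiation, `dG_m1`/`dG_m2` are the first
and last mismatch increments against their closing pairs, and `lambda`
counts closing pairs in which U faces a purine (RU closures). For a
bulge of one base: initiation plus the stacking of the flanking pairs,
the C-bulge bonus (−0.9 kcal/mol when a C is bulged next to a paired C),
`-RT ln(t)` for the `t` sequence-identical conformations (the run length
of the bulged base across the site), and 0.45 per RU closing pair;
larger bulges cost initiation alone. A helix sums its pair-step stacks,
adds the self-complementary duplex correction where applicable and 0.45
per RU terminal pair. Loops beyond the 30-nt tables extrapolate as
`dG_i(30) + 1.75 RT ln(n/30)` with `RT = 8.3144621 * 310.15 / 4184`
kcal/mol.

Two conventions deserve a note. First, we read the lambda indicator as
*counting the RU closures present* — the standard NN usage; the opposite
reading would never apply the penalty at all. Second, the equations
charge RU both at a helix terminus (0.45) and at the closures of the
adjacent loop (0.7 for internal loops); we apply both as written, so a
stem interrupted by a loop with AU closings pays at each level. This
makes AU-rich stems strictly less attractive than GC-rich ones beyond
what stacking alone implies, which is the intended direction.

A dangling end is a *single* unpaired base stacked on a terminal pair.
We score a terminal unpaired run only when it carries exactly one base
(a lone insertion or deletion); a terminal mismatch leaves two unpaired
bases and is left unscored, as are longer terminal runs. Scoring both
bases of a terminal mismatch as two independent dangles over-rewards
windows shifted off a perfect stem by one position, which distorts locus
selection.

## Parameter provenance

The scalar penalties (asymmetry 0.6, RU closure 0.7, RU end 0.45,
C bulge −0.9, `R`, `T`, the 1.75 long-loop coefficient) are fixed in the
model definition. The lookup tables — stacking, loop initiations,
interior mismatches, dangles — are the published Turner-2004 NN set,
shipped as versioned tab-separated files under `inst/extdata/nn_params/`
and pinned by checksum in the tests. Unit conversion happens once at the
source (tables are stored in kcal/mol). Internal-loop initiation has no
published generic value below `n = 3` (1×1 and 1×2 loops have dedicated
tables in the full model, which this simpler additive model does not
use); we set `dG_i(1) = dG_i(2) = dG_i(3)` so the table is total on
`[1, 30]`. The mismatch table is the interior-loop one — the strong
hairpin/exterior terminal-mismatch values would overstabilize loops in
this context. The self-complementary correction (0.43 kcal/mol) can in
principle trigger when a helix's two strands read identically 5'→3';
within a single hairpin this is rare but costs nothing to handle.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `l` (arm length) | 25 | nt | mean mature miRNA length (22) plus a 3-nt offset covering one standard deviation of mature lengths |
| `n_min`, `n_max` (loop) | 5, 20 | nt | the bulk of the metazoan terminal-loop length distribution; plants need `n_max` up to ~70 |
| `energy_threshold` | −20.6 | kcal/mol | random-genome calibration on metazoan chromosomes; plant scans run far lower (≈ −43) |
| `dw` (band half-width) | 5 | cells | bounds bulge length; 4–5 loses almost nothing against the full matrix while pruning most of it |
| `both_strands` | TRUE | — | hairpins are reported per strand; the reverse complement of a hairpin is again a hairpin |

`full_matrix = TRUE` is the exact-search mode (`dw = l`). The DP explores
at most `(l+1)(2dw+1)` cells in the banded mode against `(l+1)^2` for the
full matrix — the instrumented cell counters in the test suite assert
exactly this scaling.

## Degenerate inputs and numerical choices

- Arms must be pure ACGU after T→U normalization; scan windows whose
  arms contain anything else (assembly gaps, masked bases) are skipped
  and counted, while `N` in the terminal loop is harmless because the
  loop is never scored. Masking with `apply_mask()` exploits this: an
  `N`-run can host no arm.
- Alignments with no canonical pair decompose to no motifs and energy 0,
  which no sensible threshold accepts.
- DP tie-breaks prefer diagonal moves over deletion over insertion, so
  identical inputs give byte-identical alignments.
- Overlap resolution is greedy on ascending energy with ties broken by
  start position then loop length — deterministic, one candidate per
  locus per strand.
- `calibrate_threshold()` works on the continuous candidate energies (no
  binning); it returns the largest random-genome candidate energy below
  which no coordinate-matching hit exists, the configured ceiling when
  there is none, and `-Inf` (with a warning) when even the deepest
  random candidate coincides with a true locus.
- Zero-denominator metrics (no controls, no predictions) are reported as
  `NA`, never as 0.

## The read-stack modules

PROCIN-style inference assumes the highest stack of sRNA-seq reads marks
a processed arm: reads covering the middle coordinate of the putative
precursor are discarded, reads whose start positions agree within ±1 nt
form a stack, and the arm length follows `l = i + 1` (5'-side stack,
right-most read end `i`, 0-based) or `l = p − j + 1` (3'-side stack,
left-most read start `j`, 1-based, region length `p`). The mirrored arm
fixes the maximum loop length `t = p − 2l`, so `2l + t = p` exactly.
Ties between equally high stacks go to the 5' arm. Because the two
printed formulas cannot share one base-index convention, we chose the
conventions that make both yield the distance from the region edge
through the stack's outer boundary — the only reading in which the two
formulas are mirror images, as the mirroring step requires.

The Dicer-signature check partitions reads over a candidate into
mature/loop/star by majority, ties toward an arm; a read's overlap
percentage is the share of its bases outside its primary region. The
filter fails a candidate when the fraction of reads exceeding the
per-read tolerance exceeds the population tolerance; `(0, 0)` is the
strict mode. It is advisory and never applied implicitly — scan output
is identical with the filter ignored. Whether the population tolerance
should count reads per hairpin or globally is not fixed by the model; we
count per hairpin, which keeps verdicts independent across loci.

## What the synthetic data does and does not show

The fixture generator emulates the study conditions the package is
tested under: a 50 kb uniform multinomial genome, ten planted stem-loops
with GC-rich 25-nt arms and 8-nt loops, a designated 22-nt mature
interval centered in each 5' arm, and read stacks anchored at the arm
boundaries with ±1 nt jitter (ten reads of 21 nt per arm, optional
loop-spanning reads). Arm degradation is parameterized as exact counts
per planted 3' arm — substitutions (each breaks one pair) and
single-base insertions (each makes a bulge). With perfect arms every
mature interval must be recovered at default settings; with two
substitutions and one bulge per arm the recovery bound is 80%.

What this does **not** show about real data: real genomes are not
i.i.d. — repeats, inverted repeats and AT-rich stretches produce chance
hairpins with different statistics, so the precision observed on
fixtures (a fraction of a percent, dominated by sub-threshold background
windows) transfers only in order of magnitude. Real read libraries have
length heterogeneity, sequencing errors and multi-mapping ambiguity the
fabricated stacks lack; multi-mapped reads are counted at every reported
alignment, since miRNA families are often multi-copy. Controls derived
from miRNA databases are themselves partly predictions. And the planted
hairpins fold exactly as planted, whereas a real precursor's annotated
structure may differ from its minimum-energy stem.

## Problem sizes in the tests

The checked-in suite uses arm lengths 3–8 against exhaustive in-band
path enumeration (200 pairs, bands 1–3), 1 000 random alignments for
additivity, 100 random window geometries, and two full scans of the
50 kb fixture genome — sizes at which the exhaustive oracles are exact
and the whole suite completes in a few minutes on one CPU. The
acceptance script mirrors these computations end to end from a single
seed.

## Known limitations

- No multibranch, pseudoknot or exterior-loop energetics; one hairpin
  geometry per window.
- The NN model here omits the special 1×1/1×2/2×2 interior-loop tables
  and coaxial stacking; energies are therefore systematically slightly
  higher (less negative) than a full folding model's.
- Temperature is fixed at 310.15 K; no enthalpy/entropy decomposition.
- The screen reports every sub-threshold window unless overlap
  resolution is requested; downstream filtering (expression evidence,
  conservation) is out of scope.
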