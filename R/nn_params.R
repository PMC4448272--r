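#' Load the bundled Nearest-Neighbour thermodynamic parameter set
#'
#' Reads the Turner-2004 style tables shipped with the package (plain
#' tab-separated files under `extdata/nn_params/`) and assembles them into a
#' parameter object used by every energy computation. All energies are in
#' kcal/mol at 37 C (310.15 K).
#'
#' The set contains: base-pair stacking increments indexed by two adjacent
#' canonical pairs; internal-loop and bulge-loop initiation energies for
#' loop sizes 1..30; interior-loop terminal mismatch increments; 5'/3'
#' dangling-end increments; and the scalar penalties printed with the
#' model equations (asymmetry 0.6 kcal/mol per unpaired-nucleotide
#' difference, RU closure 0.7, RU end 0.45, C-bulge -0.9, self-complementary
#' duplex correction) together with the gas constant and temperature.
#'
#' @param dir directory holding the parameter tables; defaults to the copy
#'   installed with the package.
#' @return an object of class `nn_params`: a list with elements `stacking`
#'   (6x6 matrix over pairs AU, UA, GC, CG, GU, UG), `internal_init` and
#'   `bulge_init` (length-30 numeric), `terminal_mismatch` (6x4x4 array:
#'   closing pair, unpaired base on the closing strand, unpaired base on the
#'   partner strand), `dangle` (6x4x2 array, third margin `5p`/`3p`), the
#'   scalars `asym_penalty`, `ru_closure`, `ru_end`, `c_bulge`,
#'   `sym_correction`, `long_loop_coeff`, `R`, `T`, and the derived `RT` in
#'   kcal/mol.
#' @examples
#' p <- nn_params()
#' p$stacking["GC", "CG"]   # strongest stack, about -3.4 kcal/mol
#' p$RT                     # about 0.616 kcal/mol at 310.15 K
#' @export
nn_params <- function(dir = system.file("extdata", "nn_params",
                                        package = "premirscan")) {
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)

  st <- rd("stacking.tsv")
  stacking <- matrix(NA_real_, 6, 6, dimnames = list(.PAIRS, .PAIRS))
  stacking[cbind(st$bp1, st$bp2)] <- st$dG

  li <- rd("loop_init.tsv")
  internal_init <- li$dG[li$kind == "internal"][order(li$n[li$kind == "internal"])]
  bulge_init <- li$dG[li$kind == "bulge"][order(li$n[li$kind == "bulge"])]

  mm <- rd("mismatch_internal.tsv")
  terminal_mismatch <- array(NA_real_, c(6, 4, 4),
                             dimnames = list(.PAIRS, .BASES, .BASES))
  terminal_mismatch[cbind(mm$pair, mm$x, mm$y)] <- mm$dG

  dg <- rd("dangles.tsv")
  dangle <- array(NA_real_, c(6, 4, 2),
                  dimnames = list(.PAIRS, .BASES, c("5p", "3p")))
  dangle[cbind(dg$pair, dg$base, dg$side)] <- dg$dG

  sc <- rd("scalars.tsv")
  s <- setNames(sc$value, sc$name)

  stopifnot(!anyNA(stacking), !anyNA(terminal_mismatch), !anyNA(dangle),
            length(internal_init) == 30, length(bulge_init) == 30,
            !anyNA(internal_init), !anyNA(bulge_init))

  p <- list(
    stacking = stacking,
    internal_init = internal_init,
    bulge_init = bulge_init,
    terminal_mismatch = terminal_mismatch,
    dangle = dangle,
    asym_penalty = unname(s["asym_penalty"]),
    ru_closure = unname(s["ru_closure"]),
    ru_end = unname(s["ru_end"]),
    c_bulge = unname(s["c_bulge"]),
    sym_correction = unname(s["sym_correction"]),
    long_loop_coeff = unname(s["long_loop_coeff"]),
    R = unname(s["gas_constant_J"]),
    T = unname(s["temperature_K"])
  )
  # R*T in J/mol, converted to kcal/mol (1 kcal = 4184 J)
  p$RT <- p$R * p$T / 4184
  class(p) <- "nn_params"
  p
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Nearest-Neighbour parameter set (kcal/mol, T =", x$T, "K)\n")
  cat("  stacking: 6x6 pair steps; range",
      sprintf("[%.2f, %.2f]\n", min(x$stacking), max(x$stacking)))
  cat("  loop initiation: internal/bulge, n = 1..30\n")
  cat(sprintf("  scalars: asym %.2f, RU closure %.2f, RU end %.2f, C bulge %.2f, sym %.2f\n",
              x$asym_penalty, x$ru_closure, x$ru_end, x$c_bulge,
              x$sym_correction))
  invisible(x)
}

#' Loop initiation energy beyond the tabulated range
#'
#' Internal and bulge loops larger than 30 unpaired nucleotides are scored
#' by Jacobson-Stockmayer extrapolation from the last tabulated value:
#' `dG_i(30) + 1.75 * RT * log(n / 30)`.
#'
#' @param params an [nn_params()] object.
#' @param kind `"internal"` or `"bulge"`.
#' @param n loop size in unpaired nucleotides; must exceed 30 (smaller
#'   loops use the tables).
#' @return energy in kcal/mol.
#' @export
long_loop_extension <- function(params, kind = c("internal", "bulge"), n) {
  kind <- match.arg(kind)
  if (n <= 30) stop("long_loop_extension() applies only to n > 30; use the tables")
  base <- if (kind == "internal") params$internal_init[30] else params$bulge_init[30]
  base + params$long_loop_coeff * params$RT * log(n / 30)
}

# table lookup valid for any n >= 1 (dispatches to the extrapolation)
.loop_init <- function(params, kind, n) {
  if (n > 30) long_loop_extension(params, kind, n)
  else if (kind == "internal") params$internal_init[n]
  else params$bulge_init[n]
}

#' Dangling-end energy
#'
#' Free-energy increment of a single unpaired base stacked on a terminal
#' base pair, a pure table lookup in the bundled parameter set.
#'
#' @param params an [nn_params()] object.
#' @param closing_pair two-character canonical pair, e.g. `"GC"`.
#' @param base the dangling base, one of A, C, G, U.
#' @param side `"5p"` or `"3p"`: the side of the closing pair the base
#'   stacks on.
#' @return energy in kcal/mol (stabilizing values are negative or zero).
#' @export
dangling_end_energy <- function(params, closing_pair, base, side = c("5p", "3p")) {
  side <- match.arg(side)
  if (!closing_pair %in% .PAIRS)
    stop("non-canonical closing pair: ", closing_pair)
  if (!base %in% .BASES) stop("invalid base: ", base)
  params$dangle[closing_pair, base, side]
}
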