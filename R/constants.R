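## Physical constants for peptide isotope arithmetic.
##
## Masses and natural abundances are IUPAC/CODATA values rounded to six
## significant figures.  The table is versioned so downstream reports can
## record which constants produced a fit.

ISOTOPE_TABLE_VERSION <- "1.0"

# one row per isotope: element symbol, nominal-mass offset from the lightest
# isotope, exact mass (Da) and natural abundance (mole fraction)
.isotopes <- data.frame(
  element   = c("H", "H",
                "C", "C",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S"),
  offset    = c(0L, 1L,
                0L, 1L,
                0L, 1L,
                0L, 1L, 2L,
                0L, 1L, 2L, 4L),
  mass      = c(1.007825, 2.014102,
                12.000000, 13.003355,
                14.003074, 15.000109,
                15.994915, 16.999132, 17.999160,
                31.972071, 32.971459, 33.967867, 35.967081),
  abundance = c(0.999885, 0.000115,
                0.989300, 0.010700,
                0.996360, 0.003640,
                0.997570, 0.000380, 0.002050,
                0.949900, 0.007500, 0.042500, 0.000100),
  stringsAsFactors = FALSE
)

#' Isotope constants used by the package
#'
#' Exact masses and natural abundances of the stable isotopes of H, C, N, O
#' and S, the only elements occurring in unmodified or
#' carbamidomethylated/oxidised peptides.  All isotope arithmetic in the
#' package (monoisotopic masses, natural and enriched isotopomer patterns)
#' draws on this one table.
#'
#' @return A `data.frame` with columns `element`, `offset` (nominal-mass
#'   offset from the lightest isotope, Da), `mass` (Da) and `abundance`
#'   (natural mole fraction).  The table version is attached as attribute
#'   `"version"`.
#' @examples
#' isotope_table()
#' @export
isotope_table <- function() {
  tab <- .isotopes
  attr(tab, "version") <- ISOTOPE_TABLE_VERSION
  tab
}

# mass of a proton (Da); [M+H]+ = M + PROTON_MASS
PROTON_MASS <- 1.00728

# average 13C/15N peak spacing at unit resolution (Da); the m/z step between
# successive isotopomer bins of a singly charged peptide
BIN_SPACING <- 1.00335

# natural 15N abundance, used as the reference point for enrichment shifts
N15_NATURAL <- 0.003640

## residue elemental formulas (residue = amino acid - H2O), standard 20 codes
.residue_formulas <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

## modification composition deltas
# carbamidomethylation of Cys (iodoacetamide adduct): +C2H3NO
.mod_carbamidomethyl <- c(C = 2, H = 3, N = 1, O = 1, S = 0)
# oxidation of Met: +O
.mod_oxidation <- c(C = 0, H = 0, N = 0, O = 1, S = 0)

# H2O added once per peptide (free N and C termini)
.water <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
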