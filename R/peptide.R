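## Peptide sequences, modifications and elemental composition.

VALID_RESIDUES <- names(.residue_formulas)

check_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop_invalid("peptide sequence must be a non-empty character scalar")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), VALID_RESIDUES)
  if (length(bad))
    stop_invalid("unknown residue code(s): %s (B/Z/X/U are rejected, not approximated)",
                 paste(bad, collapse = ", "))
  res
}

#' Construct a peptide with modifications
#'
#' Modifications follow the usual database-search conventions for this kind
#' of experiment: carbamidomethylation of cysteine as a fixed modification
#' (on every C when enabled) and oxidation of methionine as a variable
#' modification at stated positions.
#'
#' @param sequence Character scalar over the 20 standard one-letter codes.
#'   Ambiguity/rare codes (B, Z, X, U) are rejected.
#' @param carbamidomethyl Logical; apply +C2H3NO to every cysteine.
#' @param oxidised_met Integer positions of oxidised methionines (+O each).
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("GLGTDEDTLIEILASR")
#' peptide("ACDMK", oxidised_met = 4)
#' @export
peptide <- function(sequence, carbamidomethyl = TRUE,
                    oxidised_met = integer(0)) {
  res <- check_residues(sequence)
  oxidised_met <- as.integer(oxidised_met)
  if (length(oxidised_met)) {
    if (any(oxidised_met < 1L | oxidised_met > length(res)))
      stop_invalid("oxidised_met positions outside the sequence")
    if (any(res[oxidised_met] != "M"))
      stop_invalid("oxidation applies only to methionine residues")
  }
  structure(list(sequence = sequence,
                 residues = res,
                 carbamidomethyl = isTRUE(carbamidomethyl),
                 oxidised_met = sort(unique(oxidised_met))),
            class = "peptide")
}

as_peptide <- function(x, ...) {
  if (inherits(x, "peptide")) x else peptide(x, ...)
}

#' @export
print.peptide <- function(x, ...) {
  mods <- character(0)
  if (x$carbamidomethyl && any(x$residues == "C"))
    mods <- c(mods, "carbamidomethyl(C, fixed)")
  if (length(x$oxidised_met))
    mods <- c(mods, sprintf("oxidation(M%d)", x$oxidised_met))
  cat(sprintf("<peptide> %s (%d residues%s)\n", x$sequence,
              length(x$residues),
              if (length(mods)) paste0("; ", paste(mods, collapse = ", "))
              else ""))
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sum of residue formulas plus one water (free termini) plus modification
#' deltas: +C2H3NO per carbamidomethylated cysteine, +O per oxidised
#' methionine.
#'
#' @param pep A [peptide()] or a plain sequence string.
#' @param ... Passed to [peptide()] when `pep` is a string.
#' @return An [elemental_formula()].
#' @examples
#' composition("G")    # C2H5NO2, glycine
#' composition("C")    # carbamidomethylated by default
#' @export
composition <- function(pep, ...) {
  pep <- as_peptide(pep, ...)
  counts <- Reduce(`+`, .residue_formulas[pep$residues])
  counts <- counts + .water
  if (pep$carbamidomethyl)
    counts <- counts + sum(pep$residues == "C") * .mod_carbamidomethyl
  counts <- counts + length(pep$oxidised_met) * .mod_oxidation
  as_formula(counts)
}

## composition of the peptide's residues only (no water, no modifications):
## the metabolically labeled part of the molecule
residue_composition <- function(pep) {
  pep <- as_peptide(pep)
  as_formula(Reduce(`+`, .residue_formulas[pep$residues]) +
               c(C = 0, H = 0, N = 0, O = 0, S = 0))
}

## non-residue atoms: terminus water plus modification deltas, which come
## from reagents, not from the labeled amino-acid pool
extra_composition <- function(pep) {
  pep <- as_peptide(pep)
  counts <- .water
  if (pep$carbamidomethyl)
    counts <- counts + sum(pep$residues == "C") * .mod_carbamidomethyl
  counts <- counts + length(pep$oxidised_met) * .mod_oxidation
  as_formula(counts)
}
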