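## In-silico tryptic digestion.

#' Tryptic digest of a protein sequence
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and returns every peptide with up to `max_missed_cleavages`
#' internal missed cleavage sites, in N-to-C order.
#'
#' @param sequence Protein sequence (string or [peptide()]).
#' @param max_missed_cleavages Non-negative integer (database-search default
#'   for this workflow: 1).
#' @param carbamidomethyl Logical, forwarded to the returned [peptide()]
#'   objects (fixed cysteine modification).
#' @return List of [peptide()] objects.
#' @examples
#' vapply(digest("MKR", 0), function(p) p$sequence, "")    # "MK", "R"
#' vapply(digest("AKPR", 0), function(p) p$sequence, "")   # "AKPR"
#' @export
digest <- function(sequence, max_missed_cleavages = 1L,
                   carbamidomethyl = TRUE) {
  if (inherits(sequence, "peptide")) sequence <- sequence$sequence
  res <- check_residues(sequence)
  if (max_missed_cleavages < 0 ||
      max_missed_cleavages != round(max_missed_cleavages))
    stop_invalid("max_missed_cleavages must be a non-negative integer")
  n <- length(res)
  # cleavage sites: after K/R unless followed by P
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  sites <- sites[res[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  out <- list()
  starts <- integer(0)
  lens <- integer(0)
  for (mc in 0:max_missed_cleavages) {
    m <- length(bounds) - 1L - mc
    if (m < 1L) next
    for (i in seq_len(m)) {
      pep <- paste(res[(bounds[i] + 1L):bounds[i + 1L + mc]], collapse = "")
      out[[length(out) + 1L]] <- peptide(pep,
                                         carbamidomethyl = carbamidomethyl)
      starts <- c(starts, bounds[i] + 1L)
      lens <- c(lens, nchar(pep))
    }
  }
  # N->C order; at equal start, fewer missed cleavages first
  out[order(starts, lens)]
}

#' Find digest peptides near a target m/z
#'
#' Exposes every tryptic peptide of a protein whose protonated monoisotopic
#' mass lies within a tolerance of an observed precursor m/z.  More than one
#' candidate can fall inside a wide MALDI precursor window; all are
#' returned so the caller can disambiguate (e.g. from MS/MS evidence).
#'
#' @param sequence Protein sequence.
#' @param target_mz Observed precursor m/z.
#' @param tolerance Da, default 1.2 (typical MALDI precursor tolerance).
#' @param max_missed_cleavages Passed to [digest()].
#' @param charge Assumed charge state (default 1, MALDI).
#' @param ... Passed to [digest()].
#' @return A `data.frame` with columns `sequence`, `mz`, `delta` sorted by
#'   absolute mass error.
#' @export
peptides_near_mass <- function(sequence, target_mz, tolerance = 1.2,
                               max_missed_cleavages = 1L, charge = 1L, ...) {
  if (tolerance <= 0) stop_invalid("tolerance must be positive")
  peps <- digest(sequence, max_missed_cleavages, ...)
  seqs <- vapply(peps, function(p) p$sequence, "")
  keep <- !duplicated(seqs)
  peps <- peps[keep]; seqs <- seqs[keep]
  mz <- vapply(peps, function(p)
    protonated_mz(monoisotopic_mass(composition(p)), charge), numeric(1))
  hit <- abs(mz - target_mz) <= tolerance
  out <- data.frame(sequence = seqs[hit], mz = mz[hit],
                    delta = mz[hit] - target_mz,
                    stringsAsFactors = FALSE)
  out[order(abs(out$delta)), , drop = FALSE]
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a single- or multi-record amino-acid FASTA file.
#' @return A named character vector of sequences; names are the full FASTA
#'   description lines.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("FASTA file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}
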