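## Turnover model: an observed peptide spectrum is a two-population mixture
## of pre-existing (natural-abundance) and newly synthesized (partially
## 15N-labeled) protein.  The fraction of new synthesis f is the normalized
## weight of the new-population component in a nonnegative least-squares
## fit of the observed isotopomer envelope.

#' Partial metabolic labeling design
#'
#' Describes the labeled amino-acid supply: `pool_fraction` (q) is the
#' probability that an amino acid drawn during synthesis comes from the
#' labeled pool, and `atom_enrichment` (p) is the 15N fraction within a
#' labeled amino acid.  The defaults, q = 0.5 and p = 0.98, describe growth
#' media containing 50% of a 98%-enriched 15N algal amino-acid mixture.
#'
#' @param pool_fraction Probability in \[0, 1\].
#' @param atom_enrichment Probability in \[0, 1\].
#' @return An object of class `"labeling_design"`.
#' @export
labeling_design <- function(pool_fraction = 0.5, atom_enrichment = 0.98) {
  for (v in c(pool_fraction, atom_enrichment))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_invalid("labeling design parameters must be probabilities in [0, 1]")
  structure(list(pool_fraction = pool_fraction,
                 atom_enrichment = atom_enrichment),
            class = "labeling_design")
}

#' @export
print.labeling_design <- function(x, ...) {
  cat(sprintf("<labeling_design> pool fraction q = %.3f, 15N atom enrichment p = %.3f\n",
              x$pool_fraction, x$atom_enrichment))
  invisible(x)
}

#' Isotopomer pattern of newly synthesized peptide
#'
#' A peptide made entirely during the labeling window incorporates each
#' amino acid intact from the free pool: independently per residue, with
#' probability q the residue is labeled (its nitrogens at enrichment p) and
#' with probability 1 - q it is unlabeled (natural abundance).  The peptide
#' pattern is the convolution over residues of these two-component residue
#' mixtures, convolved with the natural pattern of the non-residue atoms
#' (terminal water and modification groups, which come from reagents, not
#' the labeled pool).
#'
#' @param pep A [peptide()] or sequence string.
#' @param design A [labeling_design()].
#' @param n_bins Number of bins; default `N count + 6` of the full peptide.
#' @return An `isotope_pattern` anchored at the peptide's (all-light)
#'   monoisotopic mass.
#' @examples
#' new_protein_pattern("GG", labeling_design(0.5, 0.98))
#' @export
new_protein_pattern <- function(pep, design = labeling_design(),
                                n_bins = NULL) {
  pep <- as_peptide(pep)
  stopifnot(inherits(design, "labeling_design"))
  full <- composition(pep)
  if (is.null(n_bins)) n_bins <- as.integer(full[["N"]] + 6L)
  if (n_bins < 1) stop_invalid("n_bins must be a positive integer")
  q <- design$pool_fraction
  p <- design$atom_enrichment
  acc <- 1
  for (res in pep$residues) {
    f_res <- as_formula(.residue_formulas[[res]] +
                          c(C = 0, H = 0, N = 0, O = 0, S = 0))
    nat <- formula_pattern(f_res, n_bins, n15 = NULL)$abundances
    lab <- formula_pattern(f_res, n_bins, n15 = p)$abundances
    acc <- conv_trunc(acc, (1 - q) * nat + q * lab, n_bins)
  }
  extra <- extra_composition(pep)
  if (any(unclass(extra) > 0))
    acc <- conv_trunc(acc, formula_pattern(extra, n_bins)$abundances, n_bins)
  if (length(acc) < n_bins) acc <- c(acc, numeric(n_bins - length(acc)))
  new_isotope_pattern(monoisotopic_mass(full), acc / sum(acc))
}

#' Mix old and new isotopomer patterns
#'
#' Bin-wise convex combination `(1 - f) * old + f * new`, renormalised.
#' Both patterns must share the monoisotopic anchor (same peptide); lengths
#' are padded to the longer grid.
#'
#' @param f Mixing proportion (fraction of new synthesis) in \[0, 1\].
#' @param old,new `isotope_pattern` objects on the same anchor.
#' @return An `isotope_pattern`.
#' @export
mixture_pattern <- function(f, old, new) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop_invalid("f must be a proportion in [0, 1]")
  stopifnot(inherits(old, "isotope_pattern"), inherits(new, "isotope_pattern"))
  if (abs(old$monoisotopic_mass - new$monoisotopic_mass) > 1e-6)
    stop_invalid("patterns do not share a monoisotopic anchor (mismatched grids)")
  n <- max(length(old$abundances), length(new$abundances))
  a <- c(old$abundances, numeric(n - length(old$abundances)))
  b <- c(new$abundances, numeric(n - length(new$abundances)))
  mix <- (1 - f) * a + f * b
  new_isotope_pattern(old$monoisotopic_mass, mix / sum(mix))
}

#' Align an observed peak list to a theoretical bin grid
#'
#' The theoretical grid starts at `anchor_mz` (the m/z of the monoisotopic
#' peak) and steps by 1.00335/charge Da.  Every observed peak within
#' `tolerance` of a grid point is assigned to its nearest bin; intensities
#' landing in one bin are summed; bins with no peak get 0.
#'
#' @param peaks Two-column matrix/data.frame (m/z, intensity) or a peak-list
#'   file path readable by [read_peaklist()].
#' @param anchor_mz m/z of bin 0.
#' @param n_bins Number of bins.
#' @param tolerance Match window in Da (default 0.5).
#' @param charge Charge state (default 1).
#' @return Numeric intensity vector of length `n_bins`.
#' @export
align_observation <- function(peaks, anchor_mz, n_bins, tolerance = 0.5,
                              charge = 1L) {
  if (tolerance <= 0) stop_invalid("tolerance must be positive")
  if (is.character(peaks)) peaks <- read_peaklist(peaks)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) < 2L) stop_invalid("peaks must have (m/z, intensity) columns")
  peaks <- peaks[, 1:2, drop = FALSE]
  if (nrow(peaks) < 1L) stop_invalid("empty peak list")
  if (any(peaks[, 2] < 0)) stop_invalid("negative peak intensity")
  grid <- anchor_mz + (seq_len(n_bins) - 1L) * BIN_SPACING / charge
  out <- numeric(n_bins)
  for (i in seq_len(nrow(peaks))) {
    j <- which.min(abs(grid - peaks[i, 1]))
    if (abs(grid[j] - peaks[i, 1]) <= tolerance)
      out[j] <- out[j] + peaks[i, 2]
  }
  if (all(out == 0))
    stop(errorCondition("no observed peak within tolerance of any theoretical bin",
                        class = c("dynaprot_alignment_error", "error")))
  out
}

## exact nonnegative least squares for a small design matrix: best subset
## of active (positive) coefficients by enumeration, cross-checked against
## pracma::lsqnonneg which handles the general case
nnls_fit <- function(X, y) {
  fit <- pracma::lsqnonneg(X, y)
  list(coef = fit$x, resid = y - X %*% fit$x)
}

#' Fit the fraction of new synthesis to a binned spectrum
#'
#' Solves `obs ~ a * old + b * new` by least squares under `a, b >= 0` and
#' reports `f = b / (a + b)`, the fraction of the peptide population
#' synthesized during the labeling window.  The estimate is exactly
#' invariant to rescaling the observed intensities.
#'
#' @param obs Nonnegative intensity vector on the patterns' bin grid.
#' @param old `isotope_pattern` of pre-existing (natural) material.
#' @param new `isotope_pattern` of newly synthesized material (see
#'   [new_protein_pattern()]).
#' @param intercept Add a constant-offset regressor (off by default;
#'   inputs are assumed centroided and baseline-subtracted).
#' @return An object of class `"turnover_fit"`; see [fit_turnover()] for
#'   the available methods.
#' @examples
#' old <- natural_pattern(composition("GLGTDEDTLIEILASR"))
#' new <- new_protein_pattern("GLGTDEDTLIEILASR")
#' obs <- mixture_pattern(0.4, old, new)$abundances * 1e4
#' coef(fit_fraction_new(obs, old, new))
#' @export
fit_fraction_new <- function(obs, old, new, intercept = FALSE) {
  stopifnot(inherits(old, "isotope_pattern"), inherits(new, "isotope_pattern"))
  n <- length(obs)
  if (length(old$abundances) != n || length(new$abundances) != n)
    stop_invalid("observation and patterns must share one bin grid")
  if (any(obs < 0) || sum(obs) <= 0)
    stop_invalid("observed intensities must be nonnegative with positive total")
  X <- cbind(old = old$abundances, new = new$abundances)
  if (intercept) X <- cbind(X, offset = rep(1, n))
  # solve on the unit-sum observation so the estimate of f is exactly
  # invariant to rescaling the observed intensities
  total <- sum(obs)
  fit <- nnls_fit(X, obs / total)
  a <- fit$coef[1]
  b <- fit$coef[2]
  if (a + b <= 0)
    stop_degenerate("degenerate fit: both mixture coefficients are zero")
  f <- b / (a + b)
  structure(list(
    fraction_new = as.numeric(f),
    coefficients = c(a_old = as.numeric(a * total),
                     b_new = as.numeric(b * total)),
    offset = if (intercept) as.numeric(fit$coef[3] * total) else NULL,
    residual_norm = sqrt(sum(fit$resid^2)) / sqrt(sum((obs / total)^2)),
    n_bins_used = n,
    observed = as.numeric(obs),
    fitted_values = as.numeric(X %*% fit$coef) * total,
    old = old, new = new,
    design = NULL, peptide = NULL, anchor_mz = NULL
  ), class = "turnover_fit")
}
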