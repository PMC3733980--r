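## Unit-mass isotopomer patterns.
##
## A pattern is the aggregated (nominal-mass) isotopomer distribution of a
## molecule: relative abundance per +1 Da bin, anchored at the monoisotopic
## peak.  Patterns are computed by convolving per-element distributions;
## each element's n-atom distribution is a convolution power of its
## single-atom isotope distribution, evaluated by binary exponentiation.

new_isotope_pattern <- function(mono_mass, abundances) {
  structure(list(monoisotopic_mass = mono_mass,
                 abundances = abundances),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, digits = 4, ...) {
  cat(sprintf("<isotope_pattern> monoisotopic mass %.4f Da, %d bins\n",
              x$monoisotopic_mass, length(x$abundances)))
  print(round(x$abundances, digits))
  invisible(x)
}

#' @export
as.data.frame.isotope_pattern <- function(x, ..., charge = 1L) {
  k <- seq_along(x$abundances) - 1L
  data.frame(bin = k,
             mz = protonated_mz(x$monoisotopic_mass, charge) +
               k * BIN_SPACING / charge,
             abundance = x$abundances)
}

## convolution of two bin vectors, truncated to n_bins
conv_trunc <- function(a, b, n_bins) {
  n <- min(n_bins, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

## p convolved with itself n times (n-atom distribution), truncated
conv_pow <- function(p, n, n_bins) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- conv_trunc(result, base, n_bins)
    n <- n %/% 2
    if (n > 0) base <- conv_trunc(base, base, n_bins)
  }
  if (length(result) < n_bins) result <- c(result, numeric(n_bins - length(result)))
  result
}

## single-atom nominal-offset distribution for an element, optionally with
## nitrogen overridden to a two-point (14N/15N) distribution at `n15`
element_dist <- function(element, n15 = NULL) {
  if (element == "N" && !is.null(n15)) {
    d <- numeric(2)
    d[1] <- 1 - n15
    d[2] <- n15
    return(d)
  }
  rows <- .isotopes[.isotopes$element == element, ]
  d <- numeric(max(rows$offset) + 1L)
  d[rows$offset + 1L] <- rows$abundance
  d
}

## shared worker: convolve all elements of a formula
formula_pattern <- function(formula, n_bins, n15 = NULL) {
  formula <- as_formula(formula)
  if (is.null(n_bins)) n_bins <- as.integer(formula[["N"]] + 6L)
  if (n_bins < 1 || n_bins != round(n_bins))
    stop_invalid("n_bins must be a positive integer")
  acc <- 1
  for (el in ELEMENTS) {
    cnt <- formula[[el]]
    if (cnt == 0) next
    acc <- conv_trunc(acc, conv_pow(element_dist(el, n15), cnt, n_bins),
                      n_bins)
  }
  if (length(acc) < n_bins) acc <- c(acc, numeric(n_bins - length(acc)))
  s <- sum(acc)
  if (s <= 0) stop_degenerate("isotope pattern has zero total abundance")
  new_isotope_pattern(monoisotopic_mass(formula), acc / s)
}

#' Natural-abundance isotopomer pattern
#'
#' Aggregated unit-mass isotopomer distribution of a molecule with every
#' element at natural isotopic abundance, obtained by convolving per-element
#' isotope distributions.  Bin 0 is the monoisotopic (all-light) peak; the
#' vector is truncated to `n_bins` and renormalised to sum 1.
#'
#' @param formula An [elemental_formula()] (or named count vector).
#' @param n_bins Number of +1 Da bins; default `N count + 6`, wide enough to
#'   hold the full 15N envelope plus the natural heavy-isotope tail.
#' @return An `isotope_pattern`.
#' @examples
#' natural_pattern(elemental_formula(C = 1), n_bins = 2)  # 12C/13C
#' @export
natural_pattern <- function(formula, n_bins = NULL) {
  formula_pattern(formula, n_bins, n15 = NULL)
}

#' Isotopomer pattern under 15N enrichment
#'
#' Same convolution as [natural_pattern()] except that every nitrogen atom
#' is 15N with probability `n15_fraction` (binomial across the molecule's
#' nitrogens); all other elements stay at natural abundance.  This is the
#' pattern of material built entirely from amino acids of a given atom
#' enrichment, e.g. the 98%-enriched algal mixture used in partial-labeling
#' experiments.
#'
#' @inheritParams natural_pattern
#' @param n15_fraction Probability that a nitrogen atom is 15N, in \[0, 1\].
#' @return An `isotope_pattern`.  The monoisotopic anchor remains the
#'   all-light mass so enriched and natural patterns share a bin grid.
#' @examples
#' enriched_pattern(elemental_formula(N = 1), 0.98, n_bins = 2)
#' @export
enriched_pattern <- function(formula, n15_fraction, n_bins = NULL) {
  if (!is.numeric(n15_fraction) || length(n15_fraction) != 1L ||
      is.na(n15_fraction) || n15_fraction < 0 || n15_fraction > 1)
    stop_invalid("n15_fraction must be a probability in [0, 1]")
  formula_pattern(formula, n_bins, n15 = n15_fraction)
}

## mean nominal-mass offset of a pattern (bins weighted by abundance)
pattern_mean_offset <- function(pattern) {
  sum((seq_along(pattern$abundances) - 1) * pattern$abundances)
}
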