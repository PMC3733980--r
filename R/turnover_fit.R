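## User-facing fitting interface and turnover_fit methods.

#' Estimate the fraction of new synthesis from an observed spectrum
#'
#' The main fitting entry point.  Given a centroided peak list and the
#' peptide it belongs to, computes the theoretical isotopomer patterns of
#' pre-existing (natural-abundance) and newly synthesized (partially
#' 15N-labeled) material, aligns the observation to the unit-mass bin grid,
#' and fits the two-component nonnegative mixture.  The reported
#' `fraction_new` is the "% new synthesis" of the protein over the labeling
#' window.
#'
#' @param spectrum Two-column (m/z, intensity) matrix/data.frame, or path to
#'   a peak-list file (see [read_peaklist()]).
#' @param pep The peptide generating the envelope ([peptide()] or string).
#' @param design A [labeling_design()]; default q = 0.5, p = 0.98.
#' @param n_bins Bin-grid length; default `N count + 6`.
#' @param charge Assumed charge state (default 1, MALDI).
#' @param tolerance Peak-to-bin match window in Da (default 0.5).
#' @param intercept Add a constant-offset regressor (default `FALSE`).
#' @param estimate_q If `TRUE`, profile the pool fraction q over `q_grid`
#'   and keep the value minimising the residual norm (off by default: q is
#'   normally known from the medium composition).
#' @param q_grid Grid searched when `estimate_q = TRUE`.
#' @return An object of class `"turnover_fit"` with methods `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot` and
#'   `simulate`.
#' @examples
#' design <- labeling_design(0.5, 0.98)
#' sp <- simulate_spectrum("GLGTDEDTLIEILASR", f_true = 0.55,
#'                         design = design, noise_cv = 0, seed = 1)
#' fit <- fit_turnover(sp, "GLGTDEDTLIEILASR", design)
#' coef(fit)
#' @export
fit_turnover <- function(spectrum, pep, design = labeling_design(),
                         n_bins = NULL, charge = 1L, tolerance = 0.5,
                         intercept = FALSE, estimate_q = FALSE,
                         q_grid = seq(0, 1, by = 0.01)) {
  pep <- as_peptide(pep)
  full <- composition(pep)
  if (is.null(n_bins)) n_bins <- as.integer(full[["N"]] + 6L)
  anchor_mz <- protonated_mz(monoisotopic_mass(full), charge)
  obs <- align_observation(spectrum, anchor_mz, n_bins,
                           tolerance = tolerance, charge = charge)
  old <- natural_pattern(full, n_bins)
  fit_for_q <- function(q) {
    des <- labeling_design(q, design$atom_enrichment)
    new <- new_protein_pattern(pep, des, n_bins)
    fit <- fit_fraction_new(obs, old, new, intercept = intercept)
    fit$design <- des
    fit
  }
  if (estimate_q) {
    fits <- lapply(q_grid, fit_for_q)
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "residual_norm"))]]
  } else {
    fit <- fit_for_q(design$pool_fraction)
  }
  fit$peptide <- pep
  fit$anchor_mz <- anchor_mz
  fit
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("Fraction of new synthesis (two-component isotopomer mixture)\n")
  if (!is.null(x$peptide)) cat("  peptide:", x$peptide$sequence, "\n")
  cat(sprintf("  f = %.4f  (a_old = %.4g, b_new = %.4g)\n",
              x$fraction_new, x$coefficients[["a_old"]],
              x$coefficients[["b_new"]]))
  cat(sprintf("  relative residual norm %.4g over %d bins\n",
              x$residual_norm, x$n_bins_used))
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) {
  c(object$coefficients, fraction_new = object$fraction_new)
}

#' @export
fitted.turnover_fit <- function(object, ...) object$fitted_values

#' @export
residuals.turnover_fit <- function(object, ...) {
  object$observed - object$fitted_values
}

#' Predicted isotopomer pattern from a turnover fit
#'
#' @param object A `turnover_fit`.
#' @param f Mixing fraction; defaults to the fitted `fraction_new`.
#' @param ... Unused.
#' @return An `isotope_pattern` of the `(1 - f) old + f new` mixture.
#' @export
predict.turnover_fit <- function(object, f = NULL, ...) {
  if (is.null(f)) f <- object$fraction_new
  mixture_pattern(f, object$old, object$new)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  structure(list(fit = object,
                 detectable = object$fraction_new >= 0.05,
                 design = object$design),
            class = "summary.turnover_fit")
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$design)) print(x$design)
  cat(sprintf("  new synthesis %s the 0.05 detectability floor\n",
              if (x$detectable) "above" else "below"))
  invisible(x)
}

#' Plot observed and fitted isotopomer envelopes
#'
#' Stick plot of the aligned observed intensities (normalised to unit sum)
#' with the fitted mixture overlaid.
#'
#' @param x A `turnover_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.turnover_fit <- function(x, ...) {
  k <- seq_len(x$n_bins_used) - 1L
  mz <- if (!is.null(x$anchor_mz)) x$anchor_mz + k * BIN_SPACING else k
  obs <- x$observed / sum(x$observed)
  fit <- x$fitted_values / sum(x$observed)
  plot(mz, obs, type = "h", lwd = 3, col = "grey40",
       xlab = if (!is.null(x$anchor_mz)) "m/z" else "bin",
       ylab = "relative abundance", ...)
  points(mz + 0.15, fit, type = "h", lwd = 1.5, col = "red")
  legend("topright", legend = c("observed", "fitted mixture"),
         col = c("grey40", "red"), lwd = c(3, 1.5), bty = "n")
  invisible(x)
}

#' Simulate spectra from a fitted turnover model
#'
#' @param object A `turnover_fit` produced by [fit_turnover()].
#' @param nsim Number of spectra.
#' @param seed Integer seed.
#' @param noise_cv Multiplicative noise CV per bin (default 0.05).
#' @param ... Unused.
#' @return A list of peak-list `data.frame`s.
#' @export
simulate.turnover_fit <- function(object, nsim = 1, seed = 1L,
                                  noise_cv = 0.05, ...) {
  if (is.null(object$peptide))
    stop_invalid("simulate() needs a fit produced by fit_turnover()")
  lapply(seq_len(nsim), function(i)
    simulate_spectrum(object$peptide, object$fraction_new,
                      design = object$design, noise_cv = noise_cv,
                      seed = seed + i - 1L))
}

#' Tabulate and classify turnover fits across conditions
#'
#' Collects fraction-of-new-synthesis values per protein and condition,
#' flags values below the detectability floor as not detected (no
#' resolvable mass shift of the peptide envelope), and, when a control and
#' a treated condition are named, classifies each protein's response as
#' increased or decreased synthesis.
#'
#' @param fits A `data.frame` with columns `protein`, `condition`, `f`, or
#'   a list of `turnover_fit` objects accompanied by `protein`/`condition`
#'   vectors of the same length.
#' @param control,treated Condition labels compared for the classification
#'   (both optional; labels are taken from the input, never hard-coded).
#' @param floor Detectability floor on f (default 0.05, about twice the
#'   recovery error under typical 5% spectral noise).
#' @param protein,condition Companion vectors when `fits` is a list.
#' @return A `data.frame`, one row per protein, with one `f_<condition>`
#'   column per condition, `detected_<condition>` flags, and (when both
#'   labels are given) a `response` column in
#'   `c("increased", "decreased", "unchanged", "not detected")`.
#' @examples
#' tab <- data.frame(protein = c("Annexin A1", "Annexin A1"),
#'                   condition = c("control_48h", "OT_48h"),
#'                   f = c(0.55, 0.37))
#' turnover_timecourse(tab, control = "control_48h", treated = "OT_48h")
#' @export
turnover_timecourse <- function(fits, control = NULL, treated = NULL,
                                floor = 0.05, protein = NULL,
                                condition = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) {
    stopifnot(!is.null(protein), !is.null(condition))
    fits <- data.frame(protein = protein, condition = condition,
                       f = vapply(fits, `[[`, 0, "fraction_new"),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("protein", "condition", "f") %in% names(fits)))
  if (nrow(fits) < 1L) stop_invalid("at least one fit is required")
  conds <- unique(fits$condition)
  prots <- unique(fits$protein)
  out <- data.frame(protein = prots, stringsAsFactors = FALSE)
  for (cc in conds) {
    fv <- fits$f[match(paste(prots, cc),
                       paste(fits$protein, fits$condition))]
    out[[paste0("f_", cc)]] <- fv
    out[[paste0("detected_", cc)]] <- !is.na(fv) & fv >= floor
  }
  if (!is.null(control) && !is.null(treated)) {
    fc <- out[[paste0("f_", control)]]
    ft <- out[[paste0("f_", treated)]]
    resp <- rep(NA_character_, length(prots))
    det_t <- out[[paste0("detected_", treated)]]
    resp[!is.na(ft) & !det_t] <- "not detected"
    ok <- !is.na(fc) & !is.na(ft) & det_t
    resp[ok & ft > fc] <- "increased"
    resp[ok & ft < fc] <- "decreased"
    resp[ok & ft == fc] <- "unchanged"
    out$response <- resp
  }
  out
}

#' Read and write centroided peak lists
#'
#' Peak lists are two-column text files (m/z, intensity), whitespace- or
#' comma-delimited, one spectrum per file.
#'
#' @param path File path.
#' @return `read_peaklist()`: a `data.frame` with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop_invalid("peak list not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- read.table(path, sep = sep, header = FALSE,
                   col.names = c("mz", "intensity"),
                   colClasses = "numeric", comment.char = "#")
  if (is.unsorted(df$mz, strictly = TRUE))
    stop_invalid("peak list m/z values must be strictly increasing")
  df
}

#' @rdname read_peaklist
#' @param peaks Two-column (m/z, intensity) data.
#' @param sep Output delimiter (default one space).
#' @export
write_peaklist <- function(peaks, path, sep = " ") {
  write.table(format(as.data.frame(peaks)[, 1:2], trim = TRUE,
                     scientific = FALSE),
              path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
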