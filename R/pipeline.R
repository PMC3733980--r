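## Pipeline drivers tying the stages into the two experiment designs
## (dose-dependent, time-dependent) plus turnover fitting.  Each driver
## returns a report list and, when `out_dir` is given, writes CSV outputs
## and a machine-readable run manifest.

write_manifest <- function(out_dir, config) {
  config$package_version <- as.character(packageVersion("dynaprot"))
  config$isotope_table_version <- ISOTOPE_TABLE_VERSION
  jsonlite::write_json(config,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_out <- function(out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Run the dose-response experiment
#'
#' Two input modes.  Ratio mode (a single spot table of pre-computed
#' expression ratios, control fixed at 1): every spot is classified by the
#' highest-dose rule.  Raw mode (a list of replicate spot tables of raw
#' intensities): each gel is normalised to its total intensity, spots are
#' filtered by fold change and t test at every treated dose against
#' control, and the selected spots are classified.
#'
#' @param x Spot table path or `data.frame` (ratio mode), or a list of
#'   replicate `data.frame`s (raw mode, see [simulate_spot_tables()]).
#' @param out_dir Optional output directory (`selected_spots.csv`,
#'   `summary.csv`, `manifest.json`).
#' @param fold_threshold,alpha Differential criteria (raw mode).
#' @param control Control condition label; defaults to the first condition
#'   column.
#' @return A report list with elements `spots` (per-spot table including
#'   `dose_class`), `n_suppressed`, `n_induced`.
#' @examples
#' run_dose(load_dose_table())$n_suppressed
#' @export
run_dose <- function(x, out_dir = NULL, fold_threshold = 2, alpha = 0.05,
                     control = NULL) {
  if (is.character(x)) x <- read_spot_table(x, mode = "ratio")
  if (is.data.frame(x)) {
    conds <- attr(x, "conditions")
    if (is.null(conds))
      conds <- setdiff(names(x), c("spot_id", "accession", "protein_name",
                                   "cluster"))
    if (is.null(control)) control <- conds[1]
    doses <- setdiff(conds, control)
    spots <- x[, intersect(c("spot_id", "accession", "protein_name"),
                           names(x)), drop = FALSE]
    spots$dose_class <- apply(as.matrix(x[, doses, drop = FALSE]), 1L,
                              classify_dose_response)
    spots <- cbind(spots, x[, doses, drop = FALSE])
  } else {
    reps <- x
    conds <- attr(reps[[1]], "conditions")
    if (is.null(control)) control <- conds[1]
    doses <- setdiff(conds, control)
    norm <- lapply(reps, function(df) {
      for (cc in conds) df[[cc]] <- normalize_gel(df[[cc]])
      df
    })
    ctrl <- vapply(norm, function(df) df[[control]],
                   numeric(nrow(norm[[1]])))
    sel_any <- rep(FALSE, nrow(norm[[1]]))
    ratios <- matrix(NA_real_, nrow(norm[[1]]), length(doses),
                     dimnames = list(NULL, doses))
    for (dd in doses) {
      trt <- vapply(norm, function(df) df[[dd]],
                    numeric(nrow(norm[[1]])))
      flt <- differential_filter(ctrl, trt, fold_threshold, alpha,
                                 spot_id = reps[[1]]$spot_id)
      sel_any <- sel_any | flt$selected
      ratios[, dd] <- flt$fold_change
    }
    spots <- reps[[1]][, intersect(c("spot_id", "accession",
                                     "protein_name"), names(reps[[1]])),
                       drop = FALSE]
    spots <- cbind(spots, as.data.frame(ratios, check.names = FALSE))
    spots$selected <- sel_any
    spots <- spots[spots$selected, , drop = FALSE]
    if (nrow(spots) == 0L) {
      warning("no spot passed the differential criteria")
      spots$dose_class <- character(0)
    } else {
      spots$dose_class <- apply(as.matrix(spots[, doses, drop = FALSE]),
                                1L, classify_dose_response)
    }
  }
  report <- list(spots = spots,
                 n_suppressed = sum(spots$dose_class == "suppressed"),
                 n_induced = sum(spots$dose_class == "induced"))
  if (!is.null(out_dir)) {
    ensure_out(out_dir)
    write.csv(spots, file.path(out_dir, "selected_spots.csv"),
              row.names = FALSE, na = "")
    write.csv(data.frame(n_suppressed = report$n_suppressed,
                         n_induced = report$n_induced),
              file.path(out_dir, "summary.csv"), row.names = FALSE)
    write_manifest(out_dir, list(experiment = "dose", control = control,
                                 fold_threshold = fold_threshold,
                                 alpha = alpha))
  }
  report
}

#' Run the time-course experiment
#'
#' Shape-classifies every total-protein and phosphoprotein profile,
#' tabulates class percentages, computes total/phospho concordance per
#' spot, and optionally runs repeated K-means on the total profiles.
#'
#' @param x Time-course spot table path or `data.frame` with columns
#'   `total_0h`/`total_24h`/`total_48h` (and optional `phospho_*`).
#' @param out_dir Optional output directory (`assignments.csv`,
#'   `percentages.csv`, `concordance.csv`, `manifest.json`).
#' @param kmeans Also run [kmeans_profiles()] on the total profiles.
#' @param k,restarts,seed K-means settings.
#' @return A report list: `assignments`, `percentages`, `concordance`,
#'   `n_phospho`, and `kmeans` (or `NULL`).
#' @examples
#' run_time(load_time_table())$percentages
#' @export
run_time <- function(x, out_dir = NULL, kmeans = FALSE, k = 9L,
                     restarts = 100L, seed = 1L) {
  if (is.character(x)) x <- read_spot_table(x, mode = "ratio")
  tot_cols <- grep("^total_", names(x), value = TRUE)
  pho_cols <- grep("^phospho_", names(x), value = TRUE)
  if (length(tot_cols) != 3L)
    stop_invalid("time table must carry three total_* ratio columns")
  tot <- as.matrix(x[, tot_cols])
  has_tot <- stats::complete.cases(tot)
  assignments <- x[, intersect(c("spot_id", "accession", "protein_name",
                                 "cluster"), names(x)), drop = FALSE]
  assignments$shape <- NA_character_
  assignments$shape[has_tot] <-
    as.character(shape_classify(tot[has_tot, , drop = FALSE]))
  pct <- cluster_percentages(assignments$shape[has_tot])
  conc <- NULL
  n_phospho <- 0L
  if (length(pho_cols) == 3L) {
    pho <- as.matrix(x[, pho_cols])
    has_pho <- stats::complete.cases(pho)
    n_phospho <- sum(has_pho)
    assignments$phospho_shape <- NA_character_
    assignments$phospho_shape[has_pho] <-
      as.character(shape_classify(pho[has_pho, , drop = FALSE]))
    status <- vapply(seq_len(nrow(x)), function(i)
      concordance(if (has_tot[i]) tot[i, ] else NA,
                  if (has_pho[i]) pho[i, ] else NA), "")
    conc <- cbind(assignments, concordance = status)
    conc <- conc[has_pho, , drop = FALSE]
  }
  km <- if (kmeans)
    kmeans_profiles(tot[has_tot, , drop = FALSE], k = k,
                    restarts = restarts, seed = seed)
  else NULL
  report <- list(assignments = assignments, percentages = pct,
                 concordance = conc, n_phospho = n_phospho, kmeans = km)
  if (!is.null(out_dir)) {
    ensure_out(out_dir)
    out_assign <- assignments
    if (!is.null(km)) {
      out_assign$kmeans_cluster <- NA_integer_
      out_assign$kmeans_cluster[has_tot] <- km$cluster
    }
    write.csv(out_assign, file.path(out_dir, "assignments.csv"),
              row.names = FALSE, na = "")
    write.csv(data.frame(shape = names(pct), percent = as.numeric(pct)),
              file.path(out_dir, "percentages.csv"), row.names = FALSE)
    if (!is.null(conc))
      write.csv(conc, file.path(out_dir, "concordance.csv"),
                row.names = FALSE, na = "")
    write_manifest(out_dir, list(experiment = "time", kmeans = kmeans,
                                 k = k, restarts = restarts, seed = seed))
  }
  report
}

#' Run the turnover experiment
#'
#' Fit mode: `x` is a `data.frame` with columns `protein`, `condition`,
#' `peptide` and either `path` (peak-list files) or a list-column `peaks`;
#' each spectrum is fitted with [fit_turnover()].  Rate mode: `x` already
#' carries per-protein fractions `f` per `condition` (e.g. a published
#' rate table) and only the cross-condition classification is performed.
#' Alignment failures flag the affected row and the run continues.
#'
#' @param x Input `data.frame` (see above).
#' @param control,treated Condition labels compared for the
#'   increased/decreased classification.
#' @param out_dir Optional output directory (`turnover_fits.csv`,
#'   `classification.csv`, `manifest.json`).
#' @param design A [labeling_design()] (fit mode).
#' @param floor Detectability floor on f.
#' @return A report list: `fits` (per-sample table with f, coefficients,
#'   residual norm and flag; fit mode only), `classification` (output of
#'   [turnover_timecourse()]), and per-response counts.
#' @export
run_turnover <- function(x, control = NULL, treated = NULL, out_dir = NULL,
                         design = labeling_design(), floor = 0.05) {
  fits_tab <- NULL
  if (!is.null(x$f)) {
    ftab <- x[, c("protein", "condition", "f")]
  } else {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      spec <- if (!is.null(x$peaks)) x$peaks[[i]] else x$path[i]
      res <- tryCatch(fit_turnover(spec, x$peptide[i], design = design),
                      dynaprot_alignment_error = function(e) e)
      if (inherits(res, "error"))
        data.frame(protein = x$protein[i], condition = x$condition[i],
                   peptide = x$peptide[i], f = NA_real_, a_old = NA_real_,
                   b_new = NA_real_, residual_norm = NA_real_,
                   flag = "alignment_failure", stringsAsFactors = FALSE)
      else
        data.frame(protein = x$protein[i], condition = x$condition[i],
                   peptide = x$peptide[i], f = res$fraction_new,
                   a_old = res$coefficients[["a_old"]],
                   b_new = res$coefficients[["b_new"]],
                   residual_norm = res$residual_norm, flag = "ok",
                   stringsAsFactors = FALSE)
    })
    fits_tab <- do.call(rbind, rows)
    ftab <- fits_tab[fits_tab$flag == "ok", c("protein", "condition", "f")]
  }
  classification <- turnover_timecourse(ftab, control = control,
                                        treated = treated, floor = floor)
  counts <- if (!is.null(classification$response))
    table(factor(classification$response,
                 levels = c("increased", "decreased", "unchanged",
                            "not detected")))
  else NULL
  report <- list(fits = fits_tab, classification = classification,
                 counts = counts)
  if (!is.null(out_dir)) {
    ensure_out(out_dir)
    if (!is.null(fits_tab))
      write.csv(fits_tab, file.path(out_dir, "turnover_fits.csv"),
                row.names = FALSE, na = "")
    write.csv(classification, file.path(out_dir, "classification.csv"),
              row.names = FALSE, na = "")
    write_manifest(out_dir, list(experiment = "turnover",
                                 control = control, treated = treated,
                                 floor = floor,
                                 pool_fraction = design$pool_fraction,
                                 atom_enrichment = design$atom_enrichment))
  }
  report
}
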