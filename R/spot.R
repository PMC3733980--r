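## 2-DE spot-table processing: gel normalization, fold-change/t-test
## differential filtering, dose-response classification, protein accounting.

#' Read a 2-DE spot-quantification table
#'
#' CSV/TSV with a header row: `spot_id`, `accession`, `protein_name`, then
#' one column per condition.  Values are spot intensities (raw mode) or
#' ratios to the control condition (ratio mode, control fixed at 1).  Empty
#' cells (e.g. missing phosphoprotein profiles) are read as `NA`.
#'
#' @param path File path (`.csv` or tab-delimited).
#' @param mode `"ratio"` or `"raw"`; stored as an attribute.
#' @return A `data.frame` with attribute `mode` and attribute `conditions`
#'   (the non-annotation column names).
#' @export
read_spot_table <- function(path, mode = c("ratio", "raw")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_invalid("spot table not found: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  ann <- intersect(c("spot_id", "accession", "protein_name", "cluster"),
                   names(df))
  conds <- setdiff(names(df), ann)
  for (cc in conds) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (any(unlist(df[conds]) < 0, na.rm = TRUE))
    stop_invalid("spot values must be nonnegative")
  attr(df, "mode") <- mode
  attr(df, "conditions") <- conds
  df
}

#' @rdname read_spot_table
#' @param x Spot table `data.frame`.
#' @export
write_spot_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalise one gel to its total spot intensity
#'
#' Each spot intensity is divided by the summed intensity of all spots
#' detected on that gel, so values become fractions of total gel signal and
#' gels of different loading/staining efficiency are comparable.
#'
#' @param intensities Nonnegative intensity vector (one gel).
#' @return Vector of fractions summing to 1.
#' @examples
#' normalize_gel(c(2, 3, 5))
#' @export
normalize_gel <- function(intensities) {
  if (any(is.na(intensities)) || any(intensities < 0))
    stop_invalid("intensities must be nonnegative and non-missing")
  total <- sum(intensities)
  if (total <= 0) stop_degenerate("all-zero gel cannot be normalised")
  intensities / total
}

#' Select differentially expressed spots
#'
#' Per spot, the mean treated/control ratio of normalised intensities and a
#' two-sided two-sample t test across replicates.  A spot is selected when
#' the fold change exceeds the threshold in either direction (ratio above
#' `fold_threshold` or below its reciprocal) and p is below `alpha`.
#'
#' @param control,treated Matrices of normalised intensities, spots in rows
#'   and replicate gels in columns (at least 2 replicates each).
#' @param fold_threshold Fold-change gate (> 1), default 2.
#' @param alpha Significance level, default 0.05.
#' @param var_equal Classical Student's t (default `TRUE`); `FALSE` gives
#'   Welch.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) matches per-spot testing at
#'   alpha.
#' @param spot_id Optional spot identifiers.
#' @return A `data.frame` with `spot_id`, `fold_change`, `p_value`,
#'   `selected`.  Spots with zero variance in both groups and equal means
#'   get `p_value = 1` and are never selected.
#' @export
differential_filter <- function(control, treated, fold_threshold = 2,
                                alpha = 0.05, var_equal = TRUE,
                                p_adjust = "none", spot_id = NULL) {
  control <- as.matrix(control)
  treated <- as.matrix(treated)
  if (nrow(control) != nrow(treated))
    stop_invalid("control and treated must cover the same spots")
  if (ncol(control) < 2L || ncol(treated) < 2L)
    stop_invalid("at least 2 replicates per condition are required")
  if (fold_threshold <= 1) stop_invalid("fold_threshold must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  n <- nrow(control)
  ratio <- rowMeans(treated) / rowMeans(control)
  pval <- vapply(seq_len(n), function(i) {
    x <- treated[i, ]; y <- control[i, ]
    if (sd(x) == 0 && sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y, var.equal = var_equal)$p.value
  }, numeric(1))
  pval <- p.adjust(pval, method = p_adjust)
  sel <- (ratio > fold_threshold | ratio < 1 / fold_threshold) & pval < alpha
  data.frame(spot_id = if (is.null(spot_id)) seq_len(n) else spot_id,
             fold_change = ratio, p_value = pval, selected = sel,
             stringsAsFactors = FALSE)
}

#' Classify a dose-response ratio series
#'
#' A spot already selected as differential across a dose series is called
#' `"induced"` when its expression ratio at the highest dose exceeds the
#' untreated control (ratio 1), and `"suppressed"` otherwise.
#'
#' @param dose_ratios Ordered ratios at increasing doses (control implicitly
#'   1; e.g. 5, 50, 500 uM).
#' @return `"suppressed"` or `"induced"`.
#' @examples
#' classify_dose_response(c(0.27, 0.33, 0.20))  # suppressed
#' classify_dose_response(c(7.51, 11.45, 10.96))  # induced
#' @export
classify_dose_response <- function(dose_ratios) {
  if (length(dose_ratios) < 1L || any(is.na(dose_ratios)))
    stop_invalid("dose_ratios must be non-missing")
  if (dose_ratios[length(dose_ratios)] > 1) "induced" else "suppressed"
}

#' Count distinct proteins across spot tables
#'
#' Rows appearing only in phosphoprotein columns count too; duplicate spots
#' of one protein (common on 2-DE gels, e.g. modification shifts) count
#' once.
#'
#' @param tables A list of spot tables (or one table).
#' @param key `"name"` (default) or `"accession"`.  Name-based matching is
#'   the default because gel tables sometimes carry divergent accessions
#'   for one protein.
#' @return Integer count of distinct proteins.
#' @export
count_unique_proteins <- function(tables, key = c("name", "accession")) {
  key <- match.arg(key)
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) return(0L)
  col <- if (key == "name") "protein_name" else "accession"
  vals <- unlist(lapply(tables, function(t) t[[col]]))
  vals <- trimws(vals[!is.na(vals) & nzchar(trimws(vals))])
  length(unique(vals))
}
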