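## Accessors for the packaged example tables (2-DE spot quantifications of
## oxythiamine-treated MIA PaCa-2 cells and per-protein synthesis rates)
## and the Annexin A1 sequence fixture.

#' Path to a packaged example data file
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
dynaprot_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "dynaprot")))
  path <- system.file("extdata", file, package = "dynaprot")
  if (!nzchar(path)) stop_invalid("no packaged file '%s'", file)
  path
}

#' Packaged example tables
#'
#' `load_dose_table()`: 18 spots with expression ratios at 0/5/50/500 uM
#' oxythiamine (ratio mode, control fixed at 1).
#' `load_time_table()`: 48 spots with total-protein and (where stained)
#' phosphoprotein expression ratios at 0/24/48 h of 50 uM treatment, plus
#' the published shape-cluster letter (`d`/`e`/`f`) for the 46
#' total-protein rows; two rows were observed only in the phosphoprotein
#' stain.
#' `load_turnover_rates()`: per-protein fraction of new synthesis (as
#' fractions of 1) for untreated 48 h labeling and for 12/48 h of
#' treatment; `NA` where no mass shift of the peptide envelope was
#' detectable.
#'
#' @return A `data.frame` (spot tables carry `mode`/`conditions`
#'   attributes, see [read_spot_table()]).
#' @export
load_dose_table <- function() {
  read_spot_table(dynaprot_example("dose_ratio_spots.csv"), mode = "ratio")
}

#' @rdname load_dose_table
#' @export
load_time_table <- function() {
  read_spot_table(dynaprot_example("time_ratio_spots.csv"), mode = "ratio")
}

#' @rdname load_dose_table
#' @export
load_turnover_rates <- function() {
  df <- read.csv(dynaprot_example("synthesis_rates.csv"),
                 stringsAsFactors = FALSE)
  for (cc in setdiff(names(df), "protein_name"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]])) / 100
  df
}

## column helpers for the time table
total_profile_columns <- c("total_0h", "total_24h", "total_48h")
phospho_profile_columns <- c("phospho_0h", "phospho_24h", "phospho_48h")
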