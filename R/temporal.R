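## Temporal expression-shape analysis: log2 transform, deterministic
## three-class shape rule, repeated K-means with correlation distance,
## total/phospho concordance.

SHAPE_LEVELS <- c("cluster1_down", "cluster2_V_up", "cluster3_V_down")

#' Classify the temporal shape of an expression profile
#'
#' Profiles are expression ratios at baseline and two later times, baseline
#' fixed at 1.  The deterministic rule:
#' * `cluster3_V_down` (rise then fall, "downright V") when the first
#'   post-baseline ratio exceeds 1;
#' * otherwise `cluster1_down` (monotone down-regulation) when the final
#'   ratio does not exceed the intermediate one;
#' * otherwise `cluster2_V_up` (dip then recover, "upright V").
#'
#' Ties resolve as written: a flat profile is `cluster1_down`, a profile
#' exactly back at baseline after a dip is `cluster2_V_up`.
#'
#' @param ratios Numeric vector `(r0, r_t1, r_t2)` with `r0 = 1`, or a
#'   matrix/data.frame with one profile per row.
#' @return A factor with levels
#'   `cluster1_down`, `cluster2_V_up`, `cluster3_V_down` (length 1 for a
#'   vector input).
#' @examples
#' shape_classify(c(1, 0.62, 0.45))  # monotone down
#' shape_classify(c(1, 0.37, 1.35))  # upright V
#' shape_classify(c(1, 1.17, 0.26))  # downright V
#' @export
shape_classify <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- as.matrix(ratios)
  if (!is.matrix(ratios)) ratios <- matrix(ratios, nrow = 1L)
  if (ncol(ratios) != 3L)
    stop_invalid("profiles must have three time points (r0, r_t1, r_t2)")
  if (any(is.na(ratios)) || any(ratios <= 0))
    stop_invalid("expression ratios must be positive (log2 transform)")
  lab <- ifelse(ratios[, 2] > 1, "cluster3_V_down",
                ifelse(ratios[, 3] <= ratios[, 2],
                       "cluster1_down", "cluster2_V_up"))
  factor(lab, levels = SHAPE_LEVELS)
}

#' Per-class percentages of shape assignments
#'
#' @param assignments Factor/character vector of shape classes.
#' @return Named numeric vector of percentages (one decimal), one entry per
#'   shape class.
#' @export
cluster_percentages <- function(assignments) {
  if (!length(assignments)) stop_invalid("no assignments given")
  f <- factor(as.character(assignments), levels = SHAPE_LEVELS)
  round(100 * as.numeric(table(f)) / length(f), 1) |>
    setNames(SHAPE_LEVELS)
}

#' Concordance of total-protein and phosphoprotein temporal shapes
#'
#' @param total,phospho Ratio triplets (see [shape_classify()]).  A missing
#'   phospho profile (any `NA`) yields `"absent"` rather than an error.
#' @return `"concordant"`, `"discordant"` or `"absent"`.
#' @examples
#' concordance(c(1, 0.62, 0.45), c(1, 0.13, 0.08))  # concordant
#' concordance(c(1, 2.37, 0.82), c(1, 0.24, 0.07))  # discordant
#' @export
concordance <- function(total, phospho) {
  if (is.null(phospho) || any(is.na(phospho))) return("absent")
  if (is.null(total) || any(is.na(total))) return("absent")
  if (identical(as.character(shape_classify(total)),
                as.character(shape_classify(phospho))))
    "concordant" else "discordant"
}

## log2 profiles standardised row-wise; flat rows map to zero vectors.
## 1 - Pearson(x, y) = ||z(x) - z(y)||^2 / (2 (m - 1)), so K-means on
## z-scored rows is K-means under correlation distance.
standardize_log2 <- function(ratios) {
  lg <- log2(as.matrix(ratios))
  t(apply(lg, 1L, function(r) {
    s <- sd(r)
    if (s == 0) numeric(length(r)) else (r - mean(r)) / s
  }))
}

#' Repeated K-means clustering of temporal profiles
#'
#' Profiles are log2-transformed before clustering and compared by
#' correlation distance (1 - Pearson of the expression profiles).  The
#' implementation standardises each log2 profile and runs
#' [stats::kmeans()] with `restarts` random initialisations, keeping the
#' best solution by total within-cluster distance; results are
#' deterministic given `seed`.
#'
#' @param ratios Matrix/data.frame of expression ratios, one profile per
#'   row (baseline column included).
#' @param k Number of clusters (default 9, the granularity typically used
#'   before collapsing to the three shape classes).
#' @param restarts Random initialisations (default 100).
#' @param seed Integer seed.
#' @return A list of class `"profile_kmeans"`: `cluster` (assignments),
#'   `centers_log2` (cluster mean log2 profiles), `centers_ratio`
#'   (back-transformed), `shape` (each cluster's centroid collapsed through
#'   [shape_classify()]), `tot_withinss`, `k`.
#' @export
kmeans_profiles <- function(ratios, k = 9L, restarts = 100L, seed = 1L) {
  ratios <- as.matrix(ratios)
  if (any(is.na(ratios)) || any(ratios <= 0))
    stop_invalid("expression ratios must be positive")
  if (k < 1 || restarts < 1) stop_invalid("k and restarts must be >= 1")
  if (k > nrow(ratios))
    stop_invalid("k exceeds the number of profiles")
  z <- standardize_log2(ratios)
  lg <- log2(ratios)
  # cluster the distinct standardised profiles (random restarts would pick
  # coincident centers from duplicated rows), then assign every profile to
  # its nearest center
  zu <- unique(z)
  centers <- if (k == 1L || nrow(zu) <= k) {
    zu[seq_len(min(k, nrow(zu))), , drop = FALSE]
  } else {
    with_seed(seed,
              kmeans(zu, centers = k, nstart = restarts,
                     iter.max = 100L)$centers)
  }
  dd <- vapply(seq_len(nrow(centers)), function(j)
    colSums((t(z) - centers[j, ])^2), numeric(nrow(z)))
  dd <- matrix(dd, nrow = nrow(z))
  cluster <- max.col(-dd, ties.method = "first")
  k_eff <- nrow(centers)
  tot_withinss <- sum(dd[cbind(seq_len(nrow(z)), cluster)])
  # drop centers that attracted no profile and renumber compactly
  used <- sort(unique(cluster))
  cluster <- match(cluster, used)
  k <- length(used)
  km <- list(cluster = cluster, tot.withinss = tot_withinss)
  centers_log2 <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(lg[km$cluster == j, , drop = FALSE])))
  centers_ratio <- 2^centers_log2
  # anchor centroids at baseline ratio 1 before collapsing to a shape
  centers_anchored <- centers_ratio / centers_ratio[, 1]
  structure(list(cluster = km$cluster,
                 centers_log2 = centers_log2,
                 centers_ratio = centers_anchored,
                 shape = shape_classify(centers_anchored),
                 tot_withinss = km$tot.withinss,
                 k = k),
            class = "profile_kmeans")
}

#' @export
print.profile_kmeans <- function(x, ...) {
  cat(sprintf("<profile_kmeans> k = %d, %d profiles, total within-cluster SS %.4g\n",
              x$k, length(x$cluster), x$tot_withinss))
  tab <- table(x$cluster)
  for (j in seq_len(x$k))
    cat(sprintf("  cluster %d: n = %d, centroid shape %s\n",
                j, tab[[as.character(j)]], as.character(x$shape[j])))
  invisible(x)
}
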