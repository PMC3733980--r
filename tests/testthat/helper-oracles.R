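# Independent oracles used to validate the fast implementations.

# all compositions of n items into k parts (matrix, one composition per row)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# plain truncated convolution used by the oracles
conv_vec <- function(a, b, n_bins) {
  n <- min(n_bins, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  c(out, numeric(max(0L, n_bins - n)))
}

# brute-force aggregated isotopomer distribution by exhaustive enumeration
# of per-element multinomial isotope assignments (feasible for small
# formulas); nitrogen optionally overridden to a two-point 14N/15N
# distribution at `n15`
enumerate_pattern <- function(formula, n_bins, n15 = NULL) {
  iso <- isotope_table()
  per_element <- list()
  for (el in c("C", "H", "N", "O", "S")) {
    cnt <- formula[[el]]
    if (is.na(cnt) || cnt == 0) next
    if (el == "N" && !is.null(n15)) {
      offs <- c(0L, 1L); probs <- c(1 - n15, n15)
    } else {
      rows <- iso[iso$element == el, ]
      offs <- rows$offset; probs <- rows$abundance
    }
    comps <- compositions(cnt, length(offs))
    shift <- as.vector(comps %*% offs)
    lp <- apply(comps, 1L, function(cc)
      lgamma(cnt + 1) - sum(lgamma(cc + 1)) + sum(cc * log(probs)))
    per_element[[el]] <- data.frame(shift = shift, prob = exp(lp))
  }
  agg <- data.frame(shift = 0L, prob = 1)
  for (tab in per_element) {
    agg <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i)
      data.frame(shift = agg$shift[i] + tab$shift,
                 prob = agg$prob[i] * tab$prob)))
    agg <- stats::aggregate(prob ~ shift, agg, sum)
  }
  out <- numeric(n_bins)
  keep <- agg$shift < n_bins
  out[agg$shift[keep] + 1L] <- agg$prob[keep]
  out / sum(out)
}

# the oracle's own residue formula table (amino acid minus water)
oracle_residues <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0)
)

# labeled-residue-subset enumeration of the newly-synthesized peptide
# pattern: every subset S of residues is labeled with probability
# q^|S| (1-q)^(R-|S|); feasible for R <= 6
enumerate_new_pattern <- function(seq, q, p, n_bins) {
  residues <- strsplit(seq, "")[[1]]
  R <- length(residues)
  acc <- numeric(n_bins)
  for (mask in 0:(2^R - 1L)) {
    labeled <- as.logical(bitwAnd(mask, 2^(seq_len(R) - 1L)))
    w <- q^sum(labeled) * (1 - q)^(R - sum(labeled))
    pat <- 1
    for (i in seq_len(R)) {
      f <- oracle_residues[[residues[i]]]
      part <- if (labeled[i]) enumerate_pattern(f, n_bins, n15 = p)
      else enumerate_pattern(f, n_bins)
      pat <- conv_vec(pat, part, n_bins)
    }
    pat <- conv_vec(pat, enumerate_pattern(c(C = 0, H = 2, N = 0, O = 1,
                                             S = 0), n_bins), n_bins)
    acc <- acc + w * pat
  }
  acc / sum(acc)
}

# exact two-regressor nonnegative least squares by case enumeration
# (interior solution or one of the two boundary solutions)
nnls2_oracle <- function(x1, x2, y) {
  XtX <- matrix(c(sum(x1 * x1), sum(x1 * x2), sum(x1 * x2), sum(x2 * x2)),
                2, 2)
  Xty <- c(sum(x1 * y), sum(x2 * y))
  cands <- list()
  sol <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (!is.null(sol) && all(sol >= 0)) cands <- c(cands, list(sol))
  cands <- c(cands,
             list(c(max(0, Xty[1] / XtX[1, 1]), 0),
                  c(0, max(0, Xty[2] / XtX[2, 2]))))
  rss <- vapply(cands, function(b) sum((y - x1 * b[1] - x2 * b[2])^2),
                numeric(1))
  cands[[which.min(rss)]]
}

# total-protein profile matrix (rows with complete total ratios)
total_profiles <- function(tab = load_time_table()) {
  m <- as.matrix(tab[, c("total_0h", "total_24h", "total_48h")])
  m[stats::complete.cases(m), , drop = FALSE]
}

# run code under a fixed seed without touching the session RNG stream
with_seed_helper <- function(seed, code) dynaprot:::with_seed(seed, code)

# random small elemental formulas for property tests
random_formula <- function() {
  elemental_formula(C = sample(0:4, 1), H = sample(1:6, 1),
                    N = sample(0:3, 1), O = sample(0:3, 1),
                    S = sample(0:1, 1))
}
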