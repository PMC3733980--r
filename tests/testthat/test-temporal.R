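test_that("shape rule reproduces the published example profiles", {
  expect_equal(as.character(shape_classify(c(1.00, 0.62, 0.45))),
               "cluster1_down")
  expect_equal(as.character(shape_classify(c(1.00, 0.37, 1.35))),
               "cluster2_V_up")
  expect_equal(as.character(shape_classify(c(1.00, 1.17, 0.26))),
               "cluster3_V_down")
  # boundary ties resolve toward monotone-down
  expect_equal(as.character(shape_classify(c(1, 1, 1))), "cluster1_down")
  expect_error(shape_classify(c(1, -0.5, 2)),
               class = "dynaprot_invalid_input")
})

test_that("shape rule reproduces every published cluster letter", {
  tab <- load_time_table()
  has_tot <- stats::complete.cases(
    tab[, c("total_0h", "total_24h", "total_48h")])
  got <- shape_classify(tab[has_tot, c("total_0h", "total_24h",
                                       "total_48h")])
  want <- c(d = "cluster1_down", e = "cluster2_V_up",
            f = "cluster3_V_down")[tab$cluster[has_tot]]
  expect_equal(as.character(got), unname(want))
  expect_equal(as.numeric(table(got)), c(17L, 22L, 7L))
})

test_that("class percentages are reported to one decimal and sum to ~100", {
  tab <- load_time_table()
  pct <- cluster_percentages(shape_classify(total_profiles(tab)))
  expect_equal(unname(pct), c(37.0, 47.8, 15.2))
  expect_equal(sum(pct), 100, tolerance = 0.1)
  one <- cluster_percentages("cluster2_V_up")
  expect_equal(unname(one[2]), 100)
  thirds <- cluster_percentages(rep(c("cluster1_down", "cluster2_V_up",
                                      "cluster3_V_down"), 5))
  expect_equal(unname(thirds), rep(33.3, 3))
})

test_that("total/phospho concordance compares shape classes", {
  expect_equal(concordance(c(1, 0.62, 0.45), c(1, 0.13, 0.08)),
               "concordant")
  expect_equal(concordance(c(1, 2.37, 0.82), c(1, 0.24, 0.07)),
               "discordant")
  expect_equal(concordance(c(1, 0.5, 0.3), c(1, 0.5, 0.3)), "concordant")
  expect_equal(concordance(c(1, 0.5, 0.3), c(1, NA, 0.3)), "absent")
})

test_that("k-means on profiles recovers archetype groups and is seeded", {
  arch <- rbind(
    matrix(rep(archetype_profile("down"), 6), ncol = 3, byrow = TRUE),
    matrix(rep(archetype_profile("V_up"), 6), ncol = 3, byrow = TRUE),
    matrix(rep(archetype_profile("V_down"), 6), ncol = 3, byrow = TRUE))
  truth <- rep(1:3, each = 6)
  km <- kmeans_profiles(arch, k = 3, restarts = 10, seed = 1)
  # perfect recovery up to label permutation
  expect_equal(length(unique(km$cluster)), 3L)
  for (g in 1:3)
    expect_equal(length(unique(km$cluster[truth == g])), 1L)
  # deterministic given the seed, and invariant to profile order here
  km2 <- kmeans_profiles(arch, k = 3, restarts = 10, seed = 1)
  expect_identical(km$cluster, km2$cluster)
  perm <- c(7:12, 1:6, 13:18)
  km3 <- kmeans_profiles(arch[perm, ], k = 3, restarts = 10, seed = 1)
  for (g in 1:3)
    expect_equal(length(unique(km3$cluster[truth[perm] == g])), 1L)
  # k = 1 pools everything; centroid is the mean log2 profile
  km1 <- kmeans_profiles(arch, k = 1)
  expect_true(all(km1$cluster == 1L))
  expect_equal(km1$centers_log2[1, ], colMeans(log2(arch)),
               ignore_attr = TRUE)
  expect_error(kmeans_profiles(arch[1:2, ], k = 3),
               class = "dynaprot_invalid_input")
})

test_that("correlation distance ignores constant log-space offsets", {
  base <- rbind(c(1, 0.6, 0.3), c(1, 0.2, 0.7), c(1, 2.4, 0.8),
                c(1, 0.5, 0.25), c(1, 0.25, 0.6), c(1, 2.0, 0.7))
  shifted <- base
  shifted[1, ] <- base[1, ] * 2   # constant multiple = log2 offset
  km_a <- kmeans_profiles(base, k = 3, restarts = 20, seed = 4)
  km_b <- kmeans_profiles(shifted, k = 3, restarts = 20, seed = 4)
  same_partition <- function(cl) outer(cl, cl, "==")
  expect_equal(same_partition(km_a$cluster), same_partition(km_b$cluster))
})

test_that("fine clustering collapses to the same three shape classes", {
  profiles <- total_profiles()
  km <- kmeans_profiles(profiles, k = 9, restarts = 100, seed = 1)
  collapsed <- as.character(km$shape)[km$cluster]
  direct <- as.character(shape_classify(profiles))
  expect_equal(collapsed, direct)
})
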