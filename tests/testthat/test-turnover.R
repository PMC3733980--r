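design_default <- labeling_design(0.5, 0.98)

test_that("labeling design validates probabilities", {
  d <- labeling_design()
  expect_equal(d$pool_fraction, 0.5)
  expect_equal(d$atom_enrichment, 0.98)
  expect_error(labeling_design(-0.1), class = "dynaprot_invalid_input")
  expect_error(labeling_design(0.5, 1.1), class = "dynaprot_invalid_input")
})

test_that("new-protein pattern reduces to natural when the pool is unlabeled", {
  for (s in c("GG", "GAVLK")) {
    f <- composition(s)
    expect_equal(new_protein_pattern(s, labeling_design(0, 0.98))$abundances,
                 natural_pattern(f)$abundances, tolerance = 1e-12)
  }
})

test_that("new-protein pattern matches labeled-subset enumeration", {
  n_bins <- 12L
  for (s in c("GG", "GAVL", "KR")) {
    got <- new_protein_pattern(s, design_default, n_bins)$abundances
    want <- enumerate_new_pattern(s, 0.5, 0.98, n_bins)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # enumeration also pins down an asymmetric pool fraction
  got <- new_protein_pattern("GGK", labeling_design(0.3, 0.9), 10)$abundances
  expect_equal(got, enumerate_new_pattern("GGK", 0.3, 0.9, 10),
               tolerance = 1e-9)
})

test_that("mixture_pattern interpolates bin-wise and guards its grid", {
  old <- natural_pattern(composition("GG"), 6)
  new <- new_protein_pattern("GG", design_default, 6)
  expect_equal(mixture_pattern(0, old, new)$abundances, old$abundances)
  expect_equal(mixture_pattern(1, old, new)$abundances, new$abundances)
  a <- dynaprot:::new_isotope_pattern(10, c(1, 0))
  b <- dynaprot:::new_isotope_pattern(10, c(0, 1))
  expect_equal(mixture_pattern(0.5, a, b)$abundances, c(0.5, 0.5))
  c_off <- dynaprot:::new_isotope_pattern(11, c(0, 1))
  expect_error(mixture_pattern(0.5, a, c_off),
               class = "dynaprot_invalid_input")
  expect_error(mixture_pattern(1.5, a, b), class = "dynaprot_invalid_input")
})

test_that("observed peaks align to the nearest theoretical bin", {
  grid <- 1000 + (0:4) * 1.00335
  # peaks exactly on the grid copy through
  obs <- align_observation(cbind(grid, 1:5), 1000, 5)
  expect_equal(obs, as.numeric(1:5))
  # an offset peak within tolerance lands in the nearest bin
  obs <- align_observation(cbind(grid[2] + 0.4, 7), 1000, 5,
                           tolerance = 0.5)
  expect_equal(obs, c(0, 7, 0, 0, 0))
  # two peaks inside one window are summed
  obs <- align_observation(rbind(c(grid[3] - 0.2, 2), c(grid[3] + 0.2, 3)),
                           1000, 5)
  expect_equal(obs[3], 5)
  # nothing within tolerance is an alignment failure
  expect_error(align_observation(cbind(2000, 1), 1000, 3),
               class = "dynaprot_alignment_error")
})

test_that("pure-component spectra give f = 0 and f = 1 exactly", {
  old <- natural_pattern(composition("GLGTDEDTLIEILASR"))
  new <- new_protein_pattern("GLGTDEDTLIEILASR", design_default)
  expect_equal(fit_fraction_new(old$abundances, old, new)$fraction_new, 0)
  expect_equal(fit_fraction_new(new$abundances, old, new)$fraction_new, 1)
})

test_that("fit recovers a noiseless forward-simulated mixture exactly", {
  old <- natural_pattern(composition("GLGTDEDTLIEILASR"))
  new <- new_protein_pattern("GLGTDEDTLIEILASR", design_default)
  obs <- mixture_pattern(0.40, old, new)$abundances * 5e3
  fit <- fit_fraction_new(obs, old, new)
  expect_equal(fit$fraction_new, 0.40, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-10)
  # invariants of the returned object
  expect_equal(fit$fraction_new,
               fit$coefficients[["b_new"]] /
                 sum(fit$coefficients), tolerance = 1e-12)
  expect_equal(length(residuals(fit)), fit$n_bins_used)
  expect_equal(fitted(fit) + residuals(fit), fit$observed)
})

test_that("the fraction estimate is exactly scale invariant", {
  old <- natural_pattern(composition("GAVLKGAVLK"))
  new <- new_protein_pattern("GAVLKGAVLK", design_default)
  obs <- mixture_pattern(0.3, old, new)$abundances * 1e4 +
    abs(sin(1:length(old$abundances)))  # deterministic perturbation
  f1 <- fit_fraction_new(obs, old, new)$fraction_new
  for (c_scale in c(1e-6, 0.5, 3, 1e6))
    expect_identical(fit_fraction_new(c_scale * obs, old, new)$fraction_new,
                     f1)
})

test_that("nonnegative solver agrees with exhaustive case enumeration", {
  set.seed(11)
  old <- natural_pattern(composition("GGKR"), 10)
  new <- new_protein_pattern("GGKR", design_default, 10)
  for (rep in 1:10) {
    obs <- abs(mixture_pattern(runif(1), old, new)$abundances +
                 rnorm(10, sd = 0.05))
    fit <- fit_fraction_new(obs, old, new)
    want <- nnls2_oracle(old$abundances, new$abundances, obs)
    expect_equal(unname(fit$coefficients), want, tolerance = 1e-8)
  }
})

test_that("fit_turnover recovers simulated fractions from peak lists", {
  f_true <- c(0.05, 0.37, 0.55, 0.9)
  for (f in f_true) {
    sp <- simulate_spectrum("GLGTDEDTLIEILASR", f, design_default,
                            noise_cv = 0, seed = 1)
    fit <- fit_turnover(sp, "GLGTDEDTLIEILASR", design_default)
    expect_equal(fit$fraction_new, f, tolerance = 1e-6)
  }
})

test_that("recovery degrades as the labeled pool fraction vanishes", {
  pepseq <- "GLGTDEDTLIEILASR"
  med_err <- vapply(c(0.5, 0.2, 0.05), function(q) {
    des <- labeling_design(q, 0.98)
    errs <- vapply(1:40, function(i) {
      f <- with_seed_helper(1000 + i, runif(1))
      sp <- simulate_spectrum(pepseq, f, des, noise_cv = 0.05,
                              seed = 2000 + i)
      abs(fit_turnover(sp, pepseq, des)$fraction_new - f)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("profiling the pool fraction recovers the generating q", {
  sp <- simulate_spectrum("GLGTDEDTLIEILASR", 0.5,
                          labeling_design(0.5, 0.98), noise_cv = 0,
                          seed = 1)
  fit <- fit_turnover(sp, "GLGTDEDTLIEILASR", labeling_design(0.9, 0.98),
                      estimate_q = TRUE, q_grid = seq(0.1, 0.9, by = 0.05))
  expect_equal(fit$design$pool_fraction, 0.5, tolerance = 0.051)
})

test_that("timecourse table flags floors and classifies responses", {
  tab <- data.frame(
    protein = rep(c("Annexin A1", "Glyceraldehyde-3-phosphate dehydrogenase",
                    "Stalled protein"), each = 2),
    condition = rep(c("control_48h", "OT_48h"), 3),
    f = c(0.55, 0.37, 0.61, 0.70, 0.60, 0.02))
  out <- turnover_timecourse(tab, control = "control_48h",
                             treated = "OT_48h")
  expect_equal(out$response[out$protein == "Annexin A1"], "decreased")
  expect_equal(out$response[out$protein ==
                              "Glyceraldehyde-3-phosphate dehydrogenase"],
               "increased")
  expect_equal(out$response[out$protein == "Stalled protein"],
               "not detected")
  expect_false(out$detected_OT_48h[out$protein == "Stalled protein"])
})

test_that("peak lists round-trip through the text format", {
  sp <- simulate_spectrum("GGK", 0.4, noise_cv = 0.05, seed = 9)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_peaklist(sp, path)
  back <- read_peaklist(path)
  expect_equal(back$mz, sp$mz, tolerance = 1e-6)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)
})
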