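test_that("elemental composition sums residues, water and modifications", {
  g <- composition("G")
  expect_equal(unclass(g), c(C = 2, H = 5, N = 1, O = 2, S = 0),
               ignore_attr = TRUE)
  gg <- composition("GG")
  expect_equal(unclass(gg), c(C = 4, H = 8, N = 2, O = 3, S = 0),
               ignore_attr = TRUE)
  # carbamidomethylated cysteine: Cys residue + water + C2H3NO
  ccam <- composition("C", carbamidomethyl = TRUE)
  expect_equal(unclass(ccam), c(C = 5, H = 10, N = 2, O = 3, S = 1),
               ignore_attr = TRUE)
  # oxidation adds one oxygen to flagged methionines
  expect_equal(composition("M", oxidised_met = 1)[["O"]],
               composition("M")[["O"]] + 1)
  expect_error(composition("GXZ"), class = "dynaprot_invalid_input")
  expect_error(composition("GU"), class = "dynaprot_invalid_input")
  # backbone nitrogen invariant: N count >= residue count
  for (s in c("GAVL", "PPPP", "KRKR", "G"))
    expect_gte(composition(s)[["N"]], nchar(s))
})

test_that("monoisotopic masses match standard atomic mass sums", {
  expect_equal(monoisotopic_mass(elemental_formula(H = 2, O = 1)),
               18.0106, tolerance = 1e-3 / 18)
  expect_equal(monoisotopic_mass(elemental_formula()), 0)
  expect_equal(monoisotopic_mass(composition("G")), 75.0320,
               tolerance = 1e-3 / 75)
  # protonation adds one proton mass per charge
  expect_equal(protonated_mz(100), 101.00728)
  expect_equal(protonated_mz(100, charge = 2), (100 + 2 * 1.00728) / 2)
})

test_that("natural patterns reproduce published single-atom abundances", {
  c1 <- natural_pattern(elemental_formula(C = 1), 2)
  expect_equal(c1$abundances, c(0.9893, 0.0107), tolerance = 1e-9)
  n1 <- natural_pattern(elemental_formula(N = 1), 2)
  expect_equal(n1$abundances, c(0.99636, 0.00364), tolerance = 1e-9)
  expect_error(natural_pattern(elemental_formula(C = 1), 0),
               class = "dynaprot_invalid_input")
})

test_that("patterns are normalised and match exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:8) {
    f <- random_formula()
    pat <- natural_pattern(f, 8)
    expect_equal(sum(pat$abundances), 1, tolerance = 1e-12)
    expect_true(all(pat$abundances >= 0))
    expect_equal(pat$abundances, enumerate_pattern(f, 8),
                 tolerance = 1e-9)
  }
  # a peptide-sized formula against the same oracle
  f <- composition("GA")
  expect_equal(natural_pattern(f, 10)$abundances,
               enumerate_pattern(f, 10), tolerance = 1e-9)
})

test_that("pattern of a combined formula is the convolution of its parts", {
  set.seed(7)
  for (rep in 1:8) {
    a <- random_formula()
    b <- random_formula()
    n <- 10L
    pa <- natural_pattern(a, n)$abundances
    pb <- natural_pattern(b, n)$abundances
    pab <- natural_pattern(a + b, n)$abundances
    conv <- conv_vec(pa, pb, n)
    expect_equal(pab, conv / sum(conv), tolerance = 1e-9)
  }
})

test_that("15N enrichment follows the per-atom binomial", {
  n1 <- enriched_pattern(elemental_formula(N = 1), 0.98, 2)
  expect_equal(n1$abundances, c(0.02, 0.98), tolerance = 1e-12)
  n3 <- enriched_pattern(elemental_formula(N = 3), 0.98, 4)
  expect_equal(n3$abundances[4], 0.98^3, tolerance = 1e-9)
  expect_error(enriched_pattern(elemental_formula(N = 1), 1.2, 2),
               class = "dynaprot_invalid_input")
  # at the natural 15N abundance enrichment is a no-op
  f <- composition("GAVLK")
  expect_equal(enriched_pattern(f, 0.00364, 12)$abundances,
               natural_pattern(f, 12)$abundances, tolerance = 1e-9)
})

test_that("mean-mass shift under enrichment is N_count * (p - natural)", {
  for (s in c("GG", "GAVL", "KR")) {
    f <- composition(s)
    n_bins <- as.integer(f[["N"]] + 10L)
    for (p in c(0.5, 0.98)) {
      shift <- dynaprot:::pattern_mean_offset(enriched_pattern(f, p, n_bins)) -
        dynaprot:::pattern_mean_offset(natural_pattern(f, n_bins))
      expect_equal(shift, f[["N"]] * (p - 0.00364), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("isotope table is versioned and internally consistent", {
  tab <- isotope_table()
  expect_true(nzchar(attr(tab, "version")))
  sums <- tapply(tab$abundance, tab$element, sum)
  expect_true(all(abs(sums - 1) < 1e-4))
})
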