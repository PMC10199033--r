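# Isotopologue distributions and natural-abundance MDV correction.

test_that("natural distributions match the shipped table for single atoms", {
  ab <- isotope_abundances()
  # single hydrogen: the distribution is the abundance vector itself
  h <- natural_distribution(c(H = 1), ab, k_max = 1)
  expect_equal(as.numeric(h), ab$H, tolerance = 1e-15)
  # single carbon reads the table directly
  c1 <- natural_distribution("C1", ab, k_max = 1)
  expect_equal(as.numeric(c1), c(0.9893, 0.0107), tolerance = 1e-15)
  # two carbons: binomial expansion
  c2 <- natural_distribution("C2", ab, k_max = 2)
  expect_equal(c2[[2]], 2 * 0.9893 * 0.0107 / sum(attr(c2, "mass_captured")),
               tolerance = 1e-12)
  expect_error(natural_distribution(c(Xx = 1)), "missing from abundance")
  expect_error(natural_distribution(c(Se = 1), ab), "missing from abundance")
})

test_that("the convolution agrees with brute-force enumeration for small formulas", {
  ab <- isotope_abundances()
  formulas <- list(
    c(C = 3L, H = 5L), c(C = 2L, O = 2L, N = 1L), c(Si = 2L, C = 2L, H = 4L),
    c(S = 1L, C = 2L, H = 2L, O = 1L, N = 1L), c(C = 8L), c(H = 8L),
    c(O = 3L, Si = 1L, C = 1L), c(N = 4L, O = 2L)
  )
  for (f in formulas) {
    got <- natural_distribution(f, ab, k_max = 4, normalize = FALSE)
    want <- brute_isotopologue(f, ab, k_max = 4)
    expect_lt(max(abs(as.numeric(got) - want)), 1e-12)
  }
})

test_that("element processing order does not change the distribution", {
  ab <- isotope_abundances()
  f <- c(C = 4L, H = 9L, Si = 1L, O = 2L, N = 1L)
  perms <- list(c(5, 1, 3, 2, 4), c(3, 4, 1, 5, 2), 5:1)
  ref <- as.numeric(natural_distribution(f, ab, k_max = 6))
  for (p in perms) {
    expect_equal(as.numeric(natural_distribution(f[p], ab, k_max = 6)), ref,
                 tolerance = 1e-14)
  }
})

test_that("correction-matrix columns are the predicted measured distributions", {
  ab <- isotope_abundances()
  m <- build_correction_matrix("C11H26NO2Si2", 3, ab)
  expect_equal(dim(m), c(8, 4))
  # column 0 is the natural distribution of the full formula
  full <- natural_distribution("C11H26NO2Si2", ab, k_max = 7, normalize = FALSE)
  expect_equal(unname(m[, 1]), as.numeric(full), tolerance = 1e-14)
  # every column captures > 99% probability at the default window
  expect_true(all(colSums(m) > 0.99))
  expect_true(all(colSums(m) <= 1 + 1e-12))
  expect_true(all(m >= 0))
  # fully-labeled column is shifted: no mass below M+n_backbone
  expect_equal(unname(m[1:3, 4]), rep(0, 3))

  # degenerate case: no non-backbone atoms and a single-isotope carbon
  mono <- list(C = 1)
  ident <- build_correction_matrix(c(C = 2), 2, mono, k_max = 2)
  expect_lt(max(abs(unclass(ident) - diag(3))), 1e-15)

  expect_error(build_correction_matrix("C2H4", 3, ab), "exceeds formula carbon")
})

test_that("MDV correction inverts forward folding", {
  ab <- isotope_abundances()
  m <- build_correction_matrix("C11H26NO2Si2", 3, ab)
  # a matrix column corrects to a pure labeling state
  x0 <- correct_mdv(m[, 1], m)
  expect_equal(as.numeric(x0), c(1, 0, 0, 0), tolerance = 1e-10)
  expect_lt(attr(x0, "residual_norm"), 1e-10)

  # identity matrix: corrected equals measured
  meas <- c(0.7, 0.2, 0.1)
  id <- structure(diag(3), n_backbone = 2L)
  expect_equal(as.numeric(correct_mdv(meas, id)), meas, tolerance = 1e-12)

  # round trip over random backbone MDVs, noiseless
  withr::with_seed(2024, {
    worst <- 0
    for (i in 1:100) {
      x <- runif(4); x <- x / sum(x)
      folded <- as.numeric(unclass(m) %*% x)
      back <- correct_mdv(folded, m)
      worst <- max(worst, max(abs(as.numeric(back) - x)))
    }
    expect_lt(worst, 1e-8)
  })

  expect_error(correct_mdv(c(0.5, 0.5), m), "dimension mismatch")
})

test_that("corrected unlabeled biomass is unlabeled", {
  lib <- default_fragment_library()
  sim <- simulate_labeled_mdvs(lib, noise_sd = 0, n_replicates = 1, seed = 1)
  corrected <- correct_mdv_table(sim$mdvs, lib)
  for (fr in unique(corrected$fragment)) {
    x <- corrected$fraction[corrected$fragment == fr]
    expect_lt(max(abs(x - c(1, numeric(length(x) - 1)))), 1e-6)
  }
})

test_that("MDV comparison reports per-mass deviation in mol percent", {
  a <- c(0.9, 0.1); b <- c(0.8, 0.2)
  expect_equal(compare_mdv(a, a)$max_deviation_molpct, 0)
  expect_equal(compare_mdv(a, b)$max_deviation_molpct, 10, tolerance = 1e-12)
  expect_equal(compare_mdv(a, b)$deviation_molpct,
               compare_mdv(b, a)$deviation_molpct)
  expect_error(compare_mdv(a, c(1, 0, 0)), "length mismatch")
})

test_that("labeling CV excludes entries below the abundance floor", {
  lib <- default_fragment_library()[1:2, ]
  sim <- simulate_labeled_mdvs(lib, noise_sd = 0, n_replicates = 3, seed = 9)
  res <- labeling_cv(sim$mdvs, threshold_pct = 20, floor = 0.01)
  expect_true(all(res$cv$cv_pct[res$cv$defined] < 1e-8))
  expect_equal(res$fraction_below, 1)
  # floored-out entries are undefined
  low <- res$cv$mean < 0.01
  expect_true(all(!res$cv$defined[low]))
  expect_true(any(low))
})
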