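# Isotope-dilution quantification, energy charge, plate QC statistics.

test_that("isotope ratios guard against a missing internal standard", {
  expect_equal(isotope_ratio(100, 100), 1.0)
  expect_equal(isotope_ratio(0, 50), 0.0)
  expect_equal(isotope_ratio(c(10, 20), c(20, 20)), c(0.5, 1.0))
  expect_error(isotope_ratio(50, 0), "internal standard")
})

test_that("calibration fit and quantification invert each other exactly", {
  levels <- tibble::tibble(known_conc = c(1, 5, 10, 50, 100),
                           ratio = 0.01 * c(1, 5, 10, 50, 100))
  cal <- fit_calibration(levels)
  expect_equal(cal$slope, 0.01, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r2, 1, tolerance = 1e-12)

  q <- quantify(cal, 0.5)
  expect_equal(q$conc_um, 50, tolerance = 1e-9)
  expect_false(q$extrapolated)
  # quantify o fit recovers the known concentrations exactly
  expect_equal(quantify(cal, levels$ratio)$conc_um, levels$known_conc,
               tolerance = 1e-9)
  # outside the calibrated range flags extrapolation
  expect_true(quantify(cal, 0.005)$extrapolated)
  expect_true(quantify(cal, 2)$extrapolated)
  # at the intercept the concentration is zero (and extrapolated)
  expect_equal(quantify(cal, cal$intercept)$conc_um, 0)

  expect_error(fit_calibration(levels[1:2, ]), "3 levels")
  expect_error(fit_calibration(dplyr::mutate(levels, known_conc = c(1, 5, 5, 50, 100))),
               "strictly increasing")
})

test_that("1/x weighting reduces low-end relative error on heteroscedastic curves", {
  concs <- c(1, 2, 5, 10, 50, 100, 500)
  errs <- withr::with_seed(101, {
    purrr::map_dfr(1:50, function(i) {
      # noise proportional to concentration: constant relative error
      ratio <- 0.01 * concs * (1 + rnorm(length(concs), sd = 0.1))
      levels <- tibble::tibble(known_conc = concs, ratio = ratio)
      w <- fit_calibration(levels, weighting = "1/x")
      u <- fit_calibration(levels, weighting = "none")
      true_low <- 1
      ratio_low <- 0.01 * true_low
      tibble::tibble(
        weighted = abs(quantify(w, ratio_low)$conc_um - true_low) / true_low,
        unweighted = abs(quantify(u, ratio_low)$conc_um - true_low) / true_low
      )
    })
  })
  expect_lt(median(errs$weighted), median(errs$unweighted))
})

test_that("biomass normalization follows the volume-over-biomass arithmetic", {
  b <- biomass_sampled(3.0e-4, 1.0, 2.06)
  expect_equal(normalize_concentration(100, 0.1, b), 16.18123, tolerance = 1e-6)
  expect_equal(normalize_concentration(0, 0.1, b), 0)
  # homogeneity: degree -1 in biomass, +1 in volume
  expect_equal(normalize_concentration(100, 0.1, 2 * b),
               normalize_concentration(100, 0.1, b) / 2, tolerance = 1e-12)
  expect_equal(normalize_concentration(100, 0.2, b),
               2 * normalize_concentration(100, 0.1, b), tolerance = 1e-12)
  expect_error(normalize_concentration(100, 0.1, 0), ">")
})

test_that("energy charge hits its limits and is scale-invariant on [0, 1]", {
  expect_equal(energy_charge(1, 0, 0), 1.0)
  expect_equal(energy_charge(0, 0, 1), 0.0)
  expect_equal(energy_charge(1, 1, 1), 0.5)
  expect_error(energy_charge(0, 0, 0), "zero")

  withr::with_seed(7, {
    for (i in 1:200) {
      pools <- runif(3, 0, 10)
      ec <- energy_charge(pools[1], pools[2], pools[3])
      expect_gte(ec, 0)
      expect_lte(ec, 1)
      c_scale <- runif(1, 0.01, 100)
      expect_equal(energy_charge(c_scale * pools[1], c_scale * pools[2],
                                 c_scale * pools[3]),
                   ec, tolerance = 1e-12)
    }
  })
})

test_that("plate CV reproduces hand-computed values and threshold fractions", {
  # identical replicates: CV 0, all below any threshold
  ident <- matrix(5, nrow = 3, ncol = 4)
  res0 <- plate_cv(ident, 30)
  expect_equal(res0$cv$cv_pct, rep(0, 4))
  expect_equal(res0$fraction_below, 1)

  # feature {1, 3}: sd sqrt(2), mean 2 -> CV 70.71%
  res <- plate_cv(matrix(c(1, 3), nrow = 2), 30)
  expect_equal(res$cv$cv_pct, 70.71068, tolerance = 1e-6)

  # constructed features with CVs 10, 20, 40: fraction below 30% is 2/3
  d <- c(10, 20, 40) / 100 / sqrt(2)
  m <- rbind(1 - d, 1 + d)
  res3 <- plate_cv(m, 30)
  expect_equal(res3$cv$cv_pct, c(10, 20, 40), tolerance = 1e-9)
  expect_equal(res3$fraction_below, 2 / 3)

  # non-positive-mean features are undefined and leave the denominator
  m2 <- cbind(m, c(-1, 1))
  res4 <- plate_cv(m2, 30)
  expect_false(res4$cv$defined[4])
  expect_equal(res4$fraction_below, 2 / 3)

  expect_error(plate_cv(matrix(1, nrow = 1, ncol = 3)), "2 wells")
})

test_that("plate CV recovers injected CV levels within sampling error", {
  sim <- simulate_feature_matrix(n_wells = 50, n_features = 60,
                                 cv_profile = c(0.05, 0.2), seed = 21)
  res <- plate_cv(sim$matrix, 30)
  by_true <- split(res$cv$cv_pct, rep(c(0.05, 0.2), length.out = 60))
  expect_equal(median(by_true[["0.05"]]), 5, tolerance = 0.2 * 5)
  expect_equal(median(by_true[["0.2"]]), 20, tolerance = 0.2 * 20)
})

test_that("proteome coverage is a guarded percentage", {
  expect_equal(proteome_coverage(2000, 4000), 50)
  expect_equal(proteome_coverage(0, 4000), 0)
  expect_equal(proteome_coverage(4000, 4000), 100)
  expect_error(proteome_coverage(4001, 4000), "exceed")
})

test_that("outlier wells are flagged by the robust z rule, with no false positives", {
  sim <- simulate_feature_matrix(n_wells = 21, n_features = 80,
                                 cv_profile = 0.1, n_outliers = 0, seed = 31)
  clean <- flag_outlier_wells(sim$matrix)
  expect_false(any(clean$outlier))

  m <- sim$matrix
  target <- rownames(m)[3]
  m[target, ] <- m[target, ] * 10
  hit <- flag_outlier_wells(m)
  expect_identical(hit$well[hit$outlier], target)

  # two injected outliers: both flagged, nothing else, across 50 seeds
  misses <- 0L; false_pos <- 0L
  for (s in 1:50) {
    sim2 <- simulate_feature_matrix(n_wells = 21, n_features = 80,
                                    cv_profile = 0.1, n_outliers = 2,
                                    outlier_factor = 10, seed = 1000 + s)
    fl <- flag_outlier_wells(sim2$matrix)
    flagged <- sort(fl$well[fl$outlier])
    if (!identical(flagged, sort(sim2$truth$outlier_wells))) {
      misses <- misses + length(setdiff(sim2$truth$outlier_wells, flagged))
      false_pos <- false_pos + length(setdiff(flagged, sim2$truth$outlier_wells))
    }
  }
  expect_equal(misses, 0L)
  expect_equal(false_pos, 0L)

  expect_error(flag_outlier_wells(sim$matrix[1:3, ]), "4 wells")
})
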