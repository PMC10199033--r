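# Growth-curve processing: assembly, corrections, rate estimation.

test_that("series assembly undoes the measurement dilution and flags short series", {
  layout <- layout_tbl(c("A1", "A2"), c("sample", "sample"))
  readings <- readings_tbl(
    c(0, 1, 2), list(A1 = c(0.10, 0.12, 0.15), A2 = c(0.02, 0.03, 0.04))
  )
  s5 <- assemble_well_series(readings, layout, dilution_factor = 5)
  expect_equal(s5$od600_raw[s5$well == "A1"], c(0.50, 0.60, 0.75))
  s1 <- assemble_well_series(readings, layout, dilution_factor = 1)
  expect_equal(s1$od600_raw, readings$value[order(readings$well, readings$time_h)])

  short <- readings[readings$time_h < 2 | readings$well == "A2", ]
  s <- assemble_well_series(short, layout)
  expect_true(all(s$too_few_points[s$well == "A1"]))
  expect_false(any(s$too_few_points[s$well == "A2"]))
})

test_that("volume-loss fit recovers a linear dye trend in closed form", {
  t <- seq(0, 10, 0.5)
  layout <- layout_tbl(c("A1", "H12"), c("sample", "volume_control"))
  readings <- dplyr::bind_rows(
    readings_tbl(t, list(H12 = 0.5 * (1 + 0.02 * t)), channel = "OD450"),
    readings_tbl(t, list(A1 = 0.1 * exp(0.3 * t) / 5))
  )
  vfit <- fit_volume_loss(readings, layout)
  expect_equal(vfit$slope, 0.02, tolerance = 1e-10)
  expect_equal(vfit$r2, 1, tolerance = 1e-10)
  expect_identical(correction_factor(vfit, vfit$t0), 1)
  g <- glance(vfit)
  expect_equal(g$slope, 0.02, tolerance = 1e-10)

  # constant dye: zero slope, unit correction everywhere
  const <- readings_tbl(t, list(H12 = rep(0.5, length(t))), channel = "OD450")
  vfit0 <- fit_volume_loss(dplyr::bind_rows(const, readings[readings$channel == "OD600", ]),
                           layout)
  expect_equal(vfit0$slope, 0, tolerance = 1e-12)
  expect_equal(correction_factor(vfit0, t), rep(1, length(t)), tolerance = 1e-10)

  # missing dye wells is an error
  expect_error(fit_volume_loss(readings, layout_tbl("A1", "sample")),
               "volume_control")
})

test_that("a dye signal doubling over the run halves the corrected endpoint", {
  t <- seq(0, 10, 1)
  layout <- layout_tbl(c("A1", "H12"), c("sample", "volume_control"))
  readings <- dplyr::bind_rows(
    readings_tbl(t, list(H12 = 0.4 * (1 + t / 10)), channel = "OD450"),
    readings_tbl(t, list(A1 = rep(1, length(t)), H12 = rep(0, length(t))))
  )
  vfit <- fit_volume_loss(readings, layout)
  series <- assemble_well_series(readings, layout, dilution_factor = 1) |>
    apply_plate_corrections(vfit)
  a1 <- series[series$well == "A1", ]
  expect_equal(a1$od600_corrected[a1$time_h == 10], 0.5, tolerance = 1e-10)
  expect_equal(a1$od600_corrected[a1$time_h == 0], 1, tolerance = 1e-10)
})

test_that("corrections subtract background then divide by the volume factor", {
  vfit <- structure(list(slope = 0.05, t0 = 0), class = "volume_loss_fit")
  series <- well_series_tbl(10, 1.0)
  bg <- well_series_tbl(10, 0.1, well = "H12", role = "volume_control")
  out <- apply_plate_corrections(series, vfit, background_wells = bg)
  expect_equal(out$od600_corrected, (1.0 - 0.1) / 1.5, tolerance = 1e-12)

  # zero background, unit correction: identity
  out0 <- apply_plate_corrections(series, NULL,
                                  background_wells = well_series_tbl(10, 0, well = "H12"))
  expect_equal(out0$od600_corrected, out0$od600_raw)

  # constant background shifts uniformly
  t <- 0:5
  s <- well_series_tbl(t, rep(0.5, 6))
  b <- well_series_tbl(t, rep(0.05, 6), well = "H12")
  expect_equal(apply_plate_corrections(s, NULL, background_wells = b)$od600_corrected,
               rep(0.45, 6))

  # negative corrected values are masked, not clamped
  neg <- apply_plate_corrections(well_series_tbl(10, 0.05), NULL,
                                 background_wells = well_series_tbl(10, 0.1, well = "H12"))
  expect_true(is.na(neg$od600_corrected))

  # misaligned timepoints beyond tolerance error and name the times
  expect_error(
    apply_plate_corrections(well_series_tbl(10, 1), NULL,
                            background_wells = well_series_tbl(9, 0.1, well = "H12")),
    "misaligned"
  )
})

test_that("specific growth rates are exact on exponentials and scale-invariant", {
  t <- seq(0, 8, 0.5)
  exp_series <- well_series_tbl(t, 0.05 * exp(0.6 * t), corrected = TRUE)
  mu <- specific_growth_rates(exp_series)
  expect_equal(mu$mu, rep(0.6, length(t)), tolerance = 1e-10)

  flat <- well_series_tbl(t, rep(0.3, length(t)), corrected = TRUE)
  expect_equal(specific_growth_rates(flat)$mu, rep(0, length(t)), tolerance = 1e-12)

  # positive scaling of OD leaves mu untouched (log-shift invariance);
  # checked above the detection floor, which is in absolute OD units
  withr::with_seed(11, {
    od <- 0.05 * exp(0.4 * t) * exp(rnorm(length(t), sd = 0.05))
    for (c_scale in c(0.1, 3, 42)) {
      m1 <- specific_growth_rates(well_series_tbl(t, od, corrected = TRUE),
                                  min_od = 0)$mu
      m2 <- specific_growth_rates(well_series_tbl(t, c_scale * od, corrected = TRUE),
                                  min_od = 0)$mu
      expect_equal(m1, m2, tolerance = 1e-12)
    }
  })

  # everything below the detection floor: all-missing with no_growth
  dark <- well_series_tbl(t, rep(0.005, length(t)), corrected = TRUE)
  out <- specific_growth_rates(dark)
  expect_true(all(is.na(out$mu)))
  expect_true(all(out$no_growth))

  expect_error(specific_growth_rates(exp_series, window = 4), "odd")
})

test_that("exponential-phase detection brackets the true exponential segment", {
  # lag (2 h) + exponential (4 h) + plateau (4 h); checked against a brute
  # force over all contiguous windows via the returned slope/r2 contract
  dt <- 0.5  # the platform's 30-minute reading interval
  t <- seq(0, 10, dt)
  od <- ifelse(t < 2, 0.05,
               ifelse(t <= 6, 0.05 * exp(0.6 * (t - 2)), 0.05 * exp(0.6 * 4)))
  series <- well_series_tbl(t, od, corrected = TRUE)
  win <- find_exponential_phase(series)
  expect_false(win$no_growth)
  expect_lte(abs(win$t_start - 2), dt)
  expect_lte(abs(win$t_end - 6), dt)
  expect_equal(win$slope, 0.6, tolerance = 0.10)
  expect_gte(win$r2, 0.95)

  # pure exponential: the window is the whole run
  pure <- well_series_tbl(t, 0.05 * exp(0.5 * t), corrected = TRUE)
  wp <- find_exponential_phase(pure)
  expect_equal(c(wp$t_start, wp$t_end), range(t))
  expect_equal(wp$slope, 0.5, tolerance = 1e-10)

  # flat series: no growth
  flat <- well_series_tbl(t, rep(0.3, length(t)), corrected = TRUE)
  expect_true(find_exponential_phase(flat)$no_growth)
})

test_that("both mu_max estimators recover noiseless curves", {
  t <- seq(0, 10, 0.5)
  # logistic generated at the P. putida plate rate
  od <- 1.5 * 0.05 * exp(0.845 * t) / (1.5 + 0.05 * (exp(0.845 * t) - 1))
  fit_p <- suppressWarnings(fit_growth_curve(t, od, model = "parametric"))
  expect_equal(fit_p$mu_max, 0.845, tolerance = 0.01 * 0.845)
  expect_length(fit_p$flags, 0)

  # exact exponential: both models agree on 0.6 to < 0.5% relative
  od_e <- 0.05 * exp(0.6 * t[t <= 5])
  f_ll <- fit_growth_curve(t[t <= 5], od_e, model = "log_linear")
  f_pp <- suppressWarnings(fit_growth_curve(t[t <= 5], od_e, model = "parametric"))
  expect_equal(f_ll$mu_max, 0.6, tolerance = 1e-8)
  expect_equal(f_pp$mu_max, f_ll$mu_max, tolerance = 0.005 * 0.6)

  # flat series: flagged, not fitted
  f_flat <- fit_growth_curve(t, rep(0.3, length(t)))
  expect_true("no_growth" %in% f_flat$flags)
  expect_true(is.na(f_flat$mu_max))
  expect_true(glance(f_flat)$no_growth)
})

test_that("plate summary aggregates sample wells and flags contamination", {
  mu_table <- tibble::tibble(
    plate_id = "p1", well = c("A1", "A2", "H12"),
    role = c("sample", "sample", "volume_control"),
    organism = "E. coli",
    mu_max = c(0.4, 0.6, NA), mu_max_se = 0.01, snr = 40,
    method = "parametric", t_start = 1, t_end = 5, r2 = 0.99,
    no_growth = FALSE, poor_fit = FALSE
  )
  t <- 0:5
  series <- dplyr::bind_rows(
    well_series_tbl(t, 0.05 * exp(0.5 * t), corrected = TRUE),
    well_series_tbl(t, rep(0.04, 6), well = "E12", role = "contamination_control",
                    corrected = TRUE)
  )
  s <- plate_growth_summary(mu_table, series)
  expect_equal(s$mu_mean, 0.5)
  expect_equal(s$mu_sd, sd(c(0.4, 0.6)))
  expect_equal(s$mu_sd, 0.1414214, tolerance = 1e-6)
  expect_false(s$contaminated)

  # media-only well rising by 0.2 flags the plate and names the well
  grown <- series
  grown$od600_corrected[grown$well == "E12"] <- 0.04 + 0.04 * t
  s2 <- plate_growth_summary(mu_table, grown)
  expect_true(s2$contaminated)
  expect_equal(s2$contaminated_wells[[1]], "E12")
})
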