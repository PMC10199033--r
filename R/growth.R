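# Growth-curve processing: per-well OD600 series assembly, dye-based
# volume-loss correction, background subtraction, rolling specific growth
# rates, exponential-phase detection, and maximum-growth-rate fitting.

#' Assemble per-well OD600 series from readings and layout
#'
#' Joins the OD600 channel with the plate layout and undoes the measurement
#' dilution: cultures are sampled and diluted (default 5-fold) before the
#' absorbance read, so `od600_raw = value * dilution_factor` restores the
#' culture-scale OD. Wells with fewer than 3 timepoints are kept but flagged.
#'
#' @param readings Validated readings tibble (see [read_plate_readings()]).
#' @param layout Validated layout tibble (see [read_plate_layout()]).
#' @param dilution_factor Fold dilution applied before the OD read (default 5).
#' @return Long tibble: `plate_id`, `well`, `role`, `organism`,
#'   `conversion_factor`, `time_h`, `od600_raw`, `n_points`, `too_few_points`.
#' @export
assemble_well_series <- function(readings, layout, dilution_factor = 5) {
  check_number(dilution_factor, "dilution_factor", lower = 0, strict = TRUE)
  readings <- validate_plate_readings(readings)
  layout <- validate_plate_layout(layout)
  series <- readings |>
    dplyr::filter(.data$channel == "OD600") |>
    dplyr::inner_join(
      layout[c("plate_id", "well", "role", "organism", "conversion_factor")],
      by = c("plate_id", "well")
    ) |>
    dplyr::mutate(od600_raw = .data$value * dilution_factor) |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::mutate(n_points = dplyr::n(), too_few_points = .data$n_points < 3) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$plate_id, .data$well, .data$time_h)
  series[c("plate_id", "well", "role", "organism", "conversion_factor",
           "time_h", "od600_raw", "n_points", "too_few_points")]
}

#' Fit the dye-based volume-loss model
#'
#' Evaporation concentrates an inert dye (OrangeG) in dedicated control
#' wells, so its OD450 rises over the run. The mean dye signal is normalized
#' to its first timepoint and a line fitted by ordinary least squares; the
#' per-timepoint correction factor is `1 + slope * (t - t0)`, which leaves
#' the first timepoint unchanged by construction. A negative slope (dye
#' apparently diluting) raises a warning, not an error.
#'
#' @param readings Validated readings tibble containing the OD450 channel.
#' @param layout Validated layout tibble with at least one `volume_control`
#'   well.
#' @return An object of class `volume_loss_fit` with elements `plate_id`,
#'   `slope` (per hour), `intercept_normalized`, `r2`, `t0`, `n_wells`,
#'   `data` (the normalized dye series). Use [correction_factor()] to
#'   evaluate the correction, [tidy()]/[glance()] for summaries.
#' @export
fit_volume_loss <- function(readings, layout) {
  readings <- validate_plate_readings(readings)
  layout <- validate_plate_layout(layout)
  dye_wells <- layout |> dplyr::filter(.data$role == "volume_control")
  if (nrow(dye_wells) == 0) {
    abort("cannot correct volume loss: layout has no volume_control wells")
  }
  dye <- readings |>
    dplyr::filter(.data$channel == "OD450") |>
    dplyr::semi_join(dye_wells, by = c("plate_id", "well"))
  if (nrow(dye) == 0) abort("no OD450 readings for volume_control wells")
  mean_dye <- dye |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(od450 = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$time_h)
  if (nrow(mean_dye) < 3) abort("volume-loss fit needs >= 3 timepoints")
  mean_dye$normalized <- mean_dye$od450 / mean_dye$od450[1]
  fit <- lm(normalized ~ time_h, data = mean_dye)
  slope <- unname(coef(fit)[2])
  r2 <- ls_r2(mean_dye$time_h, mean_dye$normalized)
  if (is.na(r2)) r2 <- 1  # constant dye: zero slope fits perfectly
  if (slope < -1e-12) {
    warn(sprintf("volume-loss slope is negative (%.4g h^-1); dye signal decreasing", slope))
  }
  structure(
    list(
      plate_id = unique(dye$plate_id),
      slope = slope,
      intercept_normalized = 1,
      r2 = r2,
      t0 = mean_dye$time_h[1],
      n_wells = nrow(dye_wells),
      data = mean_dye,
      lm = fit
    ),
    class = "volume_loss_fit"
  )
}

#' Evaluate a volume-loss correction factor
#'
#' @param vfit A `volume_loss_fit`, or `NULL` for a unit correction.
#' @param time_h Times (hours) at which to evaluate.
#' @return Numeric factor `1 + slope * (t - t0)`, exactly 1 at the first
#'   timepoint; truncated below at a small positive value.
#' @export
correction_factor <- function(vfit, time_h) {
  if (is.null(vfit)) return(rep(1, length(time_h)))
  stopifnot(inherits(vfit, "volume_loss_fit"))
  pmax(1 + vfit$slope * (time_h - vfit$t0), .Machine$double.eps)
}

#' @export
print.volume_loss_fit <- function(x, ...) {
  cat(sprintf(
    "Volume-loss fit (%d dye well%s): slope %.4g h^-1, r2 %.4f, t0 %.2f h\n",
    x$n_wells, if (x$n_wells == 1) "" else "s", x$slope, x$r2, x$t0
  ))
  invisible(x)
}

#' Apply background and volume-loss corrections to a well series
#'
#' The plate background (media color, plate optics) is the mean OD600 of the
#' dye control wells at each timepoint; it is subtracted first, then the
#' result is divided by the volume-loss correction factor. Corrected values
#' that come out negative are masked as `NA` (not clamped) so later log fits
#' stay unbiased. Sample and background timepoints must align within
#' `time_tol` hours.
#'
#' @param series Long series tibble from [assemble_well_series()].
#' @param vfit `volume_loss_fit` from [fit_volume_loss()], or `NULL` to skip
#'   volume correction.
#' @param background_wells Optional tibble of background well series (same
#'   shape as `series`); defaults to the `volume_control` wells of `series`.
#' @param time_tol Maximum timepoint mismatch in hours (default 0.05).
#' @return `series` with an added `od600_corrected` column.
#' @export
apply_plate_corrections <- function(series, vfit = NULL, background_wells = NULL,
                                    time_tol = 0.05) {
  if (is.null(background_wells)) {
    background_wells <- dplyr::filter(series, .data$role == "volume_control")
  }
  if (nrow(background_wells) == 0) {
    bg <- tibble::tibble(time_h = sort(unique(series$time_h)), bg_od600 = 0)
  } else {
    bg <- background_wells |>
      dplyr::group_by(.data$time_h) |>
      dplyr::summarise(bg_od600 = mean(.data$od600_raw), .groups = "drop") |>
      dplyr::arrange(.data$time_h)
  }
  idx <- vapply(series$time_h, function(t) which.min(abs(bg$time_h - t)), integer(1))
  off <- abs(bg$time_h[idx] - series$time_h)
  if (any(off > time_tol)) {
    bad <- sort(unique(series$time_h[off > time_tol]))
    abort(paste0("sample/background timepoints misaligned beyond ", time_tol,
                 " h at t = ", paste(signif(head(bad, 5), 6), collapse = ", ")))
  }
  corr <- correction_factor(vfit, series$time_h)
  corrected <- (series$od600_raw - bg$bg_od600[idx]) / corr
  corrected[corrected < 0] <- NA_real_
  series$od600_corrected <- corrected
  series
}

# rolling log-linear slope of a single well; values <= min_od are masked
rolling_mu <- function(time_h, od, window, min_od) {
  ly <- ifelse(is.finite(od) & od > min_od, log(od), NA_real_)
  n <- length(time_h)
  h <- (window - 1L) %/% 2L
  mu <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    ok <- idx[!is.na(ly[idx])]
    if (length(ok) >= 2) mu[i] <- ls_slope(time_h[ok], ly[ok])
  }
  mu
}

#' Specific growth rates at each timepoint
#'
#' The specific growth rate mu(t) = d log(OD)/dt is estimated as the slope of
#' log(OD600) against time over a centered rolling window; edge points use
#' truncated windows. Values at or below `min_od` are masked before the log
#' transform so instrument noise near zero does not dominate.
#'
#' @param series Corrected series tibble (uses `od600_corrected` when
#'   present, else `od600_raw`).
#' @param window Rolling window size in points, odd, >= 3 (default 5).
#' @param min_od Detection floor in OD600 units (default 0.01).
#' @return Tibble `plate_id`, `well`, `time_h`, `mu` (h^-1; `NA` where
#'   masked) plus a logical `no_growth` per well (all points masked).
#' @export
specific_growth_rates <- function(series, window = 5, min_od = 0.01) {
  if (window < 3 || window %% 2 != 1) abort("`window` must be odd and >= 3")
  od_col <- if ("od600_corrected" %in% names(series)) "od600_corrected" else "od600_raw"
  series |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::group_modify(function(d, key) {
      mu <- rolling_mu(d$time_h, d[[od_col]], window, min_od)
      tibble::tibble(time_h = d$time_h, mu = mu, no_growth = all(is.na(mu)))
    }) |>
    dplyr::ungroup()
}

# Exponential-window search engine for one well. Scans all contiguous
# windows of >= min_points usable (positive, above-floor) log values,
# keeps those with r2 >= r2_threshold and positive slope, and among windows
# whose slope is within slope_tol of the best qualifying slope returns the
# longest (earliest start on ties).
detect_exponential_window <- function(time_h, od, min_points = 5,
                                      r2_threshold = 0.95, slope_tol = 0.10,
                                      min_od = 0.01) {
  empty <- list(found = FALSE, start = NA_integer_, end = NA_integer_,
                t_start = NA_real_, t_end = NA_real_,
                slope = NA_real_, r2 = NA_real_)
  usable <- is.finite(od) & od > min_od
  if (sum(usable) < min_points) return(empty)
  ly <- ifelse(usable, log(od), NA_real_)
  n <- length(time_h)
  cand <- list()
  for (s in seq_len(n - min_points + 1L)) {
    if (!usable[s]) next
    for (e in (s + min_points - 1L):n) {
      if (any(!usable[s:e])) break
      b <- ls_slope(time_h[s:e], ly[s:e])
      r2 <- ls_r2(time_h[s:e], ly[s:e])
      if (!is.na(b) && !is.na(r2) && b > 0 && r2 >= r2_threshold) {
        cand[[length(cand) + 1L]] <- c(s = s, e = e, slope = b, r2 = r2)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  best_slope <- max(cand[, "slope"])
  keep <- cand[cand[, "slope"] >= (1 - slope_tol) * best_slope, , drop = FALSE]
  len <- keep[, "e"] - keep[, "s"]
  pick <- keep[order(-len, keep[, "s"]), , drop = FALSE][1, ]
  list(found = TRUE, start = as.integer(pick["s"]), end = as.integer(pick["e"]),
       t_start = time_h[pick["s"]], t_end = time_h[pick["e"]],
       slope = unname(pick["slope"]), r2 = unname(pick["r2"]))
}

#' Find the exponential growth phase of each well
#'
#' Searches all contiguous windows of the log-transformed corrected series
#' and keeps the longest one whose log-linear fit has `r2 >=` the threshold
#' and whose slope is within `slope_tol` of the best qualifying window's
#' slope (ties broken by earlier start). Wells with no qualifying window are
#' flagged `no_growth`.
#'
#' @inheritParams specific_growth_rates
#' @param min_points Minimum window length in points (default 5).
#' @param r2_threshold Minimum within-window log-linear r-squared (default 0.95).
#' @param slope_tol Relative slope tolerance versus the window-maximum slope
#'   (default 0.10).
#' @return Tibble per well: `plate_id`, `well`, `t_start`, `t_end`, `slope`,
#'   `r2`, `no_growth`.
#' @export
find_exponential_phase <- function(series, min_points = 5, r2_threshold = 0.95,
                                   slope_tol = 0.10, min_od = 0.01) {
  od_col <- if ("od600_corrected" %in% names(series)) "od600_corrected" else "od600_raw"
  series |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::group_modify(function(d, key) {
      w <- detect_exponential_window(d$time_h, d[[od_col]], min_points,
                                     r2_threshold, slope_tol, min_od)
      tibble::tibble(t_start = w$t_start, t_end = w$t_end,
                     slope = w$slope, r2 = w$r2, no_growth = !w$found)
    }) |>
    dplyr::ungroup()
}

#' Fit the maximum specific growth rate of a single growth curve
#'
#' Two estimators are provided. `log_linear` takes the slope (and standard
#' error) of log(OD600) over the detected exponential window. `parametric`
#' fits a logistic curve
#' `OD(t) = K * N0 * exp(mu t) / (K + N0 * (exp(mu t) - 1))`
#' to the untransformed series by Levenberg-Marquardt least squares; `mu` is
#' the model's maximal per-capita rate (attained as OD -> 0). A
#' non-convergent parametric fit falls back to `log_linear` with a
#' `poor_fit` flag; a curve with no detectable exponential window is flagged
#' `no_growth`.
#'
#' @param time_h,od Numeric vectors of times (h) and corrected OD600.
#' @param model `"parametric"` (default) or `"log_linear"`.
#' @param min_points,r2_threshold,slope_tol,min_od Passed to the
#'   exponential-window search.
#' @return Object of class `growth_fit`: `mu_max`, `mu_max_se`, `snr`
#'   (`mu_max / mu_max_se`), `method`, `window`, `r2`, `flags` (character
#'   subset of `no_growth`, `poor_fit`), plus the data. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
fit_growth_curve <- function(time_h, od, model = c("parametric", "log_linear"),
                             min_points = 5, r2_threshold = 0.95,
                             slope_tol = 0.10, min_od = 0.01) {
  model <- match.arg(model)
  stopifnot(length(time_h) == length(od))
  win <- detect_exponential_window(time_h, od, min_points, r2_threshold,
                                   slope_tol, min_od)
  out <- list(time_h = time_h, od = od, window = win, flags = character(0),
              method = model, mu_max = NA_real_, mu_max_se = NA_real_,
              snr = NA_real_, r2 = NA_real_, fit = NULL)
  class(out) <- "growth_fit"
  if (!win$found) {
    out$flags <- "no_growth"
    return(out)
  }
  loglin <- function() {
    idx <- win$start:win$end
    fit <- lm(log(od[idx]) ~ time_h[idx])
    # summary.lm warns on essentially perfect (noiseless) fits; the SE is
    # then ~0, which is the correct answer
    est <- suppressWarnings(summary(fit))$coefficients
    list(mu = est[2, 1], se = est[2, 2], r2 = win$r2, fit = fit, method = "log_linear")
  }
  res <- NULL
  if (model == "parametric") {
    keep <- is.finite(od) & od > 0
    t_fit <- time_h[keep]; y_fit <- od[keep]
    start <- list(K = max(y_fit) * 1.05, N0 = max(y_fit[1], min_od / 2),
                  mu = win$slope)
    res <- tryCatch({
      fit <- minpack.lm::nlsLM(
        y_fit ~ K * N0 * exp(mu * t_fit) / (K + N0 * (exp(mu * t_fit) - 1)),
        start = start,
        lower = c(K = 1e-6, N0 = 1e-9, mu = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      est <- suppressWarnings(summary(fit))$coefficients
      pred <- predict(fit)
      r2 <- 1 - sum((y_fit - pred)^2) / max(sum((y_fit - mean(y_fit))^2),
                                            .Machine$double.xmin)
      list(mu = est["mu", 1], se = est["mu", 2], r2 = r2, fit = fit,
           method = "parametric")
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- loglin()
      out$flags <- "poor_fit"
    }
  } else {
    res <- loglin()
  }
  out$mu_max <- unname(res$mu)
  out$mu_max_se <- unname(res$se)
  out$snr <- if (is.finite(res$se) && res$se > 0) res$mu / res$se else NA_real_
  out$r2 <- res$r2
  out$method <- res$method
  out$fit <- res$fit
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if ("no_growth" %in% x$flags) {
    cat("Growth fit: no growth detected\n")
  } else {
    cat(sprintf("Growth fit (%s): mu_max %.4f +/- %.4f h^-1, window [%.2f, %.2f] h%s\n",
                x$method, x$mu_max, x$mu_max_se, x$window$t_start, x$window$t_end,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' Maximum growth rate for every well of a plate
#'
#' Maps [fit_growth_curve()] over the wells of a corrected series tibble.
#'
#' @inheritParams fit_growth_curve
#' @param series Corrected series tibble from [apply_plate_corrections()].
#' @return Tibble per well: `plate_id`, `well`, `role`, `organism`,
#'   `mu_max`, `mu_max_se`, `snr`, `method`, `t_start`, `t_end`, `r2`,
#'   `no_growth`, `poor_fit`.
#' @export
fit_mu_max <- function(series, model = c("parametric", "log_linear"),
                       min_points = 5, r2_threshold = 0.95, slope_tol = 0.10,
                       min_od = 0.01) {
  model <- match.arg(model)
  od_col <- if ("od600_corrected" %in% names(series)) "od600_corrected" else "od600_raw"
  series |>
    dplyr::group_by(.data$plate_id, .data$well, .data$role, .data$organism) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_growth_curve(d$time_h, d[[od_col]], model, min_points,
                              r2_threshold, slope_tol, min_od)
      tibble::tibble(
        mu_max = fit$mu_max, mu_max_se = fit$mu_max_se, snr = fit$snr,
        method = fit$method, t_start = fit$window$t_start,
        t_end = fit$window$t_end, r2 = fit$r2,
        no_growth = "no_growth" %in% fit$flags,
        poor_fit = "poor_fit" %in% fit$flags
      )
    }) |>
    dplyr::ungroup()
}

#' Plate-level growth summary and contamination check
#'
#' Mean and standard deviation of the maximum growth rate over sample wells,
#' plus a contamination check: any media-only (`contamination_control`) well
#' whose corrected OD600 rises by more than `contamination_threshold` over
#' the run flags the plate as contaminated.
#'
#' @param mu_table Per-well results from [fit_mu_max()].
#' @param series Corrected series tibble (for the contamination check).
#' @param contamination_threshold Maximum tolerated OD600 increase in a
#'   media-only well (default 0.05).
#' @return One-row tibble per plate: `plate_id`, `n_sample_wells`,
#'   `mu_mean`, `mu_sd`, `mu_cv_pct`, `n_no_growth`, `contaminated`,
#'   `contaminated_wells` (list-column).
#' @export
plate_growth_summary <- function(mu_table, series, contamination_threshold = 0.05) {
  od_col <- if ("od600_corrected" %in% names(series)) "od600_corrected" else "od600_raw"
  contam <- series |>
    dplyr::filter(.data$role == "contamination_control") |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::summarise(
      rise = {
        v <- .data[[od_col]][is.finite(.data[[od_col]])]
        if (length(v) >= 2) max(v) - v[1] else 0
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$rise > contamination_threshold)
  mu_table |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_sample_wells = dplyr::n(),
      mu_mean = mean(.data$mu_max, na.rm = TRUE),
      mu_sd = sd(.data$mu_max, na.rm = TRUE),
      mu_cv_pct = 100 * .data$mu_sd / .data$mu_mean,
      n_no_growth = sum(.data$no_growth),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      contaminated_wells = purrr::map(.data$plate_id, function(p) {
        contam$well[contam$plate_id == p]
      }),
      contaminated = purrr::map_lgl(.data$contaminated_wells, function(w) length(w) > 0)
    )
}

#' Run the full growth pipeline on a readings/layout pair
#'
#' Convenience wrapper: assemble series, fit the volume-loss model, apply
#' corrections, fit per-well maximum growth rates, summarise the plate.
#'
#' @inheritParams assemble_well_series
#' @inheritParams fit_growth_curve
#' @param contamination_threshold Passed to [plate_growth_summary()].
#' @return List with elements `series` (corrected), `volume_loss`,
#'   `mu` (per-well tibble), `summary` (plate tibble).
#' @export
analyze_growth <- function(readings, layout, dilution_factor = 5,
                           model = c("parametric", "log_linear"),
                           min_points = 5, r2_threshold = 0.95,
                           slope_tol = 0.10, min_od = 0.01,
                           contamination_threshold = 0.05) {
  model <- match.arg(model)
  series <- assemble_well_series(readings, layout, dilution_factor)
  vfit <- fit_volume_loss(readings, layout)
  series <- apply_plate_corrections(series, vfit)
  mu <- fit_mu_max(series, model, min_points, r2_threshold, slope_tol, min_od)
  summary <- plate_growth_summary(mu, series, contamination_threshold)
  list(series = series, volume_loss = vfit, mu = mu, summary = summary)
}
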