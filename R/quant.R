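# Isotope-dilution quantification, biomass normalization, adenylate energy
# charge, and plate-level QC statistics.

#' Analyte-to-internal-standard peak ratio
#'
#' Targeted quantification against a fully 13C-labeled internal standard:
#' the quantity carried forward is the 12C/13C signal ratio, which cancels
#' matrix and injection effects.
#'
#' @param area_12c Analyte (12C) peak area, >= 0.
#' @param area_13c Internal-standard (13C) peak area, > 0.
#' @return Dimensionless ratio vector.
#' @export
isotope_ratio <- function(area_12c, area_13c) {
  check_number(area_12c, "area_12c", lower = 0)
  check_number(area_13c, "area_13c")
  if (any(area_13c <= 0)) abort("missing internal standard: area_13c must be > 0")
  area_12c / area_13c
}

#' Fit a calibration curve of ratio versus known concentration
#'
#' Linear least squares of the 12C/13C ratio on the standard concentration,
#' optionally weighted by `1/x` to stabilise the relative error at the low
#' end of heteroscedastic calibrations.
#'
#' @param levels Data frame with columns `known_conc` (uM, strictly
#'   increasing) and `ratio`; at least 3 levels.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return Object of class `calibration_fit`: `slope`, `intercept`, `r2`,
#'   `weighting`, `range` (lowest/highest level). Has [tidy()], [glance()]
#'   and [autoplot()] methods; invert with [quantify()].
#' @export
fit_calibration <- function(levels, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  levels <- tibble::as_tibble(levels)
  if (!all(c("known_conc", "ratio") %in% names(levels))) {
    abort("`levels` needs columns `known_conc` and `ratio`")
  }
  if (nrow(levels) < 3) abort("calibration requires at least 3 levels")
  if (is.unsorted(levels$known_conc, strictly = TRUE)) {
    abort("`known_conc` must be strictly increasing (no duplicated levels)")
  }
  w <- if (weighting == "1/x") 1 / levels$known_conc else rep(1, nrow(levels))
  if (weighting == "1/x" && any(levels$known_conc <= 0)) {
    abort("1/x weighting requires strictly positive concentrations")
  }
  fit <- lm(ratio ~ known_conc, data = levels, weights = w)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r2 = ls_r2(levels$known_conc, levels$ratio),
      weighting = weighting,
      range = range(levels$known_conc),
      levels = levels,
      lm = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration (%s weighting): ratio = %.4g + %.4g * conc, r2 %.4f, range [%g, %g] uM\n",
    x$weighting, x$intercept, x$slope, x$r2, x$range[1], x$range[2]
  ))
  invisible(x)
}

#' Quantify from a peak ratio through a calibration curve
#'
#' Inverts the calibration: `conc = (ratio - intercept) / slope`. Results
#' outside the calibrated concentration range are flagged `extrapolated`.
#'
#' @param calibration A `calibration_fit`.
#' @param ratio Measured 12C/13C ratio(s).
#' @return Tibble with `ratio`, `conc_um`, `extrapolated`.
#' @export
quantify <- function(calibration, ratio) {
  stopifnot(inherits(calibration, "calibration_fit"))
  if (calibration$slope <= 0) abort("calibration slope must be positive to quantify")
  check_number(ratio, "ratio")
  conc <- (ratio - calibration$intercept) / calibration$slope
  tibble::tibble(
    ratio = ratio,
    conc_um = conc,
    extrapolated = conc < calibration$range[1] | conc > calibration$range[2]
  )
}

#' Normalize a metabolite concentration to biomass
#'
#' `conc (umol/gDCW) = conc (uM) * 1e-3 (mL/L) * reconstitution_volume (mL)
#' / biomass_sampled (gDCW)`.
#'
#' @param conc_um Measured concentration in the reconstituted extract (uM).
#' @param reconstitution_volume Reconstitution volume in mL (> 0).
#' @param biomass Biomass sampled in gDCW (> 0); see [biomass_sampled()].
#' @return Concentration in umol per gDCW.
#' @export
#' @examples
#' normalize_concentration(100, 0.1, 6.18e-4)
normalize_concentration <- function(conc_um, reconstitution_volume, biomass) {
  check_number(conc_um, "conc_um")
  check_number(reconstitution_volume, "reconstitution_volume", lower = 0, strict = TRUE)
  check_number(biomass, "biomass", lower = 0, strict = TRUE)
  conc_um * 1e-3 * reconstitution_volume / biomass
}

#' Adenylate energy charge
#'
#' `EC = (ATP + 0.5 * ADP) / (ATP + ADP + AMP)`; close to 1 in healthy
#' exponentially growing cells, so a low value indicates metabolite
#' degradation during quenching and extraction. Any common unit works; EC is
#' invariant under rescaling of all three pools.
#'
#' @param atp,adp,amp Adenylate pools, all >= 0, not all zero (vectorized).
#' @return Energy charge in `[0, 1]`.
#' @export
#' @examples
#' energy_charge(1, 1, 1)
energy_charge <- function(atp, adp, amp) {
  check_number(atp, "atp", lower = 0)
  check_number(adp, "adp", lower = 0)
  check_number(amp, "amp", lower = 0)
  total <- atp + adp + amp
  if (any(total == 0)) abort("energy charge undefined: ATP + ADP + AMP is zero")
  (atp + 0.5 * adp) / total
}

# coerce a wells x features input (matrix or data frame, optional `well`
# column) to a numeric matrix with well rownames
as_feature_matrix <- function(values) {
  if (is.data.frame(values)) {
    values <- tibble::as_tibble(values)
    if ("well" %in% names(values)) {
      wells <- as.character(values$well)
      values <- dplyr::select(values, -"well")
      m <- as.matrix(values)
      rownames(m) <- wells
    } else {
      m <- as.matrix(values)
    }
  } else {
    m <- as.matrix(values)
  }
  if (!is.numeric(m)) abort("feature values must be numeric")
  if (is.null(rownames(m))) rownames(m) <- paste0("well", seq_len(nrow(m)))
  m
}

#' Replicate coefficient of variation per feature
#'
#' CV = 100 * sample standard deviation / mean across replicate wells, per
#' feature. Features with non-positive mean have undefined CV and are
#' excluded from the fraction-below-threshold denominator.
#'
#' @param values Wells x features matrix, or data frame with an optional
#'   `well` column; at least 2 wells.
#' @param threshold_pct CV threshold in percent (default 30).
#' @return List of class `plate_cv`: `cv` (tibble `feature`, `mean`, `sd`,
#'   `cv_pct`, `defined`), `fraction_below` (share of defined CVs strictly
#'   below the threshold, 0-1), `threshold_pct`, `n_wells`.
#' @export
plate_cv <- function(values, threshold_pct = 30) {
  m <- as_feature_matrix(values)
  if (nrow(m) < 2) abort("CV requires at least 2 wells")
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, sd, na.rm = TRUE)
  defined <- is.finite(mu) & mu > 0
  cv <- ifelse(defined, 100 * sdv / mu, NA_real_)
  tab <- tibble::tibble(
    feature = colnames(m) %||% paste0("f", seq_along(mu)),
    mean = unname(mu), sd = unname(sdv),
    cv_pct = unname(cv), defined = unname(defined)
  )
  structure(
    list(
      cv = tab,
      fraction_below = if (any(defined)) mean(cv[defined] < threshold_pct) else NA_real_,
      threshold_pct = threshold_pct,
      n_wells = nrow(m)
    ),
    class = "plate_cv"
  )
}

#' @export
print.plate_cv <- function(x, ...) {
  cat(sprintf(
    "Replicate CV over %d wells, %d features (%d defined): %.1f%% below %g%%\n",
    x$n_wells, nrow(x$cv), sum(x$cv$defined), 100 * x$fraction_below, x$threshold_pct
  ))
  invisible(x)
}

#' Proteome coverage
#'
#' @param n_detected Number of proteins detected.
#' @param n_coding Number of protein-coding genes.
#' @return Coverage in percent.
#' @export
#' @examples
#' proteome_coverage(2000, 4000)
proteome_coverage <- function(n_detected, n_coding) {
  check_number(n_detected, "n_detected", lower = 0)
  check_number(n_coding, "n_coding", lower = 0, strict = TRUE)
  if (any(n_detected > n_coding)) {
    abort("n_detected cannot exceed n_coding")
  }
  100 * n_detected / n_coding
}

#' Flag outlier wells by robust z-score
#'
#' Each value gets a robust z-score against its feature's median and MAD;
#' a well is flagged when the median of its absolute z-scores across
#' features exceeds `z_threshold`. Features with zero MAD are excluded.
#'
#' @param values Wells x features matrix or data frame (>= 4 wells).
#' @param z_threshold Robust z cutoff (default 3).
#' @return Tibble `well`, `median_abs_z`, `outlier`.
#' @export
flag_outlier_wells <- function(values, z_threshold = 3) {
  m <- as_feature_matrix(values)
  if (nrow(m) < 4) abort("outlier detection requires at least 4 wells")
  med <- apply(m, 2, median, na.rm = TRUE)
  madv <- apply(m, 2, mad, na.rm = TRUE)
  keep <- is.finite(madv) & madv > 0
  if (!any(keep)) {
    return(tibble::tibble(well = rownames(m), median_abs_z = 0, outlier = FALSE))
  }
  z <- abs(sweep(sweep(m[, keep, drop = FALSE], 2, med[keep]), 2, madv[keep], "/"))
  mz <- apply(z, 1, median, na.rm = TRUE)
  tibble::tibble(
    well = rownames(m),
    median_abs_z = unname(mz),
    outlier = unname(mz > z_threshold)
  )
}
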