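# broom-style tidiers for the package's fitted objects.

#' @method tidy volume_loss_fit
#' @export
tidy.volume_loss_fit <- function(x, ...) {
  est <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept_normalized", "slope"),
    estimate = c(unname(coef(x$lm)[1]), x$slope),
    std.error = est[, 2]
  )
}

#' @method glance volume_loss_fit
#' @export
glance.volume_loss_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, r.squared = x$r2, t0 = x$t0,
    n_wells = x$n_wells, n_timepoints = nrow(x$data)
  )
}

#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = "mu_max",
    estimate = x$mu_max,
    std.error = x$mu_max_se
  )
}

#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    mu_max = x$mu_max, mu_max_se = x$mu_max_se, snr = x$snr,
    method = x$method, r.squared = x$r2,
    t_start = x$window$t_start, t_end = x$window$t_end,
    no_growth = "no_growth" %in% x$flags,
    poor_fit = "poor_fit" %in% x$flags
  )
}

#' @method tidy exchange_fit
#' @export
tidy.exchange_fit <- function(x, ...) {
  est <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(est),
    estimate = est[, 1],
    std.error = est[, 2]
  )
}

#' @method glance exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, slope = x$slope, r.squared = x$r2, n = x$n,
    mu = x$mu, q = x$q, direction = x$direction, passed = x$passed
  )
}

#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  est <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = est[, 2]
  )
}

#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r2,
    weighting = x$weighting, n_levels = nrow(x$levels),
    conc_low = x$range[1], conc_high = x$range[2]
  )
}

#' @method tidy plate_cv
#' @export
tidy.plate_cv <- function(x, ...) x$cv

#' @method glance plate_cv
#' @export
glance.plate_cv <- function(x, ...) {
  tibble::tibble(
    n_wells = x$n_wells, n_features = nrow(x$cv),
    n_defined = sum(x$cv$defined),
    median_cv_pct = median(x$cv$cv_pct[x$cv$defined]),
    fraction_below = x$fraction_below,
    threshold_pct = x$threshold_pct
  )
}
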