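# Biomass conversion and single-time-point uptake/secretion-rate estimation.
#
# The single-time-point strategy samples parallel cultures started at
# different dilutions once, at the end of the run. During balanced
# exponential growth the concentration change of a compound relative to
# fresh medium is proportional to the biomass present, with slope equal to
# the yield (mmol per gDCW); multiplying the yield by the growth rate gives
# the specific exchange rate q (mmol gDCW^-1 h^-1).

#' Biomass concentration from optical density
#'
#' @param od600 Culture OD600 (>= 0).
#' @param conversion_factor Organism-specific factor in gDW L^-1 OD600^-1
#'   (e.g. 2.06 for *E. coli*, 3.62 for *P. putida*, 3.31 for
#'   *S. cerevisiae*).
#' @return Biomass concentration in gDCW per litre.
#' @export
#' @examples
#' biomass_concentration(1.0, 2.06)
biomass_concentration <- function(od600, conversion_factor) {
  check_number(od600, "od600", lower = 0)
  check_number(conversion_factor, "conversion_factor", lower = 0, strict = TRUE)
  od600 * conversion_factor
}

#' Biomass in a sampled culture volume
#'
#' `biomass (gDCW) = culture_volume (L) * OD600 * conversion_factor`.
#'
#' @param culture_volume Sampled volume in litres (> 0).
#' @inheritParams biomass_concentration
#' @return Biomass in gDCW.
#' @export
#' @examples
#' biomass_sampled(3.0e-4, 1.0, 2.06)
biomass_sampled <- function(culture_volume, od600, conversion_factor) {
  check_number(culture_volume, "culture_volume", lower = 0, strict = TRUE)
  culture_volume * biomass_concentration(od600, conversion_factor)
}

#' Estimate an exchange (uptake/secretion) rate from a dilution series
#'
#' Ordinary least squares of the concentration change `delta_conc` (mM,
#' relative to fresh medium; negative for consumed substrates) on the
#' biomass concentration at sampling (gDCW/L). The slope is the yield in
#' mmol per gDCW; `q = slope * mu`. The estimate passes quality control when
#' it rests on at least three points and the squared correlation exceeds
#' `r2_threshold` (default 0.8).
#'
#' @param points Data frame with columns `biomass` (gDCW/L) and
#'   `delta_conc` (mM).
#' @param mu Growth rate in h^-1 (> 0), typically the plate-mean maximum
#'   growth rate of the organism.
#' @param r2_threshold QC gate on the squared correlation (default 0.8).
#' @param intercept Fit a free intercept (default `TRUE`); `FALSE` forces
#'   the regression through the origin.
#' @param compound Optional compound label carried into the result.
#' @return Object of class `exchange_fit`: `slope` (mmol/gDCW), `intercept`,
#'   `r2`, `n`, `mu`, `q` (mmol gDCW^-1 h^-1, signed), `direction`
#'   (`"uptake"` if the slope is negative, else `"secretion"`), `passed`.
#'   Has [tidy()] and [glance()] methods.
#' @export
estimate_exchange_rate <- function(points, mu, r2_threshold = 0.8,
                                   intercept = TRUE, compound = NA_character_) {
  points <- tibble::as_tibble(points)
  if (!all(c("biomass", "delta_conc") %in% names(points))) {
    abort("`points` needs columns `biomass` and `delta_conc`")
  }
  points <- points[is.finite(points$biomass) & is.finite(points$delta_conc), ]
  n <- nrow(points)
  if (n < 3) abort("exchange-rate estimation requires a minimum of three points")
  check_number(mu, "mu", lower = 0, strict = TRUE)
  if (var(points$biomass) == 0) {
    abort("zero spread in biomass across dilutions; regression is singular")
  }
  fit <- if (intercept) {
    lm(delta_conc ~ biomass, data = points)
  } else {
    lm(delta_conc ~ biomass - 1, data = points)
  }
  slope <- unname(coef(fit)[["biomass"]])
  r2 <- ls_r2(points$biomass, points$delta_conc)
  if (is.na(r2)) r2 <- 0
  q <- slope * mu
  structure(
    list(
      compound = compound,
      slope = slope,
      intercept = if (intercept) unname(coef(fit)[1]) else 0,
      r2 = r2,
      n = n,
      mu = mu,
      q = q,
      direction = if (slope < 0) "uptake" else "secretion",
      passed = n >= 3 && r2 > r2_threshold,
      r2_threshold = r2_threshold,
      points = points,
      lm = fit
    ),
    class = "exchange_fit"
  )
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf(
    "Exchange rate%s: q = %.4g mmol/gDCW/h (%s), yield %.4g mmol/gDCW, r2 %.3f, n %d, %s\n",
    if (is.na(x$compound)) "" else paste0(" [", x$compound, "]"),
    x$q, x$direction, x$slope, x$r2, x$n,
    if (x$passed) "passed" else "NOT passed"
  ))
  invisible(x)
}

#' Exchange rates for all organism/compound groups on a plate
#'
#' Builds (biomass, delta concentration) points per dilution level from
#' endpoint concentrations and the plate layout, then estimates the
#' exchange rate per (organism, compound) with the organism's mean maximum
#' growth rate. Groups with fewer than three dilution levels are skipped
#' with a logged reason. When every dilution level carries replicate wells,
#' the rate is additionally estimated per replicate index and the CV of `q`
#' across replicates reported.
#'
#' @param concentrations Tibble with columns `plate_id`, `well`, `od600`
#'   (at sampling), `compound`, `conc_mm` (measured concentration, mM).
#' @param layout Validated layout tibble (supplies organism, dilution level
#'   and conversion factor per well).
#' @param growth Tibble with columns `organism`, `mu` (h^-1), e.g. derived
#'   from [fit_mu_max()] results.
#' @param medium Tibble with columns `compound`, `conc_mm`: fresh-medium
#'   composition subtracted to obtain concentration changes; compounds
#'   absent from it are taken as 0 mM at inoculation.
#' @inheritParams estimate_exchange_rate
#' @return Tibble per (organism, compound): yield slope, `r2`, `n`, `mu`,
#'   `q`, `direction`, `passed`, `q_cv_pct` (NA without replicates),
#'   `skipped`, `skip_reason`.
#' @export
exchange_rate_table <- function(concentrations, layout, growth, medium = NULL,
                                r2_threshold = 0.8, intercept = TRUE) {
  layout <- validate_plate_layout(layout)
  concentrations <- tibble::as_tibble(concentrations)
  required <- c("well", "od600", "compound", "conc_mm")
  missing <- setdiff(required, names(concentrations))
  if (length(missing) > 0) {
    abort(paste0("concentration table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(medium)) medium <- tibble::tibble(compound = character(), conc_mm = numeric())
  by_cols <- intersect(c("plate_id", "well"), names(concentrations))
  pts <- concentrations |>
    dplyr::inner_join(
      layout[c("plate_id", "well", "organism", "dilution_level", "conversion_factor")],
      by = by_cols
    ) |>
    dplyr::left_join(dplyr::rename(medium, medium_mm = "conc_mm"), by = "compound") |>
    dplyr::mutate(
      medium_mm = dplyr::coalesce(.data$medium_mm, 0),
      biomass = .data$od600 * .data$conversion_factor,
      delta_conc = .data$conc_mm - .data$medium_mm
    )
  pts |>
    dplyr::group_by(.data$organism, .data$compound) |>
    dplyr::group_modify(function(d, key) {
      mu_org <- growth$mu[growth$organism == key$organism]
      base <- tibble::tibble(
        slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
        n = nrow(d), mu = NA_real_, q = NA_real_,
        direction = NA_character_, passed = FALSE, q_cv_pct = NA_real_,
        skipped = TRUE, skip_reason = NA_character_
      )
      if (length(mu_org) != 1 || !is.finite(mu_org)) {
        base$skip_reason <- "no growth rate for organism"
        return(base)
      }
      n_levels <- dplyr::n_distinct(d$dilution_level)
      if (n_levels < 3) {
        base$skip_reason <- sprintf("only %d dilution level(s); need >= 3", n_levels)
        return(base)
      }
      fit <- estimate_exchange_rate(d, mu_org, r2_threshold, intercept,
                                    compound = key$compound)
      # replicate-wise estimates when each dilution level is replicated
      reps <- d |>
        dplyr::group_by(.data$dilution_level) |>
        dplyr::mutate(.rep = dplyr::row_number()) |>
        dplyr::ungroup()
      q_cv <- NA_real_
      full_reps <- reps |>
        dplyr::count(.data$.rep) |>
        dplyr::filter(.data$n >= 3)
      if (nrow(full_reps) >= 2) {
        qs <- vapply(full_reps$.rep, function(r) {
          sub <- reps[reps$.rep == r, ]
          estimate_exchange_rate(sub, mu_org, r2_threshold, intercept)$q
        }, numeric(1))
        if (mean(qs) != 0) q_cv <- 100 * sd(qs) / abs(mean(qs))
      }
      tibble::tibble(
        slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
        n = fit$n, mu = fit$mu, q = fit$q, direction = fit$direction,
        passed = fit$passed, q_cv_pct = q_cv,
        skipped = FALSE, skip_reason = NA_character_
      )
    }) |>
    dplyr::ungroup()
}
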