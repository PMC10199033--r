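# Synthetic plate experiments with known ground truth for every pipeline
# stage: logistic growth curves with evaporation and background, endpoint
# exo-metabolite dilution series, labeled-fragment MDVs, and generic
# feature matrices for QC statistics.

logistic_od <- function(t, mu, od0, od_max) {
  od_max * od0 * exp(mu * t) / (od_max + od0 * (exp(mu * t) - 1))
}

default_conversion_factors <- c(
  "E. coli" = 2.06, "P. putida" = 3.62, "S. cerevisiae" = 3.31
)

#' Simulate a complete 96-well cultivation plate
#'
#' Sample wells grow logistically from `od0` towards `od_max` at per-well
#' rates jittered around the organism truth. Evaporation concentrates
#' everything by a linear factor `1 + evap_rate * t`, which also drives the
#' OD450 rise of the OrangeG volume-control wells; the media background
#' adds a constant OD600 offset that scales with the same factor. Readings
#' emulate the measurement: the culture is diluted `dilution_factor`-fold
#' before the absorbance read, and multiplicative lognormal noise at
#' `noise_cv` is applied. Eight control wells occupy column 12: four
#' OrangeG volume controls, two media-only contamination controls and two
#' growth controls.
#'
#' @param seed Integer seed; same seed, same tables.
#' @param mu_true Named vector of true maximum growth rates per organism
#'   (h^-1); sample wells are split evenly between organisms.
#' @param n_sample_wells Number of sample wells (default 80, max 88).
#' @param od0,od_max Initial and carrying-capacity OD600 (defaults 0.05, 1.5).
#' @param noise_cv Multiplicative noise CV on every reading (default 0.02).
#' @param evap_rate Relative volume loss per hour (default 0.01).
#' @param background_od Media OD600 background (default 0.04).
#' @param sampling_interval,duration Reading schedule in hours (defaults
#'   0.5 and 10; at least 5 readings required).
#' @param dilution_factor Measurement dilution (default 5).
#' @param mu_jitter_cv Between-well relative spread of the growth rate
#'   (default 0.03).
#' @param dye_od450 OD450 of the OrangeG wells at t = 0 (default 0.5).
#' @param edge_effect_gradient Optional fraction by which `mu` and
#'   `evap_rate` increase from plate center to corner (default `NULL`, off).
#' @param plate_id Plate identifier.
#' @param conversion_factors Named gDW/L/OD factors per organism; defaults
#'   cover *E. coli* (2.06), *P. putida* (3.62), *S. cerevisiae* (3.31).
#' @return List: `readings` (long tibble), `layout` (tibble), `truth`
#'   (list with per-well rates and the configuration).
#' @export
simulate_plate <- function(seed = 0,
                           mu_true = c("E. coli" = 0.594),
                           n_sample_wells = 80,
                           od0 = 0.05, od_max = 1.5,
                           noise_cv = 0.02, evap_rate = 0.01,
                           background_od = 0.04,
                           sampling_interval = 0.5, duration = 10,
                           dilution_factor = 5, mu_jitter_cv = 0.03,
                           dye_od450 = 0.5, edge_effect_gradient = NULL,
                           plate_id = "plate1",
                           conversion_factors = default_conversion_factors) {
  if (is.null(names(mu_true)) || any(mu_true < 0)) {
    abort("`mu_true` must be a named vector of non-negative rates")
  }
  if (noise_cv < 0 || noise_cv >= 1) abort("`noise_cv` must be in [0, 1)")
  if (n_sample_wells < 1 || n_sample_wells > 88) {
    abort("`n_sample_wells` must be between 1 and 88")
  }
  times <- seq(0, duration, by = sampling_interval)
  if (length(times) < 5) abort("duration too short: need at least 5 readings")
  withr::local_seed(seed)

  control_wells <- paste0(LETTERS[1:8], 12)
  layout <- tibble::tibble(
    plate_id = plate_id,
    well = c(setdiff(well_names(), control_wells)[seq_len(n_sample_wells)], control_wells),
    role = c(rep("sample", n_sample_wells),
             rep("volume_control", 4), rep("contamination_control", 2),
             rep("growth_control", 2))
  )
  organisms <- rep(names(mu_true), length.out = n_sample_wells)
  layout$organism <- c(sort(organisms), rep(NA, 4), rep(NA, 2),
                       rep(names(mu_true)[1], 2))
  layout$dilution_level <- NA_real_
  layout$conversion_factor <- unname(conversion_factors[layout$organism])
  layout <- validate_plate_layout(layout)

  grows <- layout$role %in% c("sample", "growth_control")
  mu_well <- rep(NA_real_, nrow(layout))
  mu_well[grows] <- mu_true[layout$organism[grows]] *
    (1 + rnorm(sum(grows), sd = mu_jitter_cv))
  evap_well <- rep(evap_rate, nrow(layout))
  if (!is.null(edge_effect_gradient)) {
    pos <- well_position(layout$well)
    dist <- sqrt(((pos$row - 4.5) / 3.5)^2 + ((pos$col - 6.5) / 5.5)^2) / sqrt(2)
    scale <- 1 + edge_effect_gradient * dist
    mu_well <- mu_well * scale
    evap_well <- evap_well * scale
  }

  one_well <- function(i) {
    evap <- 1 + evap_well[i] * times
    role <- layout$role[i]
    if (role %in% c("sample", "growth_control")) {
      od600 <- (logistic_od(times, mu_well[i], od0, od_max) + background_od) * evap
      od450 <- 0.02 * evap
    } else if (role == "volume_control") {
      od600 <- background_od * evap
      od450 <- dye_od450 * evap
    } else {  # contamination_control: media only
      od600 <- background_od * evap
      od450 <- 0.02 * evap
    }
    n <- length(times)
    tibble::tibble(
      plate_id = plate_id, well = layout$well[i],
      time_h = rep(times, 2),
      channel = rep(c("OD600", "OD450"), each = n),
      value = c(od600, od450) / dilution_factor * lognormal_factor(2 * n, noise_cv)
    )
  }
  readings <- purrr::map_dfr(seq_len(nrow(layout)), one_well) |>
    validate_plate_readings()

  truth <- list(
    wells = tibble::tibble(well = layout$well, role = layout$role,
                           organism = layout$organism, mu_true = mu_well),
    mu_true = mu_true,
    config = list(seed = seed, n_sample_wells = n_sample_wells, od0 = od0,
                  od_max = od_max, noise_cv = noise_cv, evap_rate = evap_rate,
                  background_od = background_od,
                  sampling_interval = sampling_interval, duration = duration,
                  dilution_factor = dilution_factor, mu_jitter_cv = mu_jitter_cv,
                  dye_od450 = dye_od450,
                  edge_effect_gradient = edge_effect_gradient)
  )
  list(readings = readings, layout = layout, truth = truth)
}

#' Simulate a single-time-point exo-metabolome dilution series
#'
#' Cultures started at different dilutions are sampled once; the biomass at
#' sampling spans `od_range`, and each compound's concentration change from
#' fresh medium is `yield * biomass` (yield in mmol/gDCW, negative for
#' consumed substrates), with optional multiplicative noise. The true
#' exchange rate is `q = yield * mu`.
#'
#' @param seed Integer seed.
#' @param yields Named vector of compound yields in mmol per gDCW (signed).
#' @param mu True growth rate (h^-1).
#' @param n_dilutions Number of dilution levels (>= 3, default 6).
#' @param n_replicates Replicate wells per dilution level (default 1).
#' @param od_range OD600 range spanned by the dilution levels at sampling.
#' @param conversion_factor gDW/L/OD conversion (default 2.06, *E. coli*).
#' @param medium Named fresh-medium concentrations in mM (default glucose
#'   22.2, i.e. 4 g/L); compounds absent default to 0.
#' @param noise_cv Multiplicative noise CV on concentration changes
#'   (default 0).
#' @param organism,plate_id Labels for the generated tables.
#' @return List: `concentrations` (tibble `plate_id`, `well`, `od600`,
#'   `compound`, `conc_mm`), `layout`, `growth` (organism/mu tibble),
#'   `truth` (list with `q`, `yields`, `mu`).
#' @export
simulate_exo_series <- function(seed = 0,
                                yields = c(glucose = -10, acetate = 4),
                                mu = 0.6, n_dilutions = 6, n_replicates = 1,
                                od_range = c(0.2, 1.2),
                                conversion_factor = 2.06,
                                medium = c(glucose = 22.2),
                                noise_cv = 0, organism = "E. coli",
                                plate_id = "plate1") {
  if (n_dilutions < 3) abort("`n_dilutions` must be >= 3")
  if (is.null(names(yields))) abort("`yields` must be named by compound")
  check_number(mu, "mu", lower = 0, strict = TRUE)
  withr::local_seed(seed)
  ods <- seq(od_range[2], od_range[1], length.out = n_dilutions)
  grid <- tidyr::expand_grid(dilution_level = seq_len(n_dilutions),
                             replicate = seq_len(n_replicates))
  grid$well <- well_names()[seq_len(nrow(grid))]
  grid$od600 <- ods[grid$dilution_level]
  layout <- tibble::tibble(
    plate_id = plate_id, well = grid$well, role = "sample",
    organism = organism, dilution_level = grid$dilution_level,
    conversion_factor = conversion_factor
  ) |> validate_plate_layout()
  conc <- tidyr::expand_grid(grid, compound = names(yields)) |>
    dplyr::mutate(
      biomass = .data$od600 * conversion_factor,
      medium_mm = unname(medium[.data$compound]),
      medium_mm = dplyr::coalesce(.data$medium_mm, 0),
      delta_true = unname(yields[.data$compound]) * .data$biomass,
      conc_mm = .data$medium_mm +
        .data$delta_true * lognormal_factor(dplyr::n(), noise_cv),
      plate_id = plate_id
    )
  list(
    concentrations = conc[c("plate_id", "well", "od600", "compound", "conc_mm")],
    layout = layout,
    growth = tibble::tibble(organism = organism, mu = mu),
    truth = list(q = yields * mu, yields = yields, mu = mu,
                 medium = medium, seed = seed)
  )
}

#' Simulate measured MDVs of labeled fragments
#'
#' Forward-folds known backbone labeling distributions through each
#' fragment's natural-abundance correction matrix, adds truncated-normal
#' noise and renormalizes, emulating GC-MS MDV measurements of replicate
#' wells.
#'
#' @param library Validated fragment-library tibble.
#' @param backbone_mdvs Named list: fragment -> backbone MDV of length
#'   `n_backbone + 1`. Default: unlabeled (all mass in M+0).
#' @param noise_sd Additive noise SD on fractions (default 0.003),
#'   truncated at zero.
#' @param n_replicates Number of replicate samples (default 3).
#' @param seed Integer seed.
#' @param abundances Isotope-abundance list.
#' @return List: `mdvs` (long tibble `sample`, `fragment`, `mass_offset`,
#'   `fraction`), `truth` (backbone and noiseless measured MDVs).
#' @export
simulate_labeled_mdvs <- function(library, backbone_mdvs = NULL,
                                  noise_sd = 0.003, n_replicates = 3,
                                  seed = 0, abundances = isotope_abundances()) {
  library <- validate_fragment_library(library)
  withr::local_seed(seed)
  if (is.null(backbone_mdvs)) {
    backbone_mdvs <- lapply(seq_len(nrow(library)), function(i) {
      c(1, numeric(library$n_backbone[i]))
    })
    names(backbone_mdvs) <- library$name
  }
  unknown <- setdiff(names(backbone_mdvs), library$name)
  if (length(unknown) > 0) {
    abort(paste0("fragment(s) not in library: ", paste(unknown, collapse = ", ")))
  }
  rows <- list(); measured_true <- list()
  for (nm in names(backbone_mdvs)) {
    i <- match(nm, library$name)
    x <- backbone_mdvs[[nm]]
    if (length(x) != library$n_backbone[i] + 1L) {
      abort(sprintf("backbone MDV for %s must have length %d", nm,
                    library$n_backbone[i] + 1L))
    }
    x <- x / sum(x)
    mat <- build_correction_matrix(library$elements[[i]], library$n_backbone[i],
                                   abundances)
    mt <- as.numeric(unclass(mat) %*% x)
    mt <- mt / sum(mt)
    measured_true[[nm]] <- mt
    for (r in seq_len(n_replicates)) {
      noisy <- pmax(mt + rnorm(length(mt), sd = noise_sd), 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = sprintf("rep%02d", r), fragment = nm,
        mass_offset = seq_along(mt) - 1L, fraction = noisy / sum(noisy)
      )
    }
  }
  list(
    mdvs = dplyr::bind_rows(rows),
    truth = list(backbone_mdvs = lapply(backbone_mdvs, function(x) x / sum(x)),
                 measured_true = measured_true, noise_sd = noise_sd, seed = seed)
  )
}

#' Simulate a wells-by-features intensity matrix
#'
#' Lognormal feature intensities with per-feature CVs drawn from
#' `cv_profile`, optionally with whole-well outliers scaled by a constant
#' factor — the shape of replicate metabolomics/proteomics plate data used
#' by the QC statistics.
#'
#' @param n_wells Number of replicate wells (>= 4 when outlier detection is
#'   to be run; default 21).
#' @param n_features Number of features (default 100).
#' @param cv_profile Vector of relative SDs features are sampled from
#'   (default 0.1).
#' @param n_outliers Number of outlier wells (default 0).
#' @param outlier_factor Multiplicative scale of outlier wells (default 10).
#' @param seed Integer seed.
#' @return List: `matrix` (wells x features, well rownames), `truth`
#'   (outlier wells, per-feature CVs).
#' @export
simulate_feature_matrix <- function(n_wells = 21, n_features = 100,
                                    cv_profile = 0.1, n_outliers = 0,
                                    outlier_factor = 10, seed = 0) {
  if (n_wells < 2) abort("`n_wells` must be >= 2")
  withr::local_seed(seed)
  base <- exp(rnorm(n_features, mean = log(1000), sd = 1))
  cvs <- rep(cv_profile, length.out = n_features)
  m <- vapply(seq_len(n_features), function(j) {
    base[j] * lognormal_factor(n_wells, cvs[j])
  }, numeric(n_wells))
  rownames(m) <- well_names()[seq_len(n_wells)]
  colnames(m) <- sprintf("feature%03d", seq_len(n_features))
  outliers <- character(0)
  if (n_outliers > 0) {
    idx <- sample(n_wells, n_outliers)
    m[idx, ] <- m[idx, , drop = FALSE] * outlier_factor
    outliers <- rownames(m)[sort(idx)]
  }
  list(matrix = m,
       truth = list(outlier_wells = outliers, cv_true = cvs, seed = seed))
}
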