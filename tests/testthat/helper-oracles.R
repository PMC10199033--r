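# Independent oracles and small fixture builders used across the suite.

# Brute-force isotopologue distribution: enumerate every per-atom isotope
# assignment, multiply abundances, bin by total mass offset. Tractable for
# formulas with <= 8 atoms; independent of the convolution implementation.
brute_isotopologue <- function(formula, abundances = isotope_abundances(),
                               k_max = 4) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  atoms <- rep(names(counts), counts)
  stopifnot(length(atoms) <= 8)
  grids <- lapply(atoms, function(el) seq_along(abundances[[el]]) - 1L)
  grid <- as.matrix(expand.grid(grids))
  prob <- rep(1, nrow(grid))
  for (a in seq_along(atoms)) {
    prob <- prob * abundances[[atoms[a]]][grid[, a] + 1L]
  }
  mass <- rowSums(grid)
  vapply(0:k_max, function(k) sum(prob[mass == k]), numeric(1))
}

# Single-well series tibble in the shape produced by assemble_well_series().
well_series_tbl <- function(time_h, od, well = "A1", plate_id = "p1",
                            role = "sample", organism = "E. coli",
                            conversion_factor = 2.06, corrected = FALSE) {
  out <- tibble::tibble(
    plate_id = plate_id, well = well, role = role, organism = organism,
    conversion_factor = conversion_factor, time_h = time_h, od600_raw = od,
    n_points = length(time_h), too_few_points = length(time_h) < 3
  )
  if (corrected) out$od600_corrected <- od
  out
}

# Minimal layout tibble.
layout_tbl <- function(wells, roles, plate_id = "p1", organism = "E. coli",
                       conversion_factor = 2.06) {
  tibble::tibble(
    plate_id = plate_id, well = wells, role = roles,
    organism = ifelse(roles == "sample", organism, NA_character_),
    dilution_level = NA_real_,
    conversion_factor = ifelse(roles == "sample", conversion_factor, NA_real_)
  )
}

# Long readings tibble from per-well value vectors.
readings_tbl <- function(time_h, values_by_well, channel = "OD600",
                         plate_id = "p1") {
  purrr::imap_dfr(values_by_well, function(v, w) {
    tibble::tibble(plate_id = plate_id, well = w, time_h = time_h,
                   channel = channel, value = v)
  })
}
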