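# Readers, writers and validators for the plate-level tables: layouts,
# optical readings, and GC-MS fragment libraries. All readers return plain
# tibbles validated against the declared invariants; validation errors name
# the offending record and never silently repair.

plate_roles <- c("sample", "growth_control", "contamination_control", "volume_control")
plate_channels <- c("OD450", "OD600")

#' Validate a plate-layout table
#'
#' A layout maps wells of an 8 x 12 plate to roles (`sample`,
#' `growth_control`, `contamination_control`, `volume_control`), organisms,
#' dilution levels and OD600-to-biomass conversion factors
#' (gDW L^-1 OD600^-1). Optional fields may be `NA`.
#'
#' @param layout Data frame with columns `plate_id`, `well`, `role`,
#'   `organism`, `dilution_level`, `conversion_factor`.
#' @return The validated layout as a tibble, invisibly usable in pipes.
#' @export
validate_plate_layout <- function(layout) {
  layout <- tibble::as_tibble(layout)
  required <- c("plate_id", "well", "role", "organism", "dilution_level", "conversion_factor")
  missing <- setdiff(required, names(layout))
  if (length(missing) > 0) {
    abort(paste0("layout is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_well <- layout$well[!is_valid_well(layout$well)]
  if (length(bad_well) > 0) {
    abort(paste0("invalid well coordinate(s): ", paste(unique(bad_well), collapse = ", ")))
  }
  dup <- layout |>
    dplyr::count(.data$plate_id, .data$well) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate well(s) in layout: ",
                 paste(paste0(dup$plate_id, ":", dup$well), collapse = ", ")))
  }
  bad_role <- setdiff(unique(layout$role), plate_roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", "),
                 "; expected one of ", paste(plate_roles, collapse = ", ")))
  }
  dl <- layout$dilution_level
  if (any(!is.na(dl) & dl <= 0)) abort("dilution_level must be > 0 where present")
  cf <- layout$conversion_factor
  if (any(!is.na(cf) & cf <= 0)) abort("conversion_factor must be > 0 where present")
  layout
}

#' Read a plate-layout CSV
#'
#' Expected header: `plate_id,well,role,organism,dilution_level,conversion_factor`.
#' Extra columns are preserved but ignored by downstream steps.
#'
#' @param path Path to the CSV file.
#' @return A validated layout tibble.
#' @export
read_plate_layout <- function(path) {
  layout <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("well" %in% names(layout)) layout$well <- as.character(layout$well)
  for (col in c("organism")) {
    if (col %in% names(layout)) layout[[col]] <- as.character(layout[[col]])
  }
  validate_plate_layout(layout)
}

#' Write a plate layout to CSV
#'
#' @param layout Layout tibble (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  readr::write_csv(validate_plate_layout(layout), path, progress = FALSE)
  invisible(path)
}

#' Validate a plate-reading table
#'
#' Long-format optical readings: one row per plate, well, timepoint and
#' channel (OD450 for the volume-loss dye, OD600 for biomass). Values must
#' be finite and timestamps strictly increasing within each
#' (plate, well, channel) series.
#'
#' @param readings Data frame with columns `plate_id`, `well`, `time_h`,
#'   `channel`, `value`.
#' @return The validated readings tibble, sorted by plate, well, time.
#' @export
validate_plate_readings <- function(readings) {
  readings <- tibble::as_tibble(readings)
  required <- c("plate_id", "well", "time_h", "channel", "value")
  missing <- setdiff(required, names(readings))
  if (length(missing) > 0) {
    abort(paste0("readings table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_chan <- setdiff(unique(readings$channel), plate_channels)
  if (length(bad_chan) > 0) {
    abort(paste0("unknown channel(s): ", paste(bad_chan, collapse = ", ")))
  }
  bad <- which(!is.finite(readings$value))
  if (length(bad) > 0) {
    abort(paste0("non-finite reading value(s) at record(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(!is.finite(readings$time_h)) || any(readings$time_h < 0)) {
    abort("time_h must be finite and >= 0")
  }
  nonmono <- readings |>
    dplyr::group_by(.data$plate_id, .data$well, .data$channel) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(nonmono) > 0) {
    abort(paste0("timestamps not strictly increasing for: ",
                 paste(paste0(nonmono$plate_id, ":", nonmono$well, ":", nonmono$channel),
                       collapse = ", ")))
  }
  dplyr::arrange(readings, .data$plate_id, .data$well, .data$time_h, .data$channel)
}

#' Read a plate-reading CSV
#'
#' Expected header: `plate_id,well,time_h,channel,value` with channel in
#' `OD450`/`OD600`. A `time_unit = "minutes"` flag converts timestamps to
#' hours on ingest; all downstream computation is in hours.
#'
#' @param path Path to the CSV file.
#' @param time_unit Unit of the time column, `"hours"` (default) or `"minutes"`.
#' @return A validated readings tibble sorted by (plate, well, time).
#' @export
read_plate_readings <- function(path, time_unit = c("hours", "minutes")) {
  time_unit <- match.arg(time_unit)
  readings <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_h" %in% names(readings) && "time" %in% names(readings)) {
    readings <- dplyr::rename(readings, time_h = "time")
  }
  if ("value" %in% names(readings) && !is.numeric(readings$value)) {
    suppressWarnings(readings$value <- as.numeric(readings$value))
  }
  if (time_unit == "minutes" && "time_h" %in% names(readings)) {
    readings$time_h <- readings$time_h / 60
  }
  validate_plate_readings(readings)
}

#' Write a plate-reading table to CSV
#'
#' @param readings Readings tibble (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_readings <- function(readings, path) {
  readr::write_csv(validate_plate_readings(readings), path, progress = FALSE)
  invisible(path)
}

#' Validate a fragment library
#'
#' @param library Data frame with columns `name`, `formula` (Hill notation),
#'   `n_backbone` (tracked amino-acid backbone carbons).
#' @return Tibble with an added list-column `elements` of parsed
#'   element-count vectors.
#' @export
validate_fragment_library <- function(library) {
  library <- tibble::as_tibble(library)
  required <- c("name", "formula", "n_backbone")
  missing <- setdiff(required, names(library))
  if (length(missing) > 0) {
    abort(paste0("fragment library is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(library$name)) abort("fragment names must be unique")
  library$n_backbone <- as.integer(library$n_backbone)
  if (any(is.na(library$n_backbone)) || any(library$n_backbone < 1)) {
    abort("n_backbone must be an integer >= 1")
  }
  library$elements <- lapply(library$formula, parse_formula)
  n_c <- vapply(library$elements, function(e) unname(e["C"] %|0|% 0), numeric(1))
  bad <- which(n_c < library$n_backbone)
  if (length(bad) > 0) {
    abort(paste0("n_backbone exceeds formula carbons for fragment(s): ",
                 paste(library$name[bad], collapse = ", ")))
  }
  library
}

`%|0|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Read a fragment-library TSV
#'
#' Tab-separated columns `name`, `formula`, `n_backbone`. The formula is the
#' complete elemental composition of the measured (derivatized) fragment ion;
#' `n_backbone` counts the amino-acid backbone carbons whose labeling is
#' tracked.
#'
#' @param path Path to the TSV file.
#' @return A validated fragment-library tibble with parsed `elements`.
#' @seealso [default_fragment_library()] for the TBDMS amino-acid set
#'   shipped with the package.
#' @export
read_fragment_library <- function(path) {
  library <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_fragment_library(library)
}

#' Write a fragment library to TSV
#'
#' @param library Fragment-library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_library <- function(library, path) {
  library <- validate_fragment_library(library)
  readr::write_tsv(library[c("name", "formula", "n_backbone")], path, progress = FALSE)
  invisible(path)
}

#' The TBDMS proteinogenic amino-acid fragment library
#'
#' [M-57] fragments of TBDMS-derivatized proteinogenic amino acids commonly
#' used for 13C labeling analysis by GC-MS. Formulas are the complete
#' fragment-ion compositions including the derivatization-agent atoms (Si,
#' extra C/H) that natural-abundance correction must remove.
#'
#' @return A validated fragment-library tibble.
#' @export
#' @examples
#' default_fragment_library()
default_fragment_library <- function() {
  path <- system.file("extdata", "tbdms_fragments.tsv", package = "plateomics")
  read_fragment_library(path)
}
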