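# Shared helpers: well coordinates, seeds, simple numeric utilities.

#' Well coordinates of an 8 x 12 microplate
#'
#' @param order `"row"` (A1, A2, ..., H12) or `"column"` (A1, B1, ..., H12).
#' @return Character vector of 96 well names.
#' @export
#' @examples
#' head(well_names())
well_names <- function(order = c("row", "column")) {
  order <- match.arg(order)
  if (order == "row") {
    as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  } else {
    as.vector(outer(LETTERS[1:8], 1:12, paste0))
  }
}

is_valid_well <- function(well) {
  grepl("^[A-H](?:[1-9]|1[0-2])$", well)
}

#' Split a well coordinate into row and column indices
#'
#' @param well Character vector of well names such as `"A1"`.
#' @return Tibble with columns `well`, `row` (1-8), `col` (1-12).
#' @export
well_position <- function(well) {
  bad <- well[!is_valid_well(well)]
  if (length(bad) > 0) {
    abort(paste0("invalid well coordinate(s): ", paste(unique(bad), collapse = ", ")))
  }
  tibble::tibble(
    well = well,
    row = match(substr(well, 1, 1), LETTERS),
    col = as.integer(substring(well, 2))
  )
}

# slope of y ~ x by least squares; NA when degenerate
ls_slope <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sxx
}

# r-squared of a simple linear fit; NA when y has no variance
ls_r2 <- function(x, y) {
  b <- ls_slope(x, y)
  if (is.na(b)) return(NA_real_)
  a <- mean(y) - b * mean(x)
  ss_res <- sum((y - a - b * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

# lognormal multiplicative noise with a given coefficient of variation
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (finite && any(!is.finite(x)))) {
    abort(paste0("`", name, "` must be finite numeric"))
  }
  if (strict && any(x <= lower)) abort(paste0("`", name, "` must be > ", lower))
  if (!strict && any(x < lower)) abort(paste0("`", name, "` must be >= ", lower))
  invisible(x)
}

#' Write a JSON run summary
#'
#' Records the parameters, package version and seed of an analysis run
#' alongside its CSV outputs.
#'
#' @param path Output file path.
#' @param ... Named parameters to record.
#' @param seed Seed used for any stochastic step (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, ..., seed = NULL) {
  info <- list(
    package = "plateomics",
    version = as.character(utils::packageVersion("plateomics")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    parameters = list(...)
  )
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
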