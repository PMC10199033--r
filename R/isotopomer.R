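# Theoretical isotopologue distributions, natural-abundance correction of
# mass-distribution vectors (MDVs) of derivatized fragments, and MDV
# comparison statistics.
#
# A measured fragment MDV mixes the tracer-derived labeling of the amino
# acid's backbone carbons with the natural heavy-isotope background of every
# other atom (H, N, O, Si from the TBDMS derivatization agent, non-backbone
# C, ...). The correction matrix maps a pure backbone labeling state j to
# the distribution the instrument would measure; solving the resulting
# linear system by nonnegative least squares recovers the backbone MDV.

# truncated convolution: (a * b)[1..len]
conv_trunc <- function(a, b, len) {
  n <- min(len, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0 || i > n) next
    jmax <- min(length(b), n - i + 1L)
    out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# distribution of n identical atoms, truncated at `len` mass offsets
element_distribution <- function(abund, n, len) {
  out <- 1
  for (i in seq_len(n)) out <- conv_trunc(out, abund, len)
  out
}

#' Theoretical natural-abundance isotopologue distribution
#'
#' Convolves the per-element multinomial isotopologue distributions of a
#' formula, truncated at mass offset `k_max`. The truncated probability mass
#' is reported as an attribute; by default the vector is renormalized to
#' sum 1.
#'
#' @param formula Formula string (Hill notation) or named element-count
#'   vector.
#' @param abundances Isotope-abundance list (default [isotope_abundances()]).
#' @param k_max Highest mass offset to keep (default 4).
#' @param normalize Renormalize after truncation (default `TRUE`).
#' @return Numeric vector of length `k_max + 1` (M+0 ... M+k_max), with
#'   attributes `mass_captured` (pre-normalization sum) and
#'   `truncated_mass`.
#' @export
#' @examples
#' natural_distribution("C1", k_max = 1)
natural_distribution <- function(formula, abundances = isotope_abundances(),
                                 k_max = 4, normalize = TRUE) {
  counts <- as_formula(formula)
  if (k_max < 0) abort("`k_max` must be >= 0")
  missing <- setdiff(names(counts), names(abundances))
  if (length(missing) > 0) {
    abort(paste0("element(s) missing from abundance table: ",
                 paste(missing, collapse = ", ")))
  }
  len <- k_max + 1L
  dist <- 1
  for (el in names(counts)) {
    dist <- conv_trunc(dist, element_distribution(abundances[[el]], counts[[el]], len), len)
  }
  dist <- c(dist, numeric(len - length(dist)))
  captured <- sum(dist)
  if (normalize) {
    if (captured <= 0) abort("all probability mass truncated; increase k_max")
    dist <- dist / captured
  }
  structure(dist, mass_captured = captured, truncated_mass = 1 - captured)
}

#' Natural-abundance correction matrix for a fragment
#'
#' Column `j` (j = 0 ... n_backbone) is the isotopologue distribution the
#' instrument measures when exactly `j` backbone carbons carry the tracer:
#' the natural distribution of the formula minus the backbone carbons,
#' convolved with `n_backbone - j` carbons at natural abundance, shifted up
#' by `j` mass units. Columns are unnormalized, so each sums to at most 1;
#' at the default mass window the truncated mass is below 1%.
#'
#' @param formula Fragment formula (string or named counts), including all
#'   derivatization atoms.
#' @param n_backbone Number of tracked backbone carbons (>= 1, at most the
#'   formula's carbon count).
#' @param abundances Isotope-abundance list.
#' @param k_max Highest measured mass offset (default `n_backbone + 4`).
#' @return `(k_max + 1) x (n_backbone + 1)` matrix of class
#'   `correction_matrix` (plain numeric matrix with attributes
#'   `n_backbone`, `column_mass` = per-column sums).
#' @export
build_correction_matrix <- function(formula, n_backbone,
                                    abundances = isotope_abundances(),
                                    k_max = n_backbone + 4) {
  counts <- as_formula(formula)
  n_backbone <- as.integer(n_backbone)
  if (n_backbone < 1) abort("`n_backbone` must be >= 1")
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_c < n_backbone) {
    abort(sprintf("n_backbone (%d) exceeds formula carbon count (%d)", n_backbone, n_c))
  }
  if (!"C" %in% names(abundances)) abort("element(s) missing from abundance table: C")
  residual <- counts
  residual["C"] <- residual["C"] - n_backbone
  residual <- residual[residual > 0]
  len <- k_max + 1L
  base <- if (length(residual) > 0) {
    as.numeric(natural_distribution(residual, abundances, k_max, normalize = FALSE))
  } else {
    c(1, numeric(k_max))
  }
  cdist <- abundances[["C"]]
  mat <- matrix(0, nrow = len, ncol = n_backbone + 1L)
  for (j in 0:n_backbone) {
    unlabeled <- element_distribution(cdist, n_backbone - j, len - j)
    col <- conv_trunc(base, unlabeled, len - j)
    mat[(j + 1L):(j + length(col)), j + 1L] <- col
  }
  rownames(mat) <- paste0("M+", 0:k_max)
  colnames(mat) <- paste0("x", 0:n_backbone)
  structure(mat, n_backbone = n_backbone, column_mass = colSums(mat),
            class = c("correction_matrix", class(mat)))
}

#' Correct a measured MDV for natural isotope abundance
#'
#' Solves `matrix %*% x ~= measured` by nonnegative least squares and
#' renormalizes `x` to sum 1, yielding the labeling distribution of the
#' backbone carbons. The residual norm of the solve is reported as a
#' diagnostic.
#'
#' @param measured Measured MDV (fractions over M+0 ... M+k; normalized
#'   internally); length must equal `nrow(matrix)`.
#' @param matrix Correction matrix from [build_correction_matrix()].
#' @return Numeric backbone MDV of length `n_backbone + 1`, with attribute
#'   `residual_norm`.
#' @export
correct_mdv <- function(measured, matrix) {
  if (length(measured) != nrow(matrix)) {
    abort(sprintf("dimension mismatch: measured MDV has %d masses, matrix %d rows",
                  length(measured), nrow(matrix)))
  }
  check_number(measured, "measured", lower = 0)
  s <- sum(measured)
  if (s <= 0) abort("measured MDV sums to zero")
  measured <- measured / s
  sol <- pracma::lsqnonneg(unclass(matrix), measured)
  x <- sol$x
  if (sum(x) <= 0) abort("degenerate correction: all coefficients zero")
  resid <- sqrt(sum((unclass(matrix) %*% x - measured)^2))
  structure(x / sum(x), residual_norm = resid)
}

#' Compare two MDVs in mol%
#'
#' @param a,b MDVs of equal length (fractions).
#' @return List: `deviation_molpct` (per-mass `100 * |a - b|`),
#'   `max_deviation_molpct`.
#' @export
compare_mdv <- function(a, b) {
  if (length(a) != length(b)) abort("MDV length mismatch")
  dev <- 100 * abs(a - b)
  list(deviation_molpct = dev, max_deviation_molpct = max(dev))
}

#' Theoretical MDV table for a fragment library
#'
#' Natural-abundance (unlabeled) distribution of every fragment, in the
#' long `fragment, mass_offset, fraction` schema.
#'
#' @param library Validated fragment-library tibble.
#' @param abundances Isotope-abundance list.
#' @param k_max Highest mass offset; default `n_backbone + 4` per fragment.
#' @return Long tibble `fragment`, `mass_offset`, `fraction`.
#' @export
theoretical_mdv_table <- function(library, abundances = isotope_abundances(),
                                  k_max = NULL) {
  library <- validate_fragment_library(library)
  purrr::map2_dfr(library$name, seq_len(nrow(library)), function(nm, i) {
    km <- k_max %||% (library$n_backbone[i] + 4L)
    mdv <- natural_distribution(library$elements[[i]], abundances, km)
    tibble::tibble(fragment = nm, mass_offset = 0:km, fraction = as.numeric(mdv))
  })
}

#' Correct a table of measured MDVs
#'
#' Applies [correct_mdv()] per (sample, fragment) of a long MDV table using
#' correction matrices built from a fragment library.
#'
#' @param mdvs Long tibble `sample`, `fragment`, `mass_offset`, `fraction`.
#' @param library Validated fragment-library tibble.
#' @param abundances Isotope-abundance list.
#' @return Long tibble `sample`, `fragment`, `mass_offset` (0 ...
#'   n_backbone), `fraction` (corrected backbone MDV), `residual_norm`.
#' @export
correct_mdv_table <- function(mdvs, library, abundances = isotope_abundances()) {
  library <- validate_fragment_library(library)
  mdvs <- tibble::as_tibble(mdvs)
  required <- c("sample", "fragment", "mass_offset", "fraction")
  missing <- setdiff(required, names(mdvs))
  if (length(missing) > 0) {
    abort(paste0("MDV table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(mdvs$fragment), library$name)
  if (length(unknown) > 0) {
    abort(paste0("fragment(s) not in library: ", paste(unknown, collapse = ", ")))
  }
  mats <- lapply(seq_len(nrow(library)), function(i) {
    build_correction_matrix(library$elements[[i]], library$n_backbone[i], abundances)
  })
  names(mats) <- library$name
  mdvs |>
    dplyr::group_by(.data$sample, .data$fragment) |>
    dplyr::group_modify(function(d, key) {
      mat <- mats[[key$fragment]]
      d <- dplyr::arrange(d, .data$mass_offset)
      if (!identical(as.integer(d$mass_offset), 0:(nrow(mat) - 1L))) {
        abort(sprintf("fragment %s of sample %s: mass offsets must be 0..%d",
                      key$fragment, key$sample, nrow(mat) - 1L))
      }
      x <- correct_mdv(d$fraction, mat)
      tibble::tibble(mass_offset = 0:(length(x) - 1L), fraction = as.numeric(x),
                     residual_norm = attr(x, "residual_norm"))
    }) |>
    dplyr::ungroup()
}

#' Replicate CV of MDV measurements
#'
#' Treats each (fragment, mass offset) as a feature across replicate
#' samples and delegates to [plate_cv()] semantics; entries whose mean
#' fraction falls below `floor` have undefined CV and are excluded from the
#' fraction-below-threshold denominator.
#'
#' @param mdvs Long tibble `sample`, `fragment`, `mass_offset`, `fraction`
#'   with >= 2 samples.
#' @param threshold_pct CV threshold in percent (default 20).
#' @param floor Minimum mean abundance for a defined CV (default 0.01).
#' @return A `plate_cv` object (see [plate_cv()]).
#' @export
labeling_cv <- function(mdvs, threshold_pct = 20, floor = 0.01) {
  mdvs <- tibble::as_tibble(mdvs)
  wide <- mdvs |>
    dplyr::mutate(feature = paste0(.data$fragment, ":M+", .data$mass_offset)) |>
    dplyr::select("sample", "feature", "fraction") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "fraction")
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$sample)
  if (nrow(m) < 2) abort("labeling CV requires at least 2 replicate samples")
  res <- plate_cv(m, threshold_pct)
  low <- res$cv$mean < floor
  res$cv$defined <- res$cv$defined & !low
  res$cv$cv_pct[!res$cv$defined] <- NA_real_
  def <- res$cv$defined
  res$fraction_below <- if (any(def)) mean(res$cv$cv_pct[def] < threshold_pct) else NA_real_
  res
}
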