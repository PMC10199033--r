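# Elemental formulas (Hill notation) and isotope-abundance tables.

# Element symbols accepted by the parser; covers biomolecules and common
# derivatization chemistry.
known_elements <- c(
  "C", "H", "N", "O", "P", "S", "Si", "Se", "F", "Cl", "Br", "I",
  "B", "Na", "K", "Ca", "Mg", "Fe", "Zn", "Cu", "Mn", "Co", "Mo", "D"
)

#' Parse an elemental formula in Hill notation
#'
#' `"C14H30NO2Si2"` parses to `c(C = 14, H = 30, N = 1, O = 2, Si = 2)`.
#' Counts default to 1; repeated symbols are summed. Unknown tokens raise an
#' error naming the offending text.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C11H26NO2Si2")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula) || formula == "") {
    abort("`formula` must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1 || covered != nchar(formula)) {
    rest <- formula
    for (tk in tokens) rest <- sub(tk, "", rest, fixed = TRUE)
    abort(paste0("unparseable formula token in '", formula, "': '", rest, "'"))
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  bad <- setdiff(syms, known_elements)
  if (length(bad) > 0) {
    abort(paste0("unparseable formula token in '", formula, "': '",
                 paste(bad, collapse = "', '"), "'"))
  }
  out <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  setNames(as.integer(out), names(out))
}

# Accept a formula string or a named count vector/list; returns counts > 0.
as_formula <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
    abort("formula must be a string or a named numeric vector of element counts")
  }
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    abort("element counts must be non-negative integers")
  }
  x <- x[x > 0]
  if (length(x) == 0) abort("formula is empty")
  setNames(as.integer(x), names(x))
}

#' Read an isotope-abundance table
#'
#' CSV with columns `element`, `mass_offset` (0, 1, 2, ... relative to the
#' lightest isotope) and `abundance`. Abundances of each element must sum to
#' 1 within 1e-6.
#'
#' @param path Path to the CSV file.
#' @return Named list: element -> numeric vector of abundances indexed by
#'   mass offset (position 1 = offset 0).
#' @export
read_isotope_abundances <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("element", "mass_offset", "abundance")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("abundance table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- lapply(split(tab, tab$element), function(d) {
    v <- numeric(max(d$mass_offset) + 1)
    v[d$mass_offset + 1] <- d$abundance
    v
  })
  bad <- names(out)[vapply(out, function(v) abs(sum(v) - 1) > 1e-6, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("isotope abundances do not sum to 1 for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Standard terrestrial isotope abundances
#'
#' The natural-abundance table shipped with the package (C, H, N, O, Si, S,
#' P); the basis of all theoretical isotopologue distributions and
#' correction matrices. Edit a copy and load it with
#' [read_isotope_abundances()] to use different values.
#'
#' @return Named list of per-element abundance vectors (mass offset 0, 1, ...).
#' @export
#' @examples
#' isotope_abundances()$C
isotope_abundances <- function() {
  read_isotope_abundances(
    system.file("extdata", "isotope_abundances.csv", package = "plateomics")
  )
}
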