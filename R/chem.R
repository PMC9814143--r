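#' @importFrom rlang .data abort warn %||%
#' @importFrom stats rexp rnorm rpois runif setNames
#' @importFrom utils head modifyList
NULL

# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA values),
# pinned as package data so results never depend on an external lookup.
.ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  D  = 2.01410177785
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- .ELEMENT_MASSES[["H"]] - .ELECTRON_MASS

# Supported singly-charged positive adducts: name -> mass added to the
# neutral molecule (adduct species mass minus one electron).
.ADDUCTS <- c(
  "[M+H]+"   = 1.00782503207 - 0.000548579909,
  "[M+NH4]+" = 14.0030740048 + 4 * 1.00782503207 - 0.000548579909,
  "[M+Na]+"  = 22.9897692809 - 0.000548579909
)

#' Parse an elemental formula string
#'
#' Parses Hill-like formula notation (`"C5H15NO4P"`) into a named integer
#' vector of element counts. A trailing `"+"` or `"-"` sets a unit charge,
#' stored as the `"charge"` attribute.
#'
#' @param text A single formula string. Element symbols must be present in
#'   the package element table (C, H, N, O, P, S, Na, K, Cl, D).
#' @return A named integer vector of counts with a `charge` attribute.
#' @examples
#' parse_formula("C5H15NO4P+")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text) || TRUE)
  charge <- 0L
  body <- text
  if (grepl("\\+$", body)) {
    charge <- 1L
    body <- sub("\\+$", "", body)
  } else if (grepl("-$", body)) {
    charge <- -1L
    body <- sub("-$", "", body)
  }
  counts <- integer(0)
  if (nzchar(body)) {
    toks <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
    if (sum(nchar(toks)) != nchar(body)) {
      abort(sprintf("Malformed formula string: '%s'", text))
    }
    for (tok in toks) {
      sym <- gsub("[0-9]", "", tok)
      num <- gsub("[A-Za-z]", "", tok)
      n <- if (nzchar(num)) as.integer(num) else 1L
      if (!sym %in% names(.ELEMENT_MASSES)) {
        abort(sprintf("Unknown element symbol '%s' in formula '%s'", sym, text))
      }
      cur <- if (sym %in% names(counts)) counts[[sym]] else 0L
      counts[sym] <- cur + n
    }
  }
  new_formula(counts, charge = charge)
}

new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0L]
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) {
    abort(sprintf(
      "Negative element count for %s",
      paste(names(counts)[counts < 0L], collapse = ", ")
    ))
  }
  structure(counts, charge = as.integer(charge), class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(new_formula(x))
  abort("Cannot interpret input as an elemental formula")
}

#' Format an elemental formula
#'
#' Serializes a formula in Hill order (C, H, then alphabetical), appending
#' `"+"`/`"-"` for unit charge. `parse_formula(format_formula(x))` is the
#' identity.
#'
#' @param x A formula (string or parsed).
#' @return A single string.
#' @export
format_formula <- function(x) {
  x <- as_formula(x)
  counts <- unclass(x)
  charge <- attr(x, "charge") %||% 0L
  syms <- names(counts)
  ord <- c(
    intersect(c("C", "H"), syms),
    sort(setdiff(syms, c("C", "H")))
  )
  body <- paste0(
    vapply(ord, function(s) {
      n <- counts[[s]]
      if (n == 1L) s else paste0(s, n)
    }, character(1)),
    collapse = ""
  )
  paste0(body, if (charge > 0L) "+" else if (charge < 0L) "-" else "")
}

#' Monoisotopic mass of a formula
#'
#' Sums per-element monoisotopic masses and subtracts `charge` electron
#' masses, so a `+1` formula gives the m/z of the cation directly.
#'
#' @param formula Formula string or parsed formula.
#' @return Mass in Da (m/z for charged formulas).
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C5H15NO4P+") # protonated phosphocholine head group
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  counts <- unclass(f)
  charge <- attr(f, "charge") %||% 0L
  sum(.ELEMENT_MASSES[names(counts)] * counts) - charge * .ELECTRON_MASS
}

#' Adduct m/z of a neutral molecule
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"` (singly
#'   charged positive adducts only).
#' @return m/z of the adduct ion.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (!adduct %in% names(.ADDUCTS)) {
    abort(sprintf(
      "Unsupported adduct '%s'. Supported: %s",
      adduct, paste(names(.ADDUCTS), collapse = ", ")
    ))
  }
  neutral_mass + .ADDUCTS[[adduct]]
}

#' Apply a signed formula delta
#'
#' Adds a delta (element -> signed count, e.g. a neutral-loss composition)
#' to a formula. Charge is preserved. Errors if any resulting count would be
#' negative.
#'
#' @param formula Base formula (string or parsed).
#' @param delta Named numeric vector of signed counts, or a formula whose
#'   counts are all added, or a string parsed as such.
#' @param sign `+1` to add, `-1` to subtract the delta.
#' @return The resulting parsed formula.
#' @export
apply_delta <- function(formula, delta, sign = 1L) {
  f <- as_formula(formula)
  if (is.character(delta)) delta <- unclass(as_formula(delta))
  if (inherits(delta, "elemental_formula")) delta <- unclass(delta)
  counts <- unclass(f)
  for (s in names(delta)) {
    if (!s %in% names(.ELEMENT_MASSES)) {
      abort(sprintf("Unknown element symbol '%s' in delta", s))
    }
    cur <- if (s %in% names(counts)) counts[[s]] else 0L
    counts[s] <- cur + sign * delta[[s]]
  }
  new_formula(counts, charge = attr(f, "charge") %||% 0L)
}

#' Parts-per-million mass error
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    abort("theoretical_mz must be positive")
  }
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}
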