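# Subclass registry: data-driven mapping from lipid subclass to head-group
# scaffold formula, chain count, default chain linkages, default adduct and
# head-group diagnostic ions. Shipped as a TSV so the vocabulary can be
# extended without code changes.

.registry_env <- new.env(parent = emptyenv())

load_subclass_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "subclasses.tsv", package = "lipidoad")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  dplyr::mutate(
    raw,
    n_chains = as.integer(.data$n_chains),
    chain_linkages = strsplit(.data$chain_linkages, ","),
    head_ions = purrr::map(.data$head_ions, parse_head_ion_spec)
  )
}

parse_head_ion_spec <- function(spec) {
  if (is.na(spec) || !nzchar(trimws(spec))) {
    return(tibble::tibble(type = character(), formula = character(), rel_intensity = numeric()))
  }
  entries <- strsplit(trimws(spec), ";")[[1]]
  parts <- strsplit(entries, ":")
  tibble::tibble(
    type = vapply(parts, `[[`, "", 1L),
    formula = vapply(parts, `[[`, "", 2L),
    rel_intensity = as.numeric(vapply(parts, `[[`, "", 3L))
  )
}

#' Lipid subclass registry
#'
#' Returns the registry of supported lipid subclasses: head-group scaffold
#' formula, expected chain count, default linkage per chain slot, default
#' adduct, and the head-group diagnostic ions used in reference spectra
#' (either a standalone product ion, e.g. the protonated phosphocholine head
#' at m/z 184.0733 for PC, or a neutral loss such as C2H8NO4P for PE).
#'
#' @param path Optional path to a replacement registry TSV.
#' @return A tibble with one row per subclass.
#' @export
subclass_registry <- function(path = NULL) {
  if (!is.null(path)) {
    return(load_subclass_registry(path))
  }
  if (is.null(.registry_env$registry)) {
    .registry_env$registry <- load_subclass_registry()
  }
  .registry_env$registry
}

registry_entry <- function(subclass) {
  reg <- subclass_registry()
  hit <- reg[reg$subclass == subclass, ]
  if (nrow(hit) == 0L) {
    abort(sprintf("Unknown lipid subclass '%s'", subclass))
  }
  hit
}

# Elemental contribution of one chain to the full lipid, as a signed count
# vector. Linkage chemistry:
#   ester/amide: fatty acid CcH(2c-2d)O2 condensed (- H2O) -> CcH(2c-2d-2)O
#   ether (O-):  alkyl substituent replacing H        -> CcH(2c-2d)
#   vinyl (P-):  1-alkenyl substituent (one extra C=C not in the db count)
#                -> CcH(2c-2d-2)
#   sphingoid:   free long-chain base CcH(2c+3-2d)N(Ooh)
# Each hydroxyl suffix (";O", ";O2") adds one O.
chain_contribution <- function(carbons, db, oh, linkage) {
  h <- switch(linkage,
    ester = ,
    amide = ,
    vinyl = 2L * carbons - 2L * db - 2L,
    ether = 2L * carbons - 2L * db,
    sphingoid = 2L * carbons + 3L - 2L * db,
    abort(sprintf("Unknown linkage '%s'", linkage))
  )
  o <- switch(linkage,
    ester = ,
    amide = 1L + oh,
    ether = ,
    vinyl = ,
    sphingoid = oh
  )
  n <- if (linkage == "sphingoid") 1L else 0L
  out <- c(C = carbons, H = h, O = o, N = n)
  out[out != 0]
}

#' Elemental formula of a lipid species
#'
#' Assembles the neutral molecular formula from the subclass scaffold plus
#' per-chain contributions (linkage-dependent condensation chemistry).
#'
#' @param species A `lipid_species` (from [parse_lipid_name()]).
#' @return A parsed `elemental_formula`.
#' @export
lipid_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  entry <- registry_entry(species$subclass)
  f <- as_formula(entry$scaffold[[1]])
  for (i in seq_len(nrow(species$chains))) {
    ch <- species$chains[i, ]
    f <- apply_delta(f, chain_contribution(ch$carbons, ch$db, ch$oh, ch$linkage))
  }
  f
}

#' Precursor m/z of a lipid species
#'
#' @param species A `lipid_species`.
#' @param adduct Adduct name; defaults to the species' own adduct, falling
#'   back to the subclass default (e.g. `[M+NH4]+` for TG).
#' @return Precursor m/z in Da.
#' @export
precursor_mz <- function(species, adduct = NULL) {
  adduct <- adduct %||% species$adduct
  if (is.null(adduct) || is.na(adduct)) {
    adduct <- registry_entry(species$subclass)$default_adduct[[1]]
  }
  adduct_mz(monoisotopic_mass(lipid_formula(species)), adduct)
}
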