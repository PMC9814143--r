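# In-silico OAD fragmentation. Oxygen attachment at a C=C cleaves the
# carbon backbone at one of three bonds around the double bond at n-x:
# bond_site -1 -> n-(x-1)_n-x, 0 -> the C=C itself, +1 -> n-(x+1)_n-(x+2).
# The lost neutral spans the methyl terminus through the cleaved bond: for k
# carbons lost containing u complete double bonds it is C_k H_(2k+1-2u),
# adjusted by the rule's hydrogen delta; oxygen-retaining rules keep one O
# on the charged fragment (net loss minus O); water-loss rules dehydrate the
# fragment further. For 18:1(n-9) the diagnostic pair is OAD03
# (NL C8H17 - O = 97.1381 Da) and OAD16 (NL C10H19 = 139.1487 Da).

.rules_env <- new.env(parent = emptyenv())

#' OAD fragmentation rule table
#'
#' The packaged 20-type rule set (OAD01..OAD20) applied per double bond,
#' plus the vinyl-ether special entries. Exactly two rules are flagged
#' diagnostic: the oxygen-retaining cleavage one bond methyl-side of the C=C
#' and the hydrocarbon-radical cleavage one bond carboxyl-side — the
#' "fragment pair" whose joint detection is required to call a position.
#'
#' @param path Optional replacement rule TSV with columns `rule_id`,
#'   `bond_site`, `hydrogen_delta`, `oxygen_delta`, `water_loss`,
#'   `rel_intensity`, `diagnostic`, `applicability`.
#' @return A tibble of fragmentation rules.
#' @export
oad_rule_table <- function(path = NULL) {
  read <- function(p) {
    readr::read_tsv(p, col_types = readr::cols(
      rule_id = readr::col_character(),
      bond_site = readr::col_integer(),
      hydrogen_delta = readr::col_integer(),
      oxygen_delta = readr::col_integer(),
      water_loss = readr::col_logical(),
      rel_intensity = readr::col_double(),
      diagnostic = readr::col_logical(),
      applicability = readr::col_character()
    ))
  }
  if (!is.null(path)) return(read(path))
  if (is.null(.rules_env$rules)) {
    .rules_env$rules <- read(system.file("extdata", "oad_rules.tsv", package = "lipidoad"))
  }
  .rules_env$rules
}

#' Rule subset for special fragmentation contexts
#'
#' The sphingoid delta-4 double bond and the vinyl-ether bond of plasmalogens
#' fragment differently from conventional acyl-chain C=C bonds; sphingoid
#' positions at delta-8 or deeper behave like ordinary acyl chains.
#'
#' @param context One of `"sphingoid_delta4"`, `"sphingoid_delta_ge8"`,
#'   `"vinyl_ether"`.
#' @return A tibble of applicable rules (with scaled intensities for the
#'   low-abundance delta-4 context).
#' @export
special_case_rules <- function(context = c("sphingoid_delta4", "sphingoid_delta_ge8", "vinyl_ether")) {
  context <- match.arg(context)
  rules <- oad_rule_table()
  switch(context,
    sphingoid_delta4 = {
      sub <- rules[rules$rule_id %in% c("OAD02", "OAD03", "OAD16", "OAD19"), ]
      sub$rel_intensity <- sub$rel_intensity * oad_config()$delta4_intensity_scale
      sub
    },
    sphingoid_delta_ge8 = rules[rules$applicability == "all", ],
    vinyl_ether = rules[rules$applicability == "vinyl_ether", ]
  )
}

# Neutral-loss mass for a cleavage: k carbons, h hydrogens, minus one O if
# the oxygen stays on the charged fragment, plus H2O if further dehydrated.
nl_mass_num <- function(k, h, oxygen_delta, water_loss) {
  k * .ELEMENT_MASSES[["C"]] + h * .ELEMENT_MASSES[["H"]] -
    oxygen_delta * .ELEMENT_MASSES[["O"]] +
    water_loss * (2 * .ELEMENT_MASSES[["H"]] + .ELEMENT_MASSES[["O"]])
}

#' Neutral loss of one OAD fragmentation event
#'
#' @param chain A list with `carbons`, `positions` (full integer vector of
#'   n-positions) and `linkage`, or one row of a species' chain table.
#' @param db_index Which double bond (1-based, methyl end first).
#' @param rule One row of [oad_rule_table()] (tibble row or list).
#' @return A list with `delta` (signed element counts of the net loss) and
#'   `mass` (Da).
#' @export
fragment_neutral_loss <- function(chain, db_index, rule) {
  positions <- chain$positions
  if (is.list(positions)) positions <- vapply(positions, `[[`, integer(1), 1L)
  if (length(positions) < db_index) {
    abort("Chain has no assigned position for the requested double bond")
  }
  if (identical(rule$applicability, "vinyl_ether") && !identical(chain$linkage, "vinyl")) {
    abort(sprintf("Rule %s applies only to vinyl-ether chains", rule$rule_id))
  }
  x <- positions[db_index]
  k <- x + rule$bond_site
  u <- sum(positions + 1L <= k)
  h <- 2L * k + 1L - 2L * u + rule$hydrogen_delta
  if (k < 1L || k > chain$carbons - 1L || h < 0L) {
    abort(sprintf(
      "Rule %s not applicable at n-%d on a %d-carbon chain",
      rule$rule_id, x, chain$carbons
    ))
  }
  delta <- c(
    C = k,
    H = h + 2L * rule$water_loss,
    O = rule$water_loss - rule$oxygen_delta
  )
  list(
    delta = delta[delta != 0],
    mass = nl_mass_num(k, h, rule$oxygen_delta, rule$water_loss)
  )
}

# Diagnostic-pair neutral losses as a vectorized closed form. Under the
# methylene-interruption invariant, the number of complete double bonds in
# the lost fragment depends only on the bond index i: u = i - 1 for the
# methyl-side cleavage, u = i for the carboxyl-side one.
diagnostic_pair_nl <- function(position, db_index) {
  x <- position; i <- db_index
  list(
    nl03 = nl_mass_num(x - 1L, 2L * (x - 1L) + 1L - 2L * (i - 1L), 1L, FALSE),
    nl16 = nl_mass_num(x + 1L, 2L * (x + 1L) + 1L - 2L * i, 0L, FALSE)
  )
}

# All fragment ions of one chain with fully assigned positions, as neutral
# losses from the precursor. Returns a tibble with one row per (db, rule).
chain_fragment_ions <- function(carbons, positions, linkage, config = oad_config()) {
  rules <- oad_rule_table()
  std <- rules[rules$applicability == "all", ]
  out <- list()
  if (length(positions) > 0) {
    for (i in seq_along(positions)) {
      x <- positions[i]
      is_d4 <- linkage == "sphingoid" && (carbons - x) == 4L
      rr <- if (is_d4) special_case_rules("sphingoid_delta4") else std
      k <- x + rr$bond_site
      u <- vapply(k, function(kk) sum(positions + 1L <= kk), integer(1))
      h <- 2L * k + 1L - 2L * u + rr$hydrogen_delta
      ok <- k >= 1L & k <= carbons - 1L & h >= 0L
      out[[length(out) + 1L]] <- tibble::tibble(
        rule_id = rr$rule_id[ok],
        db_index = i,
        position = x,
        nl_mass = nl_mass_num(k[ok], h[ok], rr$oxygen_delta[ok], rr$water_loss[ok]),
        rel_intensity = rr$rel_intensity[ok],
        diagnostic = rr$diagnostic[ok],
        delta4 = is_d4
      )
    }
  }
  if (linkage == "vinyl") {
    # implicit delta-1 double bond of the 1-alkenyl ether, at n-(C-1)
    ve <- special_case_rules("vinyl_ether")
    x <- carbons - 1L
    k <- x + ve$bond_site
    u <- vapply(k, function(kk) sum(positions + 1L <= kk), integer(1))
    h <- 2L * k + 1L - 2L * u + ve$hydrogen_delta
    ok <- k >= 1L & k <= carbons - 1L & h >= 0L
    out[[length(out) + 1L]] <- tibble::tibble(
      rule_id = ve$rule_id[ok],
      db_index = NA_integer_,
      position = x,
      nl_mass = nl_mass_num(k[ok], h[ok], ve$oxygen_delta[ok], ve$water_loss[ok]),
      rel_intensity = ve$rel_intensity[ok],
      diagnostic = FALSE,
      delta4 = FALSE
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      rule_id = character(), db_index = integer(), position = integer(),
      nl_mass = numeric(), rel_intensity = numeric(),
      diagnostic = logical(), delta4 = logical()
    ))
  }
  dplyr::bind_rows(out)
}

first_positions <- function(pos_list) {
  vapply(pos_list, function(v) as.integer(v[[1]]), integer(1))
}

head_group_peaks <- function(species, prec_mz, adduct) {
  entry <- registry_entry(species$subclass)
  ions <- entry$head_ions[[1]]
  if (nrow(ions) == 0) {
    return(tibble::tibble(mz = numeric(), rel_intensity = numeric(), label = character()))
  }
  mz <- numeric(nrow(ions))
  for (i in seq_len(nrow(ions))) {
    if (ions$type[i] == "ion") {
      mz[i] <- monoisotopic_mass(ions$formula[i])
    } else {
      nl <- monoisotopic_mass(ions$formula[i])
      if (adduct == "[M+NH4]+") nl <- nl + monoisotopic_mass("NH3")
      mz[i] <- prec_mz - nl
    }
  }
  tibble::tibble(
    mz = mz,
    rel_intensity = ions$rel_intensity,
    label = paste0("head:", ions$type, ":", ions$formula)
  )
}

#' Generate the in-silico OAD reference spectrum of a lipid
#'
#' Produces the theoretical OAD-MS/MS spectrum of a C=C-resolved lipid:
#' per-double-bond fragment ions from the rule table for every chain,
#' subclass head-group ions from the registry, and the precursor ion.
#' Every unsaturated chain must carry a complete position assignment.
#' Peaks closer than `config$merge_tol_da` are merged keeping the larger
#' intensity. The result carries the full per-ion annotation table in the
#' `"ions"` attribute and the precursor m/z in `"precursor_mz"`.
#'
#' @param species A `lipid_species` with full positions.
#' @param adduct Adduct override (default: species adduct or subclass
#'   default).
#' @param config See [oad_config()].
#' @return A tibble of (`mz`, `rel_intensity`, `label`, ...) sorted by m/z,
#'   of class `oad_spectrum`.
#' @export
generate_reference_spectrum <- function(species, adduct = NULL, config = oad_config()) {
  stopifnot(inherits(species, "lipid_species"))
  adduct <- adduct %||% species$adduct
  if (is.null(adduct) || is.na(adduct)) {
    adduct <- registry_entry(species$subclass)$default_adduct[[1]]
  }
  ch <- species$chains
  unresolved <- ch$db > 0 & lengths(ch$positions) == 0
  if (any(unresolved)) {
    abort(sprintf(
      "Chain(s) %s have unresolved double-bond positions",
      paste(ch$chain_index[unresolved], collapse = ", ")
    ))
  }
  prec <- precursor_mz(species, adduct)

  frag <- purrr::map_dfr(seq_len(nrow(ch)), function(i) {
    ions <- chain_fragment_ions(
      ch$carbons[i], first_positions(ch$positions[[i]]), ch$linkage[i], config
    )
    if (nrow(ions) > 0) ions$chain_index <- i
    ions
  })
  peaks <- tibble::tibble(
    mz = prec, rel_intensity = config$precursor_intensity, label = "precursor",
    rule_id = NA_character_, chain_index = NA_integer_, db_index = NA_integer_,
    position = NA_integer_, diagnostic = FALSE, delta4 = FALSE, nl_mass = 0
  )
  hg <- head_group_peaks(species, prec, adduct)
  if (nrow(hg) > 0) {
    peaks <- dplyr::bind_rows(peaks, dplyr::mutate(
      hg,
      rule_id = NA_character_, chain_index = NA_integer_, db_index = NA_integer_,
      position = NA_integer_, diagnostic = FALSE, delta4 = FALSE, nl_mass = NA_real_
    ))
  }
  if (nrow(frag) > 0) {
    peaks <- dplyr::bind_rows(peaks, tibble::tibble(
      mz = prec - frag$nl_mass,
      rel_intensity = frag$rel_intensity,
      label = paste0(frag$rule_id, ":chain", frag$chain_index, ":n-", frag$position),
      rule_id = frag$rule_id, chain_index = frag$chain_index,
      db_index = frag$db_index, position = frag$position,
      diagnostic = frag$diagnostic, delta4 = frag$delta4, nl_mass = frag$nl_mass
    ))
  }
  peaks <- peaks[peaks$mz > 0, ]
  ions <- dplyr::arrange(peaks, .data$mz)
  merged <- merge_peaks(ions, config$merge_tol_da)
  structure(
    merged,
    ions = ions,
    precursor_mz = prec,
    adduct = adduct,
    name = serialize_lipid_name(species),
    class = c("oad_spectrum", class(merged))
  )
}

# Merge peaks within tol, summing intensities (two double bonds that emit
# the same fragment both contribute ion current); the annotation of the
# diagnostic/most-intense contributor is kept for the merged row.
merge_peaks <- function(peaks, tol) {
  if (nrow(peaks) <= 1) return(peaks)
  peaks <- dplyr::arrange(peaks, .data$mz)
  cluster <- cumsum(c(1, diff(peaks$mz) > tol))
  total <- vapply(split(peaks$rel_intensity, cluster), sum, numeric(1))
  peaks$.cluster <- cluster
  out <- peaks |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::arrange(dplyr::desc(.data$diagnostic), dplyr::desc(.data$rel_intensity), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$mz)
  out$rel_intensity <- unname(total[as.character(out$.cluster)])
  out <- dplyr::select(out, -".cluster")
  out$rel_intensity <- out$rel_intensity / max(out$rel_intensity)
  out
}

#' @export
print.oad_spectrum <- function(x, ...) {
  cat(sprintf(
    "<oad_spectrum> %s %s, precursor m/z %.4f, %d peaks\n",
    attr(x, "name") %||% "", attr(x, "adduct") %||% "", attr(x, "precursor_mz"), nrow(x)
  ))
  NextMethod()
}
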