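# LIPID MAPS-style shorthand parsing. Internally every C=C location is
# stored as an n-position (counted from the methyl terminus), because the
# OAD fragmentation rules are anchored at the methyl end. Delta-descriptions
# on input are converted via delta = carbons - n; sphingoid bases are
# re-serialized in delta-description per field convention.

.CHAIN_RE <- "^(?:([OPN])-)?([0-9]+):([0-9]+)(?:\\(([^()]*)\\))?(?:;O([0-9]*))?(?:\\(([^()]*)\\))?$"

#' Convert between n- and delta-descriptions of a double-bond position
#'
#' The n-position counts from the methyl (omega) terminus, the
#' delta-position from the carboxyl end: `delta = carbons - n`. The mapping
#' is its own inverse.
#'
#' @param carbons Chain length.
#' @param n_pos,delta_pos Position, `1 <= pos < carbons`.
#' @return The converted position.
#' @examples
#' n_to_delta(20, 6) # arachidonate n-6 is delta-14
#' delta_to_n(18, 4) # sphingosine delta-4 is n-14
#' @export
n_to_delta <- function(carbons, n_pos) {
  if (any(n_pos < 1 | n_pos >= carbons)) {
    abort("Position out of range: need 1 <= pos < carbons")
  }
  carbons - n_pos
}

#' @rdname n_to_delta
#' @export
delta_to_n <- function(carbons, delta_pos) {
  n_to_delta(carbons, delta_pos)
}

parse_position_block <- function(content, carbons, db, token) {
  content <- gsub("[[:space:]]", "", content)
  if (!nzchar(content)) {
    return(list(positions = list(), geometry = character()))
  }
  mode <- "delta"
  if (startsWith(content, "n-")) {
    mode <- "n"
    content <- sub("^n-", "", content)
  } else if (grepl("^[Δd]", content)) {
    content <- sub("^[Δd]", "", content)
  }
  entries <- strsplit(content, ",")[[1]]
  entries <- sub("^[Δd]", "", entries) # tolerate a repeated delta marker
  vals <- vector("list", length(entries))
  geom <- rep(NA_character_, length(entries))
  for (i in seq_along(entries)) {
    alts <- strsplit(entries[i], "&", fixed = TRUE)[[1]]
    g <- unique(stats::na.omit(stringr::str_match(alts, "([EZ])$")[, 2]))
    if (length(g) == 1L) geom[i] <- g
    nums <- sub("[EZ]$", "", alts)
    if (!all(grepl("^[0-9]+$", nums))) {
      abort(sprintf("Malformed position entry '%s' in chain token '%s'", entries[i], token))
    }
    v <- as.integer(nums)
    if (mode == "delta") v <- carbons - v
    vals[[i]] <- sort(unique(v))
  }
  ord <- order(vapply(vals, min, integer(1)))
  list(positions = vals[ord], geometry = geom[ord])
}

parse_acyl_chain <- function(token, default_linkage = "ester", strict = TRUE) {
  token <- trimws(token)
  m <- stringr::str_match(token, .CHAIN_RE)
  if (is.na(m[1, 1])) {
    abort(sprintf("Malformed chain token '%s'", token))
  }
  prefix <- m[1, 2]
  carbons <- as.integer(m[1, 3])
  db <- as.integer(m[1, 4])
  oh <- if (is.na(m[1, 6])) 0L else if (!nzchar(m[1, 6])) 1L else as.integer(m[1, 6])
  pos_raw <- if (!is.na(m[1, 5])) m[1, 5] else m[1, 7]

  linkage <- if (!is.na(prefix)) {
    switch(prefix, O = "ether", P = "vinyl", N = "amide")
  } else {
    default_linkage
  }
  pos <- if (!is.na(pos_raw)) {
    parse_position_block(pos_raw, carbons, db, token)
  } else {
    list(positions = list(), geometry = character())
  }
  chain <- list(
    carbons = carbons, db = db, oh = oh, linkage = linkage,
    positions = pos$positions, geometry = pos$geometry
  )
  validate_chain(chain, token, strict = strict)
  chain
}

validate_chain <- function(chain, token, strict = TRUE) {
  if (chain$carbons < 2L) abort(sprintf("Chain '%s': need >= 2 carbons", token))
  np <- length(chain$positions)
  if (np > 0L && np != chain$db) {
    abort(sprintf(
      "Chain '%s': %d position(s) declared for %d double bond(s)",
      token, np, chain$db
    ))
  }
  if (np > 0L && strict) {
    p <- vapply(chain$positions, min, integer(1))
    if (any(p < 3L) || any(vapply(chain$positions, max, integer(1)) > chain$carbons - 2L)) {
      abort(sprintf(
        "Chain '%s': positions outside the supported range n-3 .. n-%d",
        token, chain$carbons - 2L
      ))
    }
    if (np > 1L && any(diff(p) < 2L)) {
      abort(sprintf("Chain '%s': conjugated double bonds (gap < 2) not supported", token))
    }
  }
  invisible(chain)
}

chains_to_tbl <- function(chains) {
  tibble::tibble(
    chain_index = seq_along(chains),
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    db = vapply(chains, `[[`, integer(1), "db"),
    oh = vapply(chains, `[[`, integer(1), "oh"),
    linkage = vapply(chains, `[[`, character(1), "linkage"),
    positions = lapply(chains, `[[`, "positions"),
    geometry = lapply(chains, `[[`, "geometry")
  )
}

#' Parse a shorthand lipid name
#'
#' Parses molecular-species or C=C-resolved shorthand names as found in
#' MS-DIAL alignment exports, e.g. `"PC 18:1_22:6"`,
#' `"PE P-18:0/18:1(n-9)"`, `"SM 18:1(Δ4);O2/18:1(n-9)"`, or
#' `"PE-N(FA 20:4(n-6,9,12,15)) 18:1(n-9)/18:1(n-9)"`. `"_"` between chains
#' marks unknown sn-order, `"/"` known order. Both `"Δ"` and `"d"` are
#' accepted as the delta marker; delta-positions are stored internally as
#' n-positions.
#'
#' @param text The lipid name.
#' @param adduct Optional adduct name attached to the species.
#' @param strict Enforce position-range invariants (n-3 .. n-(C-2), gap >= 2).
#' @return A `lipid_species` object.
#' @export
parse_lipid_name <- function(text, adduct = NULL, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) abort("Empty lipid name")

  head_chain <- NULL
  if (grepl("^PE-N ?\\(FA ", text)) {
    subclass <- "PE-N(FA)"
    inner_start <- regexpr("(", text, fixed = TRUE)
    depth <- 0L
    close_at <- NA_integer_
    chars <- strsplit(text, "")[[1]]
    for (i in seq(inner_start, length(chars))) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L) { close_at <- i; break }
      }
    }
    if (is.na(close_at)) abort(sprintf("Unbalanced parentheses in '%s'", text))
    inner <- substr(text, inner_start + 1L, close_at - 1L)
    head_chain <- parse_acyl_chain(sub("^FA ?", "", inner), "amide", strict = strict)
    rest <- trimws(substr(text, close_at + 1L, nchar(text)))
  } else {
    sp <- regexpr(" ", text, fixed = TRUE)
    if (sp < 0L) abort(sprintf("Cannot split subclass from chains in '%s'", text))
    subclass <- substr(text, 1L, sp - 1L)
    rest <- trimws(substr(text, sp + 1L, nchar(text)))
  }

  entry <- registry_entry(subclass)
  sep <- if (grepl("_", rest, fixed = TRUE)) "_" else "/"
  toks <- strsplit(rest, sep, fixed = TRUE)[[1]]
  defaults <- entry$chain_linkages[[1]]
  if (!is.null(head_chain)) defaults <- defaults[-1L] # amide slot consumed

  chains <- purrr::map2(
    toks, defaults[seq_along(toks)] %|na|% "ester",
    function(tok, lk) parse_acyl_chain(tok, lk, strict = strict)
  )
  if (!is.null(head_chain)) chains <- c(list(head_chain), chains)
  if (length(chains) != entry$n_chains) {
    abort(sprintf(
      "Subclass %s expects %d chain(s), got %d in '%s'",
      subclass, entry$n_chains, length(chains), text
    ))
  }
  new_lipid_species(subclass, chains, chain_order_known = sep == "/", adduct = adduct)
}

`%|na|%` <- function(x, y) { x[is.na(x)] <- y; x }

new_lipid_species <- function(subclass, chains, chain_order_known = FALSE, adduct = NULL) {
  structure(
    list(
      subclass = subclass,
      chains = chains_to_tbl(chains),
      chain_order_known = chain_order_known,
      adduct = adduct
    ),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species>", serialize_lipid_name(x), "\n")
  invisible(x)
}

format_position_block <- function(positions, geometry, carbons, sphingoid = FALSE) {
  if (length(positions) == 0L) return("")
  if (sphingoid) {
    deltas <- lapply(rev(positions), function(v) sort(carbons - v))
    geometry <- rev(geometry)
    body <- paste(
      purrr::map2_chr(deltas, geometry, function(v, g) {
        paste0(paste(v, collapse = "&"), if (!is.na(g)) g else "")
      }),
      collapse = ","
    )
    paste0("(Δ", body, ")")
  } else {
    body <- paste(
      purrr::map2_chr(positions, geometry, function(v, g) {
        paste0(paste(v, collapse = "&"), if (!is.na(g)) g else "")
      }),
      collapse = ","
    )
    paste0("(n-", body, ")")
  }
}

format_chain <- function(carbons, db, oh, linkage, positions, geometry,
                         default_linkage = "ester") {
  prefix <- switch(linkage,
    ether = "O-",
    vinyl = "P-",
    amide = if (default_linkage == "amide") "" else "N-",
    ""
  )
  pos <- format_position_block(positions, geometry, carbons, sphingoid = linkage == "sphingoid")
  ohs <- if (oh == 0L) "" else if (oh == 1L) ";O" else paste0(";O", oh)
  paste0(prefix, carbons, ":", db, pos, ohs)
}

#' Serialize a lipid species to shorthand text
#'
#' Emits n-description for acyl chains and delta-description for sphingoid
#' bases; ambiguous position alternatives are joined with `"&"`
#' (e.g. `"(n-3&6)"`). `parse_lipid_name(serialize_lipid_name(x))`
#' round-trips for valid species.
#'
#' @param species A `lipid_species`.
#' @param pc_plasmalogen_as_ether If `TRUE`, PC vinyl-ether (P-) chains are
#'   demoted to ether (O-) notation with the vinyl double bond folded into
#'   the count, reflecting the reduced confidence convention for PC
#'   plasmalogens. Not round-trip-safe; off by default.
#' @return The shorthand name.
#' @export
serialize_lipid_name <- function(species, pc_plasmalogen_as_ether = FALSE) {
  stopifnot(inherits(species, "lipid_species"))
  entry <- registry_entry(species$subclass)
  defaults <- entry$chain_linkages[[1]]
  ch <- species$chains
  toks <- character(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    carbons <- ch$carbons[i]; db <- ch$db[i]; linkage <- ch$linkage[i]
    positions <- ch$positions[[i]]; geometry <- ch$geometry[[i]]
    if (pc_plasmalogen_as_ether && species$subclass == "PC" && linkage == "vinyl") {
      linkage <- "ether"; db <- db + 1L
      positions <- list(); geometry <- character()
    }
    toks[i] <- format_chain(carbons, db, ch$oh[i], linkage, positions, geometry,
                            default_linkage = defaults[i] %|na|% "ester")
  }
  sep <- if (species$chain_order_known) "/" else "_"
  if (species$subclass == "PE-N(FA)") {
    paste0("PE-N(FA ", toks[1], ") ", paste(toks[-1], collapse = sep))
  } else {
    paste(species$subclass, paste(toks, collapse = sep))
  }
}
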