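# Core annotation: greedy per-chain resolution of C=C positions against a
# measured OAD-MS/MS spectrum. Chains are evaluated in decreasing
# double-bond-equivalent order; for each chain every enumerated candidate is
# screened for its essential diagnostic pair, and survivors are ranked by
# reverse dot product of the in-silico spectrum (candidate ions plus the
# already-fixed context) against the measured spectrum.

#' Annotate C=C positions of one lipid from its OAD spectrum
#'
#' @param species A `lipid_species` at the molecular-species level (from a
#'   CID-level annotation, e.g. `parse_lipid_name("PC 18:1_22:6")`). Chains
#'   with declared positions are kept fixed.
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param config See [oad_config()].
#' @param adduct Optional adduct override.
#' @return An `oad_annotation` object: resolved name, status (`resolved`,
#'   `ambiguous`, `chain-unresolved`, or `unresolved`), reverse dot-product
#'   score, per-chain candidate statistics, surviving candidates, and the
#'   matched diagnostic ions with ppm errors.
#' @export
annotate_spectrum <- function(species, measured, config = oad_config(), adduct = NULL) {
  stopifnot(inherits(species, "lipid_species"))
  meas <- as_peak_tbl(measured)
  base <- if (nrow(meas) > 0) max(meas$intensity) else 0
  adduct <- adduct %||% species$adduct
  if (is.null(adduct) || is.na(adduct)) {
    adduct <- registry_entry(species$subclass)$default_adduct[[1]]
  }
  prec <- precursor_mz(species, adduct)
  chains <- species$chains
  ord <- chain_evaluation_order(species)

  # context for per-chain screening: precursor + head-group ions + ions of
  # chains whose positions were declared on input. Chains searched here are
  # scored against this context only; conditioning on the other searched
  # chains happens in the joint refinement, because ions of one chain can
  # alias a candidate of another (the neutral loss depends only on the
  # methyl-end position and the bond index, not on the carrying chain).
  context <- tibble::tibble(mz = prec, rel_intensity = config$precursor_intensity)
  hg <- head_group_peaks(species, prec, adduct)
  if (nrow(hg) > 0) context <- dplyr::bind_rows(context, hg[, c("mz", "rel_intensity")])
  for (i in seq_len(nrow(chains))) {
    if (chains$db[i] > 0 && length(chains$positions[[i]]) > 0) {
      ions <- chain_fragment_ions(chains$carbons[i], first_positions(chains$positions[[i]]),
                                  chains$linkage[i], config)
      context <- dplyr::bind_rows(context,
        tibble::tibble(mz = prec - ions$nl_mass, rel_intensity = ions$rel_intensity))
    } else if (chains$linkage[i] == "vinyl") {
      ions <- chain_fragment_ions(chains$carbons[i], integer(0), chains$linkage[i], config)
      context <- dplyr::bind_rows(context,
        tibble::tibble(mz = prec - ions$nl_mass, rel_intensity = ions$rel_intensity))
    }
  }

  chain_rows <- list()
  status <- "resolved"
  tied_sets <- list() # per searched chain: the score-tied candidate matrices
  for (ci in ord) {
    if (chains$db[ci] == 0 || length(chains$positions[[ci]]) > 0) next
    cands <- enumerate_positions(chains$carbons[ci], chains$db[ci],
                                 config$min_pos, config$max_offset, config$min_gap)
    n_cand <- nrow(cands)
    if (n_cand == 0) { status <- "unresolved"; break }
    surv_idx <- which(screen_candidates(cands, chains$carbons[ci], chains$linkage[ci],
                                        meas, base, prec, config))
    if (length(surv_idx) == 0) {
      chain_rows[[length(chain_rows) + 1L]] <- tibble::tibble(
        chain_index = ci, carbons = chains$carbons[ci], db = chains$db[ci],
        n_candidates = n_cand, n_survivors = 0L,
        positions = NA_character_, ambiguous = FALSE
      )
      status <- "unresolved"
      break
    }
    scores <- vapply(surv_idx, function(r) {
      ions <- chain_fragment_ions(chains$carbons[ci], cands[r, ], chains$linkage[ci], config)
      ref <- dplyr::bind_rows(
        context,
        tibble::tibble(mz = prec - ions$nl_mass, rel_intensity = ions$rel_intensity)
      )
      ref <- merge_simple(ref, config$merge_tol_da)
      reverse_dot_product(meas, ref, config$tol_ppm)
    }, numeric(1))
    top <- max(scores)
    # candidate pool for joint refinement: a score window (not the bare tie
    # epsilon) because ions of other chains can distort single-chain scores
    # when fragments collide; final selection happens jointly
    pool <- surv_idx[top - scores <= config$joint_delta]
    if (length(pool) > config$joint_pool) {
      pool <- pool[order(-scores[match(pool, surv_idx)])][seq_len(config$joint_pool)]
    }
    pool <- sort(pool)
    tied_sets[[as.character(ci)]] <- cands[pool, , drop = FALSE]
    tied <- surv_idx[top - scores <= config$tie_epsilon]
    chosen <- cands[tied[1], ]
    chains$positions[[ci]] <- lapply(chosen, identity)
    chains$geometry[[ci]] <- rep(NA_character_, length(chosen))
    chain_rows[[length(chain_rows) + 1L]] <- tibble::tibble(
      chain_index = ci, carbons = chains$carbons[ci], db = chains$db[ci],
      n_candidates = n_cand, n_survivors = length(surv_idx),
      positions = NA_character_, ambiguous = FALSE
    )
  }

  any_ambiguous <- FALSE
  score <- NA_real_
  diagnostics <- NULL
  if (status != "unresolved") {
    # joint refinement: re-score the cross product of per-chain tied
    # candidates against the full reference spectrum; ions of one chain can
    # mimic a candidate of another, and only the joint view separates them
    joint <- refine_joint(chains, tied_sets, species, adduct, meas, config)
    chains <- joint$chains
    score <- joint$score
    any_ambiguous <- joint$ambiguous
    for (k in seq_along(chain_rows)) {
      ci <- chain_rows[[k]]$chain_index
      if (chain_rows[[k]]$n_survivors > 0) {
        slots <- chains$positions[[ci]]
        chain_rows[[k]]$positions <- paste(
          vapply(slots, paste, "", collapse = "&"), collapse = ","
        )
        chain_rows[[k]]$ambiguous <- any(lengths(slots) > 1L)
      }
    }
    first_only <- species
    first_only$chains <- chains
    first_only$chains$positions <- lapply(chains$positions, function(p) {
      lapply(p, function(v) v[[1]])
    })
    diag_tbl <- verify_essential_pair(meas, first_only, config, adduct = adduct)
    diagnostics <- dplyr::mutate(
      diag_tbl,
      ppm03 = ifelse(is.na(.data$rel03), NA_real_, nearest_ppm(.data$mz03, meas)),
      ppm16 = ifelse(is.na(.data$rel16), NA_real_, nearest_ppm(.data$mz16, meas))
    )
    if (joint$swap || (!species$chain_order_known && chain_swap_ambiguous(chains))) {
      status <- "chain-unresolved"
    } else if (any_ambiguous) {
      status <- "ambiguous"
    }
  }

  resolved <- species
  resolved$chains <- chains
  chain_detail <- if (length(chain_rows)) dplyr::bind_rows(chain_rows) else
    tibble::tibble(chain_index = integer(), carbons = integer(), db = integer(),
                   n_candidates = integer(), n_survivors = integer(),
                   positions = character(), ambiguous = logical())

  structure(
    list(
      input_name = serialize_lipid_name(species),
      species = resolved,
      name = if (status == "unresolved") NA_character_ else serialize_lipid_name(resolved),
      status = status,
      score = score,
      adduct = adduct,
      precursor_mz = prec,
      chain_detail = chain_detail,
      diagnostics = diagnostics,
      measured = meas
    ),
    class = "oad_annotation"
  )
}

# Re-score the cross product of per-chain candidate pools on the full
# in-silico spectrum and keep the joint assignment(s) with the best reverse
# dot product. Tied joints that are pure permutations of position sets
# among equal-DBE chains collapse to one pick flagged as a chain swap;
# genuinely different tied joints become "&" ambiguity sets per slot.
refine_joint <- function(chains, tied_sets, species, adduct, meas, config,
                         max_combos = 512L) {
  ids <- as.integer(names(tied_sets))
  sizes <- vapply(tied_sets, nrow, integer(1))
  assign_chains <- function(assignment) {
    ch <- chains
    for (k in seq_along(ids)) {
      ch$positions[[ids[k]]] <- lapply(tied_sets[[k]][assignment[k], ], identity)
    }
    ch
  }
  score_for <- function(assignment) {
    sp <- species
    sp$chains <- assign_chains(assignment)
    sp$chains$positions <- lapply(sp$chains$positions, function(p) lapply(p, `[[`, 1L))
    ref <- generate_reference_spectrum(sp, adduct = adduct, config = config)
    reverse_dot_product(meas, ref, config$tol_ppm)
  }
  if (length(ids) == 0 || prod(sizes) == 1L) {
    sp <- species
    sp$chains <- chains
    sp$chains$positions <- lapply(chains$positions, function(p) lapply(p, `[[`, 1L))
    ref <- generate_reference_spectrum(sp, adduct = adduct, config = config)
    return(list(chains = chains, ambiguous = FALSE, swap = FALSE,
                score = reverse_dot_product(meas, ref, config$tol_ppm)))
  }
  if (prod(sizes) > max_combos) {
    # too many joints to expand: report the union per slot as ambiguous
    for (k in seq_along(ids)) {
      m <- tied_sets[[k]]
      chains$positions[[ids[k]]] <- lapply(seq_len(ncol(m)), function(j) sort(unique(m[, j])))
    }
    return(list(chains = chains, ambiguous = TRUE, swap = FALSE,
                score = score_for(rep(1L, length(ids)))))
  }
  combos <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  scores <- apply(combos, 1, score_for)
  top <- max(scores)
  tied <- which(top - scores <= config$tie_epsilon)

  # species-level key: per double-bond-count group, the sorted multiset of
  # position tuples; identical keys mean the tied joints differ only by
  # which chain carries which set (a chain swap, not positional ambiguity)
  joint_key <- function(assignment) {
    ch <- assign_chains(assignment)
    uns <- ch[ch$db > 0, ]
    keys <- vapply(split(uns$positions, uns$db), function(plist) {
      paste(sort(vapply(plist, function(p) paste(vapply(p, `[[`, 0L, 1L), collapse = ","), "")),
            collapse = "|")
    }, "")
    paste(names(keys), keys, sep = "=", collapse = ";")
  }
  keys <- vapply(tied, function(t) joint_key(combos[t, ]), "")
  if (length(unique(keys)) == 1L) {
    chains <- assign_chains(combos[tied[1], ])
    return(list(chains = chains, ambiguous = FALSE,
                swap = length(tied) > 1L, score = top))
  }
  for (k in seq_along(ids)) {
    m <- tied_sets[[k]][combos[tied, k], , drop = FALSE]
    chains$positions[[ids[k]]] <- lapply(seq_len(ncol(m)), function(j) sort(unique(m[, j])))
  }
  list(chains = chains, ambiguous = TRUE, swap = FALSE, score = top)
}

nearest_ppm <- function(mz_theo, meas) {
  idx <- nearest_index(mz_theo, meas$mz)
  (meas$mz[idx] - mz_theo) / mz_theo * 1e6
}

# A '_'-separated lipid whose equal-DBE chains resolve to different position
# sets cannot be chain-assigned: the swapped isomer yields the identical
# spectrum because OAD neutral losses depend only on the methyl-end position.
chain_swap_ambiguous <- function(chains) {
  uns <- chains[chains$db > 0, ]
  if (nrow(uns) < 2) return(FALSE)
  for (d in unique(uns$db)) {
    grp <- uns[uns$db == d, ]
    if (nrow(grp) < 2) next
    keys <- vapply(grp$positions, function(p) paste(vapply(p, paste, "", collapse = "&"), collapse = ","), "")
    if (length(unique(keys)) > 1) return(TRUE)
  }
  FALSE
}

# screen every candidate row for its diagnostic pair via a (position, bond
# index) pass grid; pair neutral losses depend only on that pair.
screen_candidates <- function(cands, carbons, linkage, meas, base, prec, config) {
  n <- nrow(cands); d <- ncol(cands)
  if (d == 0L) return(rep(TRUE, n))
  if (nrow(meas) == 0 || base <= 0) return(rep(FALSE, n))
  xs <- sort(unique(as.vector(cands)))
  pass_grid <- matrix(FALSE, max(xs), d)
  for (i in seq_len(d)) {
    nl <- diagnostic_pair_nl(xs, i)
    d4 <- linkage == "sphingoid" & (carbons - xs) == 4L
    thr <- ifelse(d4, config$min_rel_intensity_delta4, config$min_rel_intensity)
    ok03 <- peak_present(prec - nl$nl03, meas, base, thr, config$tol_ppm)
    ok16 <- peak_present(prec - nl$nl16, meas, base, thr, config$tol_ppm)
    pass_grid[xs, i] <- ok03 & ok16
  }
  pass_mat <- matrix(pass_grid[cbind(as.vector(cands), rep(seq_len(d), each = n))], n, d)
  if (config$require_pair_all_bonds) rowSums(pass_mat) == d else rowSums(pass_mat) >= 1L
}

peak_present <- function(mz_theo, meas, base, thr, tol_ppm) {
  idx <- nearest_index(mz_theo, meas$mz)
  hit <- !is.na(idx) & abs((meas$mz[idx] - mz_theo) / mz_theo * 1e6) <= tol_ppm
  hit & !is.na(idx) & (meas$intensity[pmax(idx, 1L)] / base) >= thr
}

merge_simple <- function(peaks, tol) {
  peaks <- dplyr::arrange(peaks, .data$mz)
  if (nrow(peaks) <= 1) return(peaks)
  cl <- cumsum(c(1, diff(peaks$mz) > tol))
  mzs <- vapply(split(seq_len(nrow(peaks)), cl), function(ii) {
    peaks$mz[ii[which.max(peaks$rel_intensity[ii])]]
  }, numeric(1))
  tibble::tibble(
    mz = mzs,
    rel_intensity = vapply(split(peaks$rel_intensity, cl), sum, numeric(1))
  )
}

#' @export
print.oad_annotation <- function(x, ...) {
  cat(sprintf(
    "<oad_annotation> %s -> %s [%s]%s\n",
    x$input_name, x$name %|na|% "(unresolved)", x$status,
    if (!is.na(x$score)) sprintf(" score %.4f", x$score) else ""
  ))
  invisible(x)
}
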