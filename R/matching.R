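# Peak matching, essential diagnostic-pair verification, and reverse
# dot-product scoring (steps 3-4 of the annotation algorithm).

as_peak_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mz") %in% names(x)))
    if (!"intensity" %in% names(x) && "rel_intensity" %in% names(x)) {
      x$intensity <- x$rel_intensity
    }
    return(dplyr::arrange(tibble::as_tibble(x[, c("mz", "intensity")]), .data$mz))
  }
  abort("Expected a data frame of peaks with columns mz and intensity")
}

# Nearest sorted-vector lookup: index of element of `sorted` closest to each
# x, or NA when `sorted` is empty.
nearest_index <- function(x, sorted) {
  n <- length(sorted)
  if (n == 0L) return(rep(NA_integer_, length(x)))
  i <- findInterval(x, sorted)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, n)
  ifelse(abs(x - sorted[lo]) <= abs(sorted[hi] - x), lo, hi)
}

#' Match reference peaks to a measured spectrum
#'
#' Each reference peak is matched to the nearest measured peak within the
#' ppm tolerance (at most one); unmatched peaks are retained with `NA`
#' match columns.
#'
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param reference Data frame of reference peaks (`mz`, and optionally
#'   `rel_intensity` plus annotation columns, e.g. an `oad_spectrum`).
#' @param tol_ppm Match tolerance in ppm (default 15).
#' @return The reference table with added `matched_mz`, `matched_intensity`,
#'   `ppm` columns.
#' @export
match_peaks <- function(measured, reference, tol_ppm = 15) {
  stopifnot(tol_ppm > 0)
  meas <- as_peak_tbl(measured)
  ref <- tibble::as_tibble(reference)
  idx <- nearest_index(ref$mz, meas$mz)
  matched_mz <- meas$mz[idx]
  matched_int <- meas$intensity[idx]
  ppm <- (matched_mz - ref$mz) / ref$mz * 1e6
  ok <- !is.na(ppm) & abs(ppm) <= tol_ppm
  ref$matched_mz <- ifelse(ok, matched_mz, NA_real_)
  ref$matched_intensity <- ifelse(ok, matched_int, NA_real_)
  ref$ppm <- ifelse(ok, ppm, NA_real_)
  ref
}

#' Verify the essential diagnostic fragment pair for every double bond
#'
#' For each assigned C=C the two pair ions (oxygen-retaining methyl-side
#' cleavage and hydrocarbon-radical carboxyl-side cleavage) must both be
#' present within the ppm tolerance and at or above the minimum relative
#' intensity (fraction of the base peak); sphingoid delta-4 bonds use the
#' lower delta-4 floor.
#'
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param species A `lipid_species` with full position assignments.
#' @param config See [oad_config()].
#' @param adduct Optional adduct override.
#' @return A tibble with one row per (chain, double bond): theoretical pair
#'   m/z values, matched intensities, and a `pass` flag.
#' @export
verify_essential_pair <- function(measured, species, config = oad_config(), adduct = NULL) {
  meas <- as_peak_tbl(measured)
  base <- if (nrow(meas) > 0) max(meas$intensity) else 0
  prec <- precursor_mz(species, adduct)
  ch <- species$chains
  rows <- list()
  for (i in seq_len(nrow(ch))) {
    if (ch$db[i] == 0) next
    pos <- first_positions(ch$positions[[i]])
    if (length(pos) == 0) {
      abort(sprintf("Chain %d has no position assignment", i))
    }
    d4 <- ch$linkage[i] == "sphingoid" & (ch$carbons[i] - pos) == 4L
    nl <- diagnostic_pair_nl(pos, seq_along(pos))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chain_index = i, db_index = seq_along(pos), position = pos,
      delta4 = d4, mz03 = prec - nl$nl03, mz16 = prec - nl$nl16
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      chain_index = integer(), db_index = integer(), position = integer(),
      delta4 = logical(), mz03 = numeric(), mz16 = numeric(),
      rel03 = numeric(), rel16 = numeric(), pass = logical()
    ))
  }
  tbl <- dplyr::bind_rows(rows)
  thr <- ifelse(tbl$delta4, config$min_rel_intensity_delta4, config$min_rel_intensity)
  rel_at <- function(mz_theo) {
    idx <- nearest_index(mz_theo, meas$mz)
    hit <- !is.na(idx) & abs((meas$mz[idx] - mz_theo) / mz_theo * 1e6) <= config$tol_ppm
    out <- rep(NA_real_, length(mz_theo))
    out[hit] <- meas$intensity[idx[hit]] / base
    out
  }
  tbl$rel03 <- rel_at(tbl$mz03)
  tbl$rel16 <- rel_at(tbl$mz16)
  tbl$pass <- !is.na(tbl$rel03) & !is.na(tbl$rel16) &
    tbl$rel03 >= thr & tbl$rel16 >= thr
  tbl
}

#' Reverse dot-product spectral similarity
#'
#' Cosine-type similarity computed over reference peaks only, with
#' square-root-transformed intensities: unmatched reference peaks contribute
#' zero measured weight, and measured peaks absent from the reference are
#' ignored. The score is in `[0, 1]`, equals 1 for a perfect copy, and is
#' invariant under uniform intensity scaling.
#'
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param reference Data frame of reference peaks (`mz`, `rel_intensity`).
#' @param tol_ppm Match tolerance in ppm.
#' @return Score in `[0, 1]`.
#' @export
reverse_dot_product <- function(measured, reference, tol_ppm = 15) {
  ref <- tibble::as_tibble(reference)
  if (nrow(ref) == 0) abort("Empty reference spectrum")
  if (!"rel_intensity" %in% names(ref)) {
    if ("intensity" %in% names(ref)) ref$rel_intensity <- ref$intensity
    else abort("Reference needs a rel_intensity (or intensity) column")
  }
  m <- match_peaks(measured, ref[, c("mz", "rel_intensity")], tol_ppm)
  w_ref <- sqrt(m$rel_intensity)
  w_meas <- sqrt(ifelse(is.na(m$matched_intensity), 0, m$matched_intensity))
  denom <- sum(w_meas^2) * sum(w_ref^2)
  if (denom == 0) return(0)
  (sum(w_meas * w_ref))^2 / denom
}

#' Rank C=C position candidates against a measured spectrum
#'
#' Verifies the essential diagnostic pair for every double bond of each
#' candidate species, scores the survivors by reverse dot product against
#' their in-silico reference spectra, and ranks them. Ties within
#' `config$tie_epsilon` of the top score are flagged.
#'
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param candidates A list of fully position-assigned `lipid_species`.
#' @param config See [oad_config()].
#' @return A tibble with columns `name`, `survived`, `score`, `rank`,
#'   `tied_top`, ordered by decreasing score.
#' @export
rank_candidates <- function(measured, candidates, config = oad_config()) {
  stopifnot(length(candidates) >= 1)
  res <- purrr::map_dfr(candidates, function(sp) {
    ver <- verify_essential_pair(measured, sp, config)
    survived <- if (config$require_pair_all_bonds) all(ver$pass) else any(ver$pass) || nrow(ver) == 0
    score <- NA_real_
    if (survived) {
      ref <- generate_reference_spectrum(sp, config = config)
      score <- reverse_dot_product(measured, ref, config$tol_ppm)
    }
    tibble::tibble(name = serialize_lipid_name(sp), survived = survived, score = score)
  })
  res <- dplyr::arrange(res, dplyr::desc(!is.na(.data$score)), dplyr::desc(.data$score))
  res$rank <- ifelse(res$survived, rank(-res$score, ties.method = "min", na.last = "keep"), NA_integer_)
  top <- suppressWarnings(max(res$score, na.rm = TRUE))
  res$tied_top <- res$survived & !is.na(res$score) & (top - res$score) <= config$tie_epsilon
  res
}
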