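# Batch pipeline: read CID-level molecular-species annotations (MS-DIAL
# alignment-export dialect) and OAD-MS/MS spectra (MGF or mzML), join them
# on precursor m/z and retention time, annotate, and write a tab-delimited
# report.

.DIALECT_DEFAULT <- list(
  lipid_name = c("Metabolite name", "Metabolite.name", "lipid_name", "Name", "name"),
  precursor_mz = c("Average Mz", "Average.Mz", "Precursor m/z", "precursor_mz", "Mz", "mz"),
  retention_time = c("Average Rt(min)", "Average.Rt.min.", "RT (min)", "retention_time", "Rt", "rt"),
  adduct = c("Adduct type", "Adduct.type", "adduct", "Adduct")
)

#' Read a molecular-species-level alignment table
#'
#' Reads a tab-delimited alignment export (MS-DIAL dialect). Column names
#' are resolved through a synonym mapping so different export versions can
#' be consumed; rows whose lipid name cannot be parsed are dropped with a
#' warning (count available as `attr(x, "n_skipped")`).
#'
#' @param path Path to the tab-delimited file.
#' @param dialect Optional named list mapping canonical column names
#'   (`lipid_name`, `precursor_mz`, `retention_time`, `adduct`) to accepted
#'   header synonyms; merged over the defaults.
#' @return A tibble with canonical columns plus `record_id`; extra input
#'   columns are passed through.
#' @export
read_alignment_table <- function(path, dialect = NULL) {
  dia <- .DIALECT_DEFAULT
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()))
  out <- tibble::as_tibble(raw)
  missing <- character()
  for (canon in names(dia)) {
    hit <- intersect(dia[[canon]], names(out))
    if (length(hit) == 0) {
      if (canon == "adduct") { out$adduct <- NA_character_; next }
      missing <- c(missing, canon)
      next
    }
    names(out)[names(out) == hit[1]] <- canon
  }
  if (length(missing) > 0) {
    abort(sprintf("Missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  ok <- vapply(out$lipid_name, function(nm) {
    !inherits(try(parse_lipid_name(nm), silent = TRUE), "try-error")
  }, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d record(s) with unparseable lipid names", n_skipped))
  }
  out <- out[ok, ]
  out$record_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "record_id")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an alignment table
#'
#' Inverse of [read_alignment_table()] (MS-DIAL-style headers).
#'
#' @param records Tibble with `lipid_name`, `precursor_mz`,
#'   `retention_time`, `adduct`.
#' @param path Output path.
#' @export
write_alignment_table <- function(records, path) {
  out <- dplyr::select(
    records,
    "Metabolite name" = "lipid_name",
    "Average Mz" = "precursor_mz",
    "Average Rt(min)" = "retention_time",
    "Adduct type" = "adduct"
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read OAD-MS/MS spectra
#'
#' Reads centroided MS2 spectra from MGF or (via the `mzR` package) mzML.
#' MGF spectra without a `PEPMASS` line are skipped with a warning;
#' retention times are converted to minutes.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"`, or `"mzml"`.
#' @return A tibble with one row per spectrum: `spectrum_id`, `title`,
#'   `precursor_mz`, `rt` (minutes, `NA` when absent), and a `peaks`
#'   list-column of (`mz`, `intensity`) tibbles.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "mzml"
  }
  if (format == "mgf") read_mgf(path) else read_mzml(path)
}

read_mgf <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("Malformed MGF: unbalanced BEGIN/END IONS")
  specs <- vector("list", length(starts))
  skipped <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    fields <- block[kv]
    keys <- toupper(sub("=.*", "", fields))
    vals <- sub("^[^=]*=", "", fields)
    pep <- vals[keys == "PEPMASS"]
    if (length(pep) == 0) {
      warn(sprintf("MGF spectrum %d has no PEPMASS; skipped", b))
      skipped <- skipped + 1L
      next
    }
    rts <- vals[keys == "RTINSECONDS"]
    title <- vals[keys == "TITLE"]
    pk <- block[!kv & nzchar(trimws(block))]
    mat <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
    peaks <- if (is.null(mat)) {
      tibble::tibble(mz = numeric(), intensity = numeric())
    } else {
      tibble::tibble(mz = as.numeric(mat[, 1]), intensity = as.numeric(mat[, 2]))
    }
    specs[[b]] <- tibble::tibble(
      title = if (length(title)) title[1] else NA_character_,
      precursor_mz = as.numeric(strsplit(pep[1], "[ \t]+")[[1]][1]),
      rt = if (length(rts)) as.numeric(rts[1]) / 60 else NA_real_,
      peaks = list(dplyr::arrange(peaks, .data$mz))
    )
  }
  out <- dplyr::bind_rows(specs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(title = character(), precursor_mz = numeric(),
                          rt = numeric(), peaks = list())
  }
  out$spectrum_id <- seq_len(nrow(out))
  dplyr::relocate(out, "spectrum_id")
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Reading mzML requires the mzR package")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms2 <- which(hdr$msLevel == 2)
  specs <- purrr::map(ms2, function(i) {
    pk <- mzR::peaks(ms, i)
    tibble::tibble(
      title = as.character(hdr$seqNum[i]),
      precursor_mz = hdr$precursorMZ[i],
      rt = hdr$retentionTime[i] / 60,
      peaks = list(tibble::tibble(mz = pk[, 1], intensity = pk[, 2]))
    )
  })
  out <- dplyr::bind_rows(specs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(title = character(), precursor_mz = numeric(),
                          rt = numeric(), peaks = list())
  }
  out$spectrum_id <- seq_len(nrow(out))
  dplyr::relocate(out, "spectrum_id")
}

#' Write spectra to MGF
#'
#' @param spectra Spectrum tibble as returned by [read_spectra()].
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  out <- character()
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    out <- c(
      out, "BEGIN IONS",
      sprintf("TITLE=%s", spectra$title[i] %|na|% sprintf("spectrum_%d", i)),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      if (!is.na(spectra$rt[i])) sprintf("RTINSECONDS=%.3f", spectra$rt[i] * 60),
      sprintf("%.6f %.4f", pk$mz, pk$intensity),
      "END IONS", ""
    )
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Pair CID-level records with OAD spectra
#'
#' Each alignment record is paired with the nearest-precursor spectrum
#' within both the m/z and RT windows (ties broken by smaller m/z, then RT
#' difference). Records without a partner keep `spectrum_id = NA` and will
#' receive status `no-spectrum` downstream. Spectra without RT are excluded
#' from RT-based joining.
#'
#' @param records Alignment tibble ([read_alignment_table()]).
#' @param spectra Spectrum tibble ([read_spectra()]).
#' @param mz_tol_da Precursor window in Da (default 0.01).
#' @param rt_tol_min RT window in minutes (default 0.15).
#' @return `records` with `spectrum_id` and a `peaks` list-column added.
#' @export
join_cid_oad <- function(records, spectra, mz_tol_da = 0.01, rt_tol_min = 0.15) {
  stopifnot(mz_tol_da > 0, rt_tol_min > 0)
  sid <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    dmz <- abs(spectra$precursor_mz - records$precursor_mz[i])
    drt <- abs(spectra$rt - records$retention_time[i])
    ok <- !is.na(drt) & dmz <= mz_tol_da & drt <= rt_tol_min
    if (!any(ok)) { sid[i] <- NA_integer_; next }
    cand <- which(ok)
    cand <- cand[order(dmz[cand], drt[cand])]
    sid[i] <- spectra$spectrum_id[cand[1]]
  }
  records$spectrum_id <- sid
  records$peaks <- lapply(sid, function(s) {
    if (is.na(s)) NULL else spectra$peaks[[match(s, spectra$spectrum_id)]]
  })
  records
}

#' Annotate a batch of paired records
#'
#' Runs the full enumeration -> in-silico spectrum -> diagnostic-pair
#' verification -> reverse dot-product ranking chain on every record.
#' Per-record failures are captured (status `error`) and the batch
#' continues; results are deterministic given identical inputs and config.
#'
#' @param paired Output of [join_cid_oad()] (needs `lipid_name`, `adduct`,
#'   `peaks`).
#' @param config See [oad_config()].
#' @return A results tibble, one row per input record, with the full
#'   `oad_annotation` objects in the `annotation` list-column.
#' @export
annotate_batch <- function(paired, config = oad_config()) {
  if (nrow(paired) == 0) {
    return(tibble::tibble(
      record_id = integer(), input_name = character(),
      resolved_name = character(), status = character(), score = numeric(),
      n_candidates = integer(), n_survivors = integer(),
      diagnostic_ions = character(), annotation = list()
    ))
  }
  rows <- vector("list", nrow(paired))
  for (i in seq_len(nrow(paired))) {
    rec <- paired[i, ]
    ann <- NULL
    if (is.null(rec$peaks[[1]])) {
      row <- tibble::tibble(
        record_id = rec$record_id, input_name = rec$lipid_name,
        resolved_name = NA_character_, status = "no-spectrum",
        score = NA_real_, n_candidates = NA_integer_, n_survivors = NA_integer_,
        diagnostic_ions = NA_character_
      )
    } else {
      res <- tryCatch({
        sp <- parse_lipid_name(rec$lipid_name, adduct = if (is.na(rec$adduct)) NULL else rec$adduct)
        annotate_spectrum(sp, rec$peaks[[1]], config = config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row <- tibble::tibble(
          record_id = rec$record_id, input_name = rec$lipid_name,
          resolved_name = NA_character_, status = "error",
          score = NA_real_, n_candidates = NA_integer_, n_survivors = NA_integer_,
          diagnostic_ions = conditionMessage(res)
        )
      } else {
        ann <- res
        row <- tibble::tibble(
          record_id = rec$record_id, input_name = ann$input_name,
          resolved_name = ann$name, status = ann$status, score = ann$score,
          n_candidates = sum(ann$chain_detail$n_candidates),
          n_survivors = sum(ann$chain_detail$n_survivors),
          diagnostic_ions = format_diagnostics(ann$diagnostics)
        )
      }
    }
    row$annotation <- list(ann)
    rows[[i]] <- row
  }
  dplyr::bind_rows(rows)
}

format_diagnostics <- function(diag) {
  if (is.null(diag) || nrow(diag) == 0) return(NA_character_)
  paste(sprintf(
    "chain%d:n-%d[%.4f@%+.1fppm,%.4f@%+.1fppm]",
    diag$chain_index, diag$position,
    diag$mz03, diag$ppm03 %|na|% Inf, diag$mz16, diag$ppm16 %|na|% Inf
  ), collapse = ";")
}

#' Write an annotation results table
#'
#' One row per input record; numeric columns are fixed-format so repeated
#' runs produce byte-identical files.
#'
#' @param results Output of [annotate_batch()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  out <- dplyr::select(results, -dplyr::any_of(c("annotation", "peaks")))
  out$score <- ifelse(is.na(out$score), "", sprintf("%.6f", out$score))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read back an annotation results table
#'
#' @param path Path written by [write_results()].
#' @return A tibble.
#' @export
read_results <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    record_id = readr::col_integer(),
    input_name = readr::col_character(),
    resolved_name = readr::col_character(),
    status = readr::col_character(),
    score = readr::col_double(),
    n_candidates = readr::col_integer(),
    n_survivors = readr::col_integer(),
    diagnostic_ions = readr::col_character()
  ))
  out
}

#' Export a reference spectrum as MSP-style text
#'
#' @param spectrum An `oad_spectrum` from [generate_reference_spectrum()].
#' @param path Output path.
#' @export
export_msp <- function(spectrum, path) {
  lines <- c(
    sprintf("NAME: %s", attr(spectrum, "name") %||% "reference"),
    sprintf("PRECURSORMZ: %.6f", attr(spectrum, "precursor_mz")),
    sprintf("PRECURSORTYPE: %s", attr(spectrum, "adduct") %||% ""),
    sprintf("Num Peaks: %d", nrow(spectrum)),
    sprintf("%.6f\t%.4f\t\"%s\"", spectrum$mz, spectrum$rel_intensity, spectrum$label),
    ""
  )
  readr::write_lines(lines, path)
  invisible(path)
}
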