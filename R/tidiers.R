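#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annotation: one row per verified double bond
#'
#' @param x An `oad_annotation`.
#' @param ... Unused.
#' @return A tibble of diagnostic-ion evidence (theoretical pair m/z,
#'   matched relative intensities, ppm errors, pass flag) per chain and
#'   double bond, or the per-chain candidate statistics when the record is
#'   unresolved.
#' @export
tidy.oad_annotation <- function(x, ...) {
  if (!is.null(x$diagnostics)) {
    tibble::as_tibble(x$diagnostics)
  } else {
    x$chain_detail
  }
}

#' Glance at an annotation: one-row summary
#'
#' @param x An `oad_annotation`.
#' @param ... Unused.
#' @return A one-row tibble: input and resolved names, status, score,
#'   candidate counts.
#' @export
glance.oad_annotation <- function(x, ...) {
  tibble::tibble(
    input_name = x$input_name,
    resolved_name = x$name,
    status = x$status,
    score = x$score,
    precursor_mz = x$precursor_mz,
    adduct = x$adduct,
    n_candidates = sum(x$chain_detail$n_candidates),
    n_survivors = sum(x$chain_detail$n_survivors)
  )
}

#' Tidy an evaluation: one row per record verdict
#'
#' @param x An `oad_evaluation`.
#' @param ... Unused.
#' @return The per-record verdict tibble.
#' @export
tidy.oad_evaluation <- function(x, ...) {
  x$verdicts
}

#' Glance at an evaluation: PPV summary
#'
#' @param x An `oad_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with attempted/annotated/correct counts and PPV
#'   under both denominators.
#' @export
glance.oad_evaluation <- function(x, ...) {
  x$summary
}
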