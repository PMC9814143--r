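#' Head-to-tail plot of a measured spectrum against a reference
#'
#' Measured peaks point up, reference peaks down; diagnostic pair ions are
#' highlighted.
#'
#' @param measured Data frame of measured peaks (`mz`, `intensity`).
#' @param reference An `oad_spectrum` (or any data frame with `mz`,
#'   `rel_intensity`).
#' @return A ggplot object.
#' @export
plot_spectrum_match <- function(measured, reference) {
  meas <- as_peak_tbl(measured)
  if (nrow(meas) > 0) meas$rel <- meas$intensity / max(meas$intensity)
  ref <- tibble::as_tibble(reference)
  if (!"diagnostic" %in% names(ref)) ref$diagnostic <- FALSE
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = meas,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$rel),
      colour = "grey30"
    ) +
    ggplot2::geom_segment(
      data = ref,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = -.data$rel_intensity,
                   colour = .data$diagnostic)
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "reference", `TRUE` = "diagnostic pair"),
      name = NULL
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "relative intensity (measured up / reference down)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrum_match
#' @param object An `oad_annotation`.
#' @param ... Unused.
#' @export
autoplot.oad_annotation <- function(object, ...) {
  if (object$status == "unresolved") {
    abort("Cannot plot an unresolved annotation (no reference spectrum)")
  }
  sp <- object$species
  sp$chains$positions <- lapply(sp$chains$positions, function(p) lapply(p, `[[`, 1L))
  ref <- generate_reference_spectrum(sp, adduct = object$adduct)
  plot_spectrum_match(object$measured, ref) +
    ggplot2::ggtitle(sprintf("%s (score %.3f, %s)", object$name, object$score, object$status))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PPV threshold-sweep curve
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A ggplot object: PPV (%) against the minimum intensity
#'   threshold, one line per stratum.
#' @export
plot_ppv_curve <- function(sweep) {
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = 100 * .data$threshold, y = .data$ppv, colour = .data$stratum)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "minimum intensity threshold (% of base peak)",
      y = "positive predictive value (%)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
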