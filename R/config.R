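#' Annotation configuration
#'
#' Central configuration for the annotation engine. Defaults reproduce the
#' published operating point of the method: 15 ppm fragment mass tolerance,
#' 0.01% minimum relative intensity for diagnostic ions (0.005% for the
#' sphingoid delta-4 bond), 0.01 Da / 0.15 min CID-OAD integration windows.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of settings:
#' \describe{
#'   \item{tol_ppm}{fragment m/z match tolerance, ppm (15)}
#'   \item{min_rel_intensity}{diagnostic-ion intensity floor, fraction of
#'     base peak (1e-4, i.e. 0.01\%)}
#'   \item{min_rel_intensity_delta4}{floor for sphingoid delta-4 ions (5e-5)}
#'   \item{tie_epsilon}{score difference treated as a tie (1e-6)}
#'   \item{mz_tol_da, rt_tol_min}{precursor m/z and RT windows used to join
#'     CID-level records with OAD spectra (0.01 Da, 0.15 min)}
#'   \item{min_pos, max_offset, min_gap}{candidate enumeration constraints
#'     (n-3 floor, n-(C-2) ceiling, methylene interruption)}
#'   \item{precursor_intensity}{relative intensity of the precursor peak in
#'     reference spectra (0.5)}
#'   \item{delta4_intensity_scale}{intensity multiplier for sphingoid
#'     delta-4 fragment ions (0.2)}
#'   \item{merge_tol_da}{reference peaks closer than this are merged,
#'     summing intensities (1e-4)}
#'   \item{joint_delta, joint_pool}{per-chain candidates within
#'     `joint_delta` of the chain-stage top score (at most `joint_pool` of
#'     them) are re-scored jointly on the full reference spectrum}
#'   \item{require_pair_all_bonds}{require the diagnostic pair for every
#'     double bond (TRUE); FALSE relaxes to at least one bond}
#'   \item{pc_plasmalogen_as_ether}{serialize PC P- species as PC O- (FALSE)}
#' }
#' @export
oad_config <- function(...) {
  defaults <- list(
    tol_ppm = 15,
    min_rel_intensity = 1e-4,
    min_rel_intensity_delta4 = 5e-5,
    tie_epsilon = 1e-6,
    mz_tol_da = 0.01,
    rt_tol_min = 0.15,
    min_pos = 3L,
    max_offset = 2L,
    min_gap = 2L,
    precursor_intensity = 0.5,
    delta4_intensity_scale = 0.2,
    merge_tol_da = 1e-4,
    joint_delta = 0.05,
    joint_pool = 8L,
    require_pair_all_bonds = TRUE,
    pc_plasmalogen_as_ether = FALSE
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) > 0) {
      abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  defaults
}
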