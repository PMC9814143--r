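# Independent mass oracle: element masses typed from the IUPAC table and a
# deliberately simple character-walk parser, kept separate from the package
# implementation so mass assertions are not self-referential.
ORACLE_MASSES <- c(
  C = 12.0, H = 1.007825032, N = 14.003074005, O = 15.994914620,
  P = 30.973761630, Na = 22.989769281, S = 31.972071000
)
ORACLE_ELECTRON <- 0.00054857991

oracle_formula_mass <- function(text) {
  # walk "C44H86NO8P" character by character
  chars <- strsplit(text, "")[[1]]
  total <- 0
  i <- 1
  while (i <= length(chars)) {
    sym <- chars[i]
    if (i < length(chars) && grepl("[a-z]", chars[i + 1])) {
      sym <- paste0(sym, chars[i + 1]); i <- i + 1
    }
    i <- i + 1
    num <- ""
    while (i <= length(chars) && grepl("[0-9]", chars[i])) {
      num <- paste0(num, chars[i]); i <- i + 1
    }
    total <- total + ORACLE_MASSES[[sym]] * (if (nzchar(num)) as.integer(num) else 1L)
  }
  total
}

noise_free_sim <- function() {
  simulation_config(intensity_sigma = 0, mz_sigma_ppm = 0, noise_lambda = 0)
}

# brute-force position enumeration: filter every d-subset of 1..C
brute_force_positions <- function(carbons, d, min_pos = 3, max_offset = 2, min_gap = 2) {
  if (d == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  all_sub <- utils::combn(seq_len(carbons), d)
  keep <- apply(all_sub, 2, function(p) {
    p <- sort(p)
    p[1] >= min_pos && p[d] <= carbons - max_offset &&
      (d < 2 || all(diff(p) >= min_gap))
  })
  t(all_sub[, keep, drop = FALSE])
}
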