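# Combinatorial enumeration of C=C position candidates. Constraints follow
# the methylene-interrupted chemistry of biological fatty acyl chains:
# the first position from the methyl end is n-3, the last n-(C-2), and two
# double bonds are separated by at least two bonds (no conjugation). Under
# these defaults the candidate count is choose(C - 3 - d, d): 14 for 18:1
# (n-3 .. n-16) and 1,716 for 22:6 ((n-3,5,..,13) .. (n-10,12,..,20)).

#' Enumerate candidate double-bond position assignments
#'
#' Generates every tuple `p1 < ... < pd` of n-positions satisfying
#' `p1 >= min_pos`, `pd <= carbons - max_offset`, and consecutive gaps
#' `>= min_gap`, in lexicographic order.
#'
#' @param carbons Chain length (carbon count).
#' @param double_bonds Number of C=C bonds to place.
#' @param min_pos Smallest allowed n-position (default 3).
#' @param max_offset Positions may not exceed `carbons - max_offset`
#'   (default 2).
#' @param min_gap Minimum difference between consecutive positions
#'   (default 2, i.e. no conjugated systems).
#' @return An integer matrix with `double_bonds` columns, one candidate per
#'   row (a single zero-column row for saturated chains; zero rows when the
#'   chain is too short to host the requested double bonds).
#' @examples
#' nrow(enumerate_positions(18, 1)) # 14
#' nrow(enumerate_positions(22, 6)) # 1716
#' @export
enumerate_positions <- function(carbons, double_bonds,
                                min_pos = 3L, max_offset = 2L, min_gap = 2L) {
  d <- as.integer(double_bonds)
  if (d == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  # Map to strictly increasing r_i = p_i - (min_gap - 1) * (i - 1); then a
  # candidate is any d-combination of r-values, restoring lexicographic order.
  r_max <- carbons - max_offset - (min_gap - 1L) * (d - 1L)
  if (r_max - min_pos + 1L < d) {
    return(matrix(integer(0), nrow = 0L, ncol = d))
  }
  rvals <- seq.int(min_pos, r_max)
  combos <- if (length(rvals) == d) matrix(rvals, ncol = 1L) else utils::combn(rvals, d)
  offs <- (min_gap - 1L) * (seq_len(d) - 1L)
  t(combos + offs)
}

#' Order chains for sequential double-bond evaluation
#'
#' In multi-chain lipids the chain with the highest double-bond equivalent
#' is resolved first; ties break to the longer chain, then input order.
#'
#' @param species A `lipid_species`.
#' @return Integer vector of chain indices in evaluation order.
#' @examples
#' sp <- parse_lipid_name("TG 16:0_18:1_18:3")
#' chain_evaluation_order(sp) # 18:3 first, then 18:1, then 16:0
#' @export
chain_evaluation_order <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  ch <- species$chains
  order(-ch$db, -ch$carbons, ch$chain_index)
}
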