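# Crystal packing metrics: Matthews coefficient and fractional solvent
# content from unit-cell contents.

#' Matthews coefficient and solvent content
#'
#' \deqn{V_m = V_{cell} / (Z \cdot n_{chains} \cdot M)} in cubic Angstrom per
#' Dalton, and the fractional solvent content
#' \deqn{V_s = 1 - 1.23 / V_m,} using the conventional constant 1.23
#' (protein partial specific volume over the crystal-volume-per-mass scale).
#' The general triclinic cell volume is used, which reduces exactly to
#' `a*b*c` for orthorhombic cells.
#'
#' @param cell Length-6 unit-cell parameters (a, b, c Angstrom, angles deg).
#' @param z_asu_per_cell Asymmetric units per cell (space-group multiplicity).
#' @param chains_per_asu Protein chains per asymmetric unit.
#' @param chain_mass Chain mass in Dalton (default 8565, an 8.6 kDa chain).
#' @return Tibble with one row: `v_cell_A3`, `v_m_A3_per_Da`,
#'   `solvent_fraction`.
#' @export
#' @examples
#' # a primitive orthorhombic cell with four asymmetric units of three chains
#' matthews_solvent(c(43.72, 50.36, 93.46, 90, 90, 90), 4, 3)
matthews_solvent <- function(cell, z_asu_per_cell, chains_per_asu,
                             chain_mass = 8565) {
  stopifnot(z_asu_per_cell >= 1, chains_per_asu >= 1, chain_mass > 0)
  v_cell <- cell_volume(cell)
  v_m <- v_cell / (z_asu_per_cell * chains_per_asu * chain_mass)
  v_s <- 1 - 1.23 / v_m
  if (v_s < 0) {
    warning("V_m at or below the protein-only limit; solvent content clipped to 0",
            call. = FALSE)
    v_s <- 0
  }
  tibble::tibble(v_cell_A3 = v_cell, v_m_A3_per_Da = v_m,
                 solvent_fraction = v_s)
}
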