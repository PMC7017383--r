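# Screening-level QSAR estimators of second-order rate constants.
#
# These correlations were derived for phenolic compounds and are
# order-of-magnitude screening tools; estimates carry a provenance flag so
# they are never confused with measured constants downstream.

.N_AVOGADRO <- 6.02e23

#' Aqueous hydroxyl-radical rate constant from the gas-phase one
#'
#' A power-law correlation links gas-phase and aqueous-phase
#' hydroxyl-radical rate constants:
#' `k_water = (0.35 * N_A * k_gas)^0.76` when `k_gas` is in
#' cm^3 molecule^-1 s^-1, or `k_water = (350 * k_gas)^0.76` when `k_gas`
#' is in L mol^-1 s^-1 (N_A = 6.02e23).
#'
#' @param k_gas gas-phase rate constant (> 0).
#' @param units `"cm3_molecule_s"` or `"L_mol_s"`.
#' @return aqueous rate constant, L mol^-1 s^-1, with attribute
#'   `provenance = "QSAR-estimate"`.
#' @examples
#' oh_water_from_gas(1e-11, "cm3_molecule_s")
#' @export
oh_water_from_gas <- function(k_gas, units = c("cm3_molecule_s", "L_mol_s")) {
  units <- match.arg(units)
  if (any(!is.finite(k_gas)) || any(k_gas <= 0))
    stop("k_gas must be positive")
  k <- switch(units,
              cm3_molecule_s = (0.35 * .N_AVOGADRO * k_gas)^0.76,
              L_mol_s = (350 * k_gas)^0.76)
  structure(k, provenance = "QSAR-estimate")
}

#' Transient rate constants from the one-electron oxidation potential
#'
#' The second-order rate constants of a substrate with singlet oxygen, the
#' carbonate radical and triplet CDOM correlate with its one-electron
#' oxidation potential `E1` (V; e.g. -1.6 V for ibuprofen):
#' `k_1O2 = 7.8e9 * 10^(2.46 E1)`, `k_CO3 = 5.6e9 * 10^(1.54 E1)`,
#' `k_3CDOM = 2e12 * 10^(3.3 E1)` (all L mol^-1 s^-1). Accuracy is within
#' about an order of magnitude, best for phenolic compounds.
#'
#' @param e1 one-electron oxidation potential, V, in the `[-3, 1]` sanity
#'   window.
#' @return named numeric vector `c(k_1o2, k_co3, k_3cdom)` with attribute
#'   `provenance = "QSAR-estimate"`.
#' @examples
#' from_oxidation_potential(-1.6)
#' @export
from_oxidation_potential <- function(e1) {
  if (!is.finite(e1) || e1 < -3 || e1 > 1)
    stop("E1 outside the [-3, 1] V sanity window")
  structure(c(k_1o2 = 7.8e9 * 10^(2.46 * e1),
              k_co3 = 5.6e9 * 10^(1.54 * e1),
              k_3cdom = 2e12 * 10^(3.3 * e1)),
            provenance = "QSAR-estimate")
}
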