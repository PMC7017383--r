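# The "literature-default-1" parameter profile.
#
# The steady-state engine needs several photoreactivity constants of the
# natural sensitizers and scavengers that are standard in the aquatic
# photochemistry literature. They ship here as a named, versioned profile;
# every value can be overridden per run. The nitrate and nitrite molar
# absorption spectra are synthetic parametric bands (single Gaussians with
# the literature band position, peak molar absorption and width); measured
# spectra can be substituted through the same interface.

#' Quantum yields of transient photoproduction by CDOM
#'
#' @param phi_oh hydroxyl-radical formation quantum yield of irradiated CDOM
#'   (mol Einstein^-1). The default 3e-5 also subsumes Fe-mediated
#'   photochemistry (photo-Fenton), which is not modelled separately.
#' @param phi_1o2 singlet-oxygen formation quantum yield (default 1.25e-3).
#' @param phi_3cdom triplet-state formation quantum yield (default 1.28e-3).
#' @param eta_co3 dimensionless parameter for carbonate-radical production
#'   from triplet CDOM + carbonate; default 0 (carbonate radical sourced from
#'   the hydroxyl radical only).
#' @return An object of class `"cdom_photo_params"`.
#' @export
cdom_photo_params <- function(phi_oh = 3e-5, phi_1o2 = 1.25e-3,
                              phi_3cdom = 1.28e-3, eta_co3 = 0) {
  v <- c(phi_oh = phi_oh, phi_1o2 = phi_1o2, phi_3cdom = phi_3cdom,
         eta_co3 = eta_co3)
  if (any(!is.finite(v)) || any(v < 0)) stop("parameters must be >= 0")
  if (any(v[1:3] > 1)) stop("quantum yields must be <= 1")
  structure(as.list(v), class = "cdom_photo_params")
}

#' Hydroxyl-radical quantum yields of the inorganic photosensitizers
#'
#' @param phi_oh_no3 quantum yield of nitrate photolysis to the hydroxyl
#'   radical (mol Einstein^-1); literature-default 0.01.
#' @param phi_oh_no2 quantum yield of nitrite photolysis to the hydroxyl
#'   radical; literature-default 0.025.
#' @return An object of class `"source_quantum_yields"`.
#' @export
source_quantum_yields <- function(phi_oh_no3 = 0.01, phi_oh_no2 = 0.025) {
  v <- c(phi_oh_no3 = phi_oh_no3, phi_oh_no2 = phi_oh_no2)
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("quantum yields must lie in (0, 1]")
  structure(as.list(v), class = "source_quantum_yields")
}

#' Scavenging/quenching rate constants of the transients
#'
#' Second-order rate constants of the natural sinks of the four transients,
#' plus the first-order decay constants of singlet oxygen (collisional
#' deactivation by water) and of triplet CDOM in aerated solution.
#'
#' @param k_oh_dom hydroxyl + DOM, L mg_C^-1 s^-1 (default 5e4).
#' @param k_oh_hco3 hydroxyl + bicarbonate, L mol^-1 s^-1 (default 8.5e6).
#' @param k_oh_co3 hydroxyl + carbonate, L mol^-1 s^-1 (default 3.9e8).
#' @param k_oh_no2 hydroxyl + nitrite, L mol^-1 s^-1 (default 1.0e10).
#' @param k_oh_br hydroxyl + bromide, L mol^-1 s^-1 (default 1.1e10).
#' @param k_co3_dom carbonate radical + DOM, L mg_C^-1 s^-1 (default 1e2).
#' @param k_3cdom_decay first-order triplet inactivation in aerated water,
#'   s^-1 (default 6e5).
#' @param k_1o2_decay first-order singlet-oxygen deactivation by water,
#'   s^-1 (default 2.5e5).
#' @return An object of class `"scavenging_params"`.
#' @export
scavenging_params <- function(k_oh_dom = 5e4, k_oh_hco3 = 8.5e6,
                              k_oh_co3 = 3.9e8, k_oh_no2 = 1.0e10,
                              k_oh_br = 1.1e10, k_co3_dom = 1e2,
                              k_3cdom_decay = 6e5, k_1o2_decay = 2.5e5) {
  v <- c(k_oh_dom = k_oh_dom, k_oh_hco3 = k_oh_hco3, k_oh_co3 = k_oh_co3,
         k_oh_no2 = k_oh_no2, k_oh_br = k_oh_br, k_co3_dom = k_co3_dom,
         k_3cdom_decay = k_3cdom_decay, k_1o2_decay = k_1o2_decay)
  if (any(!is.finite(v)) || any(v <= 0)) stop("rate constants must be > 0")
  structure(as.list(v), class = "scavenging_params")
}

# Synthetic Gaussian absorption bands of the inorganic chromophores
# (band centre nm, peak molar absorption L mol^-1 cm^-1, sd nm).
.gaussian_band <- function(grid, centre, peak, width) {
  spectrum(grid, peak * exp(-0.5 * ((grid - centre) / width)^2),
           "molar_absorption")
}

#' Default molar absorption spectra of nitrate and nitrite
#'
#' Synthetic single-Gaussian representations of the weak n->pi* absorption
#' bands: nitrate centred at 302 nm (peak 7.2 L mol^-1 cm^-1, sd 17 nm),
#' nitrite centred at 354 nm (peak 22.5 L mol^-1 cm^-1, sd 24 nm). Part of
#' the `"literature-default-1"` profile; replaceable with measured spectra.
#'
#' @param grid wavelength grid (nm).
#' @return A `molar_absorption` [spectrum()].
#' @export
nitrate_absorption <- function(grid) .gaussian_band(grid, 302, 7.2, 17)

#' @rdname nitrate_absorption
#' @export
nitrite_absorption <- function(grid) .gaussian_band(grid, 354, 22.5, 24)

#' The engine's default parameter profile
#'
#' Bundles the CDOM photoproduction quantum yields, the inorganic-source
#' quantum yields, the scavenging constants and the sensitizer absorption
#' spectra into one named, versioned profile. Every component is
#' overridable.
#'
#' @param cdom a [cdom_photo_params()].
#' @param sources a [source_quantum_yields()].
#' @param scavenging a [scavenging_params()].
#' @param nitrate_spectrum,nitrite_spectrum functions of a wavelength grid
#'   returning `molar_absorption` spectra.
#' @param ssd_equivalent_seconds seconds of reference-irradiance exposure
#'   equivalent to one summer sunny day (SSD), the model's output time unit.
#'   Default 3.6e4 s (10 h at 22 W m^-2 UV as one fair mid-July day at
#'   mid-latitude); configurable because the day-night cycle folding is a
#'   convention, not a measured constant.
#' @return An object of class `"photo_profile"`.
#' @examples
#' default_profile()
#' @export
default_profile <- function(cdom = cdom_photo_params(),
                            sources = source_quantum_yields(),
                            scavenging = scavenging_params(),
                            nitrate_spectrum = nitrate_absorption,
                            nitrite_spectrum = nitrite_absorption,
                            ssd_equivalent_seconds = 3.6e4) {
  stopifnot(inherits(cdom, "cdom_photo_params"),
            inherits(sources, "source_quantum_yields"),
            inherits(scavenging, "scavenging_params"),
            is.function(nitrate_spectrum), is.function(nitrite_spectrum))
  if (!is.finite(ssd_equivalent_seconds) || ssd_equivalent_seconds <= 0)
    stop("ssd_equivalent_seconds must be positive")
  structure(list(name = "literature-default-1", cdom = cdom,
                 sources = sources, scavenging = scavenging,
                 nitrate_spectrum = nitrate_spectrum,
                 nitrite_spectrum = nitrite_spectrum,
                 ssd_equivalent_seconds = ssd_equivalent_seconds),
            class = "photo_profile")
}

#' @export
print.photo_profile <- function(x, ...) {
  cat(sprintf("<photo_profile '%s': Phi_OH,CDOM = %g, SSD = %g s>\n",
              x$name, x$cdom$phi_oh, x$ssd_equivalent_seconds))
  invisible(x)
}

#' Photoreactivity parameters of one compound
#'
#' The substrate-side inputs of the engine: the direct photolysis quantum
#' yield (a scalar, or a wavelength-resolved `phi` spectrum), the
#' second-order rate constants with the four transients, the back-reduction
#' half-effect DOC, and optionally the formation yields of one intermediate
#' along each pathway.
#'
#' @param phi_direct direct photolysis quantum yield, mol Einstein^-1
#'   (scalar in `[0, 1]`, or a [spectrum()] of wavelength-resolved values).
#' @param k_oh,k_co3,k_1o2,k_3cdom second-order rate constants with the
#'   hydroxyl radical, carbonate radical, singlet oxygen and triplet CDOM
#'   (L mol^-1 s^-1, >= 0).
#' @param doc_half DOC at which back-reduction by DOM antioxidant moieties
#'   halves the apparent triplet reactivity (mg_C L^-1); default `Inf`
#'   (no back-reduction).
#' @param yields named numeric vector of intermediate formation yields in
#'   `[0, 1]` with names among `phot`, `oh`, `co3`, `o2`, `dom`; default all
#'   zero.
#' @return An object of class `"photo_reactivity"`.
#' @examples
#' # ibuprofen
#' photo_reactivity(phi_direct = 0.33, k_oh = 1.0e10, k_1o2 = 6e4,
#'                  k_3cdom = 4.5e7,
#'                  yields = c(phot = 0.25, oh = 0.023, dom = 0.31))
#' @export
photo_reactivity <- function(phi_direct = 0, k_oh = 0, k_co3 = 0, k_1o2 = 0,
                             k_3cdom = 0, doc_half = Inf, yields = NULL) {
  ks <- c(k_oh = k_oh, k_co3 = k_co3, k_1o2 = k_1o2, k_3cdom = k_3cdom)
  if (any(!is.finite(ks)) || any(ks < 0)) stop("rate constants must be >= 0")
  if (is_spectrum(phi_direct)) {
    if (any(phi_direct$value > 1)) stop("quantum yields must be <= 1")
  } else if (!is.finite(phi_direct) || phi_direct < 0 || phi_direct > 1) {
    stop("phi_direct must lie in [0, 1]")
  }
  if (!(is.finite(doc_half) && doc_half > 0) && !is.infinite(doc_half))
    stop("doc_half must be positive (Inf for no back-reduction)")
  y <- c(phot = 0, oh = 0, co3 = 0, o2 = 0, dom = 0)
  if (!is.null(yields)) {
    if (is.null(names(yields)) || !all(names(yields) %in% names(y)))
      stop("yields must be named among phot, oh, co3, o2, dom")
    if (any(yields < 0) || any(yields > 1)) stop("yields must lie in [0, 1]")
    y[names(yields)] <- yields
  }
  structure(list(phi_direct = phi_direct, k_oh = k_oh, k_co3 = k_co3,
                 k_1o2 = k_1o2, k_3cdom = k_3cdom, doc_half = doc_half,
                 yields = y),
            class = "photo_reactivity")
}
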