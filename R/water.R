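# Water composition, analytical unit conversions, carbonate speciation.

#' Water body composition and depth
#'
#' Container for the photochemically relevant chemistry of a freshwater
#' column: nitrate, nitrite, bicarbonate, carbonate (mol L^-1), dissolved
#' organic carbon (mg_C L^-1) and bromide (mol L^-1, relevant in saltwaters
#' only, default 0), plus the depth of the well-mixed column.
#'
#' An optional measured water absorbance spectrum (`aw`, cm^-1) takes
#' priority over the DOC-based estimate of [cdom_absorbance()].
#'
#' @param depth_m water column depth (m), > 0.
#' @param nitrate,nitrite,bicarbonate,carbonate mol L^-1, >= 0.
#' @param doc dissolved organic carbon, mg_C L^-1, >= 0. `TOC` may be used as
#'   a surrogate (a warning is emitted via [water_body_from_toc()]).
#' @param bromide mol L^-1, >= 0 (default 0).
#' @param aw optional measured `absorbance_per_cm` [spectrum()].
#' @param psi path-correction factor >= 1 applied to the water-column light
#'   path (default 1: light path equals the depth).
#' @return An object of class `"water_body"`.
#' @examples
#' water_body(5, nitrate = 1e-4, nitrite = 1e-6,
#'            bicarbonate = 1e-3, carbonate = 1e-5, doc = 3)
#' @export
water_body <- function(depth_m, nitrate = 0, nitrite = 0, bicarbonate = 0,
                       carbonate = 0, doc = 0, bromide = 0, aw = NULL,
                       psi = 1) {
  vals <- c(nitrate = nitrate, nitrite = nitrite, bicarbonate = bicarbonate,
            carbonate = carbonate, doc = doc, bromide = bromide)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all concentrations must be finite and >= 0")
  if (!is.finite(depth_m) || depth_m <= 0) stop("depth must be positive")
  if (!is.null(aw)) {
    stopifnot(is_spectrum(aw))
    if (aw$kind != "absorbance_per_cm")
      stop("aw must be an absorbance_per_cm spectrum")
  }
  if (!is.finite(psi) || psi < 1) stop("psi must be >= 1")
  structure(list(depth_m = depth_m, nitrate = nitrate, nitrite = nitrite,
                 bicarbonate = bicarbonate, carbonate = carbonate, doc = doc,
                 bromide = bromide, aw = aw, psi = psi),
            class = "water_body")
}

#' @export
print.water_body <- function(x, ...) {
  cat(sprintf(paste0("<water_body: d = %g m, [NO3-] = %g M, [NO2-] = %g M, ",
                     "[HCO3-] = %g M, [CO32-] = %g M, DOC = %g mgC/L>\n"),
              x$depth_m, x$nitrate, x$nitrite, x$bicarbonate, x$carbonate,
              x$doc))
  invisible(x)
}

#' Build a water body using TOC as a DOC surrogate
#'
#' In most freshwaters organic matter is prevalently dissolved, so the total
#' organic carbon is a decent approximation for the DOC; a warning records
#' the substitution.
#'
#' @param depth_m depth (m).
#' @param toc total organic carbon, mg_C L^-1.
#' @param ... further arguments to [water_body()].
#' @return A [water_body()].
#' @export
water_body_from_toc <- function(depth_m, toc, ...) {
  warning("using TOC as a surrogate for DOC")
  water_body(depth_m, doc = toc, ...)
}

# Gram formula / equivalent weights in mg mol^-1, as used for analytical
# unit conversion of nitrate and nitrite data.
.MG_PER_MOL <- c(NO3 = 62000, NO2 = 46000, N = 14000)

#' Convert analytical mass concentrations to molarity
#'
#' Nitrate and nitrite data are commonly reported as mg(NO3-)/L, mg(NO2-)/L
#' or mg(N)/L (nitrate-N / nitrite-N); light-absorption calculations need
#' mol L^-1.
#'
#' @param value concentration, mg L^-1 (>= 0).
#' @param species `"NO3"`, `"NO2"` or `"N"` (molecular weights 62,000 and
#'   46,000 mg mol^-1, and equivalent weight 14,000 mg mol^-1).
#' @return concentration in mol L^-1.
#' @examples
#' mass_to_molar(62, "NO3")  # 1e-3 M
#' @export
mass_to_molar <- function(value, species = c("NO3", "NO2", "N")) {
  species <- match.arg(species)
  if (any(!is.finite(value)) || any(value < 0))
    stop("mass concentration must be >= 0")
  value / .MG_PER_MOL[[species]]
}

#' Carbonate speciation from alkalinity and pH
#'
#' Solves `Alk = [HCO3-] + 2 [CO3^2-] + [OH-] - [H+]` together with the
#' second carbonic-acid dissociation `[CO3^2-]/[HCO3-] = K2/[H+]` for the
#' bicarbonate and carbonate concentrations. Equilibrium constants default
#' to 25 degrees C, zero ionic strength. `include_water = FALSE` drops the
#' `[OH-] - [H+]` terms (the simpler two-term carbonate alkalinity).
#'
#' @param alk alkalinity, eq L^-1 (>= 0).
#' @param ph pH in `[2, 12]`.
#' @param pk2 second dissociation pK of carbonic acid (default 10.33).
#' @param pkw water ion product pK (default 14.00).
#' @param include_water include the water terms `[OH-] - [H+]` (default TRUE).
#' @return named numeric vector `c(bicarbonate = , carbonate = )`, mol L^-1.
#' @examples
#' carbonate_from_alkalinity(1e-3, 7)
#' @export
carbonate_from_alkalinity <- function(alk, ph, pk2 = 10.33, pkw = 14.00,
                                      include_water = TRUE) {
  if (!is.finite(alk) || alk < 0) stop("alkalinity must be >= 0")
  if (!is.finite(ph) || ph < 2 || ph > 12) stop("pH must be in [2, 12]")
  h <- 10^(-ph)
  oh <- 10^(-(pkw - ph))
  k2 <- 10^(-pk2)
  carb_alk <- if (include_water) alk - oh + h else alk
  if (carb_alk < 0)
    stop("alkalinity inconsistent with pH: [OH-] - [H+] exceeds Alk")
  hco3 <- carb_alk / (1 + 2 * k2 / h)
  co3 <- hco3 * k2 / h
  c(bicarbonate = hco3, carbonate = co3)
}

#' Acid-base pair of a monoprotic compound
#'
#' Couples the pKa of a compound with any rate-like quantity of its acidic
#' and basic forms (e.g. pathway rate constants), for pH-weighted
#' combination.
#'
#' @param pka acid dissociation pK, in (0, 14) for the intended use.
#' @param k_acid,k_base rate-like quantities sharing units (numeric scalars
#'   or equally named numeric vectors).
#' @return An object of class `"acid_base_pair"`.
#' @export
acid_base_pair <- function(pka, k_acid = NULL, k_base = NULL) {
  if (!is.finite(pka) || pka <= 0 || pka >= 14)
    stop("pKa must lie in (0, 14)")
  structure(list(pka = pka, k_acid = k_acid, k_base = k_base),
            class = "acid_base_pair")
}

#' Acid/base speciation fractions at a given pH
#'
#' `alpha_acid = 10^(-pH) / (10^(-pH) + 10^(-pKa))`; the two fractions sum
#' to one at every pH.
#'
#' @param pka acid dissociation pK (or an [acid_base_pair()]).
#' @param ph pH (vectorized).
#' @return A data.frame with columns `ph`, `alpha_acid`, `alpha_base`.
#' @examples
#' speciation_fractions(7.3, c(6, 7.3, 9))
#' @export
speciation_fractions <- function(pka, ph) {
  if (inherits(pka, "acid_base_pair")) pka <- pka$pka
  a <- 10^(-ph) / (10^(-ph) + 10^(-pka))
  data.frame(ph = ph, alpha_acid = a, alpha_base = 1 - a)
}
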