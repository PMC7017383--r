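# The steady-state photochemical engine.
#
# Transient budgets follow the classic formation/scavenging structure:
# nitrate and nitrite photolysis and CDOM photoexcitation form the hydroxyl
# radical; the hydroxyl radical flux into bicarbonate/carbonate forms the
# carbonate radical; triplet CDOM forms singlet oxygen via dissolved O2.
# Each transient's steady-state concentration is its volumetric formation
# rate divided by its first-order scavenging rate constant.

# Volume-normalization: an areal absorbed flux (Einstein cm^-2 s^-1) over a
# column of depth d_cm is a volumetric rate of Pa/d_cm Einstein cm^-3 s^-1,
# i.e. 1000 * Pa / d_cm Einstein L^-1 s^-1.
.areal_to_volumetric <- function(pa_areal, depth_cm) 1000 * pa_areal / depth_cm

# The competing natural absorbers of a water body on the grid of p0.
.water_absorbers <- function(water, profile, grid) {
  a1 <- if (!is.null(water$aw)) water$aw else cdom_absorbance(water$doc, grid)
  abs_list <- list(absorber("CDOM", a1, 1))
  if (water$nitrate > 0)
    abs_list <- c(abs_list, list(absorber("NO3", profile$nitrate_spectrum(grid),
                                          water$nitrate)))
  if (water$nitrite > 0)
    abs_list <- c(abs_list, list(absorber("NO2", profile$nitrite_spectrum(grid),
                                          water$nitrite)))
  absorber_set(abs_list)
}

#' Formation/scavenging budgets and steady-state transient concentrations
#'
#' Computes, for the hydroxyl radical, the carbonate radical, singlet oxygen
#' and triplet CDOM: the volumetric formation rate, the pseudo-first-order
#' scavenging rate constant, and the steady-state concentration
#' (formation / scavenging). The incident spectrum should be normalized to
#' the reference UV irradiance (see [scale_to_uv_irradiance()]) when
#' reference-condition outputs are wanted.
#'
#' @param p0 incident `photon_flux_density` [spectrum()] at the surface.
#' @param water a [water_body()].
#' @param profile a [default_profile()] (or a customized one).
#' @return An object of class `"transient_budgets"`: a list with one
#'   `list(formation, scavenging, steady_state)` per transient (`oh`, `co3`,
#'   `o2`, `dom`), the hydroxyl source apportionment (`oh_sources`), the
#'   per-sensitizer absorbed fluxes, and the water.
#' @examples
#' w <- water_body(5, nitrate = 1e-4, nitrite = 1e-6,
#'                 bicarbonate = 1e-3, carbonate = 1e-5, doc = 3)
#' b <- transient_budgets(synthetic_solar_spectrum(), w)
#' b$oh$steady_state
#' @export
transient_budgets <- function(p0, water, profile = default_profile()) {
  stopifnot(inherits(water, "water_body"), inherits(profile, "photo_profile"))
  grid <- p0$wavelength
  depth_cm <- water$depth_m * 100
  path_cm <- depth_cm * water$psi
  absorbers <- .water_absorbers(water, profile, grid)
  pa <- competitive_absorption(p0, absorbers, path_cm)
  pa_vol <- .areal_to_volumetric(pa, depth_cm)
  pa_no3 <- if ("NO3" %in% names(pa_vol)) pa_vol[["NO3"]] else 0
  pa_no2 <- if ("NO2" %in% names(pa_vol)) pa_vol[["NO2"]] else 0
  pa_cdom <- pa_vol[["CDOM"]]

  sq <- profile$sources
  cd <- profile$cdom
  sc <- profile$scavenging

  r_oh <- c(NO3 = sq$phi_oh_no3 * pa_no3,
            NO2 = sq$phi_oh_no2 * pa_no2,
            CDOM = cd$phi_oh * pa_cdom)
  r_3cdom <- cd$phi_3cdom * pa_cdom
  r_1o2 <- cd$phi_1o2 * pa_cdom

  s_oh <- sc$k_oh_dom * water$doc + sc$k_oh_hco3 * water$bicarbonate +
    sc$k_oh_co3 * water$carbonate + sc$k_oh_no2 * water$nitrite +
    sc$k_oh_br * water$bromide
  oh_ss <- .steady_state(sum(r_oh), s_oh, "hydroxyl radical")

  r_co3 <- oh_ss * (sc$k_oh_hco3 * water$bicarbonate +
                      sc$k_oh_co3 * water$carbonate) +
    cd$eta_co3 * r_3cdom
  s_co3 <- sc$k_co3_dom * water$doc
  co3_ss <- .steady_state(r_co3, s_co3, "carbonate radical")

  budgets <- list(
    oh = list(formation = sum(r_oh), scavenging = s_oh, steady_state = oh_ss),
    co3 = list(formation = r_co3, scavenging = s_co3, steady_state = co3_ss),
    o2 = list(formation = r_1o2, scavenging = sc$k_1o2_decay,
              steady_state = r_1o2 / sc$k_1o2_decay),
    dom = list(formation = r_3cdom, scavenging = sc$k_3cdom_decay,
               steady_state = r_3cdom / sc$k_3cdom_decay),
    oh_sources = if (sum(r_oh) > 0) r_oh / sum(r_oh) else r_oh * 0,
    pa_volumetric = pa_vol,
    water = water,
    profile_name = profile$name
  )
  class(budgets) <- "transient_budgets"
  budgets
}

.steady_state <- function(formation, scavenging, what) {
  if (scavenging <= 0) {
    if (formation > 0)
      stop(sprintf("no steady state: %s formed but not scavenged", what))
    return(0)
  }
  formation / scavenging
}

#' @export
print.transient_budgets <- function(x, ...) {
  cat("<transient_budgets (mol/L at reference irradiance)>\n")
  for (tr in c("oh", "co3", "o2", "dom"))
    cat(sprintf("  [%s]ss = %.3e\n", toupper(tr), x[[tr]]$steady_state))
  invisible(x)
}

#' Direct photolysis pseudo-first-order rate constant
#'
#' The substrate competes with the natural chromophores (CDOM, nitrate,
#' nitrite) for the incident photons; its volumetric absorbed flux times the
#' photolysis quantum yield, divided by the probe concentration, gives the
#' pseudo-first-order rate constant. The probe concentration (default
#' 1e-8 mol L^-1) is low enough that absorption is linear in it and the
#' result is concentration-independent.
#'
#' @param p0 incident `photon_flux_density` [spectrum()].
#' @param epsilon the substrate's `molar_absorption` [spectrum()].
#' @param phi_direct scalar quantum yield, or a wavelength-resolved
#'   [spectrum()] of quantum yields.
#' @param water a [water_body()] supplying the co-absorbers.
#' @param profile a [default_profile()].
#' @param s0 probe concentration, mol L^-1 (default 1e-8).
#' @return rate constant in s^-1 (0 if the substrate does not absorb within
#'   the source window).
#' @export
direct_photolysis_k <- function(p0, epsilon, phi_direct, water,
                                profile = default_profile(), s0 = 1e-8) {
  stopifnot(inherits(water, "water_body"))
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  grid <- p0$wavelength
  depth_cm <- water$depth_m * 100
  path_cm <- depth_cm * water$psi
  eps_grid <- spectrum_at(epsilon, grid)
  if (all(eps_grid * spectrum_at(p0, grid) == 0)) return(0)
  co <- .water_absorbers(water, profile, grid)
  mix <- absorber_set(c(list(absorber("substrate", epsilon, s0)), unclass(co)))

  if (is_spectrum(phi_direct)) {
    # wavelength-resolved yield: weight the substrate's spectral absorbed
    # flux by phi(lambda) before integrating
    p <- spectrum_at(p0, grid)
    amat <- vapply(mix, .absorbance_on, numeric(length(grid)), grid = grid)
    amat <- matrix(amat, nrow = length(grid))
    atot <- rowSums(amat)
    frac <- ifelse(atot > 0, amat[, 1] / atot, 0)
    integrand <- spectrum_at(phi_direct, grid) * p * frac *
      (1 - 10^(-atot * path_cm))
    pa_s <- pracma::trapz(grid, integrand)
    return(.areal_to_volumetric(pa_s, depth_cm) / s0)
  }
  if (phi_direct == 0) return(0)
  pa_s <- competitive_absorption(p0, mix, path_cm)[["substrate"]]
  phi_direct * .areal_to_volumetric(pa_s, depth_cm) / s0
}

.PATHWAYS <- c("phot", "oh", "co3", "o2", "dom")

#' Pathway-resolved degradation kinetics of a substrate
#'
#' Combines the transient steady-state concentrations with a compound's
#' second-order rate constants (and its direct photolysis rate constant)
#' into pathway-resolved pseudo-first-order rate constants, pathway
#' fractions, the half-life, and intermediate formation rate constants.
#' The triplet pathway is attenuated by back-reduction as
#' `k_3cdom / (1 + DOC / DOC_half)`.
#'
#' @param reactivity a [photo_reactivity()].
#' @param budgets a [transient_budgets()] result.
#' @param k_phot direct photolysis rate constant (s^-1), from
#'   [direct_photolysis_k()]; default 0.
#' @param ssd_equivalent_seconds seconds per summer sunny day used to
#'   convert s^-1 rate constants (under the reference spectrum) to SSD^-1.
#' @return An object of class `"pathway_result"`: per-pathway rate constants
#'   (`k_s` in s^-1 and `k_ssd` in SSD^-1), pathway `fractions`, `t_half_ssd`
#'   (SSD; `Inf` when nothing degrades), intermediate formation rate
#'   constants and overall yield, the transient concentrations and hydroxyl
#'   source apportionment.
#' @export
degrade <- function(reactivity, budgets, k_phot = 0,
                    ssd_equivalent_seconds = 3.6e4) {
  stopifnot(inherits(reactivity, "photo_reactivity"),
            inherits(budgets, "transient_budgets"))
  doc <- budgets$water$doc
  k_3_app <- reactivity$k_3cdom / (1 + doc / reactivity$doc_half)
  k_s <- c(phot = k_phot,
           oh = reactivity$k_oh * budgets$oh$steady_state,
           co3 = reactivity$k_co3 * budgets$co3$steady_state,
           o2 = reactivity$k_1o2 * budgets$o2$steady_state,
           dom = k_3_app * budgets$dom$steady_state)
  k_tot <- sum(k_s)
  fractions <- if (k_tot > 0) k_s / k_tot else k_s * 0
  k_ssd <- k_s * ssd_equivalent_seconds
  t_half_ssd <- if (k_tot > 0) log(2) / sum(k_ssd) else Inf
  kf <- reactivity$yields[.PATHWAYS] * k_s
  y_overall <- if (k_tot > 0) sum(kf) / k_tot else 0
  structure(list(k_s = k_s, k_ssd = k_ssd, k_tot_s = k_tot,
                 k_tot_ssd = sum(k_ssd), fractions = fractions,
                 t_half_ssd = t_half_ssd,
                 intermediate_k_ssd = kf * ssd_equivalent_seconds,
                 intermediate_yield = y_overall,
                 transients = c(oh = budgets$oh$steady_state,
                                co3 = budgets$co3$steady_state,
                                o2 = budgets$o2$steady_state,
                                dom = budgets$dom$steady_state),
                 oh_sources = budgets$oh_sources,
                 ssd_equivalent_seconds = ssd_equivalent_seconds),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat("<pathway_result>\n")
  cat(sprintf("  t_1/2 = %s SSD (k_tot = %.3e SSD^-1)\n",
              if (is.finite(x$t_half_ssd)) sprintf("%.3g", x$t_half_ssd)
              else "Inf", x$k_tot_ssd))
  for (p in names(x$fractions))
    cat(sprintf("  %-5s k = %.3e SSD^-1  fraction = %.3f\n",
                p, x$k_ssd[[p]], x$fractions[[p]]))
  invisible(x)
}

#' Run the full photochemical fate model for one compound
#'
#' Convenience wrapper: normalizes the incident spectrum to the reference
#' UV irradiance, computes the transient budgets, the direct photolysis
#' rate constant and the pathway-resolved degradation kinetics.
#'
#' @param molecule a list with elements `p0` (incident spectrum), `epsilon`
#'   (the compound's molar absorption spectrum) and optionally `phi`
#'   (wavelength-resolved quantum yield spectrum overriding the scalar in
#'   `reactivity`), e.g. from [read_molecule_csv()].
#' @param water a [water_body()].
#' @param reactivity a [photo_reactivity()].
#' @param profile a [default_profile()].
#' @param s0 probe concentration (mol L^-1), default 1e-8.
#' @param normalize normalize `p0` to 22 W m^-2 over 290-400 nm before the
#'   run (default TRUE).
#' @return A `"pathway_result"` (see [degrade()]).
#' @examples
#' mol <- synthetic_molecule_table()
#' w <- water_body(2, nitrate = 1e-4, nitrite = 1e-6,
#'                 bicarbonate = 1e-3, carbonate = 1e-5, doc = 2)
#' r <- photo_reactivity(phi_direct = 0.33, k_oh = 1e10, k_1o2 = 6e4,
#'                       k_3cdom = 4.5e7)
#' photic_run(mol, w, r)
#' @export
photic_run <- function(molecule, water, reactivity,
                       profile = default_profile(), s0 = 1e-8,
                       normalize = TRUE) {
  stopifnot(is_spectrum(molecule$p0), is_spectrum(molecule$epsilon))
  p0 <- if (normalize) scale_to_uv_irradiance(molecule$p0) else molecule$p0
  phi <- if (!is.null(molecule$phi)) molecule$phi else reactivity$phi_direct
  budgets <- transient_budgets(p0, water, profile)
  k_phot <- direct_photolysis_k(p0, molecule$epsilon, phi, water, profile, s0)
  degrade(reactivity, budgets, k_phot,
          ssd_equivalent_seconds = profile$ssd_equivalent_seconds)
}

#' Flatten a pathway result to one output-table row
#'
#' Produces the flat tabular form of the model output (one row per run):
#' total and per-pathway rate constants (SSD^-1), half-life (SSD; empty/NA
#' when infinite), steady-state transient concentrations, pathway fractions
#' and hydroxyl-radical source fractions.
#'
#' @param result a `"pathway_result"`.
#' @param x,y optional values of the swept X/Y variables to prepend.
#' @return A one-row data.frame.
#' @export
as_savetable <- function(result, x = NA_real_, y = NA_real_) {
  stopifnot(inherits(result, "pathway_result"))
  data.frame(
    X = x, Y = y,
    t_tot = if (is.finite(result$t_half_ssd)) result$t_half_ssd else NA_real_,
    k_tot = result$k_tot_ssd,
    k_OH = result$k_ssd[["oh"]],
    k_CO3 = result$k_ssd[["co3"]],
    k_1O2 = result$k_ssd[["o2"]],
    k_3DOM = result$k_ssd[["dom"]],
    k_Phot = result$k_ssd[["phot"]],
    conc_OH = result$transients[["oh"]],
    conc_CO3 = result$transients[["co3"]],
    conc_1O2 = result$transients[["o2"]],
    conc_3DOM = result$transients[["dom"]],
    f_OH = result$fractions[["oh"]],
    f_CO3 = result$fractions[["co3"]],
    f_1O2 = result$fractions[["o2"]],
    f_3DOM = result$fractions[["dom"]],
    f_Phot = result$fractions[["phot"]],
    fOH_NO3 = result$oh_sources[["NO3"]],
    fOH_NO2 = result$oh_sources[["NO2"]],
    fOH_CDOM = result$oh_sources[["CDOM"]],
    kf_Phot = result$intermediate_k_ssd[["phot"]],
    kf_OH = result$intermediate_k_ssd[["oh"]],
    kf_CO3 = result$intermediate_k_ssd[["co3"]],
    kf_1O2 = result$intermediate_k_ssd[["o2"]],
    kf_3DOM = result$intermediate_k_ssd[["dom"]],
    y_interm = result$intermediate_yield
  )
}
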