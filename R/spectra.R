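# Spectral containers and photon-absorption integrals.
#
# All photon fluxes are spectral photon flux densities in
# Einstein cm^-2 s^-1 nm^-1, molar absorption coefficients in L mol^-1 cm^-1,
# water absorbance in cm^-1, and optical paths in cm internally.

#' Wavelength-resolved spectrum
#'
#' A light container for a tabulated, wavelength-indexed nonnegative function:
#' an incident spectral photon flux density, a molar absorption coefficient,
#' or a water absorbance referred to a 1 cm path.
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing.
#' @param value numeric vector of nonnegative values, same length.
#' @param kind one of `"photon_flux_density"` (Einstein cm^-2 s^-1 nm^-1),
#'   `"molar_absorption"` (L mol^-1 cm^-1), `"absorbance_per_cm"` (cm^-1).
#' @return An object of class `"spectrum"`.
#' @examples
#' sp <- spectrum(300:400, rep(1e-9, 101), "photon_flux_density")
#' @export
spectrum <- function(wavelength, value,
                     kind = c("photon_flux_density", "molar_absorption",
                              "absorbance_per_cm")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 1L) stop("empty spectrum")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("non-finite entries in spectrum")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(value < 0)) stop("spectrum values must be nonnegative")
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength = x$wavelength, value = x$value)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Evaluate a spectrum on a wavelength grid
#'
#' Linear interpolation; wavelengths outside the tabulated support evaluate
#' to zero (the function is taken as unsupported there).
#'
#' @param sp a [spectrum()].
#' @param wavelength numeric grid (nm).
#' @return numeric vector of values on `wavelength`.
#' @export
spectrum_at <- function(sp, wavelength) {
  stopifnot(is_spectrum(sp))
  if (length(sp$wavelength) == 1L) {
    out <- ifelse(wavelength == sp$wavelength, sp$value, 0)
    return(as.numeric(out))
  }
  stats::approx(sp$wavelength, sp$value, xout = wavelength,
                method = "linear", yleft = 0, yright = 0)$y
}

#' Laboratory or water-column optical path
#'
#' Converts an optical path to the internal cm unit. The dimensionless
#' path-correction factor `psi` (light travels slightly further than the
#' vertical depth) is applied to water-column paths (`unit = "m"`) only,
#' never to a laboratory cuvette/reactor path.
#'
#' @param length path length, in `unit`.
#' @param unit `"cm"` (laboratory path) or `"m"` (water column).
#' @param psi path-correction factor >= 1; default 1.
#' @return path length in cm.
#' @export
optical_path <- function(length, unit = c("cm", "m"), psi = 1) {
  unit <- match.arg(unit)
  if (!is.finite(length) || length <= 0) stop("path length must be positive")
  if (!is.finite(psi) || psi < 1) stop("psi must be >= 1")
  switch(unit, cm = length, m = length * 100 * psi)
}

#' One absorbing solute
#'
#' @param label character tag.
#' @param spec a `molar_absorption` spectrum (L mol^-1 cm^-1) with
#'   `concentration` in mol L^-1, or an `absorbance_per_cm` spectrum with
#'   `concentration = 1` (e.g. the CDOM background).
#' @param concentration mol L^-1 (>= 0), or 1 for an absorbance spectrum.
#' @return An object of class `"absorber"`.
#' @export
absorber <- function(label, spec, concentration = 1) {
  stopifnot(is_spectrum(spec))
  if (!is.finite(concentration) || concentration < 0)
    stop("concentration must be >= 0")
  if (spec$kind == "photon_flux_density")
    stop("absorber spectrum must be molar_absorption or absorbance_per_cm")
  structure(list(label = as.character(label), spec = spec,
                 concentration = concentration),
            class = "absorber")
}

#' A set of competing absorbers
#'
#' @param ... [absorber()] objects (or a single list of them).
#' @return An object of class `"absorber_set"` (a list of absorbers).
#' @export
absorber_set <- function(...) {
  abs_list <- list(...)
  if (length(abs_list) == 1L && !inherits(abs_list[[1L]], "absorber"))
    abs_list <- abs_list[[1L]]
  if (!all(vapply(abs_list, inherits, logical(1), "absorber")))
    stop("all elements must be absorber objects")
  labels <- vapply(abs_list, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("absorber labels must be unique")
  names(abs_list) <- labels
  structure(abs_list, class = "absorber_set")
}

# Restrict a photon-flux grid to a window and to >= 1 overlap point.
.window_grid <- function(p0, window) {
  grid <- p0$wavelength
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] >= window[2])
      stop("window must be c(lambda1, lambda2) with lambda1 < lambda2")
    grid <- grid[grid >= window[1] & grid <= window[2]]
  }
  if (length(grid) < 2L) stop("no spectral overlap")
  grid
}

# Per-cm decadic absorbance of one absorber on a grid.
.absorbance_on <- function(ab, grid) {
  spectrum_at(ab$spec, grid) * ab$concentration
}

#' Water (CDOM) absorption spectrum from the dissolved organic carbon
#'
#' When no measured water absorbance is available, the absorbance of the
#' chromophoric dissolved organic matter is estimated from the DOC as
#' `A1(lambda) = 0.45 * DOC * exp(-0.015 * lambda)` (cm^-1), with DOC in
#' mg C per litre.
#'
#' @param doc dissolved organic carbon, mg_C L^-1 (>= 0).
#' @param wavelength numeric grid (nm).
#' @return An `absorbance_per_cm` [spectrum()].
#' @examples
#' cdom_absorbance(2, seq(300, 500, 5))
#' @export
cdom_absorbance <- function(doc, wavelength) {
  if (!is.finite(doc) || doc < 0) stop("DOC must be nonnegative")
  spectrum(wavelength, 0.45 * doc * exp(-0.015 * wavelength),
           "absorbance_per_cm")
}

#' Photon flux absorbed by a single compound
#'
#' The absorbed photon flux is
#' `Pa = integral p0(lambda) * (1 - 10^(-eps(lambda) * b * c)) dlambda`
#' (trapezoidal quadrature on the incident-flux grid), the Lambert-Beer
#' absorbed fraction of the incident spectral photon flux density.
#'
#' @param p0 incident `photon_flux_density` [spectrum()].
#' @param spec the compound's `molar_absorption` spectrum (or an
#'   `absorbance_per_cm` spectrum with `concentration = 1`).
#' @param concentration mol L^-1.
#' @param path_cm optical path in cm (see [optical_path()]).
#' @param window optional integration window `c(lambda1, lambda2)` (nm);
#'   default: the full incident grid.
#' @return absorbed photon flux, Einstein cm^-2 s^-1.
#' @export
absorbed_photon_flux <- function(p0, spec, concentration, path_cm,
                                 window = NULL) {
  stopifnot(is_spectrum(p0), p0$kind == "photon_flux_density")
  ab <- absorber("target", spec, concentration)
  grid <- .window_grid(p0, window)
  a <- .absorbance_on(ab, grid) * path_cm
  p <- spectrum_at(p0, grid)
  pracma::trapz(grid, p * (1 - 10^(-a)))
}

#' Photon flux absorbed by each member of a mixture
#'
#' In a multi-chromophore solution every absorber receives the fraction
#' `A_i(lambda) / A_tot(lambda)` of the total absorbed photon flux at each
#' wavelength; grid points where the total absorbance is zero contribute
#' nothing (the 0/0 limit). The per-absorber fluxes sum exactly to the
#' absorbed flux of the lumped system.
#'
#' @param p0 incident `photon_flux_density` [spectrum()].
#' @param absorbers an [absorber_set()].
#' @param path_cm optical path in cm.
#' @param window optional integration window (nm).
#' @return named numeric vector of absorbed photon fluxes
#'   (Einstein cm^-2 s^-1), one per absorber label.
#' @export
competitive_absorption <- function(p0, absorbers, path_cm, window = NULL) {
  stopifnot(is_spectrum(p0), p0$kind == "photon_flux_density")
  if (!inherits(absorbers, "absorber_set")) absorbers <- absorber_set(absorbers)
  if (length(absorbers) < 1L) stop("need at least one absorber")
  grid <- .window_grid(p0, window)
  p <- spectrum_at(p0, grid)
  amat <- vapply(absorbers, .absorbance_on, numeric(length(grid)), grid = grid)
  amat <- matrix(amat, nrow = length(grid))
  atot <- rowSums(amat)
  absorbed <- p * (1 - 10^(-atot * path_cm))
  frac <- amat / ifelse(atot > 0, atot, 1)
  frac[atot == 0, ] <- 0
  out <- apply(frac * absorbed, 2L, function(v) pracma::trapz(grid, v))
  names(out) <- names(absorbers)
  out
}

#' Light-screening factor of co-solutes on a compound's direct photolysis
#'
#' `chi` is the ratio between the photon flux a compound absorbs in the
#' presence of co-solutes (which compete for the incident photons) and the
#' flux it would absorb alone. Integration runs over the window where the
#' compound's absorption overlaps the source spectrum; `0 < chi <= 1`.
#'
#' @param p0 incident `photon_flux_density` [spectrum()].
#' @param target an [absorber()]: the compound whose photolysis is screened.
#' @param co_solutes an [absorber_set()] of the competing absorbers.
#' @param path_cm optical path in cm.
#' @return dimensionless screening factor in (0, 1].
#' @export
screening_factor_chi <- function(p0, target, co_solutes, path_cm) {
  stopifnot(is_spectrum(p0), p0$kind == "photon_flux_density",
            inherits(target, "absorber"))
  if (!inherits(co_solutes, "absorber_set")) co_solutes <- absorber_set(co_solutes)
  grid <- .window_grid(p0, NULL)
  a_t <- .absorbance_on(target, grid)
  supp <- which(a_t > 0 & spectrum_at(p0, grid) > 0)
  if (length(supp) < 2L)
    stop("target absorbs nowhere within the source spectrum; chi undefined")
  window <- range(grid[supp])
  alone <- absorbed_photon_flux(p0, target$spec, target$concentration,
                                path_cm, window = window)
  mix <- absorber_set(c(list(target), unclass(co_solutes)))
  with_co <- competitive_absorption(p0, mix, path_cm, window = window)[[target$label]]
  with_co / alone
}

# J per Einstein at wavelength lambda (nm): N_A * h * c / lambda.
.NA_HC_J_NM <- 6.02214076e23 * 6.62607015e-34 * 2.99792458e8 * 1e9

#' Energy carried by one Einstein of photons
#'
#' @param wavelength nm.
#' @return J per Einstein (mole of photons).
#' @export
einstein_energy <- function(wavelength) .NA_HC_J_NM / wavelength

#' Band-integrated irradiance of a photon-flux spectrum
#'
#' Converts the spectral photon flux density to energy units and integrates
#' over a wavelength band.
#'
#' @param p0 `photon_flux_density` [spectrum()].
#' @param band `c(lambda1, lambda2)` nm; default the 290-400 nm UV band.
#' @return irradiance in W m^-2.
#' @export
band_irradiance <- function(p0, band = c(290, 400)) {
  grid <- .window_grid(p0, band)
  p <- spectrum_at(p0, grid)
  # Einstein cm^-2 s^-1 nm^-1 * J Einstein^-1 -> W cm^-2; x 1e4 -> W m^-2
  pracma::trapz(grid, p * einstein_energy(grid)) * 1e4
}

#' Normalize a spectrum to a target UV irradiance
#'
#' Rescales an incident photon-flux spectrum so that its energy integral
#' over the UV band equals the target irradiance. The reference condition of
#' the model's steady-state outputs is 22 W m^-2 over 290-400 nm.
#'
#' @param p0 `photon_flux_density` [spectrum()].
#' @param target_w_m2 target band irradiance (W m^-2); default 22.
#' @param band wavelength band (nm); default `c(290, 400)`.
#' @return the rescaled [spectrum()].
#' @export
scale_to_uv_irradiance <- function(p0, target_w_m2 = 22, band = c(290, 400)) {
  cur <- band_irradiance(p0, band)
  if (cur <= 0) stop("zero photon flux in the normalization band")
  spectrum(p0$wavelength, p0$value * (target_w_m2 / cur), p0$kind)
}
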