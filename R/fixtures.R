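# Synthetic data generators: a parametric solar spectrum, laboratory lamp
# spectra, a synthetic test compound, and noisy kinetic traces with known
# ground truth. These make the whole package testable offline; none of the
# spectra are measured data.

#' Synthetic solar UV-visible spectrum
#'
#' A smooth parametric stand-in for a mid-latitude summer surface sunlight
#' spectrum: a sigmoidal atmospheric cut-on near 300 nm times a slowly
#' rising envelope, normalized so the 290-400 nm band irradiance is
#' 22 W m^-2 (the model's reference UV irradiance). Deterministic.
#'
#' @param grid wavelength grid (nm); default `seq(280, 500, 2)`.
#' @param uv_w_m2 band irradiance to normalize to (default 22).
#' @return a `photon_flux_density` [spectrum()].
#' @export
synthetic_solar_spectrum <- function(grid = seq(280, 500, 2), uv_w_m2 = 22) {
  onset <- 1 / (1 + exp(-(grid - 305) / 6))
  envelope <- 1 + 0.004 * (grid - 300)
  sp <- spectrum(grid, 1e-9 * onset * pmax(envelope, 0),
                 "photon_flux_density")
  scale_to_uv_irradiance(sp, uv_w_m2)
}

#' Synthetic laboratory lamp spectra
#'
#' Gaussian emission bands typical of the lamps used in irradiation
#' kinetics: UVB (313 nm), UVA (365 nm) and yellow (575 nm, for
#' visible-light dye sensitizers).
#'
#' @param type `"uvb"`, `"uva"` or `"yellow"`.
#' @param grid wavelength grid (nm); default spans the band.
#' @param peak peak spectral photon flux density (default 1e-9
#'   Einstein cm^-2 s^-1 nm^-1).
#' @return a `photon_flux_density` [spectrum()].
#' @export
lamp_spectrum <- function(type = c("uvb", "uva", "yellow"), grid = NULL,
                          peak = 1e-9) {
  type <- match.arg(type)
  par <- switch(type, uvb = c(313, 10), uva = c(365, 15),
                yellow = c(575, 25))
  if (is.null(grid))
    grid <- seq(par[1] - 4 * par[2], par[1] + 4 * par[2], length.out = 81)
  spectrum(grid, peak * exp(-0.5 * ((grid - par[1]) / par[2])^2),
           "photon_flux_density")
}

#' Synthetic test-compound spectral table
#'
#' The package's built-in test compound mimics an ibuprofen-like profile:
#' a molar absorption spectrum decaying exponentially through the UVB into
#' a weak environmental-UV tail (synthetic, not a measured spectrum),
#' paired with the synthetic solar spectrum. The matching scalar
#' photoreactivity (quantum yield 0.33; rate constants 1.0e10 with the
#' hydroxyl radical, 6e4 with singlet oxygen, 4.5e7 with triplet CDOM;
#' intermediate yields 0.25/0.023/0/0.31 for direct
#' photolysis/hydroxyl/singlet-oxygen/triplet) is available from
#' [ibuprofen_reactivity()].
#'
#' @param grid wavelength grid (nm); default that of
#'   [synthetic_solar_spectrum()].
#' @return list with `p0` and `epsilon` spectra (a molecule list for
#'   [photic_run()]).
#' @export
synthetic_molecule_table <- function(grid = seq(280, 500, 2)) {
  p0 <- synthetic_solar_spectrum(grid)
  eps <- spectrum(grid, 260 * exp(-(grid - 264) / 9), "molar_absorption")
  list(p0 = p0, epsilon = eps)
}

#' Ibuprofen-like photoreactivity parameter set
#'
#' @param with_yields include the intermediate (4-isobutylacetophenone)
#'   formation yields (default TRUE).
#' @return a [photo_reactivity()].
#' @export
ibuprofen_reactivity <- function(with_yields = TRUE) {
  photo_reactivity(
    phi_direct = 0.33, k_oh = 1.0e10, k_co3 = 0, k_1o2 = 6e4,
    k_3cdom = 4.5e7,
    yields = if (with_yields) c(phot = 0.25, oh = 0.023, o2 = 0, dom = 0.31)
    else NULL)
}

#' Noisy first-order kinetic trace with known ground truth
#'
#' @param times sampling times (s).
#' @param c0 initial concentration (mol L^-1).
#' @param k first-order rate constant (s^-1).
#' @param noise multiplicative noise sd (fraction; 0 = noiseless).
#' @param seed optional RNG seed (set when given).
#' @return a [kinetic_trace()] with attribute `truth = c(c0, k)`.
#' @export
synthetic_first_order_trace <- function(times, c0, k, noise = 0,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- c0 * exp(-k * times)
  if (noise > 0) conc <- conc * (1 + stats::rnorm(length(times), 0, noise))
  tr <- kinetic_trace(times, pmax(conc, 0))
  attr(tr, "truth") <- c(c0 = c0, k = k)
  tr
}

#' Write the offline fixture set
#'
#' Generates, deterministically for a given seed, the synthetic spectra
#' (solar, UVB/UVA/yellow lamps), the synthetic test-compound molecule
#' table (quantum-yield column fixed at 0.33, water-absorbance column
#' disabled with -1 sentinels), and noisy kinetic traces/rate tables for
#' every fitting procedure, each with its generating parameters recorded
#' in `ground_truth.csv`.
#'
#' @param dir output directory (created if missing).
#' @param seed RNG seed (default 1).
#' @param noise multiplicative noise on the synthetic measurements
#'   (default 0.02).
#' @return invisible named character vector of the written paths.
#' @export
generate_fixtures <- function(dir, seed = 1, noise = 0.02) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- c()
  put <- function(name) {
    p <- file.path(dir, name)
    paths[[name]] <<- p
    p
  }

  write_spectrum_csv(synthetic_solar_spectrum(), put("solar.csv"))
  for (lt in c("uvb", "uva", "yellow"))
    write_spectrum_csv(lamp_spectrum(lt), put(paste0("lamp_", lt, ".csv")))

  mol <- synthetic_molecule_table()
  mol$phi <- spectrum(mol$p0$wavelength,
                      rep(0.33, length(mol$p0$wavelength)),
                      "photon_flux_density")
  write_molecule_csv(mol, put("ibuprofen_synthetic.csv"))

  truth <- list()

  # first-order trace
  tr <- synthetic_first_order_trace(seq(0, 4e5, length.out = 25), 2e-5,
                                    1e-5, noise = noise)
  utils::write.csv(data.frame(time_s = tr$time, conc_molL = tr$conc),
                   put("trace_first_order.csv"), row.names = FALSE)
  truth$trace_first_order <- c(c0 = 2e-5, k = 1e-5)

  # hydroxyl-radical competition rates
  des <- oh_competition_design(s0 = 2e-5, h2o2 = 5e-3,
                               alcohol = "2-propanol",
                               alcohol_grid = c(0, 1e-4, 3e-4, 1e-3, 3e-3,
                                                1e-2))
  r <- oh_competition_rates(des, r_oh = 1e-9, k17 = 5e9)
  r <- r * (1 + stats::rnorm(length(r), 0, noise))
  utils::write.csv(data.frame(alcohol_molL = des$alcohol_grid,
                              rate_molL_s = r),
                   put("oh_competition_rates.csv"), row.names = FALSE)
  truth$oh_competition <- c(r_oh = 1e-9, k17 = 5e9)

  # back-reduction dose-response
  phoh <- c(0, 1, 2, 4, 6, 10)
  rb <- back_reduction_rates(phoh, r0 = 2e-10, phoh_half = 4)
  rb <- rb * (1 + stats::rnorm(length(rb), 0, noise))
  utils::write.csv(data.frame(phoh_umolL = phoh, rate_molL_s = rb),
                   put("back_reduction_rates.csv"), row.names = FALSE)
  truth$back_reduction <- c(r0 = 2e-10, phoh_half = 4)

  # substrate + intermediate pair (direct-photolysis channel, yield 0.25)
  times <- seq(0, 6e5, length.out = 31)
  s0 <- 1e-4
  k_s <- 8e-6
  k_i <- 3e-6
  kp <- 0.25 * k_s
  tr_s <- synthetic_first_order_trace(times, s0, k_s, noise = noise)
  conc_i <- intermediate_trace(times, s0, k_s, k_i, kp)
  conc_i <- conc_i * (1 + stats::rnorm(length(times), 0, noise))
  conc_i[1] <- 0
  utils::write.csv(data.frame(time_s = times, conc_molL = tr_s$conc),
                   put("trace_intermediate_s.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = times, conc_molL = pmax(conc_i, 0)),
                   put("trace_intermediate_i.csv"), row.names = FALSE)
  truth$intermediate <- c(s0 = s0, k_s = k_s, k_i = k_i, kprime_i = kp,
                          y_i = 0.25)

  tdf <- do.call(rbind, lapply(names(truth), function(nm)
    data.frame(experiment = nm, parameter = names(truth[[nm]]),
               value = unname(truth[[nm]]))))
  utils::write.csv(tdf, put("ground_truth.csv"), row.names = FALSE)
  invisible(unlist(paths))
}
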