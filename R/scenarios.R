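# Scenario extensions layered on the engine: pH-combined kinetics,
# stratified lakes, rivers, evaporative concentration, and 2D parameter
# sweeps.

#' Combine acid/base-form rate constants at a given pH
#'
#' A compound with a monoprotic acid-base equilibrium is modelled twice
#' (acidic and basic form) on the same water; the overall rate constant is
#' the speciation-weighted mean
#' `k = (10^(-pH) k_HA + 10^(-pKa) k_A) / (10^(-pH) + 10^(-pKa))`,
#' applied per pathway and to totals.
#'
#' @param pair an [acid_base_pair()] carrying `pka`, `k_acid`, `k_base`
#'   (scalars or equally named vectors).
#' @param ph pH value(s).
#' @return combined rate constant(s); for vector `k`s, a matrix with one
#'   row per pH.
#' @examples
#' combine_ph(acid_base_pair(7.3, k_acid = 2, k_base = 8), ph = 7.3)
#' @export
combine_ph <- function(pair, ph) {
  stopifnot(inherits(pair, "acid_base_pair"))
  if (is.null(pair$k_acid) || is.null(pair$k_base))
    stop("pair must carry k_acid and k_base")
  a <- speciation_fractions(pair$pka, ph)
  out <- outer(a$alpha_acid, pair$k_acid) + outer(a$alpha_base, pair$k_base)
  if (length(pair$k_acid) == 1L || length(ph) == 1L) drop(out)
  else `rownames<-`(out, NULL)
}

#' Stratified lake description
#'
#' @param d_th thermocline depth (m), `0 < d_th < d_tot`.
#' @param d_tot total lake depth (m).
#' @param water a [water_body()] carrying the shared chemistry (its own
#'   depth is ignored).
#' @return An object of class `"stratified_lake"`.
#' @export
stratified_lake <- function(d_th, d_tot, water) {
  if (!(d_th > 0 && d_th < d_tot)) stop("need 0 < d_th < d_tot")
  stopifnot(inherits(water, "water_body"))
  structure(list(d_th = d_th, d_tot = d_tot, water = water),
            class = "stratified_lake")
}

#' Sunlight spectrum transmitted to the thermocline
#'
#' Lambert-Beer attenuation of the surface spectrum through the epilimnion:
#' `p_th(lambda) = p_epi(lambda) * 10^(-A1(lambda) * d_th)`, with the
#' water absorbance in cm^-1 and the (psi-corrected) thermocline depth in
#' cm.
#'
#' @param p_epi surface `photon_flux_density` [spectrum()].
#' @param a1 water `absorbance_per_cm` [spectrum()].
#' @param d_th_m thermocline depth (m).
#' @param psi path-correction factor (default 1).
#' @return the attenuated [spectrum()].
#' @export
thermocline_spectrum <- function(p_epi, a1, d_th_m, psi = 1) {
  stopifnot(is_spectrum(p_epi), p_epi$kind == "photon_flux_density",
            is_spectrum(a1), a1$kind == "absorbance_per_cm")
  d_cm <- optical_path(d_th_m, "m", psi)
  att <- 10^(-spectrum_at(a1, p_epi$wavelength) * d_cm)
  spectrum(p_epi$wavelength, p_epi$value * att, p_epi$kind)
}

#' Run the engine for the layers of a stratified lake
#'
#' Three runs with shared chemistry: the epilimnion (surface spectrum,
#' depth `d_th`), the hypolimnion (thermocline-attenuated spectrum, depth
#' `d_tot - d_th`) and the fully mixed lake (surface spectrum, depth
#' `d_tot`).
#'
#' @param molecule as in [photic_run()].
#' @param lake a [stratified_lake()].
#' @param reactivity a [photo_reactivity()].
#' @param profile a [default_profile()].
#' @param ... passed to [photic_run()].
#' @return named list of `"pathway_result"`s: `epilimnion`, `hypolimnion`,
#'   `mixed`.
#' @export
run_stratified <- function(molecule, lake, reactivity,
                           profile = default_profile(), ...) {
  stopifnot(inherits(lake, "stratified_lake"))
  w <- lake$water
  p_epi <- scale_to_uv_irradiance(molecule$p0)
  a1 <- if (!is.null(w$aw)) w$aw else cdom_absorbance(w$doc, p_epi$wavelength)
  p_th <- thermocline_spectrum(p_epi, a1, lake$d_th, w$psi)
  relayer <- function(depth) {
    w2 <- w
    w2$depth_m <- depth
    w2
  }
  mol_epi <- molecule
  mol_epi$p0 <- p_epi
  mol_hypo <- molecule
  mol_hypo$p0 <- p_th
  list(
    epilimnion = photic_run(mol_epi, relayer(lake$d_th), reactivity,
                            profile, normalize = FALSE, ...),
    hypolimnion = photic_run(mol_hypo, relayer(lake$d_tot - lake$d_th),
                             reactivity, profile, normalize = FALSE, ...),
    mixed = photic_run(mol_epi, relayer(lake$d_tot), reactivity, profile,
                       normalize = FALSE, ...)
  )
}

#' River reference geometry
#'
#' @param q0 reference flow rate, m^3 s^-1.
#' @param v0 reference mean flow velocity, m s^-1.
#' @param d0 reference mean depth, m.
#' @param w0 reference mean width, m.
#' @return An object of class `"river_geometry"`. `q0` must equal
#'   `v0 * d0 * w0` within 1%.
#' @export
river_geometry <- function(q0, v0, d0, w0) {
  v <- c(q0 = q0, v0 = v0, d0 = d0, w0 = w0)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all fields must be positive")
  if (abs(q0 - v0 * d0 * w0) > 0.01 * q0)
    stop("q0 must equal v0 * d0 * w0 within 1%")
  structure(as.list(v), class = "river_geometry")
}

#' Rescale river geometry to a new flow rate
#'
#' A change in flow rate is assumed evenly distributed over the three
#' spatial directions, so velocity, depth and width all scale as the cube
#' root of the flow ratio: `v/v0 = d/d0 = w/w0 = (Q/Q0)^(1/3)`. For
#' artificial channels with pinned width, the change splits between
#' velocity and depth as the square root instead.
#'
#' @param geom a [river_geometry()].
#' @param q new flow rate, m^3 s^-1 (> 0).
#' @param fixed_width pin the width (default FALSE: natural channel).
#' @return named numeric vector `c(v = , d = , w = )` (m s^-1, m, m).
#' @examples
#' river_rescale(river_geometry(100, 1, 4, 25), q = 1)  # d = 0.86 m
#' @export
river_rescale <- function(geom, q, fixed_width = FALSE) {
  stopifnot(inherits(geom, "river_geometry"))
  if (!is.finite(q) || q <= 0) stop("q must be positive")
  if (fixed_width) {
    s <- sqrt(q / geom$q0)
    c(v = geom$v0 * s, d = geom$d0 * s, w = geom$w0)
  } else {
    s <- (q / geom$q0)^(1 / 3)
    c(v = geom$v0 * s, d = geom$d0 * s, w = geom$w0 * s)
  }
}

#' Half-life length of a substrate in a flowing river
#'
#' The river length over which photoreactions halve the substrate
#' concentration: `l_1/2 = v * t_1/2`.
#'
#' @param t_half_s half-life in seconds (use
#'   `t_half_ssd * ssd_equivalent_seconds` to convert from SSD).
#' @param v mean flow velocity, m s^-1.
#' @return list with `m` and `km`.
#' @examples
#' half_life_length(10 * 86400, 1)$km  # 864 km
#' @export
half_life_length <- function(t_half_s, v) {
  if (t_half_s < 0 || v < 0) stop("inputs must be nonnegative")
  l <- v * t_half_s
  list(m = l, km = l / 1000)
}

#' Evaporative concentration of a shrinking water body
#'
#' Evaporation removes water but not solutes; with volume contraction
#' assumed even along the three axes, every solute concentration scales as
#' `(d0 / d)^3` when the depth drops from `d0` to `d`.
#'
#' @param base a [water_body()] at the initial depth.
#' @param d new depth (m), `0 < d <= depth of base`.
#' @return a [water_body()] at depth `d` with scaled concentrations.
#' @export
evaporate <- function(base, d) {
  stopifnot(inherits(base, "water_body"))
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (d > base$depth_m) stop("dilution not modeled here (d > d0)")
  f <- (base$depth_m / d)^3
  water_body(d, nitrate = base$nitrate * f, nitrite = base$nitrite * f,
             bicarbonate = base$bicarbonate * f,
             carbonate = base$carbonate * f, doc = base$doc * f,
             bromide = base$bromide * f, aw = NULL, psi = base$psi)
}

# Engine input variables addressable in sweeps (output-table names).
.SWEEP_VARS <- c("d", "DOC", "CNO3", "CNO2", "CHCO3", "CCO3", "CBr",
                 "fi_P", "kP_OH", "kP_CO3", "kP_1O2", "kP_3DOM")

.apply_sweep_var <- function(water, reactivity, var, value) {
  switch(var,
         d = water$depth_m <- value,
         DOC = water$doc <- value,
         CNO3 = water$nitrate <- value,
         CNO2 = water$nitrite <- value,
         CHCO3 = water$bicarbonate <- value,
         CCO3 = water$carbonate <- value,
         CBr = water$bromide <- value,
         fi_P = reactivity$phi_direct <- value,
         kP_OH = reactivity$k_oh <- value,
         kP_CO3 = reactivity$k_co3 <- value,
         kP_1O2 = reactivity$k_1o2 <- value,
         kP_3DOM = reactivity$k_3cdom <- value,
         stop(sprintf("unknown sweep variable '%s'", var)))
  list(water = water, reactivity = reactivity)
}

#' Map legacy -1/-2 sentinels to named sweep variables
#'
#' Compatibility shim for the historical convention where setting an engine
#' input to -1 declared it the X variable and -2 the Y variable of a run.
#'
#' @param config named list/vector of engine inputs, possibly containing
#'   -1 and -2 sentinels.
#' @return list with `x_var`, `y_var` (names or NULL) and `fixed` (the
#'   remaining config entries).
#' @export
resolve_sweep_sentinels <- function(config) {
  vals <- unlist(config)
  x_var <- names(vals)[vals == -1]
  y_var <- names(vals)[vals == -2]
  if (length(x_var) > 1L || length(y_var) > 1L)
    stop("at most one -1 (X) and one -2 (Y) sentinel allowed")
  fixed <- config[!(names(config) %in% c(x_var, y_var))]
  list(x_var = if (length(x_var)) x_var else NULL,
       y_var = if (length(y_var)) y_var else NULL,
       fixed = fixed)
}

#' Sweep one or two engine inputs over a grid
#'
#' Evaluates [photic_run()] on the X (times Y) grid of any two engine
#' inputs (see the variable names in the output-table convention: `d`,
#' `DOC`, `CNO3`, `CNO2`, `CHCO3`, `CCO3`, `CBr`, `fi_P`, `kP_OH`,
#' `kP_CO3`, `kP_1O2`, `kP_3DOM`). Rows are X-major.
#'
#' When `scenario = "river"` and the swept variable is the depth, each row
#' also reports the flow rate recovered from the cube-root scaling,
#' `Q = Q0 (d/d0)^3`, and the matching velocity. When
#' `scenario = "evaporation"` and the swept variable is the depth, all
#' solute concentrations are scaled by `(d0/d)^3` from the base water
#' before the run.
#'
#' @param molecule,water,reactivity,profile as in [photic_run()].
#' @param x_var,x_grid the X variable name and its numeric grid.
#' @param y_var,y_grid optional Y variable and grid.
#' @param scenario `"none"`, `"river"` or `"evaporation"`.
#' @param river a [river_geometry()] (required for the river scenario).
#' @param ... passed to [photic_run()].
#' @return data.frame of output-table rows, one per grid cell.
#' @export
photic_sweep <- function(molecule, water, reactivity, x_var, x_grid,
                         y_var = NULL, y_grid = NULL,
                         profile = default_profile(),
                         scenario = c("none", "river", "evaporation"),
                         river = NULL, ...) {
  scenario <- match.arg(scenario)
  if (!x_var %in% .SWEEP_VARS)
    stop(sprintf("unknown sweep variable '%s'", x_var))
  if (!is.null(y_var)) {
    if (!y_var %in% .SWEEP_VARS)
      stop(sprintf("unknown sweep variable '%s'", y_var))
    if (identical(x_var, y_var)) stop("x_var and y_var must differ")
  }
  if (scenario == "river" && is.null(river))
    stop("the river scenario needs a river_geometry")
  if (length(x_grid) < 1L) stop("empty x_grid")
  y_vals <- if (is.null(y_var)) NA_real_ else y_grid
  if (length(y_vals) < 1L) stop("empty y_grid")
  base_water <- water

  rows <- list()
  for (xv in x_grid) {
    for (yv in y_vals) {
      w <- base_water
      r <- reactivity
      if (scenario == "evaporation" && identical(x_var, "d")) {
        w <- evaporate(base_water, xv)
      } else {
        st <- .apply_sweep_var(w, r, x_var, xv)
        w <- st$water
        r <- st$reactivity
      }
      if (!is.null(y_var)) {
        st <- .apply_sweep_var(w, r, y_var, yv)
        w <- st$water
        r <- st$reactivity
      }
      res <- photic_run(molecule, w, r, profile, ...)
      row <- as_savetable(res, x = xv, y = yv)
      if (scenario == "river" && identical(x_var, "d")) {
        row$Q <- river$q0 * (xv / river$d0)^3
        row$v <- river$v0 * (xv / river$d0)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
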