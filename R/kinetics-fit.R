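# Fitting procedures for laboratory irradiation kinetics: initial rates,
# quantum yields, scavenger competition for the hydroxyl radical, probe
# determination of singlet-oxygen and triplet reactivity, back-reduction,
# competition kinetics with a reference compound, and intermediate yields.
#
# Nonlinear fits are least squares (minpack.lm), initialized from the
# linearized forms of the same rate equations. Residual weighting is
# absolute by default; "relative" weights each residual by 1/y.

#' A concentration-versus-time irradiation trace
#'
#' @param times seconds, increasing.
#' @param conc mol L^-1, >= 0.
#' @param label optional character tag.
#' @return An object of class `"kinetic_trace"` (a data.frame with columns
#'   `time` and `conc`).
#' @export
kinetic_trace <- function(times, conc, label = "trace") {
  if (length(times) != length(conc)) stop("times and conc lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  structure(data.frame(time = as.numeric(times), conc = as.numeric(conc)),
            label = label, class = c("kinetic_trace", "data.frame"))
}

.fit_weights <- function(y, weighting) {
  if (weighting == "relative") 1 / pmax(y, max(y) * 1e-6)^2 else rep(1, length(y))
}

#' Initial transformation rate from a kinetic trace
#'
#' Fits either a first-order decay `C0 * exp(-k t)` or a zero-order line
#' `C0 * (1 - k t)` by least squares, and returns the initial rate
#' `R0 = k * C0` (first order) or the constant rate (zero order). A fitted
#' negative rate constant on a noisy trace is clipped at zero with a
#' warning.
#'
#' @param trace a [kinetic_trace()] with >= 3 points and positive initial
#'   concentration.
#' @param model `"first_order"` or `"zero_order"`.
#' @param weighting `"absolute"` (default) or `"relative"` residuals.
#' @return list with `r0` (mol L^-1 s^-1), `k` (s^-1 for first order,
#'   mol L^-1 s^-1 for zero order), `c0`, and the fitted model object (or
#'   NULL for degenerate traces).
#' @export
initial_rate <- function(trace, model = c("first_order", "zero_order"),
                         weighting = c("absolute", "relative")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  stopifnot(inherits(trace, "kinetic_trace"))
  if (nrow(trace) < 3L) stop("need at least 3 points")
  if (trace$conc[1] <= 0) stop("initial concentration must be positive")
  w <- .fit_weights(trace$conc, weighting)
  if (model == "zero_order") {
    fit <- stats::lm(conc ~ time, data = trace, weights = w)
    c0 <- unname(stats::coef(fit)[1])
    r0 <- -unname(stats::coef(fit)[2])
    if (r0 < 0) {
      warning("fitted rate is negative; clipped at 0")
      r0 <- 0
    }
    return(list(r0 = r0, k = r0, c0 = c0, fit = fit))
  }
  # first order: log-linear initialization, then nonlinear refinement
  pos <- trace$conc > 0
  k0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(conc) ~ time, data = trace[pos, ]))[2]
    max(-unname(sl), 0)
  } else 0
  fit <- tryCatch(
    minpack.lm::nlsLM(conc ~ c0 * exp(-k * time), data = trace,
                      start = list(c0 = trace$conc[1], k = k0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- k0
    c0 <- trace$conc[1]
  } else {
    k <- unname(stats::coef(fit)[["k"]])
    c0 <- unname(stats::coef(fit)[["c0"]])
  }
  if (k < 0) {
    warning("fitted rate constant is negative; clipped at 0")
    k <- 0
  }
  list(r0 = k * c0, k = k, c0 = c0, fit = fit)
}

#' Direct photolysis quantum yield from rate and absorbed flux
#'
#' `Phi = R0 / Pa`: moles transformed per Einstein absorbed. `R0` must be
#' corrected for dark (hydrolysis/biotic) losses beforehand.
#'
#' @param r0 initial phototransformation rate, mol L^-1 s^-1 (>= 0).
#' @param pa absorbed photon flux, Einstein L^-1 s^-1 (> 0); e.g.
#'   [absorbed_photon_flux()] divided by the irradiated volume per area.
#' @return quantum yield, mol Einstein^-1.
#' @export
quantum_yield <- function(r0, pa) {
  if (!is.finite(pa) || pa <= 0)
    stop("substrate does not absorb in the source window (Pa = 0)")
  if (!is.finite(r0) || r0 < 0) stop("r0 must be >= 0 (dark-corrected)")
  r0 / pa
}

# Hydroxyl-radical rate constants of the usual alcohol scavengers,
# L mol^-1 s^-1.
.ALCOHOL_K16 <- c(methanol = 9.7e8, ethanol = 1.9e9, `2-propanol` = 1.9e9,
                  `t-butanol` = 6.0e8)

#' Design of a hydroxyl-radical scavenger-competition experiment
#'
#' Hydrogen peroxide photolysis forms the hydroxyl radical; an alcohol
#' scavenger of known reactivity competes with the substrate for it. The
#' substrate rate as a function of the alcohol concentration follows
#' `R_S = R_OH * k17 [S] / (k15 [H2O2] + k16 [Alcohol] + k17 [S])`.
#'
#' @param s0 substrate concentration, mol L^-1.
#' @param h2o2 hydrogen peroxide concentration, mol L^-1.
#' @param alcohol one of `"methanol"`, `"ethanol"`, `"2-propanol"`,
#'   `"t-butanol"` (k16 = 9.7e8, 1.9e9, 1.9e9, 6.0e8 L mol^-1 s^-1).
#' @param alcohol_grid alcohol concentrations, mol L^-1, including 0.
#' @param k15 hydroxyl + H2O2 rate constant (default 2.7e7 L mol^-1 s^-1).
#' @return An object of class `"oh_competition_design"`.
#' @export
oh_competition_design <- function(s0, h2o2, alcohol = "2-propanol",
                                  alcohol_grid, k15 = 2.7e7) {
  alcohol <- match.arg(alcohol, names(.ALCOHOL_K16))
  if (!any(alcohol_grid == 0)) stop("alcohol_grid must include 0")
  if (s0 <= 0 || h2o2 <= 0) stop("s0 and h2o2 must be positive")
  structure(list(s0 = s0, h2o2 = h2o2, alcohol = alcohol,
                 alcohol_grid = sort(as.numeric(alcohol_grid)),
                 k15 = k15, k16 = .ALCOHOL_K16[[alcohol]]),
            class = "oh_competition_design")
}

#' Predicted substrate rates in a scavenger-competition experiment
#'
#' Forward model of the steady-state competition rate law, used to generate
#' synthetic data and as the fit function.
#'
#' @param design an [oh_competition_design()].
#' @param r_oh hydroxyl-radical formation rate, mol L^-1 s^-1.
#' @param k17 substrate + hydroxyl rate constant, L mol^-1 s^-1.
#' @param baseline additive scavenger-independent rate (e.g. residual direct
#'   photolysis), mol L^-1 s^-1; default 0.
#' @return rates at each alcohol level, mol L^-1 s^-1.
#' @export
oh_competition_rates <- function(design, r_oh, k17, baseline = 0) {
  stopifnot(inherits(design, "oh_competition_design"))
  with(design,
       r_oh * k17 * s0 / (k15 * h2o2 + k16 * alcohol_grid + k17 * s0) +
         baseline)
}

#' Fit the hydroxyl-radical competition rate law
#'
#' Estimates the hydroxyl formation rate `R_OH` and the substrate rate
#' constant `k17` from substrate rates measured at increasing scavenger
#' levels. A linearization of the reciprocal rate versus the alcohol
#' concentration supplies starting values for the nonlinear fit; with
#' `baseline = TRUE` a constant additive term absorbs residual direct
#' photolysis.
#'
#' @param design an [oh_competition_design()] (>= 4 alcohol levels incl. 0).
#' @param rates substrate initial rates at `design$alcohol_grid`,
#'   mol L^-1 s^-1.
#' @param baseline fit an additive constant term (default FALSE).
#' @param weighting `"absolute"` or `"relative"`.
#' @return list with `r_oh`, `k17`, their standard errors (`se_r_oh`,
#'   `se_k17`), the linearized estimates (`linear`), `baseline` and the
#'   nls fit object.
#' @export
fit_oh_competition <- function(design, rates, baseline = FALSE,
                               weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(design, "oh_competition_design"))
  alc <- design$alcohol_grid
  if (length(rates) != length(alc)) stop("rates and alcohol grid differ")
  if (length(alc) < 4L) stop("need >= 4 alcohol levels")
  if (any(rates <= 0)) stop("rates must be positive")
  slope <- stats::coef(stats::lm(rates ~ alc))[2]
  if (slope > 0)
    stop("rates increase with the scavenger: inconsistent with •OH scavenging")
  r_max <- rates[which.min(alc)]
  if (min(rates) > 0.5 * r_max)
    warning("max scavenger suppresses the rate by < 50%; extend the alcohol range")

  # linearization: 1/R_S = intercept + [k16 / (R_OH k17 [S])] * [Alcohol]
  lfit <- stats::lm(I(1 / rates) ~ alc)
  sl <- unname(stats::coef(lfit)[2])
  ic <- unname(stats::coef(lfit)[1])
  rohk17 <- design$k16 / (sl * design$s0)          # = R_OH * k17
  r_oh0 <- 1 / (ic - design$k15 * design$h2o2 * sl / design$k16)
  k17_0 <- rohk17 / r_oh0
  linear <- c(r_oh = r_oh0, k17 = k17_0)

  dat <- data.frame(alc = alc, r = rates)
  w <- .fit_weights(rates, weighting)
  k15h <- design$k15 * design$h2o2
  k16 <- design$k16
  s0 <- design$s0
  if (baseline) {
    fit <- minpack.lm::nlsLM(
      r ~ r_oh * k17 * s0 / (k15h + k16 * alc + k17 * s0) + b0, data = dat,
      start = list(r_oh = r_oh0, k17 = k17_0, b0 = 0), weights = w,
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(
      r ~ r_oh * k17 * s0 / (k15h + k16 * alc + k17 * s0), data = dat,
      start = list(r_oh = r_oh0, k17 = k17_0), weights = w,
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  list(r_oh = unname(cf[["r_oh"]]), k17 = unname(cf[["k17"]]),
       se_r_oh = unname(se[["r_oh"]]), se_k17 = unname(se[["k17"]]),
       baseline = if (baseline) unname(cf[["b0"]]) else 0,
       linear = linear, fit = fit)
}

#' Screening verdict for carbonate-radical reactivity
#'
#' Compares three matched irradiation series: substrate + nitrate +
#' bicarbonate, substrate + nitrate + phosphate buffer (same pH, no
#' carbonate-radical source), and substrate + bicarbonate without nitrate
#' (direct photolysis check). If the nitrate-free rates are not
#' sufficiently lower than the bicarbonate series, direct photolysis masks
#' the comparison; otherwise carbonate-radical reactivity is flagged when
#' the bicarbonate series outruns the phosphate series.
#'
#' @param r_bicarb,r_phosph,r_nocat rate arrays on a common level grid.
#' @param threshold nitrate-free rates at or above this fraction of the
#'   bicarbonate rates are "not sufficiently lower" (default 0.5).
#' @return `"co3_candidate"`, `"co3_negligible"` or
#'   `"inconclusive_direct_photolysis"`.
#' @export
carbonate_screening <- function(r_bicarb, r_phosph, r_nocat,
                                threshold = 0.5) {
  n <- length(r_bicarb)
  if (length(r_phosph) != n || length(r_nocat) != n)
    stop("the three series must share one level grid")
  if (mean(r_nocat) >= threshold * mean(r_bicarb))
    return("inconclusive_direct_photolysis")
  if (mean(r_bicarb) > mean(r_phosph)) "co3_candidate" else "co3_negligible"
}

#' Singlet-oxygen rate constant from a dye-sensitized experiment
#'
#' A visible-light dye photosensitizer forms singlet oxygen; the substrate
#' rate at low concentration is linear, `R_S = m [S]`. A furfuryl-alcohol
#' probe run under the same set-up fixes the singlet-oxygen formation rate
#' `R_1O2 = R_FFA (k28 + k31 [FFA]) / (k31 [FFA])`, whence
#' `k29 = m k28 k31 [FFA] / (R_FFA (k28 + k31 [FFA]))`.
#'
#' @param slope_m slope of `R_S` vs `[S]` in the linear regime, s^-1.
#' @param r_ffa initial degradation rate of the probe, mol L^-1 s^-1.
#' @param ffa probe concentration, mol L^-1 (> 0).
#' @param k28 first-order singlet-oxygen deactivation, s^-1 (default 2.5e5).
#' @param k31 probe + singlet oxygen rate constant (default 1e8
#'   L mol^-1 s^-1).
#' @return list with `k29` (L mol^-1 s^-1) and `r_1o2` (mol L^-1 s^-1).
#' @export
fit_1o2 <- function(slope_m, r_ffa, ffa, k28 = 2.5e5, k31 = 1e8) {
  if (!is.finite(ffa) || ffa <= 0) stop("probe concentration must be positive")
  if (slope_m < 0) stop("slope must be >= 0")
  r_1o2 <- r_ffa * (k28 + k31 * ffa) / (k31 * ffa)
  k29 <- if (slope_m == 0) 0 else slope_m * k28 * k31 * ffa /
    (r_ffa * (k28 + k31 * ffa))
  list(k29 = k29, r_1o2 = r_1o2)
}

#' Triplet-state rate constant from a ketone-proxy experiment
#'
#' With an aromatic-ketone CDOM proxy (4-carboxybenzophenone), the
#' substrate rate at low concentration is `R_S = m [S]` after correcting
#' the direct photolysis by the screening factor chi. The proxy's triplet
#' also forms singlet oxygen, which is subtracted:
#' `k = k' (m / Pa - 0.68 S_delta k29 / k28) = 6e5 m / Pa - 0.75 k29`.
#'
#' @param slope_m slope of the corrected `R_S` vs `[S]` plot, s^-1.
#' @param pa_cbbp photon flux absorbed by the proxy, Einstein L^-1 s^-1
#'   (from [competitive_absorption()], volume-normalized).
#' @param k29 substrate + singlet-oxygen rate constant, L mol^-1 s^-1
#'   (default 0: no singlet-oxygen correction).
#' @param k_prime first-order triplet inactivation in aerated solution,
#'   s^-1 (default 6e5).
#' @param s_delta singlet-oxygen yield of the triplet + O2 encounter
#'   (default 0.46).
#' @param k28 singlet-oxygen deactivation, s^-1 (default 2.5e5).
#' @return substrate + triplet rate constant, L mol^-1 s^-1.
#' @export
fit_triplet_cbbp <- function(slope_m, pa_cbbp, k29 = 0, k_prime = 6e5,
                             s_delta = 0.46, k28 = 2.5e5) {
  if (!is.finite(pa_cbbp) || pa_cbbp <= 0) stop("pa_cbbp must be positive")
  k <- k_prime * (slope_m / pa_cbbp - 0.68 * s_delta * k29 / k28)
  if (k < 0)
    stop("singlet-oxygen correction exceeds the observed reactivity")
  k
}

#' Predicted rates under antioxidant back-reduction
#'
#' Forward model `R_S = R_S0 / (1 + [Ph-OH] / [Ph-OH]_1/2)`.
#'
#' @param phoh phenolic antioxidant concentrations (same unit as
#'   `phoh_half`).
#' @param r0 rate without antioxidant, mol L^-1 s^-1.
#' @param phoh_half antioxidant concentration halving the rate.
#' @return predicted rates.
#' @export
back_reduction_rates <- function(phoh, r0, phoh_half) {
  r0 / (1 + phoh / phoh_half)
}

#' Fit the back-reduction dose-response
#'
#' Phenolic antioxidant moieties of DOM reduce one-electron-oxidized
#' substrate intermediates back to the parent, suppressing the apparent
#' triplet-sensitized rate. Fitting the phenol dose-response yields the
#' half-effect concentration; the DOM-equivalent is
#' `DOC_1/2 = 0.4 [Ph-OH]_1/2` (DOC_1/2 in mg_C L^-1, phenol in umol L^-1).
#'
#' @param phoh phenol concentrations, umol L^-1, including 0.
#' @param rates substrate rates at `phoh`, mol L^-1 s^-1.
#' @param weighting `"absolute"` or `"relative"`.
#' @return list with `phoh_half` (umol L^-1), `doc_half` (mg_C L^-1),
#'   `r0` and the fit object.
#' @export
fit_back_reduction <- function(phoh, rates,
                               weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  if (length(phoh) != length(rates)) stop("lengths differ")
  if (!any(phoh == 0)) stop("phoh must include a 0 level")
  if (any(rates <= 0)) stop("rates must be positive")
  if (stats::coef(stats::lm(rates ~ phoh))[2] > 0)
    stop("rates do not decrease with the antioxidant")
  # linearization: 1/R = 1/R0 + [Ph-OH] / ([Ph-OH]_1/2 R0)
  lfit <- stats::lm(I(1 / rates) ~ phoh)
  r0_0 <- 1 / unname(stats::coef(lfit)[1])
  half0 <- 1 / (unname(stats::coef(lfit)[2]) * r0_0)
  dat <- data.frame(phoh = phoh, r = rates)
  fit <- minpack.lm::nlsLM(r ~ r0 / (1 + phoh / half), data = dat,
                           start = list(r0 = r0_0, half = half0),
                           weights = .fit_weights(rates, weighting),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(phoh_half = unname(cf[["half"]]), doc_half = 0.4 * unname(cf[["half"]]),
       r0 = unname(cf[["r0"]]), fit = fit)
}

#' Second-order rate constant by competition kinetics
#'
#' Substrate `S` and a reference compound `R` of known rate constant with a
#' transient `X` are co-irradiated with the photosensitizer; a second run
#' without the photosensitizer measures their direct photolysis. After
#' correcting each compound's direct photolysis rate by its screening
#' factor chi (the photosensitizer absorbs part of the light the compounds
#' would otherwise receive), the rate-constant ratio equals the corrected
#' rate ratio:
#' `k_SX = k_RX (R_S' - chi_S R_S'') / (R_R' - chi_R R_R'')`.
#'
#' @param k_rx reference compound's rate constant with X, L mol^-1 s^-1.
#' @param trace_s,trace_r [kinetic_trace()]s of S and R with the
#'   photosensitizer.
#' @param trace_s_direct,trace_r_direct optional traces without the
#'   photosensitizer (omit when the compounds do not photolyze directly).
#' @param chi_s,chi_r screening factors from [screening_factor_chi()]
#'   (default 1).
#' @return list with `k_sx`, the corrected rates `r_s`, `r_r`, and the
#'   first-order constants of the four traces.
#' @export
competition_kinetics <- function(k_rx, trace_s, trace_r,
                                 trace_s_direct = NULL, trace_r_direct = NULL,
                                 chi_s = 1, chi_r = 1) {
  if (k_rx <= 0) stop("k_rx must be positive")
  fs <- initial_rate(trace_s)
  fr <- initial_rate(trace_r)
  if (abs(fs$c0 - fr$c0) > 0.02 * fr$c0)
    warning("initial concentrations of S and R differ by more than 2%")
  rs2 <- if (!is.null(trace_s_direct)) initial_rate(trace_s_direct)$r0 else 0
  rr2 <- if (!is.null(trace_r_direct)) initial_rate(trace_r_direct)$r0 else 0
  r_s <- fs$r0 - chi_s * rs2
  r_r <- fr$r0 - chi_r * rr2
  if (r_r <= 0) stop("reference compound not degraded by X")
  k_sx <- k_rx * r_s / r_r
  ratio <- k_sx / k_rx
  if (ratio < 0.1 || ratio > 10)
    warning("k_SX / k_RX outside [0.1, 10]; competition is poorly balanced")
  list(k_sx = k_sx, r_s = r_s, r_r = r_r,
       k_first_order = c(s = fs$k, r = fr$k))
}

#' Intermediate time course under sequential first-order kinetics
#'
#' Forward model: the substrate decays as `[S]0 e^(-kS t)`, forms the
#' intermediate with rate constant `kprime_i`, and the intermediate decays
#' with `k_i`:
#' `[I]t = kprime_i [S]0 / (kS - kI) (e^(-kI t) - e^(-kS t))`, with the
#' degenerate `kI -> kS` limit `kprime_i [S]0 t e^(-kS t)`.
#'
#' @param times seconds.
#' @param s0 initial substrate concentration, mol L^-1.
#' @param k_s substrate first-order decay constant, s^-1.
#' @param k_i intermediate decay constant, s^-1.
#' @param kprime_i intermediate formation rate constant, s^-1.
#' @return intermediate concentrations at `times`.
#' @export
intermediate_trace <- function(times, s0, k_s, k_i, kprime_i) {
  if (abs(k_s - k_i) < 1e-9 * max(k_s, k_i, 1e-30))
    return(kprime_i * s0 * times * exp(-k_s * times))
  kprime_i * s0 / (k_s - k_i) * (exp(-k_i * times) - exp(-k_s * times))
}

#' Intermediate formation yield from paired traces
#'
#' Fits the sequential first-order model to the intermediate trace, with
#' the substrate decay constant fixed from its own trace. Identifiability
#' of the otherwise non-orthogonal `(kI, k'I)` pair is restored by
#' initializing `k'I` from the analytic initial slope
#' `d[I]/dt (t=0) = k'I [S]0`, estimated by an early-point secant.
#' The formation yield is `y_I = k'I / kS`.
#'
#' @param trace_s substrate [kinetic_trace()] (first-order decay).
#' @param trace_i intermediate [kinetic_trace()], starting at `[I]0 = 0`.
#' @param weighting `"absolute"` or `"relative"`.
#' @return list with `k_s`, `k_i`, `kprime_i` (s^-1), the yield `y_i`, and
#'   the fit object.
#' @export
intermediate_yield <- function(trace_s, trace_i,
                               weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(trace_s, "kinetic_trace"),
            inherits(trace_i, "kinetic_trace"))
  if (trace_i$conc[1] != 0) stop("intermediate trace must start at [I]0 = 0")
  fs <- initial_rate(trace_s)
  k_s <- fs$k
  s0 <- fs$c0
  if (k_s <= 0) stop("substrate trace shows no first-order decay")
  # early-point secant replaces the graphical tangent at t = 0
  i2 <- min(3L, nrow(trace_i))
  slope0 <- (trace_i$conc[i2] - trace_i$conc[1]) /
    (trace_i$time[i2] - trace_i$time[1])
  kp0 <- max(slope0 / s0, k_s * 1e-4)
  dat <- data.frame(time = trace_i$time, conc = trace_i$conc)
  w <- .fit_weights(pmax(dat$conc, max(dat$conc) * 1e-3), weighting)
  fit <- minpack.lm::nlsLM(
    conc ~ intermediate_trace(time, s0, k_s, k_i, kp), data = dat,
    start = list(k_i = 0.5 * k_s, kp = kp0), weights = w,
    lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  kp <- unname(cf[["kp"]])
  if (kp > k_s)
    warning("fitted yield exceeds 1; check the intermediate identification")
  list(k_s = k_s, k_i = unname(cf[["k_i"]]), kprime_i = kp,
       y_i = kp / k_s, fit = fit)
}
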