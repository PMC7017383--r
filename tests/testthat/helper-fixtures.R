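# Shared fixtures and the independent per-wavelength engine oracle.

# flat photon-flux band: constant p over [lo, hi]
flat_flux <- function(lo, hi, p = 1e-9, n = 11) {
  spectrum(seq(lo, hi, length.out = n), rep(p, n), "photon_flux_density")
}

flat_molar <- function(lo, hi, eps, n = 11) {
  spectrum(seq(lo, hi, length.out = n), rep(eps, n), "molar_absorption")
}

# water of the DOC-trend modelling example (5 m column)
fig3_water <- function(doc = 3, depth = 5) {
  water_body(depth, nitrate = 1e-4, nitrite = 1e-6, bicarbonate = 1e-3,
             carbonate = 1e-5, doc = doc)
}

# Brute-force per-wavelength reimplementation of the transient budgets:
# explicit loop over trapezoid panels, scalar arithmetic only. Kept
# deliberately naive and independent of the vectorized engine internals.
naive_budgets_oracle <- function(p0, water, profile = default_profile()) {
  grid <- p0$wavelength
  d_cm <- water$depth_m * 100
  b <- d_cm * water$psi
  pa <- c(CDOM = 0, NO3 = 0, NO2 = 0)
  for (i in seq_len(length(grid) - 1)) {
    panel <- 0 * pa
    for (lam in c(grid[i], grid[i + 1])) {
      a_cdom <- 0.45 * water$doc * exp(-0.015 * lam)
      a_no3 <- spectrum_at(profile$nitrate_spectrum(grid), lam) * water$nitrate
      a_no2 <- spectrum_at(profile$nitrite_spectrum(grid), lam) * water$nitrite
      a_tot <- a_cdom + a_no3 + a_no2
      p <- spectrum_at(p0, lam)
      tot_abs <- p * (1 - 10^(-a_tot * b))
      fr <- if (a_tot > 0) c(a_cdom, a_no3, a_no2) / a_tot else c(0, 0, 0)
      panel <- panel + fr * tot_abs / 2
    }
    pa <- pa + panel * (grid[i + 1] - grid[i])
  }
  pa_vol <- 1000 * pa / d_cm
  sc <- profile$scavenging
  r_oh <- profile$sources$phi_oh_no3 * pa_vol[["NO3"]] +
    profile$sources$phi_oh_no2 * pa_vol[["NO2"]] +
    profile$cdom$phi_oh * pa_vol[["CDOM"]]
  s_oh <- sc$k_oh_dom * water$doc + sc$k_oh_hco3 * water$bicarbonate +
    sc$k_oh_co3 * water$carbonate + sc$k_oh_no2 * water$nitrite +
    sc$k_oh_br * water$bromide
  oh <- r_oh / s_oh
  r_3cdom <- profile$cdom$phi_3cdom * pa_vol[["CDOM"]]
  co3 <- (oh * (sc$k_oh_hco3 * water$bicarbonate +
                  sc$k_oh_co3 * water$carbonate) +
            profile$cdom$eta_co3 * r_3cdom) / (sc$k_co3_dom * water$doc)
  list(oh = oh, co3 = co3,
       o2 = profile$cdom$phi_1o2 * pa_vol[["CDOM"]] / sc$k_1o2_decay,
       dom = r_3cdom / sc$k_3cdom_decay)
}
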