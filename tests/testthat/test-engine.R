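# Steady-state transient budgets and pathway-resolved degradation.

test_that("no photoproduction means zero steady states", {
  p0 <- synthetic_solar_spectrum()
  w <- water_body(5, bicarbonate = 1e-3, carbonate = 1e-5, doc = 3)
  prof <- default_profile(cdom = cdom_photo_params(0, 0, 0))
  b <- transient_budgets(p0, w, prof)
  expect_equal(b$oh$steady_state, 0)
  expect_equal(b$co3$steady_state, 0)
  expect_equal(b$o2$steady_state, 0)
  expect_equal(b$dom$steady_state, 0)
})

test_that("doubling every hydroxyl sink halves its steady state", {
  p0 <- synthetic_solar_spectrum()
  w <- fig3_water()
  sc <- scavenging_params()
  sc2 <- scavenging_params(k_oh_dom = 2 * sc$k_oh_dom,
                           k_oh_hco3 = 2 * sc$k_oh_hco3,
                           k_oh_co3 = 2 * sc$k_oh_co3,
                           k_oh_no2 = 2 * sc$k_oh_no2,
                           k_oh_br = 2 * sc$k_oh_br)
  b1 <- transient_budgets(p0, w, default_profile(scavenging = sc))
  b2 <- transient_budgets(p0, w, default_profile(scavenging = sc2))
  expect_equal(b2$oh$steady_state, b1$oh$steady_state / 2, tolerance = 1e-12)
})

test_that("vectorized budgets match the naive per-wavelength oracle", {
  p0 <- scale_to_uv_irradiance(synthetic_solar_spectrum())
  w <- fig3_water()
  b <- transient_budgets(p0, w)
  o <- naive_budgets_oracle(p0, w)
  for (tr in c("oh", "co3", "o2", "dom"))
    expect_equal(b[[tr]]$steady_state, o[[tr]], tolerance = 1e-8)
})

test_that("zero scavenging with nonzero formation has no steady state", {
  p0 <- synthetic_solar_spectrum()
  w <- water_body(5, nitrate = 1e-4, doc = 0)  # no OH sinks at all
  expect_error(transient_budgets(p0, w), "no steady state")
})

test_that("direct photolysis rate constant is probe-concentration independent", {
  mol <- synthetic_molecule_table()
  w <- fig3_water()
  p0 <- scale_to_uv_irradiance(mol$p0)
  ks <- vapply(c(1e-9, 1e-8, 1e-7), function(s0)
    direct_photolysis_k(p0, mol$epsilon, 0.33, w, s0 = s0), numeric(1))
  expect_lt(diff(range(ks)) / ks[2], 1e-3)
  # no absorption or no quantum yield: zero, not an error
  expect_equal(direct_photolysis_k(p0, mol$epsilon, 0, w), 0)
  dark <- spectrum(mol$epsilon$wavelength,
                   rep(0, length(mol$epsilon$wavelength)), "molar_absorption")
  expect_equal(direct_photolysis_k(p0, dark, 0.33, w), 0)
})

test_that("monochromatic optically-thin direct photolysis matches the closed form", {
  grid <- seq(339, 341, 0.5)
  p0 <- spectrum(grid, rep(1e-9, 5), "photon_flux_density")
  eps <- spectrum(grid, rep(10, 5), "molar_absorption")
  w <- water_body(0.01, doc = 0)  # 1 cm pure-water column, no co-absorbers
  k <- direct_photolysis_k(p0, eps, 0.5, w)
  # thin limit: k = 2.303 * Phi * (p0 * dl) * eps * 1000 / s0-free
  k_thin <- log(10) * 0.5 * (1e-9 * 2) * 10 * 1000
  expect_equal(k, k_thin, tolerance = 5e-3)
})

test_that("wavelength-resolved quantum yields reduce to the scalar case", {
  mol <- synthetic_molecule_table()
  w <- fig3_water()
  p0 <- scale_to_uv_irradiance(mol$p0)
  phi_flat <- spectrum(p0$wavelength, rep(0.33, length(p0$wavelength)),
                       "photon_flux_density")
  k_spec <- direct_photolysis_k(p0, mol$epsilon, phi_flat, w)
  k_scal <- direct_photolysis_k(p0, mol$epsilon, 0.33, w)
  expect_equal(k_spec, k_scal, tolerance = 1e-10)
})

test_that("pathway bookkeeping: fractions, half-life, intermediates", {
  p0 <- synthetic_solar_spectrum()
  b <- transient_budgets(p0, fig3_water())

  # single nonzero pathway has fraction 1
  only_oh <- photo_reactivity(k_oh = 1e10)
  r1 <- degrade(only_oh, b)
  expect_equal(unname(r1$fractions[["oh"]]), 1)
  expect_equal(r1$t_half_ssd, log(2) / r1$k_tot_ssd)

  # full parameter set: fractions sum to 1, all ks nonnegative
  ibu <- ibuprofen_reactivity()
  r2 <- degrade(ibu, b, k_phot = 1e-6)
  expect_equal(sum(r2$fractions), 1, tolerance = 1e-12)
  expect_true(all(r2$k_s >= 0))
  # intermediate formation: kf_i = y_i * k_i, overall yield per definition
  expect_equal(unname(r2$intermediate_k_ssd[["phot"]]),
               0.25 * unname(r2$k_ssd[["phot"]]))
  expect_equal(r2$intermediate_yield,
               sum(c(0.25, 0.023, 0, 0, 0.31) *
                     r2$k_s[c("phot", "oh", "co3", "o2", "dom")]) / r2$k_tot_s)

  # nothing degrades: infinite half-life, represented not thrown
  r3 <- degrade(photo_reactivity(), b)
  expect_true(is.infinite(r3$t_half_ssd))
  expect_true(is.na(as_savetable(r3)$t_tot))
})

test_that("back-reduction at DOC = DOC_half halves the triplet pathway", {
  p0 <- synthetic_solar_spectrum()
  b <- transient_budgets(p0, fig3_water(doc = 3))
  free <- degrade(photo_reactivity(k_3cdom = 4.5e7), b)
  half <- degrade(photo_reactivity(k_3cdom = 4.5e7, doc_half = 3), b)
  expect_equal(unname(half$k_s[["dom"]]), unname(free$k_s[["dom"]]) / 2,
               tolerance = 1e-12)
})

test_that("degradation slows with depth and with DOC", {
  mol <- synthetic_molecule_table()
  ibu <- ibuprofen_reactivity(with_yields = FALSE)
  run <- function(depth, doc)
    photic_run(mol, fig3_water(doc = doc, depth = depth), ibu)
  by_depth <- lapply(c(1, 2, 5, 10), run, doc = 3)
  k_phot <- vapply(by_depth, function(r) r$k_s[["phot"]], numeric(1))
  k_oh <- vapply(by_depth, function(r) r$k_s[["oh"]], numeric(1))
  k_tot <- vapply(by_depth, function(r) r$k_tot_s, numeric(1))
  expect_true(all(diff(k_phot) < 0))
  expect_true(all(diff(k_oh) < 0))
  expect_true(all(diff(k_tot) < 0))
  by_doc <- lapply(c(0.5, 2, 5, 15), function(d) run(5, d))
  k_phot2 <- vapply(by_doc, function(r) r$k_s[["phot"]], numeric(1))
  k_oh2 <- vapply(by_doc, function(r) r$k_s[["oh"]], numeric(1))
  expect_true(all(diff(k_phot2) < 0))
  expect_true(all(diff(k_oh2) < 0))
})

test_that("measured water absorbance takes priority over the DOC estimate", {
  mol <- synthetic_molecule_table()
  grid <- mol$p0$wavelength
  aw <- spectrum(grid, rep(0.05, length(grid)), "absorbance_per_cm")
  w_doc <- fig3_water()
  w_aw <- water_body(5, nitrate = 1e-4, nitrite = 1e-6, bicarbonate = 1e-3,
                     carbonate = 1e-5, doc = 3, aw = aw)
  b1 <- transient_budgets(mol$p0, w_doc)
  b2 <- transient_budgets(mol$p0, w_aw)
  expect_gt(abs(b2$dom$steady_state / b1$dom$steady_state - 1), 0.01)
})

test_that("hydroxyl source apportionment sums to one", {
  b <- transient_budgets(synthetic_solar_spectrum(), fig3_water())
  expect_equal(sum(b$oh_sources), 1, tolerance = 1e-12)
  expect_true(all(b$oh_sources >= 0))
})
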