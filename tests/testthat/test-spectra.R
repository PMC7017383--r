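# Spectral containers and photon-absorption integrals.

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(300, 300), c(1, 1), "molar_absorption"),
               "strictly increasing")
  expect_error(spectrum(300:302, c(1, -1, 1), "molar_absorption"),
               "nonnegative")
  expect_error(spectrum(300:302, 1:2, "molar_absorption"), "length")
  sp <- spectrum(c(300, 310), c(1, 2), "molar_absorption")
  expect_equal(spectrum_at(sp, 305), 1.5)
  expect_equal(spectrum_at(sp, c(200, 400)), c(0, 0))  # outside support
})

test_that("DOC-based water absorbance follows the exponential model", {
  expect_equal(spectrum_at(cdom_absorbance(0, 300:400), c(310, 380)), c(0, 0))
  expect_equal(spectrum_at(cdom_absorbance(1, c(300, 350)), 300),
               0.45 * exp(-4.5), tolerance = 1e-12)
  expect_equal(spectrum_at(cdom_absorbance(2, c(300, 350)), 350),
               0.9 * exp(-5.25), tolerance = 1e-12)
  expect_error(cdom_absorbance(-1, 300:400), "nonnegative")
})

test_that("absorbed photon flux matches Lambert-Beer closed forms", {
  eps <- flat_molar(349.5, 350.5, eps = 1e4, n = 2)
  p0 <- flat_flux(349.5, 350.5, p = 1e-9, n = 2)
  # eps * b * c = 1 over a 1 nm band: Pa = p * (1 - 10^-1) * 1 nm
  pa <- absorbed_photon_flux(p0, eps, concentration = 1e-4, path_cm = 1)
  expect_equal(pa, 9e-10, tolerance = 1e-12)
  # no absorber
  expect_equal(absorbed_photon_flux(p0, eps, 0, 1), 0)
  # total absorption limit: Pa -> integral of p0
  pa_sat <- absorbed_photon_flux(p0, eps, concentration = 10, path_cm = 10)
  expect_equal(pa_sat, 1e-9, tolerance = 1e-9)
  # no spectral overlap
  expect_error(absorbed_photon_flux(p0, eps, 1e-4, 1, window = c(500, 600)),
               "no spectral overlap")
})

test_that("competitive absorption splits flux by absorbance share and conserves photons", {
  p0 <- flat_flux(300, 400, p = 2e-9, n = 51)
  eps <- flat_molar(300, 400, eps = 5e3, n = 51)
  twin <- absorber_set(absorber("a", eps, 1e-4), absorber("b", eps, 1e-4))
  pa <- competitive_absorption(p0, twin, path_cm = 1)
  expect_equal(pa[["a"]], pa[["b"]], tolerance = 1e-12)
  total <- absorbed_photon_flux(p0, eps, 2e-4, 1)
  expect_equal(sum(pa), total, tolerance = 1e-10)

  zero <- absorber("z", flat_molar(300, 400, 0, 51), 1)
  pa2 <- competitive_absorption(p0, absorber_set(absorber("a", eps, 1e-4), zero), 1)
  expect_equal(pa2[["z"]], 0)
})

test_that("photon conservation holds for random absorber mixtures", {
  set.seed(42)
  grid <- seq(300, 450, 3)
  p0 <- spectrum(grid, 1e-9 * (1 + runif(length(grid))),
                 "photon_flux_density")
  for (rep in 1:5) {
    abs_list <- lapply(1:3, function(i)
      absorber(paste0("x", i),
               spectrum(grid, runif(length(grid), 0, 2e3), "molar_absorption"),
               runif(1, 1e-5, 1e-3)))
    aset <- absorber_set(abs_list)
    pa <- competitive_absorption(p0, aset, path_cm = 2)
    # lumped absorbance spectrum
    atot <- Reduce(`+`, lapply(abs_list, function(a)
      spectrum_at(a$spec, grid) * a$concentration))
    lumped <- spectrum(grid, atot, "absorbance_per_cm")
    total <- absorbed_photon_flux(p0, lumped, 1, path_cm = 2)
    expect_equal(sum(pa), total, tolerance = 1e-10)
    # absorbed + transmitted = incident
    transmitted <- pracma::trapz(grid, spectrum_at(p0, grid) * 10^(-atot * 2))
    incident <- pracma::trapz(grid, spectrum_at(p0, grid))
    expect_equal(sum(pa) + transmitted, incident, tolerance = 1e-8)
  }
})

test_that("optically thin absorption matches the linear limit within 0.2%", {
  grid <- seq(300, 400, 2)
  p0 <- spectrum(grid, 1e-9 * exp(-((grid - 350) / 40)^2),
                 "photon_flux_density")
  a <- spectrum(grid, 1e-4 * (1 + 0.5 * sin(grid / 20)), "absorbance_per_cm")
  pa <- absorbed_photon_flux(p0, a, 1, path_cm = 1)
  thin <- log(10) * pracma::trapz(grid, spectrum_at(p0, grid) *
                                    spectrum_at(a, grid))
  expect_equal(pa, thin, tolerance = 2e-3)
})

test_that("screening factor chi is 1 without co-solutes and decreases with them", {
  p0 <- flat_flux(320, 360, n = 21)
  target <- absorber("S", flat_molar(320, 360, 100, 21), 1e-5)
  none <- absorber_set(absorber("P", flat_molar(320, 360, 1e4, 21), 0))
  expect_equal(screening_factor_chi(p0, target, none, 1), 1, tolerance = 1e-12)
  chis <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(cp)
    screening_factor_chi(
      p0, target, absorber_set(absorber("P", flat_molar(320, 360, 1e4, 21), cp)),
      1),
    numeric(1))
  expect_true(all(diff(chis) < 0))
  expect_true(all(chis > 0 & chis <= 1))
})

test_that("monochromatic chi matches the closed-form competition expression", {
  # A_S*b = 0.01, A_P*b = 1 on a flat band: integrals cancel to scalars
  p0 <- flat_flux(330, 332, n = 5)
  target <- absorber("S", flat_molar(330, 332, 1e3, 5), 1e-5)   # A_S = 0.01
  co <- absorber_set(absorber("P", flat_molar(330, 332, 1e4, 5), 1e-4))  # A_P = 1
  chi <- screening_factor_chi(p0, target, co, path_cm = 1)
  expected <- (0.01 / 1.01 * (1 - 10^(-1.01))) / (1 - 10^(-0.01))
  expect_equal(chi, expected, tolerance = 1e-10)
  expect_equal(expected, 0.394, tolerance = 5e-3)
})

test_that("chi is undefined for a target that does not absorb", {
  p0 <- flat_flux(320, 360, n = 21)
  dark <- absorber("S", flat_molar(320, 360, 0, 21), 1e-5)
  co <- absorber_set(absorber("P", flat_molar(320, 360, 1e4, 21), 1e-4))
  expect_error(screening_factor_chi(p0, dark, co, 1), "absorbs nowhere")
})

test_that("UV normalization hits the target irradiance and is idempotent", {
  sp <- synthetic_solar_spectrum()
  expect_equal(band_irradiance(sp), 22, tolerance = 1e-6)
  again <- scale_to_uv_irradiance(sp, 22)
  expect_equal(again$value, sp$value, tolerance = 1e-9)
  expect_error(scale_to_uv_irradiance(flat_flux(500, 600), 22),
               "no spectral overlap")
  # one Einstein of 300 nm photons carries ~3.99e5 J
  expect_equal(einstein_energy(300), 3.99e5, tolerance = 1e-3)
})

test_that("integrals are stable under grid refinement", {
  coarse <- seq(300, 400, 4)
  fine <- seq(300, 400, 2)
  make <- function(g) spectrum(g, 1e-9 * exp(-((g - 340) / 30)^2),
                               "photon_flux_density")
  a_of <- function(g) spectrum(g, 0.02 * exp(-0.01 * (g - 300)),
                               "absorbance_per_cm")
  pa_c <- absorbed_photon_flux(make(coarse), a_of(coarse), 1, 100)
  pa_f <- absorbed_photon_flux(make(fine), a_of(fine), 1, 100)
  expect_equal(pa_c, pa_f, tolerance = 5e-3)
})
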