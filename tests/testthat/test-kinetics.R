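# Laboratory-kinetics fitting procedures: noiseless round trips,
# linearized/nonlinear agreement, and the documented edge cases.

test_that("initial rate recovers exact first- and zero-order kinetics", {
  times <- seq(0, 3e5, length.out = 20)
  tr <- kinetic_trace(times, 2e-5 * exp(-1e-5 * times))
  f <- initial_rate(tr, "first_order")
  expect_equal(f$k, 1e-5, tolerance = 1e-8)
  expect_equal(f$r0, 1e-5 * 2e-5, tolerance = 1e-8)

  tz <- kinetic_trace(times, 2e-5 * (1 - 1e-6 * times))
  fz <- initial_rate(tz, "zero_order")
  expect_equal(fz$r0, 2e-5 * 1e-6, tolerance = 1e-10)

  const <- kinetic_trace(times, rep(2e-5, 20))
  fc <- initial_rate(const, "first_order")
  expect_equal(fc$k, 0, tolerance = 1e-12)
  expect_equal(fc$r0, 0, tolerance = 1e-16)

  set.seed(7)
  up <- kinetic_trace(times, 2e-5 * (1 + 1e-6 * times) *
                        (1 + rnorm(20, 0, 0.05)))
  expect_warning(fu <- initial_rate(up, "first_order"), "clipped")
  expect_equal(fu$k, 0)
})

test_that("quantum yield is the rate-to-absorbed-flux ratio", {
  expect_equal(quantum_yield(1e-9, 1e-9), 1)
  expect_equal(quantum_yield(0, 1e-9), 0)
  # round trip at the reference value 0.33
  pa <- 4.3e-9
  expect_equal(quantum_yield(0.33 * pa, pa), 0.33, tolerance = 1e-12)
  expect_error(quantum_yield(1e-9, 0), "does not absorb")
})

test_that("hydroxyl competition fit recovers its generating parameters", {
  des <- oh_competition_design(s0 = 2e-5, h2o2 = 5e-3, alcohol = "2-propanol",
                               alcohol_grid = c(0, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2))
  rates <- oh_competition_rates(des, r_oh = 1e-9, k17 = 5e9)
  f <- fit_oh_competition(des, rates)
  expect_equal(f$r_oh, 1e-9, tolerance = 1e-6)
  expect_equal(f$k17, 5e9, tolerance = 1e-6)
  # linearized and nonlinear estimates coincide on noiseless data
  expect_equal(unname(f$linear[["r_oh"]]), f$r_oh, tolerance = 1e-6)
  expect_equal(unname(f$linear[["k17"]]), f$k17, tolerance = 1e-6)
  # alcohol-free level sits on the fitted curve at the closed-form value
  expect_equal(rates[1],
               1e-9 * 5e9 * des$s0 / (des$k15 * des$h2o2 + 5e9 * des$s0),
               tolerance = 1e-12)
})

test_that("hydroxyl competition fit flags inconsistent or weak designs", {
  des <- oh_competition_design(s0 = 2e-5, h2o2 = 5e-3,
                               alcohol_grid = c(0, 1e-4, 1e-3, 1e-2))
  expect_error(fit_oh_competition(des, c(1e-10, 2e-10, 3e-10, 4e-10)),
               "inconsistent")
  # weak suppression (< 50% at max alcohol) warns
  weak <- oh_competition_rates(des, 1e-9, 5e9)
  weak <- weak[1] * (1 - 0.3 * seq(0, 1, length.out = 4))
  expect_warning(fit_oh_competition(des, weak), "50%")
  expect_error(oh_competition_design(2e-5, 5e-3, alcohol_grid = c(1e-4, 1e-3)),
               "include 0")
})

test_that("additive baseline absorbs residual direct photolysis", {
  des <- oh_competition_design(s0 = 2e-5, h2o2 = 5e-3,
                               alcohol_grid = c(0, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2))
  rates <- oh_competition_rates(des, r_oh = 1e-9, k17 = 5e9, baseline = 2e-11)
  f <- fit_oh_competition(des, rates, baseline = TRUE)
  expect_equal(f$k17, 5e9, tolerance = 1e-4)
  expect_equal(f$baseline, 2e-11, tolerance = 1e-4)
})

test_that("carbonate-radical screening reaches the three verdicts", {
  lv <- 1:5
  base <- 1e-10 * (1 + 0.2 * lv)
  expect_equal(carbonate_screening(base * 1.5, base, base * 0.1),
               "co3_candidate")
  expect_equal(carbonate_screening(base, base * 1.5, base * 0.1),
               "co3_negligible")
  expect_equal(carbonate_screening(base, base, base * 0.95),
               "inconclusive_direct_photolysis")
  expect_error(carbonate_screening(base, base[1:3], base), "grid")
})

test_that("singlet-oxygen probe arithmetic inverts the forward model", {
  k28 <- 2.5e5
  k31 <- 1e8
  ffa <- 5e-5
  r_1o2 <- 3e-9
  k29 <- 3e7
  # forward: linear-regime slope and probe rate
  m <- r_1o2 * k29 / k28
  r_ffa <- r_1o2 * k31 * ffa / (k28 + k31 * ffa)
  f <- fit_1o2(m, r_ffa, ffa)
  expect_equal(f$k29, k29, tolerance = 1e-12)
  expect_equal(f$r_1o2, r_1o2, tolerance = 1e-12)
  # probe saturation: R_1O2 -> R_FFA when k31[FFA] >> k28
  f_sat <- fit_1o2(m, r_ffa = 1e-9, ffa = 1)
  expect_equal(f_sat$r_1o2, 1e-9, tolerance = 3e-3)
  expect_equal(fit_1o2(0, r_ffa, ffa)$k29, 0)
  expect_error(fit_1o2(m, r_ffa, 0), "positive")
})

test_that("triplet-proxy estimator: both printed forms agree and invert", {
  # the lumped coefficient: k' * 0.68 * S_delta / k28 = 0.75 (2 d.p.)
  expect_equal(6e5 * 0.68 * 0.46 / 2.5e5, 0.75, tolerance = 0.005)
  set.seed(11)
  for (i in 1:10) {
    m <- runif(1, 1e-6, 1e-4)
    pa <- runif(1, 1e-9, 1e-7)
    k29 <- runif(1, 0, min(3e7, 6e5 * m / pa / 0.75 * 0.9))
    a <- fit_triplet_cbbp(m, pa, k29)
    b <- 6e5 * m / pa - 0.75 * k29
    expect_equal(a, b, tolerance = 0.02)
  }
  # round trip: forward-simulate a known triplet rate constant
  k_true <- 4.5e7
  k29 <- 6e4
  pa <- 2e-8
  m <- (k_true + 6e5 * 0.68 * 0.46 / 2.5e5 * k29) * pa / 6e5
  expect_equal(fit_triplet_cbbp(m, pa, k29), k_true, tolerance = 1e-6)
  expect_equal(fit_triplet_cbbp(m, pa, 0), 6e5 * m / pa, tolerance = 1e-12)
  expect_error(fit_triplet_cbbp(1e-9, 1e-6, k29 = 1e9), "exceeds")
})

test_that("back-reduction fit recovers the half-effect concentration", {
  phoh <- c(0, 1, 2, 4, 6, 10)
  rates <- back_reduction_rates(phoh, r0 = 2e-10, phoh_half = 4)
  f <- fit_back_reduction(phoh, rates)
  expect_equal(f$phoh_half, 4, tolerance = 1e-6)
  expect_equal(f$r0, 2e-10, tolerance = 1e-6)
  expect_equal(f$doc_half, 1.6, tolerance = 1e-6)
  # definition: at [Ph-OH] = [Ph-OH]_1/2 the rate halves
  expect_equal(back_reduction_rates(4, 2e-10, 4), 1e-10)
  expect_error(fit_back_reduction(phoh, rev(rates)), "decrease")
})

test_that("sulfadiazine-style DOC_half values pass through the engine", {
  b <- transient_budgets(synthetic_solar_spectrum(), fig3_water())
  acid <- degrade(photo_reactivity(k_3cdom = 1e9, doc_half = 17), b)
  basic <- degrade(photo_reactivity(k_3cdom = 1e9, doc_half = 0.7), b)
  expect_gt(acid$k_s[["dom"]], basic$k_s[["dom"]])
})

test_that("competition kinetics inverts a forward-simulated experiment", {
  times <- seq(0, 2e5, length.out = 15)
  k_rx <- 1.6e9  # acetaminophen + triplet proxy
  x_ss <- 1e-12
  k_sx_true <- 5e8
  c0 <- 1e-5
  # sensitized runs: first-order decay at k = k_X * [X]ss (no direct photolysis)
  tr_s <- kinetic_trace(times, c0 * exp(-k_sx_true * x_ss * times))
  tr_r <- kinetic_trace(times, c0 * exp(-k_rx * x_ss * times))
  f <- competition_kinetics(k_rx, tr_s, tr_r)
  expect_equal(f$k_sx, k_sx_true, tolerance = 1e-6)

  # identical traces: k_SX = k_RX
  f2 <- competition_kinetics(k_rx, tr_r, tr_r)
  expect_equal(f2$k_sx, k_rx, tolerance = 1e-9)

  # with direct photolysis and screening correction
  kd_s <- 2e-6
  kd_r <- 1e-6
  chi_s <- 0.7
  chi_r <- 0.8
  tr_s2 <- kinetic_trace(times, c0 * exp(-(k_sx_true * x_ss + chi_s * kd_s) * times))
  tr_r2 <- kinetic_trace(times, c0 * exp(-(k_rx * x_ss + chi_r * kd_r) * times))
  tr_s_dir <- kinetic_trace(times, c0 * exp(-kd_s * times))
  tr_r_dir <- kinetic_trace(times, c0 * exp(-kd_r * times))
  f3 <- competition_kinetics(k_rx, tr_s2, tr_r2, tr_s_dir, tr_r_dir,
                             chi_s = chi_s, chi_r = chi_r)
  expect_equal(f3$k_sx, k_sx_true, tolerance = 1e-4)

  # unbalanced rate constants warn; undegraded reference errors
  tr_slow <- kinetic_trace(times, c0 * exp(-k_rx * x_ss * times / 100))
  expect_warning(competition_kinetics(k_rx, tr_slow, tr_r), "0.1")
  # reference whose direct photolysis outruns its sensitized run: the
  # chi-corrected reference rate is non-positive
  tr_r_weak <- kinetic_trace(times, c0 * exp(-1e-6 * times))
  tr_r_dirfast <- kinetic_trace(times, c0 * exp(-2e-6 * times))
  expect_error(competition_kinetics(k_rx, tr_s, tr_r_weak,
                                    trace_r_direct = tr_r_dirfast),
               "not degraded")
})

test_that("intermediate model: initial slope identity and mass balance", {
  set.seed(3)
  for (i in 1:10) {
    s0 <- 10^runif(1, -5, -4)
    k_s <- 10^runif(1, -6, -4)
    k_i <- k_s * runif(1, 0.1, 0.9)
    kp <- k_s * runif(1, 0.05, 0.9)
    h <- 1e-3 / k_s
    d0 <- (intermediate_trace(h, s0, k_s, k_i, kp) -
             intermediate_trace(0, s0, k_s, k_i, kp)) / h
    expect_equal(d0, kp * s0, tolerance = 1e-2)
  }
  # stable intermediate: plateau at (k'I/kS) * S0
  tinf <- 50 / 1e-5
  plateau <- intermediate_trace(tinf, 1e-4, 1e-5, 0, 2.5e-6)
  expect_equal(plateau, 0.25 * 1e-4, tolerance = 1e-6)
  # degenerate kI -> kS limit is continuous
  expect_equal(intermediate_trace(1e4, 1e-4, 1e-5, 1e-5, 2e-6),
               intermediate_trace(1e4, 1e-4, 1e-5, 1e-5 * (1 + 1e-7), 2e-6),
               tolerance = 1e-5)
})

test_that("intermediate-yield fit recovers the direct-photolysis channel", {
  times <- seq(0, 6e5, length.out = 31)
  s0 <- 1e-4
  k_s <- 8e-6
  k_i <- 3e-6
  kp <- 0.25 * k_s
  tr_s <- kinetic_trace(times, s0 * exp(-k_s * times))
  tr_i <- kinetic_trace(times, intermediate_trace(times, s0, k_s, k_i, kp))
  f <- intermediate_yield(tr_s, tr_i)
  expect_equal(f$y_i, 0.25, tolerance = 1e-6)
  expect_equal(f$k_i, k_i, tolerance = 1e-5)

  # 1% noise, fixed seed: yield within 0.01
  set.seed(5)
  noisy <- pmax(tr_i$conc * (1 + rnorm(31, 0, 0.01)), 0)
  noisy[1] <- 0
  f2 <- intermediate_yield(tr_s, kinetic_trace(times, noisy))
  expect_equal(f2$y_i, 0.25, tolerance = 0.04)

  expect_error(intermediate_yield(tr_s, kinetic_trace(times, rev(sort(noisy)))),
               "I\\]0 = 0")
})
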