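# Cellular-level rate laws: Hill machinery, consumption, biphasic secretion,
# oxygen modulation, the necrosis cut and the local-insulin compartment.

test_that("hill reproduces half-max, zero and direct-arithmetic values", {
  p <- hill_params(r_max = 1, c_half = 7, n = 2.5)
  expect_equal(hill(7, p), 0.5)
  expect_equal(hill(0, p), 0)
  expect_equal(hill(3, p), 3^2.5 / (3^2.5 + 7^2.5))
  expect_equal(hill(3, p), 0.1073, tolerance = 1e-3)
  # half-max by construction for other parameterizations
  for (pars in list(c(-0.034, 1e-3, 1), c(3e-5, 7, 2.5), c(21e-5, 0.03, 2))) {
    pp <- hill_params(pars[1], pars[2], pars[3])
    expect_equal(hill(pars[2], pp), pars[1] / 2)
  }
  # sign follows r_max; small negative noise clipped
  expect_lt(hill(5, hill_params(-2, 1, 1)), 0)
  expect_equal(hill(-1e-14, p), 0)
})

test_that("hill is monotone and saturates within 1% beyond c_half * 100^(1/n)", {
  grid <- expand.grid(r_max = c(1, 3e-5), c_half = c(0.03, 1, 7), n = c(1, 2, 2.5, 3))
  for (k in seq_len(nrow(grid))) {
    p <- hill_params(grid$r_max[k], grid$c_half[k], grid$n[k])
    cs <- seq(0, 5 * grid$c_half[k], length.out = 60)
    expect_true(all(diff(hill(cs, p)) > 0))
    c_sat <- grid$c_half[k] * 100^(1 / grid$n[k]) * 1.01
    expect_lt(abs(hill(c_sat, p) - p$r_max), 0.01 * abs(p$r_max))
  }
})

test_that("hill and hill_params reject invalid input", {
  expect_error(hill_params(1, -1, 2), "c_half")
  expect_error(hill_params(1, 1, 0), "n")
  expect_error(hill(NaN, hill_params(1, 1, 1)), "finite")
  expect_error(hill(1, list(r_max = 1)), "hill_params")
})

test_that("smoothed step ramps from 0 to 1 without overshoot, C1-continuous", {
  s <- 0.5e-4
  expect_equal(smoothed_step(-2 * s, s), 0)
  expect_equal(smoothed_step(0, s), 0.5)
  expect_equal(smoothed_step(2 * s, s), 1)
  x <- seq(-3 * s, 3 * s, length.out = 4001)
  y <- smoothed_step(x, s)
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(diff(y) >= 0))
  # continuous first derivative: centered finite differences have no jumps
  d1 <- diff(y) / diff(x)
  expect_lt(max(abs(diff(d1))), 1e-1 * max(d1))
  expect_error(smoothed_step(0, -1), "scale")
})

test_that("glucose modulation of oxygen consumption matches its calibration", {
  f3 <- 3^2.5 / (3^2.5 + 7^2.5)
  expect_equal(glucose_metabolic_factor(3), 1.8 * (0.5 + 0.5 * f3))
  # calibrated to ~1 at resting glucose
  expect_lt(abs(glucose_metabolic_factor(3) - 1), 0.01)
  expect_equal(glucose_metabolic_factor(15), 1.683, tolerance = 1e-3)
  rise <- 100 * (glucose_metabolic_factor(15) / glucose_metabolic_factor(3) - 1)
  expect_gt(rise, 65); expect_lt(rise, 75)
  # bounded and nondecreasing
  cs <- seq(0, 50, by = 0.5)
  phis <- glucose_metabolic_factor(cs)
  expect_true(all(diff(phis) >= 0))
  expect_true(all(phis >= 0.9) && all(phis <= 1.8))
})

test_that("oxygen consumption saturates, vanishes at zero oxygen, necroses", {
  expect_equal(oxygen_consumption_rate(0, 3), 0)
  # saturated Michaelis-Menten at resting glucose recovers the base rate
  expect_equal(oxygen_consumption_rate(0.2, 3), -0.034, tolerance = 0.01)
  # half-max at the 1 uM half-max concentration (viable tissue)
  expect_equal(oxygen_consumption_rate(1e-3, 3),
               -0.034 / 2 * glucose_metabolic_factor(3) *
                 smoothed_step(1e-3 - 1e-4, 0.5e-4), tolerance = 1e-12)
  expect_equal(oxygen_consumption_rate(1e-3, 3), -0.017, tolerance = 2e-2)
  # below the critical concentration the cut zeroes consumption
  expect_equal(oxygen_consumption_rate(4e-5, 15), 0)
  expect_true(all(oxygen_consumption_rate(10^seq(-6, 0, 0.25), 15) <= 0))
})

test_that("glucose consumption follows Michaelis-Menten with the necrosis cut", {
  expect_equal(glucose_consumption_rate(1e-2, 0.2), -0.014)
  expect_equal(glucose_consumption_rate(5, 0.2), -0.028 * 500 / 501)
  expect_equal(glucose_consumption_rate(0, 0.2), 0)
  expect_equal(glucose_consumption_rate(5, 2e-5), 0)  # necrotic tissue
})

test_that("second-phase secretion is the calibrated sigmoid of glucose", {
  expect_equal(secretion_rate_phase2(7), 1.5e-5)
  expect_equal(secretion_rate_phase2(1), 3e-5 * 1 / (1 + 7^2.5))
  expect_equal(secretion_rate_phase2(30), 3e-5 * 30^2.5 / (30^2.5 + 7^2.5))
  expect_equal(secretion_rate_phase2(30), 2.92e-5, tolerance = 1e-2)
  # essentially no response at low glucose
  expect_lt(secretion_rate_phase2(1) / 3e-5, 0.01)
})

test_that("gradient modulation is a unit-height bump at 5 mM", {
  expect_equal(gradient_modulation(5), 1)
  expect_lt(gradient_modulation(1e-9), 0.5)
  expect_lt(gradient_modulation(30), gradient_modulation(10))
  expect_equal(gradient_modulation(10), 0.3, tolerance = 1e-9)
  cs <- seq(0, 40, by = 0.25)
  sig <- gradient_modulation(cs)
  expect_true(all(sig > 0 & sig <= 1))
  expect_true(all(diff(sig[cs >= 5]) <= 0))  # monotone decay above the mode
})

test_that("first-phase secretion requires rising glucose", {
  expect_equal(secretion_rate_phase1(5, -0.05), 0)
  expect_equal(secretion_rate_phase1(5, 0), 0)
  expect_equal(secretion_rate_phase1(5, 0.03), 10.5e-5)
  expect_equal(secretion_rate_phase1(5, 0.10),
               21e-5 * 0.1^2 / (0.1^2 + 0.03^2))
})

test_that("oxygen limitation of secretion is the abrupt Hill factor", {
  expect_equal(oxygen_secretion_modulation(3e-3), 0.5)
  expect_equal(oxygen_secretion_modulation(6e-3), 216 / 243)
  expect_equal(oxygen_secretion_modulation(0), 0)
})

test_that("total secretion composes the phases with oxygen limits", {
  expect_equal(total_secretion_rate(15, 0.1, 0), 0)
  expect_equal(total_secretion_rate(7, 0, 0.2), 1.5e-5, tolerance = 1e-3)
  expect_equal(total_secretion_rate(5, 0.03, 3e-3),
               (10.5e-5 + secretion_rate_phase2(5)) * 0.5 *
                 necrosis_factor(3e-3), tolerance = 1e-12)
  # bounded by the sum of the phase maxima
  grid <- expand.grid(g = c(1, 5, 15, 30), d = c(0, 0.05, 1), o = c(1e-3, 0.2))
  r <- with(grid, total_secretion_rate(g, d, o))
  expect_true(all(r >= 0 & r <= 21e-5 + 3e-5))
  # nondecreasing in oxygen for fixed glucose arguments
  for (g in c(3, 7, 15)) {
    o <- 10^seq(-6, -0.5, length.out = 40)
    expect_true(all(diff(total_secretion_rate(g, 0.02, o)) >= 0))
  }
})

test_that("local insulin exchange conserves insulin and sets a ~4 min scale", {
  set.seed(1)
  for (k in 1:20) {
    cl <- runif(1, 0, 1e-2); ci <- runif(1, 0, 1e-2); r <- runif(1, 0, 3e-5)
    ex <- local_insulin_exchange(cl, ci, r)
    expect_equal(ex$d_insL + ex$d_ins, r, tolerance = 1e-12)
  }
  ex <- local_insulin_exchange(1e-3, 1e-3, 2e-5)
  expect_equal(ex$d_insL, 2e-5); expect_equal(ex$d_ins, 0)
  # steady state: compartment excess equals R_ins / k_insL
  r <- 1.5e-5
  excess <- r / kinetics_config()$k_insL
  ex <- local_insulin_exchange(0.002 + excess, 0.002, r)
  expect_equal(ex$d_insL, 0, tolerance = 1e-18)
  expect_equal(log(2) / 0.003 / 60, 3.85, tolerance = 1e-2)  # min
})

test_that("pO2 <-> concentration conversion is the linear Henry factor", {
  expect_equal(po2_to_conc(140), 0.200)
  expect_equal(po2_to_conc(0.7), 1e-3)
  expect_equal(po2_to_conc(0), 0)
  expect_equal(conc_to_po2(po2_to_conc(37.3)), 37.3)
  expect_error(po2_to_conc(-1), "nonnegative")
  expect_error(conc_to_po2(-1), "nonnegative")
})

test_that("kinetics config validates and keeps the calibration identity", {
  kin <- kinetics_config()
  expect_equal(kin$phi_base + kin$phi_metab, 1)
  f <- kin$phi_scale * (kin$phi_base + kin$phi_metab * 3^2.5 / (3^2.5 + 7^2.5))
  expect_lt(abs(f - 1), 0.01)
  expect_error(kinetics_config(k_insL = 0), "positive")
  expect_error(kinetics_config(ins_phase2 = list(1, 2, 3)), "hill_params")
})
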