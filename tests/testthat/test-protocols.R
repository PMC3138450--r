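# In-silico perifusion drivers and the dose-response analysis layer.

test_that("every upward glucose step is biphasic: transient peak then plateau", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = c(120, 1020), delta = c(4, 4)),
                   tau = 30, duration = 1920)
  cfg <- run_config(chamber = small_chamber(), protocol = prot,
                    solver = list(resolution = 30e-6))
  res <- run_staircase(cfg, sim = c(sim, list(config = cfg)))
  expect_s3_class(res$trace, "tbl_df")
  expect_equal(nrow(res$steps), 2L)
  expect_true(all(res$steps$peak > res$steps$plateau))
  # plateaus ordered by the second-phase dose response
  expect_gt(res$steps$plateau[2], res$steps$plateau[1])
  # the peak arrives within ~5 min of the step
  expect_true(all(res$steps$t_peak - res$steps$t_start < 300))
})

test_that("a larger step to the same final glucose gives a larger first-phase peak", {
  sim <- small_sim()
  peak_from <- function(low) {
    prot <- protocol(glucose_low = low,
                     steps = tibble::tibble(t = 60, delta = 15 - low),
                     tau = 30, duration = 420)
    res <- simulate_perifusion(sim$mesh, sim$flow, prot = prot, ops = sim$ops)
    base <- res$trace$insulin_outflux_mol_per_s[1]
    max(res$trace$insulin_outflux_mol_per_s) - base
  }
  expect_gt(peak_from(1), peak_from(8))
})

test_that("after a step back down secretion decays toward baseline", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = c(60, 480), delta = c(14, -14)),
                   tau = 30, duration = 1500)
  res <- simulate_perifusion(sim$mesh, sim$flow, prot = prot, ops = sim$ops)
  tr <- res$trace
  plateau_hi <- max(tr$insulin_outflux_mol_per_s[tr$time_s < 480])
  tail_flux <- tr$insulin_outflux_mol_per_s[tr$time_s > 1200]
  expect_lt(max(tail_flux), 0.5 * plateau_hi)
  expect_true(all(diff(tail_flux) <= 1e-18))  # still relaxing downward
})

test_that("dose-response extraction gives monotone, normalized plateaus", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = c(120, 1020), delta = c(6, 8)),
                   tau = 30, duration = 1920)
  cfg <- run_config(chamber = small_chamber(), protocol = prot,
                    solver = list(resolution = 30e-6))
  res <- run_single_step(cfg, sim = c(sim, list(config = cfg)))
  dr <- suppressWarnings(extract_dose_response(res, window = 120))
  expect_true(all(diff(dr$secretion) > 0))
  expect_equal(max(dr$normalized), 1)
})

test_that("small-islet dose response recovers the local Hill parameters", {
  dr <- dose_response_radial(diameter = 50e-6, n_nodes = 60)
  expect_equal(dr$normalized[dr$glucose_mM == 7] /
                 dr$normalized[dr$glucose_mM == 30],
               0.5 / (30^2.5 / (30^2.5 + 7^2.5)), tolerance = 0.03)
  fit <- fit_hill(dr)
  expect_equal(fit$n, 2.5, tolerance = 0.1)
  expect_equal(fit$c_half, 7, tolerance = 0.1)
})

test_that("fit_hill recovers exact parameters and ranks nested fits", {
  conc <- c(1, 2, 3, 5, 7, 9, 12, 15, 20, 30)
  resp <- hill(conc, hill_params(2.5e-5, 7, 2.5))
  fit <- fit_hill(data.frame(conc, resp))
  expect_equal(fit$r_max, 2.5e-5, tolerance = 0.01)
  expect_equal(fit$c_half, 7, tolerance = 0.01)
  expect_equal(fit$n, 2.5, tolerance = 0.01)
  fit1 <- fit_hill(data.frame(conc, resp), fix_n = 1)
  expect_true(fit1$restricted)
  expect_gt(fit1$rss, fit$rss)
  expect_error(fit_hill(data.frame(conc, rep(1, 10))), "degenerate")
  expect_error(fit_hill(data.frame(conc = 1:2, resp = 1:2)), "3")
})

test_that("fit_hill recovers parameters from noisy synthetic dose responses", {
  set.seed(7)
  conc <- c(1, 2, 3, 5, 7, 9, 12, 15, 20, 30)
  errs <- vapply(1:50, function(i) {
    resp <- hill(conc, hill_params(2.5e-5, 7, 2.5)) *
      exp(stats::rnorm(length(conc), 0, 0.01))
    ft <- fit_hill(data.frame(conc, resp))
    c(abs(ft$n - 2.5), abs(ft$c_half / 7 - 1))
  }, numeric(2))
  expect_lte(stats::median(errs[1, ]), 0.2)
  expect_lte(stats::median(errs[2, ]), 0.05)
})

test_that("oxygen sweep normalizes to the reference and is monotone", {
  sim <- two_islet_sim()
  cfg <- run_config(solver = list(resolution = 30e-6))
  sw <- oxygen_sweep(cfg, po2_mmHg = c(140, 60, 30, 15),
                     sim = c(sim, list(config = cfg)))
  expect_equal(sw$fraction[sw$po2_mmHg == 140], 1)
  expect_true(all(diff(sw$fraction[order(sw$po2_mmHg)]) >= 0))
  expect_true(is.finite(attr(sw, "half_max_po2")))
  expect_error(oxygen_sweep(cfg, po2_mmHg = c(60, 30)), "reference")
})

test_that("the larger islet is hit harder by hypoxia than the smaller one", {
  frac_for <- function(d) {
    g <- radial_grid(d, 300e-6, n_nodes = 80)
    s <- function(p) steady_radial(g, glucose_far = 15,
                                   oxygen_far = p / 700)$secretion_total
    s(20) / s(140)
  }
  expect_lt(frac_for(150e-6), frac_for(100e-6))
})

test_that("encapsulation comparison reports paired secretion and ratios", {
  cfg <- run_config(solver = list(resolution = 40e-6))
  cmp <- encapsulation_compare(cfg, po2_mmHg = c(140, 45))
  expect_equal(nrow(cmp$summary), 4L)
  expect_equal(nrow(cmp$ratios), 4L)
  v <- cmp$ratios$value
  names(v) <- cmp$ratios$quantity
  # capsules barely matter at normoxia ("kinetics maintained to a good degree")
  expect_gt(v["encapsulated_over_free_normoxic"], 0.8)
  expect_lte(v["encapsulated_over_free_normoxic"], 1.02)
  # hypoxia hits encapsulated islets harder than free ones
  expect_lt(v["encapsulated_hypoxic_fraction_of_normoxic"],
            v["free_hypoxic_fraction_of_normoxic"])
  expect_true(all(v > 0 & v < 1.05))
})

test_that("cross-section profiles expose islet hypoxia and necrosis", {
  sim <- two_islet_sim()
  st <- steady_perifusion(sim$mesh, sim$flow, glucose_in = 15,
                          oxygen_in = po2_to_conc(30), ops = sim$ops)
  prof <- cross_section_profiles(st, x = 6.5e-3)  # through the 150-um islet
  expect_true(all(c("y_m", "c_oxy", "c_gluc", "r_ins") %in% names(prof)))
  in_tissue <- prof$subdomain == "tissue"
  expect_true(any(in_tissue))
  # oxygen minimum lies inside the islet
  expect_true(in_tissue[which.min(prof$c_oxy)])
  # glucose dips by a much smaller fraction than oxygen
  gluc_drop <- 1 - min(prof$c_gluc) / max(prof$c_gluc)
  oxy_drop <- 1 - min(prof$c_oxy) / max(prof$c_oxy)
  expect_lt(gluc_drop, 0.2 * oxy_drop)
  # necrotic cells do not secrete
  necro <- prof$c_oxy < 1e-4 & in_tissue
  if (any(necro)) expect_lt(max(prof$r_ins[necro]), 1e-4 * max(prof$r_ins))
  expect_error(cross_section_profiles(st, x = 1), "outside")
})

test_that("results expose tidyverse-style tidiers and plots", {
  conc <- c(1, 3, 5, 7, 10, 15, 30)
  fit <- fit_hill(data.frame(conc, hill(conc, hill_params(1, 7, 2.5))))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$c_half, 7, tolerance = 0.01)
  expect_s3_class(autoplot(fit), "ggplot")
  sw <- oxygen_sweep_radial(po2_mmHg = c(140, 30, 15), n_nodes = 40)
  expect_s3_class(autoplot(sw), "ggplot")
  rad <- radial_grid(100e-6, 200e-6, n_nodes = 40)
  expect_s3_class(autoplot(steady_radial(rad)), "ggplot")
})
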