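# Coupled convection-diffusion-reaction transport: conservation, boundary
# fluxes, steady states, and the 1D radial reduced solver as oracle.

test_that("inflow glucose follows the smoothed staircase schedule", {
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = c(600, 1200, 1800),
                                          delta = c(2, 2, 2)), tau = 30)
  expect_equal(glucose_inflow(0, prot), 1)
  expect_equal(glucose_inflow(599 - 30, prot), 1)
  expect_equal(glucose_inflow(600, prot), 2)       # half of the first step
  expect_equal(glucose_inflow(c(900, 1500, 2100), prot), c(3, 5, 7))
  expect_error(protocol(steps = tibble::tibble(t = c(2, 1), delta = c(1, 1))),
               "increasing")
  expect_error(protocol(glucose_low = 1,
                        steps = tibble::tibble(t = 10, delta = -5)),
               "negative")
})

test_that("with reactions off each species is conserved through a pulse", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = c(60, 240), delta = c(10, -10)),
                   tau = 20, duration = 420)
  res <- simulate_perifusion(sim$mesh, sim$flow, kin_all_off(),
                             diffusion_set(), prot, ops = sim$ops)
  cum <- res$diagnostics$cumulative
  tot0 <- domain_totals(res$init, sim$mesh)
  tot1 <- domain_totals(res$state, sim$mesh)
  gluc_err <- abs((tot1["gluc"] - tot0["gluc"]) +
                    (cum["gluc_out"] - cum["gluc_in"])) / cum["gluc_in"]
  oxy_err <- abs((tot1["oxy"] - tot0["oxy"]) +
                   (cum["oxy_out"] - cum["oxy_in"])) / cum["oxy_in"]
  expect_lt(unname(gluc_err), 1e-3)
  expect_lt(unname(oxy_err), 1e-3)
  expect_equal(res$diagnostics$clip_count, 0)
})

test_that("insulin bookkeeping closes: outflow = secretion - inventory change", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1,
                   steps = tibble::tibble(t = 60, delta = 14),
                   tau = 30, duration = 420)
  res <- simulate_perifusion(sim$mesh, sim$flow, prot = prot, ops = sim$ops)
  cum <- res$diagnostics$cumulative
  tot0 <- domain_totals(res$init, sim$mesh)
  tot1 <- domain_totals(res$state, sim$mesh)
  lhs <- cum["ins_out"] + cum["insL_out"]
  rhs <- cum["secreted"] - ((tot1["ins"] + tot1["insL"]) -
                              (tot0["ins"] + tot0["insL"]))
  expect_lt(unname(abs(lhs - rhs) / cum["secreted"]), 0.01)
})

test_that("outflow insulin flux integrates the convective outlet flux", {
  sim <- small_sim()
  mk <- function(c0) structure(list(c_ins = rep(c0, sim$mesh$n_cells),
                                    mesh = sim$mesh), class = "species_fields")
  expect_equal(outflow_insulin_flux(mk(0), sim$flow, sim$mesh), 0)
  expect_equal(outflow_insulin_flux(mk(2.5), sim$flow, sim$mesh),
               2.5 * sim$flow$flux_out)
})

test_that("initial state without islets is uniform at the inflow values", {
  mesh <- mesh_geometry(build_chamber(chamber_spec(length = 4e-3, height = 2e-3)),
                        resolution = 60e-6)
  fl <- solve_steady_flow(mesh)
  st <- initial_state(mesh, fl, kinetics_config(), diffusion_set(),
                      protocol(glucose_low = 3, oxygen_in = 0.2))
  expect_equal(max(abs(st$c_gluc - 3)), 0, tolerance = 1e-8)
  expect_equal(max(abs(st$c_oxy - 0.2)), 0, tolerance = 1e-8)
  expect_equal(max(abs(st$c_ins)), 0, tolerance = 1e-12)
})

test_that("steady outflow balances tissue secretion; basal release is tiny", {
  sim <- small_sim()
  hi <- steady_perifusion(sim$mesh, sim$flow, glucose_in = 15,
                          oxygen_in = 0.2, ops = sim$ops)
  expect_true(hi$converged)
  expect_equal(hi$outflux / hi$secretion_total, 1, tolerance = 0.02)
  lo <- steady_perifusion(sim$mesh, sim$flow, glucose_in = 1,
                          oxygen_in = 0.2, ops = sim$ops)
  expect_lt(lo$outflux, 0.01 * hi$outflux)
})

test_that("steady secretion is insensitive to halving the mesh size", {
  geom <- build_chamber(small_chamber())
  s30 <- {
    sim <- small_sim()
    steady_perifusion(sim$mesh, sim$flow, glucose_in = 15, oxygen_in = 0.2,
                      ops = sim$ops)$secretion_total
  }
  mesh15 <- mesh_geometry(geom, resolution = 15e-6)
  fl15 <- solve_steady_flow(mesh15)
  s15 <- steady_perifusion(mesh15, fl15, glucose_in = 15,
                           oxygen_in = 0.2)$secretion_total
  expect_equal(s30 / s15, 1, tolerance = 0.02)
})

test_that("halving the time step leaves the outflow trace unchanged", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1, steps = tibble::tibble(t = 30, delta = 14),
                   tau = 20, duration = 180)
  r1 <- simulate_perifusion(sim$mesh, sim$flow, prot = prot, dt_max = 0.5,
                            ops = sim$ops)
  r2 <- simulate_perifusion(sim$mesh, sim$flow, prot = prot, dt_max = 0.25,
                            ops = sim$ops, record_every = 2L)
  f1 <- r1$trace$insulin_outflux_mol_per_s
  f2 <- r2$trace$insulin_outflux_mol_per_s[seq_along(f1)]
  expect_lt(max(abs(f1 - f2)) / max(f1), 0.02)
})

test_that("dt_max above 0.5 s is rejected when the protocol has steps", {
  sim <- small_sim()
  prot <- protocol(glucose_low = 1, steps = tibble::tibble(t = 30, delta = 7),
                   duration = 60)
  expect_error(simulate_perifusion(sim$mesh, sim$flow, prot = prot,
                                   dt_max = 1), "0.5")
})

test_that("oxygen-enriched (720 mmHg) and atmospheric inflow give the same GSIR", {
  sim <- small_sim()
  tr <- lapply(c(140, 720) / 700, function(oin) {
    prot <- protocol(glucose_low = 1, steps = tibble::tibble(t = 60, delta = 14),
                     tau = 30, oxygen_in = oin, duration = 360)
    simulate_perifusion(sim$mesh, sim$flow, prot = prot,
                        ops = sim$ops)$trace$insulin_outflux_mol_per_s
  })
  expect_lt(max(abs(tr[[1]] - tr[[2]])) / max(tr[[1]]), 0.01)
})

test_that("steady secretion decreases monotonically with incoming oxygen", {
  sim <- two_islet_sim()
  po2 <- c(140, 60, 30, 15)
  sec <- vapply(po2, function(p) steady_secretion(sim, p), numeric(1))
  expect_true(all(diff(sec) < 0))
})

test_that("oxygen attains its minimum inside islet tissue", {
  sim <- two_islet_sim()
  st <- steady_perifusion(sim$mesh, sim$flow, glucose_in = 15,
                          oxygen_in = 0.2, ops = sim$ops)
  k_min <- which.min(st$c_oxy)
  expect_gt(as.numeric(sim$mesh$frac_tissue)[k_min], 0.5)
})

test_that("encapsulated islets never secrete more than free ones", {
  free <- two_islet_sim(); enc <- enc_islet_sim()
  for (p in c(140, 45)) {
    expect_lte(steady_secretion(enc, p), steady_secretion(free, p) * 1.001)
  }
})

# --- radial reduced solver as oracle ---------------------------------------

test_that("radial solver reproduces the zeroth-order consumption profile", {
  rad <- radial_grid(150e-6, 300e-6, n_nodes = 120)
  R0 <- 0.034
  st <- steady_radial(rad, glucose_far = 3, oxygen_far = 0.2,
                      oxygen_source = function(co, cg) -R0)
  a <- 75e-6; Dt <- 2e-9; Dw <- 3e-9
  c_surf <- 0.2 - R0 * a^3 / 3 / Dw * (1 / a - 1 / rad$r_outer)
  closed <- c_surf - R0 / (6 * Dt) * (a^2 - pmin(rad$rc, a)^2)
  idx <- rad$subdomain == "tissue"
  expect_lt(max(abs(st$c_oxy[idx] - closed[idx]) / closed[idx]), 0.01)
  # center deficit below the surface matches R a^2 / 6 D
  expect_equal(c_surf - st$c_oxy[1], R0 * a^2 / (6 * Dt), tolerance = 5e-3)
})

test_that("small normoxic islet recovers the local secretion Hill law", {
  rad <- radial_grid(50e-6, 200e-6, n_nodes = 80)
  sec <- vapply(c(3, 7, 15, 30), function(g)
    steady_radial(rad, glucose_far = g, oxygen_far = 0.2)$secretion_total,
    numeric(1))
  local_frac <- (c(3, 7, 15)^2.5 / (c(3, 7, 15)^2.5 + 7^2.5)) /
    (30^2.5 / (30^2.5 + 7^2.5))
  expect_equal(sec[1:3] / sec[4], local_frac, tolerance = 0.02)
})

test_that("radial and 2D solvers agree on the islet-center oxygen", {
  ch <- chamber_spec(islets = list(islet_spec(6e-3, 2e-3, 150e-6)))
  mesh <- mesh_geometry(build_chamber(ch), resolution = 20e-6)
  fl <- solve_steady_flow(mesh)
  st <- steady_perifusion(mesh, fl, glucose_in = 3, oxygen_in = 0.2)
  co <- matrix(st$c_oxy, mesh$nx, mesh$ny)
  surf <- mesh$frac_tissue > 0.05 & mesh$frac_tissue < 0.95
  rad <- radial_grid(150e-6, 20e-6, n_nodes = 100)
  sr <- steady_radial(rad, glucose_far = 3, oxygen_far = mean(co[surf]))
  expect_equal(min(co), sr$c_oxy[1], tolerance = 0.05)
})

test_that("local insulin decays exponentially at k_insL without secretion", {
  rad <- radial_grid(150e-6, 300e-6, n_nodes = 60)
  kin0 <- kin_no_secretion()
  init <- steady_radial(rad, kin0, glucose_far = 1, oxygen_far = 0.2)
  init$c_insL <- ifelse(rad$subdomain == "tissue", 1, 0)
  res <- simulate_radial(rad, kin0, prot = protocol(glucose_low = 1,
                                                    duration = 600),
                         init = init)
  rate <- -unname(stats::coef(stats::lm(log(insL_total_mol) ~ time_s,
                                        data = res$trace))[2])
  expect_equal(rate, 0.003, tolerance = 0.1)
  expect_equal(log(2) / rate / 60, 4, tolerance = 0.1)  # ~4 min half-life
})
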