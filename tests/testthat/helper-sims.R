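# Shared, lazily built simulation objects (reused across test files).

sim_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(sim_cache[[name]])) assign(name, builder(), envir = sim_cache)
  get(name, envir = sim_cache)
}

# small single-islet chamber for fast transient tests
small_chamber <- function() {
  chamber_spec(length = 3e-3, height = 1.2e-3,
               islets = list(islet_spec(1.0e-3, 0.6e-3, 100e-6)))
}

small_sim <- function() cached("small_sim", function() {
  mesh <- mesh_geometry(build_chamber(small_chamber()), resolution = 30e-6)
  flow <- solve_steady_flow(mesh)
  list(mesh = mesh, flow = flow,
       ops = isletsim:::transport_operators(mesh, flow, diffusion_set()))
})

# the reference two-islet chamber at reduced resolution
two_islet_sim <- function() cached("two_islet_sim", function() {
  mesh <- mesh_geometry(build_chamber(default_chamber()), resolution = 30e-6)
  flow <- solve_steady_flow(mesh)
  list(mesh = mesh, flow = flow,
       ops = isletsim:::transport_operators(mesh, flow, diffusion_set()))
})

enc_islet_sim <- function() cached("enc_islet_sim", function() {
  mesh <- mesh_geometry(build_chamber(default_chamber(encapsulated = TRUE)),
                        resolution = 30e-6)
  flow <- solve_steady_flow(mesh)
  list(mesh = mesh, flow = flow,
       ops = isletsim:::transport_operators(mesh, flow, diffusion_set()))
})

steady_secretion <- function(sim, po2_mmHg, glucose = 15) {
  steady_perifusion(sim$mesh, sim$flow, kinetics_config(), diffusion_set(),
                    glucose_in = glucose, oxygen_in = po2_mmHg / 700,
                    ops = sim$ops)$secretion_total
}

# kinetics with secretion switched off / all reactions off
kin_no_secretion <- function() {
  kinetics_config(ins_phase2 = hill_params(0, 7, 2.5),
                  ins_phase1 = hill_params(0, 0.03, 2))
}

kin_all_off <- function() {
  kinetics_config(oxy_consumption = hill_params(0, 1e-3, 1),
                  gluc_consumption = hill_params(0, 1e-2, 1),
                  ins_phase2 = hill_params(0, 7, 2.5),
                  ins_phase1 = hill_params(0, 0.03, 2))
}
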