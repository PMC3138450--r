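# Configuration, fixtures, CSV serialization and the CLI backend.

#' Full run configuration
#'
#' Bundles everything a simulation needs: kinetics, diffusivities, chamber
#' geometry, flow parameters, perifusion protocol, and solver knobs. All
#' defaults equal the calibrated model values, so `run_config()` with no
#' arguments reproduces the reference two-islet setup.
#'
#' @param kinetics A [kinetics_config()].
#' @param diffusion A [diffusion_set()].
#' @param chamber A [chamber_spec()].
#' @param flow A [flow_params()].
#' @param protocol A [protocol()].
#' @param solver List of solver knobs: `resolution` (m), `dt_max` (s),
#'   `seed`, `flow_method` ("stokes" or "navier-stokes").
#' @param output List of output selections (`trace_csv`, `snapshot_times`).
#' @param analysis Optional driver annotation used by fixtures (e.g. the
#'   pO2 grid of an oxygen sweep).
#' @return An object of class `run_config`.
#' @export
run_config <- function(kinetics = kinetics_config(),
                       diffusion = diffusion_set(),
                       chamber = default_chamber(),
                       flow = flow_params(),
                       protocol = isletsim::protocol(),
                       solver = list(),
                       output = list(),
                       analysis = NULL) {
  solver_def <- list(resolution = 16e-6, dt_max = 0.5, seed = 1L,
                     flow_method = "stokes")
  unknown <- setdiff(names(solver), names(solver_def))
  if (base::length(unknown))
    stop("unknown solver option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  solver <- utils::modifyList(solver_def, solver)
  if (solver$resolution <= 0 || solver$dt_max <= 0)
    stop("solver `resolution` and `dt_max` must be positive", call. = FALSE)
  stopifnot(inherits(kinetics, "kinetics_config"),
            inherits(diffusion, "diffusion_set"),
            inherits(chamber, "chamber_spec"),
            inherits(flow, "flow_params"),
            inherits(protocol, "perifusion_protocol"))
  structure(list(kinetics = kinetics, diffusion = diffusion,
                 chamber = chamber, flow = flow, protocol = protocol,
                 solver = solver, output = output, analysis = analysis),
            class = "run_config")
}

#' @rdname run_config
#' @param x Object to coerce (a `run_config`, or a list of its components).
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.list(x)) return(do.call(run_config, x))
  stop("cannot coerce to `run_config`", call. = FALSE)
}

# -- YAML loader with unit-suffixed keys -------------------------------------

stop_key <- function(section, key, expected) {
  stop(sprintf("config key `%s.%s`: %s", section, key, expected), call. = FALSE)
}

check_known <- function(section, obj, allowed) {
  unknown <- setdiff(names(obj), allowed)
  if (base::length(unknown))
    stop(sprintf("unknown key(s) in `%s`: %s (allowed: %s)", section,
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
}

num1 <- function(section, key, v, unit) {
  if (!is.numeric(v) || base::length(v) != 1L || !is.finite(v))
    stop_key(section, key, paste0("expected a single number in ", unit))
  v
}

parse_hill_block <- function(section, obj, c_half_key, c_half_scale, default) {
  allowed <- c("r_max_mol_m3_s", c_half_key, "n")
  check_known(section, obj, allowed)
  r_max <- if (!is.null(obj$r_max_mol_m3_s))
    num1(section, "r_max_mol_m3_s", obj$r_max_mol_m3_s, "mol m-3 s-1")
  else default$r_max
  c_half <- if (!is.null(obj[[c_half_key]]))
    num1(section, c_half_key, obj[[c_half_key]], c_half_key) * c_half_scale
  else default$c_half
  n <- if (!is.null(obj$n)) num1(section, "n", obj$n, "dimensionless") else default$n
  hill_params(r_max, c_half, n)
}

parse_kinetics <- function(obj) {
  d <- kinetics_config()
  sec <- "kinetics"
  scalars <- c("phi_base", "phi_metab", "phi_scale", "k_insL_per_s",
               "c_crit_oxy_uM", "step_scale_uM", "c_mid_sigma_mM",
               "sigma_steepness_per_mM", "po2_per_conc_mmHg_per_mM",
               "insulin_molar_mass_g_mol")
  blocks <- c("oxy_consumption", "gluc_consumption", "ins_phase2",
              "ins_phase1", "ins_oxy_mod")
  check_known(sec, obj, c(scalars, blocks))
  gv <- function(key, unit, default, scale = 1)
    if (!is.null(obj[[key]])) num1(sec, key, obj[[key]], unit) * scale else default
  kinetics_config(
    oxy_consumption = if (!is.null(obj$oxy_consumption))
      parse_hill_block("kinetics.oxy_consumption", obj$oxy_consumption,
                       "c_half_uM", 1e-3, d$oxy_consumption) else d$oxy_consumption,
    gluc_consumption = if (!is.null(obj$gluc_consumption))
      parse_hill_block("kinetics.gluc_consumption", obj$gluc_consumption,
                       "c_half_uM", 1e-3, d$gluc_consumption) else d$gluc_consumption,
    ins_phase2 = if (!is.null(obj$ins_phase2))
      parse_hill_block("kinetics.ins_phase2", obj$ins_phase2,
                       "c_half_mM", 1, d$ins_phase2) else d$ins_phase2,
    ins_phase1 = if (!is.null(obj$ins_phase1))
      parse_hill_block("kinetics.ins_phase1", obj$ins_phase1,
                       "c_half_mM_per_s", 1, d$ins_phase1) else d$ins_phase1,
    ins_oxy_mod = if (!is.null(obj$ins_oxy_mod))
      parse_hill_block("kinetics.ins_oxy_mod", obj$ins_oxy_mod,
                       "c_half_uM", 1e-3, d$ins_oxy_mod) else d$ins_oxy_mod,
    phi_base = gv("phi_base", "fraction", d$phi_base),
    phi_metab = gv("phi_metab", "fraction", d$phi_metab),
    phi_scale = gv("phi_scale", "dimensionless", d$phi_scale),
    c_crit_oxy = gv("c_crit_oxy_uM", "uM", d$c_crit_oxy, 1e-3),
    step_scale = gv("step_scale_uM", "uM", d$step_scale, 1e-3),
    k_insL = gv("k_insL_per_s", "s-1", d$k_insL),
    c_mid_sigma = gv("c_mid_sigma_mM", "mM", d$c_mid_sigma),
    sigma_steepness = gv("sigma_steepness_per_mM", "mM-1", d$sigma_steepness),
    po2_per_conc = gv("po2_per_conc_mmHg_per_mM", "mmHg per mM",
                      d$po2_per_conc),
    insulin_molar_mass = gv("insulin_molar_mass_g_mol", "g mol-1",
                            d$insulin_molar_mass))
}

parse_diffusion <- function(obj) {
  d <- diffusion_set()
  check_known("diffusion", obj, c("oxy", "gluc", "ins", "insL_m2_s"))
  one <- function(name) {
    blk <- obj[[name]]
    if (is.null(blk)) return(d[[name]])
    check_known(paste0("diffusion.", name),
                blk, c("water_m2_s", "tissue_m2_s", "capsule_m2_s"))
    out <- d[[name]]
    for (k in names(blk)) {
      tgt <- sub("_m2_s$", "", k)
      out[[tgt]] <- num1(paste0("diffusion.", name), k, blk[[k]], "m2 s-1")
    }
    out
  }
  diffusion_set(oxy = one("oxy"), gluc = one("gluc"), ins = one("ins"),
                insL = if (!is.null(obj$insL_m2_s))
                  num1("diffusion", "insL_m2_s", obj$insL_m2_s, "m2 s-1")
                else d$insL)
}

parse_chamber <- function(obj) {
  d <- default_chamber()
  check_known("chamber", obj, c("length_mm", "height_mm", "islets"))
  len <- if (!is.null(obj$length_mm))
    num1("chamber", "length_mm", obj$length_mm, "mm") * 1e-3 else d$length
  hei <- if (!is.null(obj$height_mm))
    num1("chamber", "height_mm", obj$height_mm, "mm") * 1e-3 else d$height
  islets <- if (is.null(obj$islets)) d$islets else purrr::map(
    seq_along(obj$islets), function(k) {
      isl <- obj$islets[[k]]
      sec <- sprintf("chamber.islets[%d]", k)
      check_known(sec, isl, c("x_mm", "y_mm", "diameter_um", "encapsulated",
                              "capsule_thickness_um"))
      diam <- num1(sec, "diameter_um", isl$diameter_um %||% NA_real_, "um") * 1e-6
      if (!is.finite(diam) || diam <= 0)
        stop_key(sec, "diameter_um", "expected a positive diameter in um")
      islet_spec(
        x = num1(sec, "x_mm", isl$x_mm %||% (len / 2 * 1e3), "mm") * 1e-3,
        y = num1(sec, "y_mm", isl$y_mm %||% (hei / 2 * 1e3), "mm") * 1e-3,
        diameter = diam,
        encapsulated = isTRUE(isl$encapsulated),
        capsule_thickness =
          num1(sec, "capsule_thickness_um",
               isl$capsule_thickness_um %||% 150, "um") * 1e-6)
    })
  chamber_spec(len, hei, islets)
}

parse_flow <- function(obj) {
  d <- flow_params()
  check_known("flow", obj, c("density_kg_m3", "viscosity_Pa_s", "v_in_m_s",
                             "body_force_N_m3"))
  flow_params(
    density = if (!is.null(obj$density_kg_m3))
      num1("flow", "density_kg_m3", obj$density_kg_m3, "kg m-3") else d$density,
    viscosity = if (!is.null(obj$viscosity_Pa_s))
      num1("flow", "viscosity_Pa_s", obj$viscosity_Pa_s, "Pa s") else d$viscosity,
    v_in = if (!is.null(obj$v_in_m_s))
      num1("flow", "v_in_m_s", obj$v_in_m_s, "m s-1") else d$v_in,
    body_force = if (!is.null(obj$body_force_N_m3))
      num1("flow", "body_force_N_m3", obj$body_force_N_m3, "N m-3")
    else d$body_force)
}

parse_protocol <- function(obj, kin) {
  d <- protocol()
  check_known("protocol", obj, c("glucose_low_mM", "tau_s", "oxygen_mmHg",
                                 "oxygen_mM", "duration_min", "steps"))
  if (!is.null(obj$oxygen_mmHg) && !is.null(obj$oxygen_mM))
    stop("give incoming oxygen as `oxygen_mmHg` or `oxygen_mM`, not both",
         call. = FALSE)
  oxy <- d$oxygen_in
  if (!is.null(obj$oxygen_mmHg))
    oxy <- po2_to_conc(num1("protocol", "oxygen_mmHg", obj$oxygen_mmHg, "mmHg"),
                       kin)
  if (!is.null(obj$oxygen_mM))
    oxy <- num1("protocol", "oxygen_mM", obj$oxygen_mM, "mM")
  steps <- if (is.null(obj$steps)) d$steps else purrr::map_dfr(
    seq_along(obj$steps), function(k) {
      stp <- obj$steps[[k]]
      sec <- sprintf("protocol.steps[%d]", k)
      check_known(sec, stp, c("t_min", "delta_mM"))
      tibble::tibble(
        t = num1(sec, "t_min", stp$t_min %||% NA_real_, "min") * 60,
        delta = num1(sec, "delta_mM", stp$delta_mM %||% NA_real_, "mM"))
    })
  protocol(
    glucose_low = if (!is.null(obj$glucose_low_mM))
      num1("protocol", "glucose_low_mM", obj$glucose_low_mM, "mM")
    else d$glucose_low,
    steps = steps,
    tau = if (!is.null(obj$tau_s))
      num1("protocol", "tau_s", obj$tau_s, "s") else d$tau,
    oxygen_in = oxy,
    duration = if (!is.null(obj$duration_min))
      num1("protocol", "duration_min", obj$duration_min, "min") * 60
    else d$duration)
}

parse_solver <- function(obj) {
  check_known("solver", obj, c("resolution_um", "dt_max_s", "seed",
                               "flow_method"))
  out <- list()
  if (!is.null(obj$resolution_um))
    out$resolution <- num1("solver", "resolution_um", obj$resolution_um,
                           "um") * 1e-6
  if (!is.null(obj$dt_max_s))
    out$dt_max <- num1("solver", "dt_max_s", obj$dt_max_s, "s")
  if (!is.null(obj$seed)) out$seed <- as.integer(obj$seed)
  if (!is.null(obj$flow_method)) {
    if (!obj$flow_method %in% c("stokes", "navier-stokes"))
      stop_key("solver", "flow_method", "expected 'stokes' or 'navier-stokes'")
    out$flow_method <- obj$flow_method
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from a YAML file
#'
#' Declarative configuration with unit-suffixed keys (`diameter_um`,
#' `oxygen_mmHg`, `glucose_low_mM`, `t_min`, ...) converted to SI internally;
#' unknown keys are rejected with the list of allowed keys, and an empty
#' file yields the full default configuration.
#'
#' @param path Path to the YAML config file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  check_known("(top level)", raw,
              c("kinetics", "diffusion", "chamber", "flow", "protocol",
                "solver", "output"))
  kin <- parse_kinetics(raw$kinetics %||% list())
  run_config(
    kinetics = kin,
    diffusion = parse_diffusion(raw$diffusion %||% list()),
    chamber = parse_chamber(raw$chamber %||% list()),
    flow = parse_flow(raw$flow %||% list()),
    protocol = parse_protocol(raw$protocol %||% list(), kin),
    solver = parse_solver(raw$solver %||% list()),
    output = raw$output %||% list())
}

#' Ready-made experiment presets
#'
#' Named configurations matching the reference in-silico experiments:
#' `fig4_staircase` (G1 to G30 glucose staircase), `fig5_step` (single
#' G1-G15-G1 step), `fig6_sweep` (incoming-pO2 sweep at high glucose),
#' `fig11_encapsulation` (free vs encapsulated comparison), and
#' `single_islet_radial` (one 150-um islet for the reduced model).
#'
#' @param name Preset name.
#' @return A [run_config()]; sweep/comparison presets carry their driver
#'   grid in `$analysis`, the radial preset its grid spec in
#'   `$analysis$radial`.
#' @export
make_fixture <- function(name) {
  presets <- c("fig4_staircase", "fig5_step", "fig6_sweep",
               "fig11_encapsulation", "single_islet_radial")
  if (!is.character(name) || base::length(name) != 1L || !name %in% presets)
    stop("unknown fixture; available: ", paste(presets, collapse = ", "),
         call. = FALSE)
  staircase_steps <- tibble::tibble(
    t = (1:6) * 1800, delta = c(2, 2, 2, 3, 5, 15))  # 1->3->5->7->10->15->30 mM
  switch(
    name,
    fig4_staircase = run_config(
      protocol = protocol(glucose_low = 1, steps = staircase_steps,
                          duration = 12600),
      solver = list(resolution = 40e-6)),
    fig5_step = run_config(
      protocol = protocol(
        glucose_low = 1,
        steps = tibble::tibble(t = c(1800, 3600), delta = c(14, -14)),
        duration = 5400),
      solver = list(resolution = 40e-6)),
    fig6_sweep = run_config(
      protocol = protocol(glucose_low = 15, duration = 1),
      solver = list(resolution = 40e-6),
      analysis = list(type = "oxygen_sweep",
                      po2_mmHg = c(140, 80, 60, 50, 40, 30, 25, 20, 15, 10, 5),
                      glucose_mM = 15)),
    fig11_encapsulation = run_config(
      chamber = default_chamber(encapsulated = TRUE),
      protocol = protocol(glucose_low = 15, duration = 1),
      solver = list(resolution = 40e-6),
      analysis = list(type = "encapsulation_compare", po2_mmHg = c(140, 45),
                      glucose_mM = 15)),
    single_islet_radial = run_config(
      chamber = chamber_spec(islets = list(islet_spec(6e-3, 2e-3, 150e-6))),
      protocol = protocol(glucose_low = 1, duration = 1),
      analysis = list(type = "radial",
                      radial = list(diameter = 150e-6, shell = 300e-6,
                                    n_nodes = 100))))
}

#' Write an outflow time series to CSV
#'
#' Fixed column schema `time_s, gluc_in_mM, pO2_in_mmHg,
#' insulin_outflux_mol_per_s, insulin_out_conc_mM`; byte-stable for
#' identical results.
#'
#' @param result A `perifusion_result` (or its `trace` tibble).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(result, path) {
  trace <- if (inherits(result, "perifusion_result")) result$trace else
    tibble::as_tibble(result)
  schema <- c("time_s", "gluc_in_mM", "pO2_in_mmHg",
              "insulin_outflux_mol_per_s", "insulin_out_conc_mM")
  if (!all(schema %in% names(trace)))
    stop("trace is missing schema columns", call. = FALSE)
  trace <- trace[schema]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(schema, collapse = ","), con)
  if (nrow(trace)) {
    lines <- do.call(paste, c(lapply(trace, function(col)
      sprintf("%.15g", col)), sep = ","))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write field snapshots as a long CSV table
#'
#' @param state A `species_fields` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fields_csv <- function(state, path) {
  mesh <- state$mesh
  tbl <- tibble::tibble(
    x_m = rep(mesh$xc, mesh$ny), y_m = rep(mesh$yc, each = mesh$nx),
    subdomain = as.vector(mesh$subdomain),
    c_oxy_mM = state$c_oxy, c_gluc_mM = state$c_gluc,
    c_ins_mM = state$c_ins, c_insL_mM = state$c_insL)
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
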