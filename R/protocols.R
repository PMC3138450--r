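# Drivers for the in-silico perifusion experiments and the analysis layer.

#' Build the solver objects for a run configuration
#'
#' Meshes the chamber and solves the steady flow once; the pieces are reused
#' by every driver operating on the same geometry.
#'
#' @param config A [run_config()].
#' @return List with `mesh`, `flow`, `ops` (transport operators) and the
#'   config echo.
#' @export
setup_simulation <- function(config) {
  config <- as_run_config(config)
  geom <- build_chamber(config$chamber)
  mesh <- mesh_geometry(geom, resolution = config$solver$resolution)
  flow <- solve_steady_flow(mesh, config$flow, method = config$solver$flow_method)
  list(mesh = mesh, flow = flow,
       ops = transport_operators(mesh, flow, config$diffusion),
       config = config)
}

# per-step peak / plateau summary of an outflow trace
summarize_steps <- function(trace, prot, plateau_window = 120) {
  steps <- prot$steps
  bounds <- c(steps$t, max(trace$time_s) + 1)
  levels <- prot$glucose_low + cumsum(steps$delta)
  purrr::map_dfr(seq_len(nrow(steps)), function(k) {
    w <- trace$time_s >= bounds[k] & trace$time_s < bounds[k + 1]
    tr <- trace[w, ]
    if (!nrow(tr)) return(NULL)
    t_end <- max(tr$time_s)
    last <- tr$insulin_outflux_mol_per_s[tr$time_s > t_end - plateau_window]
    prev <- tr$insulin_outflux_mol_per_s[tr$time_s > t_end - 2 * plateau_window &
                                           tr$time_s <= t_end - plateau_window]
    plateau <- mean(last)
    drift <- if (base::length(prev)) abs(mean(last) - mean(prev)) /
      max(abs(plateau), 1e-300) else NA_real_
    tibble::tibble(
      step = k, t_start = steps$t[k], glucose_mM = levels[k],
      delta_mM = steps$delta[k],
      peak = max(tr$insulin_outflux_mol_per_s),
      t_peak = tr$time_s[which.max(tr$insulin_outflux_mol_per_s)],
      plateau = plateau, drift = drift, steady = is.finite(drift) & drift < 0.01)
  })
}

#' Run the glucose staircase protocol
#'
#' Executes a stepwise glucose-increment perifusion (by default the
#' G1-to-G30 staircase fixture) and summarizes each step's first-phase peak
#' and second-phase plateau.
#'
#' @param config A [run_config()]; its protocol should be a staircase.
#' @param sim Optional prebuilt [setup_simulation()] result.
#' @param ... Passed to [simulate_perifusion()].
#' @return A `perifusion_result` with an added `steps` summary tibble.
#' @export
run_staircase <- function(config = make_fixture("fig4_staircase"), sim = NULL, ...) {
  config <- as_run_config(config)
  if (is.null(sim)) sim <- setup_simulation(config)
  res <- simulate_perifusion(sim$mesh, sim$flow, config$kinetics,
                             config$diffusion, config$protocol,
                             dt_max = config$solver$dt_max, ops = sim$ops, ...)
  res$steps <- summarize_steps(res$trace, config$protocol)
  res
}

#' Run a single low-high-low glucose step
#'
#' @param config A [run_config()] whose protocol is a single up/down step
#'   (default: the G1-G15-G1 fixture).
#' @inheritParams run_staircase
#' @return A `perifusion_result` with a `steps` summary tibble.
#' @export
run_single_step <- function(config = make_fixture("fig5_step"), sim = NULL, ...) {
  run_staircase(config, sim = sim, ...)
}

#' Sweep the incoming oxygen pressure
#'
#' Computes the steady second-phase secretion of the configured geometry at
#' high glucose for a list of incoming oxygen partial pressures, normalizes
#' to the normoxic (140 mmHg) reference, and interpolates the half-maximal
#' incoming pO2 on the monotone piecewise-linear fraction curve.
#'
#' @param config A [run_config()].
#' @param po2_mmHg Incoming partial pressures (mmHg); must include the
#'   reference.
#' @param glucose_mM High-glucose level for the steady runs (mol m-3).
#' @param reference_mmHg Normoxic reference pressure.
#' @inheritParams run_staircase
#' @return An `oxygen_sweep_result`: tibble (po2_mmHg, secretion, fraction)
#'   with attributes `half_max_po2` and the reference level.
#' @export
oxygen_sweep <- function(config = run_config(),
                         po2_mmHg = c(140, 80, 60, 50, 40, 30, 25, 20, 15, 10),
                         glucose_mM = 15, reference_mmHg = 140, sim = NULL) {
  config <- as_run_config(config)
  if (!reference_mmHg %in% po2_mmHg)
    stop("`po2_mmHg` must include the reference pressure", call. = FALSE)
  if (is.null(sim)) sim <- setup_simulation(config)
  kin <- config$kinetics
  sec <- purrr::map_dbl(po2_mmHg, function(p) {
    st <- steady_perifusion(sim$mesh, sim$flow, kin, config$diffusion,
                            glucose_in = glucose_mM,
                            oxygen_in = po2_to_conc(p, kin), ops = sim$ops)
    if (!st$converged)
      warning(sprintf("steady state at %g mmHg did not fully converge", p))
    st$secretion_total
  })
  ref <- sec[match(reference_mmHg, po2_mmHg)]
  tbl <- tibble::tibble(po2_mmHg = po2_mmHg, secretion = sec,
                        fraction = sec / ref) |>
    dplyr::arrange(.data$po2_mmHg)
  structure(tbl,
            half_max_po2 = half_crossing(tbl$po2_mmHg, tbl$fraction),
            reference_mmHg = reference_mmHg, glucose_mM = glucose_mM,
            class = c("oxygen_sweep_result", class(tbl)))
}

# monotone piecewise-linear interpolation of the 50% crossing; the fraction
# curve is made nondecreasing in po2 (cummax) before inverting
half_crossing <- function(po2, fraction, level = 0.5) {
  f <- cummax(fraction)
  if (all(f < level) || all(f > level)) return(NA_real_)
  stats::approx(x = f, y = po2, xout = level, ties = "ordered")$y
}

#' Oxygen sweep with the spherically symmetric surrogate
#'
#' Fast alternative to the full-chamber [oxygen_sweep()]: each islet of the
#' configuration is solved as a sphere surrounded by a stagnant medium shell
#' whose far-field concentrations match the incoming perifusate (the
#' surrogate's surface conditions are set by the incoming pO2 and glucose),
#' and the islet totals are summed. Spheres carry the true
#' three-dimensional supply geometry of an islet, where the planar
#' two-dimensional chamber section systematically over-weights the
#' unstirred-layer oxygen deficit (see the methods vignette).
#'
#' @param diameters Islet diameters (m); default the reference pair.
#' @param po2_mmHg Incoming pO2 grid (mmHg), must include the reference.
#' @param glucose_mM High-glucose level (mol m-3).
#' @param shell Stagnant medium shell thickness (m).
#' @param capsule Optional capsule thickness (m) for encapsulated islets.
#' @param reference_mmHg Normoxic reference pressure.
#' @param kin,dset Model parameter objects.
#' @param n_nodes Radial grid size per islet.
#' @return An `oxygen_sweep_result` (see [oxygen_sweep()]).
#' @export
oxygen_sweep_radial <- function(diameters = c(100e-6, 150e-6),
                                po2_mmHg = c(140, 80, 60, 50, 40, 30, 25,
                                             20, 15, 10),
                                glucose_mM = 15, shell = 300e-6,
                                capsule = NULL, reference_mmHg = 140,
                                kin = kinetics_config(),
                                dset = diffusion_set(), n_nodes = 100) {
  if (!reference_mmHg %in% po2_mmHg)
    stop("`po2_mmHg` must include the reference pressure", call. = FALSE)
  grids <- purrr::map(diameters, radial_grid, medium_shell = shell,
                      capsule = capsule, n_nodes = n_nodes)
  sec <- purrr::map_dbl(po2_mmHg, function(p)
    sum(purrr::map_dbl(grids, function(g)
      steady_radial(g, kin, dset, glucose_far = glucose_mM,
                    oxygen_far = po2_to_conc(p, kin))$secretion_total)))
  ref <- sec[match(reference_mmHg, po2_mmHg)]
  tbl <- tibble::tibble(po2_mmHg = po2_mmHg, secretion = sec,
                        fraction = sec / ref) |>
    dplyr::arrange(.data$po2_mmHg)
  structure(tbl,
            half_max_po2 = half_crossing(tbl$po2_mmHg, tbl$fraction),
            reference_mmHg = reference_mmHg, glucose_mM = glucose_mM,
            class = c("oxygen_sweep_result", class(tbl)))
}

#' Compare free and encapsulated islets
#'
#' Runs the same islet configuration free and with hydrogel capsules
#' (default thickness 150 um, capsule diffusivities from the
#' [diffusion_set()]), at a normoxic and a hypoxic incoming pO2, and reports
#' the steady second-phase secretion together with the ratios of interest:
#' encapsulated/free at each oxygen level and each configuration's
#' hypoxic/normoxic fraction.
#'
#' @param config A [run_config()]; the chamber's islets are run both free
#'   and encapsulated regardless of their `encapsulated` flags.
#' @param po2_mmHg Two pressures: c(normoxic, hypoxic).
#' @param glucose_mM High-glucose level (mol m-3).
#' @param capsule_thickness Capsule shell thickness (m).
#' @return An `encapsulation_comparison`: list with the `summary` tibble
#'   (configuration, po2_mmHg, secretion) and a `ratios` tibble.
#' @export
encapsulation_compare <- function(config = run_config(),
                                  po2_mmHg = c(140, 45), glucose_mM = 15,
                                  capsule_thickness = 150e-6) {
  config <- as_run_config(config)
  stopifnot(base::length(po2_mmHg) == 2L)
  kin <- config$kinetics
  variant <- function(encapsulated) {
    ch <- config$chamber
    ch$islets <- purrr::map(ch$islets, function(s) {
      s$encapsulated <- encapsulated
      s$capsule_thickness <- capsule_thickness
      s
    })
    cfg <- config; cfg$chamber <- ch
    sim <- setup_simulation(cfg)
    purrr::map_dbl(po2_mmHg, function(p)
      steady_perifusion(sim$mesh, sim$flow, kin, config$diffusion,
                        glucose_in = glucose_mM,
                        oxygen_in = po2_to_conc(p, kin),
                        ops = sim$ops)$secretion_total)
  }
  free <- variant(FALSE); enc <- variant(TRUE)
  summary <- tibble::tibble(
    configuration = rep(c("free", "encapsulated"), each = 2L),
    po2_mmHg = rep(po2_mmHg, 2L),
    secretion = c(free, enc))
  ratios <- tibble::tibble(
    quantity = c("encapsulated_over_free_normoxic",
                 "encapsulated_over_free_hypoxic",
                 "free_hypoxic_fraction_of_normoxic",
                 "encapsulated_hypoxic_fraction_of_normoxic"),
    value = c(enc[1] / free[1], enc[2] / free[2],
              free[2] / free[1], enc[2] / enc[1]))
  structure(list(summary = summary, ratios = ratios,
                 po2_mmHg = po2_mmHg, glucose_mM = glucose_mM),
            class = "encapsulation_comparison")
}

#' Extract a dose-response curve from a staircase run
#'
#' Per-level plateau secretion (mean of the final `window` seconds of each
#' plateau, with a drift audit flagging plateaus that have not reached steady
#' state), optionally normalized to the maximum.
#'
#' @param result A `perifusion_result` from [run_staircase()].
#' @param window Plateau averaging window (s).
#' @param normalize Add a column normalized to the maximum plateau.
#' @return Tibble of dose-response points (glucose_mM, secretion,
#'   normalized, steady).
#' @export
extract_dose_response <- function(result, window = 120, normalize = TRUE) {
  st <- summarize_steps(result$trace, result$protocol, plateau_window = window)
  out <- tibble::tibble(glucose_mM = st$glucose_mM, secretion = st$plateau,
                        steady = st$steady)
  if (any(!out$steady, na.rm = TRUE))
    warning("some plateaus show > 1% drift over the averaging window")
  if (normalize) out$normalized <- out$secretion / max(out$secretion)
  out
}

#' Steady dose-response of a single islet (reduced model)
#'
#' Uses the spherically symmetric solver to compute the steady second-phase
#' secretion of one islet over a set of far-field glucose levels; for small
#' islets at ample oxygen this recovers the local secretion Hill law almost
#' undistorted.
#'
#' @param glucose_mM Glucose levels (mol m-3).
#' @param diameter Islet diameter (m).
#' @param oxygen_mmHg Far-field oxygen (mmHg).
#' @param shell Medium-shell thickness (m).
#' @param kin,dset Model parameter objects.
#' @param n_nodes Radial grid size.
#' @return Tibble (glucose_mM, secretion, normalized).
#' @export
dose_response_radial <- function(glucose_mM = c(1, 2, 3, 5, 7, 9, 11, 15, 20, 30),
                                 diameter = 50e-6, oxygen_mmHg = 140,
                                 shell = 200e-6, kin = kinetics_config(),
                                 dset = diffusion_set(), n_nodes = 80) {
  rad <- radial_grid(diameter, shell, n_nodes = n_nodes)
  sec <- purrr::map_dbl(glucose_mM, function(g)
    steady_radial(rad, kin, dset, glucose_far = g,
                  oxygen_far = po2_to_conc(oxygen_mmHg, kin))$secretion_total)
  tibble::tibble(glucose_mM = glucose_mM, secretion = sec,
                 normalized = sec / max(sec))
}

#' Fit the Hill equation to dose-response points
#'
#' Nonlinear least squares of `r_max * c^n / (c^n + c_half^n)` to measured
#' (concentration, response) points via a deterministic multi-start
#' Levenberg-Marquardt; optionally with the Hill slope fixed (e.g. `fix_n =
#' 1` for a Michaelis-Menten fit).
#'
#' @param points Data frame with concentrations in the first column (or a
#'   `glucose_mM` column) and responses in the second (or `secretion`).
#' @param fix_n Optional fixed Hill slope.
#' @param n_grid,c_grid Multi-start grids for the slope and half-max.
#' @return A `hill_fit` object; see [tidy.hill_fit()] and
#'   [glance.hill_fit()].
#' @export
fit_hill <- function(points, fix_n = NULL,
                     n_grid = c(0.5, 1, 1.5, 2, 2.5, 3, 4),
                     c_grid = NULL) {
  points <- as.data.frame(points)
  conc <- if ("glucose_mM" %in% names(points)) points$glucose_mM else points[[1]]
  resp <- if ("secretion" %in% names(points)) points$secretion else points[[2]]
  keep <- is.finite(conc) & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  if (base::length(conc) < 3L)
    stop("need at least 3 finite dose-response points", call. = FALSE)
  if (diff(range(resp)) <= 0)
    stop("degenerate dose-response: all responses equal", call. = FALSE)
  if (is.null(c_grid))
    c_grid <- stats::quantile(conc[conc > 0], c(0.25, 0.5, 0.75), names = FALSE)
  dat <- data.frame(conc = conc, resp = resp)
  best <- NULL
  starts <- if (is.null(fix_n)) {
    expand.grid(n = n_grid, c_half = c_grid)
  } else expand.grid(n = fix_n, c_half = c_grid)
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (is.null(fix_n)) {
        minpack.lm::nlsLM(
          resp ~ r_max * conc^n / (conc^n + c_half^n), data = dat,
          start = list(r_max = max(resp), c_half = starts$c_half[k],
                       n = starts$n[k]),
          lower = c(r_max = 0, c_half = 1e-12, n = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        n_fixed <- fix_n
        minpack.lm::nlsLM(
          resp ~ r_max * conc^n_fixed / (conc^n_fixed + c_half^n_fixed),
          data = dat,
          start = list(r_max = max(resp), c_half = starts$c_half[k]),
          lower = c(r_max = 0, c_half = 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-300 * abs(best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed from every start", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(
    r_max = unname(cf["r_max"]),
    c_half = unname(cf["c_half"]),
    n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
    restricted = !is.null(fix_n),
    rss = best$rss, residual_norm = sqrt(best$rss),
    n_points = base::length(conc),
    data = tibble::tibble(conc = conc, resp = resp),
    model = best$fit
  ), class = "hill_fit")
}

#' Sample fields along a vertical cross-section line
#'
#' Oxygen, glucose and insulin concentrations plus the local secretion rate
#' along a vertical line through the chamber (piecewise-constant on the
#' finite-volume cells).
#'
#' @param state A `species_fields` object.
#' @param x Line position (m); defaults to the mid-chamber.
#' @param kin A [kinetics_config()] for the secretion-rate column.
#' @return Tibble (y_m, subdomain, c_oxy, c_gluc, c_ins, r_ins).
#' @export
cross_section_profiles <- function(state, x = NULL, kin = kinetics_config()) {
  mesh <- state$mesh
  xmax <- mesh$x[base::length(mesh$x)]
  if (is.null(x)) x <- xmax / 2
  if (x < 0 || x > xmax) stop("line position outside the domain", call. = FALSE)
  i <- max(1L, min(mesh$nx, findInterval(x, mesh$x, all.inside = TRUE)))
  pick <- function(v) matrix(v, mesh$nx, mesh$ny)[i, ]
  c_oxy <- pick(state$c_oxy); c_gluc <- pick(state$c_gluc)
  tibble::tibble(
    y_m = mesh$yc, subdomain = mesh$subdomain[i, ],
    c_oxy = c_oxy, c_gluc = c_gluc, c_ins = pick(state$c_ins),
    r_ins = total_secretion_rate(c_gluc, 0, c_oxy, kin) *
      mesh$frac_tissue[i, ])
}
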