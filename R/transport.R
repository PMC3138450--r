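#' Species diffusivities per subdomain
#'
#' Diffusion coefficients (m^2 s-1) of the four modelled species in aqueous
#' medium, islet tissue and hydrogel capsule. Local (cell-compartment)
#' insulin is carried as a field with a vanishingly small diffusivity so it
#' stays where it was secreted.
#'
#' @param oxy,gluc,ins Named numeric vectors with entries `water`, `tissue`,
#'   `capsule`.
#' @param insL Diffusivity of the local-insulin field (everywhere).
#' @return An object of class `diffusion_set`.
#' @export
diffusion_set <- function(
    oxy = c(water = 3.0e-9, tissue = 2.0e-9, capsule = 2.5e-9),
    gluc = c(water = 0.9e-9, tissue = 0.3e-9, capsule = 0.6e-9),
    ins = c(water = 0.15e-9, tissue = 0.05e-9, capsule = 0.1e-9),
    insL = 1.0e-16) {
  for (v in list(oxy, gluc, ins)) {
    if (!all(c("water", "tissue", "capsule") %in% names(v)) || any(v <= 0))
      stop("diffusivities need positive `water`, `tissue`, `capsule` entries",
           call. = FALSE)
  }
  if (insL <= 0) stop("`insL` must be positive", call. = FALSE)
  structure(list(oxy = oxy, gluc = gluc, ins = ins, insL = insL),
            class = "diffusion_set")
}

#' Perifusion protocol
#'
#' Inflow schedule: a baseline glucose level plus smoothed-step increments
#' `c_low + sum_i c_step_i * smoothed_step(t - t_i, tau)`, a fixed incoming
#' oxygen concentration, zero incoming insulin, and a total duration.
#'
#' @param glucose_low Baseline inflow glucose (mol m-3).
#' @param steps Tibble/data frame with columns `t` (s, strictly increasing)
#'   and `delta` (mol m-3, signed step heights).
#' @param tau Half-width of the smoothed inflow step (s).
#' @param oxygen_in Incoming oxygen concentration (mol m-3; 0.200 is
#'   atmospheric, ~140 mmHg).
#' @param duration Protocol duration (s).
#' @return An object of class `perifusion_protocol`.
#' @export
protocol <- function(glucose_low = 1, steps = tibble::tibble(t = numeric(),
                                                             delta = numeric()),
                     tau = 30, oxygen_in = 0.200, duration = 3600) {
  steps <- tibble::as_tibble(steps)
  if (!all(c("t", "delta") %in% names(steps)))
    stop("`steps` needs columns `t` and `delta`", call. = FALSE)
  if (nrow(steps) > 1L && any(diff(steps$t) <= 0))
    stop("step times must be strictly increasing", call. = FALSE)
  if (glucose_low < 0 || oxygen_in < 0 || tau <= 0 || duration <= 0)
    stop("invalid protocol: concentrations >= 0, `tau` and `duration` > 0",
         call. = FALSE)
  if (nrow(steps) && glucose_low + min(cumsum(steps$delta)) < 0)
    stop("step schedule drives inflow glucose negative", call. = FALSE)
  structure(list(glucose_low = glucose_low, steps = steps, tau = tau,
                 oxygen_in = oxygen_in, duration = duration),
            class = "perifusion_protocol")
}

#' Inflow glucose concentration at time t
#'
#' @param t Time(s), s.
#' @param prot A [protocol()].
#' @return Inflow glucose (mol m-3), vectorized over `t`.
#' @export
glucose_inflow <- function(t, prot) {
  out <- rep(prot$glucose_low, base::length(t))
  for (k in seq_len(nrow(prot$steps)))
    out <- out + prot$steps$delta[k] * smoothed_step(t - prot$steps$t[k], prot$tau)
  out
}

# per-cell diffusivity of one species from subdomain fractions
species_cell_diffusivity <- function(mesh, dset, species) {
  if (species == "insL") return(matrix(dset$insL, mesh$nx, mesh$ny))
  d <- dset[[species]]
  d[["water"]] * mesh$frac_lumen + d[["tissue"]] * mesh$frac_tissue +
    d[["capsule"]] * mesh$frac_capsule
}

# Assemble the linear transport operator for one species on the 2D grid:
# dc/dt = A c + b_unit * c_in(t). Upwind convection with the staggered face
# velocities, harmonic-mean diffusive face conductances, advective inflow at
# the inlet, convective outflow at the outlet, no-flux walls.
assemble_transport <- function(mesh, flow, D_cells) {
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx; dy <- mesh$dy
  K <- matrix(seq_len(nx * ny), nx, ny)
  vol <- outer(dx, dy)
  DY <- matrix(rep(dy, each = nx), nx, ny)
  DX <- matrix(rep(dx, ny), nx, ny)

  ii <- list(); jj <- list(); xx <- list(); m <- 0L
  push <- function(r, c, v) {
    m <<- m + 1L; ii[[m]] <<- r; jj[[m]] <<- c; xx[[m]] <<- v
  }

  if (nx > 1L) {
    il <- 1:(nx - 1L)
    Dl <- D_cells[il, , drop = FALSE]; Dr <- D_cells[il + 1L, , drop = FALSE]
    hl <- matrix(rep(dx[il] / 2, ny), nx - 1L, ny)
    hr <- matrix(rep(dx[il + 1L] / 2, ny), nx - 1L, ny)
    g <- DY[il, , drop = FALSE] / (hl / Dl + hr / Dr)
    uf <- flow$u[il + 1L, , drop = FALSE]            # face between cells i, i+1
    fpos <- pmax(uf, 0) * DY[il, , drop = FALSE]
    fneg <- pmin(uf, 0) * DY[il, , drop = FALSE]
    kl <- K[il, , drop = FALSE]; kr <- K[il + 1L, , drop = FALSE]
    push(kl, kl, -g - fpos); push(kl, kr, g - fneg)
    push(kr, kr, -g + fneg); push(kr, kl, g + fpos)
  }
  if (ny > 1L) {
    jl <- 1:(ny - 1L)
    Dl <- D_cells[, jl, drop = FALSE]; Dr <- D_cells[, jl + 1L, drop = FALSE]
    hl <- matrix(rep(dy[jl] / 2, each = nx), nx, ny - 1L)
    hr <- matrix(rep(dy[jl + 1L] / 2, each = nx), nx, ny - 1L)
    g <- DX[, jl, drop = FALSE] / (hl / Dl + hr / Dr)
    vf <- flow$v[, jl + 1L, drop = FALSE]
    fpos <- pmax(vf, 0) * DX[, jl, drop = FALSE]
    fneg <- pmin(vf, 0) * DX[, jl, drop = FALSE]
    kl <- K[, jl, drop = FALSE]; kr <- K[, jl + 1L, drop = FALSE]
    push(kl, kl, -g - fpos); push(kl, kr, g - fneg)
    push(kr, kr, -g + fneg); push(kr, kl, g + fpos)
  }
  # inlet: advective influx with the local face velocity
  b_flux <- numeric(nx * ny)
  b_flux[K[1L, ]] <- flow$u[1L, ] * dy
  # outlet: convective outflow (upwind cell value)
  uo <- flow$u[nx + 1L, ]
  push(K[nx, ], K[nx, ], -pmax(uo, 0) * dy)

  A_flux <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                 dims = c(nx * ny, nx * ny))
  inv_vol <- 1 / as.numeric(vol)
  list(A = Matrix::Diagonal(x = inv_vol) %*% A_flux,
       b_unit = b_flux * inv_vol,
       outflux_w = pmax(uo, 0) * dy,       # weights on the outlet cell column
       outlet_cells = K[nx, ],
       vol = as.numeric(vol))
}

#' Outflow insulin flux of a state
#'
#' Convective flux of released insulin through the outlet boundary,
#' `integral of c_ins (u . n)` along the outlet (per unit depth of the planar
#' cross-section).
#'
#' @param state A `species_fields` object (from [steady_perifusion()] or a
#'   simulation step).
#' @param flow A [solve_steady_flow()] result.
#' @param mesh The matching [mesh_geometry()] mesh.
#' @return Flux in mol s-1 (per m depth).
#' @export
outflow_insulin_flux <- function(state, flow, mesh) {
  nx <- mesh$nx
  c_out <- matrix(state$c_ins, nx, mesh$ny)[nx, ]
  sum(pmax(flow$u[nx + 1L, ], 0) * mesh$dy * c_out)
}

new_species_fields <- function(mesh, c_oxy, c_gluc, c_ins, c_insL, time = 0,
                               extra = list()) {
  structure(c(list(c_oxy = c_oxy, c_gluc = c_gluc, c_ins = c_ins,
                   c_insL = c_insL, time = time, mesh = mesh), extra),
            class = "species_fields")
}

#' Steady state of the coupled perifusion system
#'
#' Solves the steady convection-diffusion-reaction system at fixed inflow
#' glucose and oxygen by a damped fixed-point iteration: the Michaelis-Menten
#' consumption terms are quasi-linearized (rate = -k(c_old) c_new) so every
#' iterate solves a positivity-preserving linear transport system; released
#' insulin then solves a linear system with the steady secretion source, and
#' the local compartment follows algebraically
#' (`c_insL = c_ins + R_ins / k_insL` in tissue). At steady state the glucose
#' time-derivative vanishes, so secretion is purely second-phase.
#'
#' @param mesh A [mesh_geometry()] mesh.
#' @param flow A [solve_steady_flow()] velocity field.
#' @param kin A [kinetics_config()].
#' @param dset A [diffusion_set()].
#' @param glucose_in,oxygen_in Inflow concentrations (mol m-3).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @param relax Under-relaxation factor in (0, 1].
#' @param ops Optional precomputed transport operators (reused across sweep
#'   points).
#' @return A `species_fields` object with fields plus `secretion_total`
#'   (mol s-1 per m depth), `outflux`, `iterations`, `converged`.
#' @export
steady_perifusion <- function(mesh, flow, kin = kinetics_config(),
                              dset = diffusion_set(), glucose_in = 15,
                              oxygen_in = 0.200, tol = 1e-9, max_iter = 400L,
                              relax = 0.7, ops = NULL) {
  if (is.null(ops)) ops <- transport_operators(mesh, flow, dset)
  ft <- as.numeric(mesh$frac_tissue)
  vol <- ops$gluc$vol
  c_gluc <- rep(glucose_in, mesh$n_cells)
  c_oxy <- rep(oxygen_in, mesh$n_cells)
  Kg <- kin$gluc_consumption$c_half; Rg <- abs(kin$gluc_consumption$r_max)
  Ko <- kin$oxy_consumption$c_half; Ro <- abs(kin$oxy_consumption$r_max)
  converged <- FALSE
  it <- 0L
  # the necrosis cut is damped separately: an undamped fixed point can
  # flip cells between dead and alive indefinitely near the cut
  delta_s <- rep(1, mesh$n_cells)
  ch_prev <- Inf
  for (it in seq_len(max_iter)) {
    delta_s <- 0.5 * necrosis_factor(c_oxy, kin) + 0.5 * delta_s
    k_g <- Rg * delta_s / (c_gluc + Kg) * ft
    g_new <- as.numeric(Matrix::solve(
      Matrix::Diagonal(x = k_g) - ops$gluc$A, ops$gluc$b_unit * glucose_in))
    phi <- glucose_metabolic_factor(g_new, kin)
    k_o <- Ro * phi * delta_s / (c_oxy + Ko) * ft
    o_new <- as.numeric(Matrix::solve(
      Matrix::Diagonal(x = k_o) - ops$oxy$A, ops$oxy$b_unit * oxygen_in))
    g_new <- pmax(g_new, 0); o_new <- pmax(o_new, 0)
    ch <- max(max(abs(g_new - c_gluc)) / max(glucose_in, 1e-12),
              max(abs(o_new - c_oxy)) / max(oxygen_in, 1e-12))
    c_gluc <- relax * g_new + (1 - relax) * c_gluc
    c_oxy <- relax * o_new + (1 - relax) * c_oxy
    if (ch < tol) { converged <- TRUE; break }
    if (it %% 50L == 0L && ch > 0.5 * ch_prev) relax <- max(relax * 0.6, 0.05)
    if (it %% 50L == 0L) ch_prev <- ch
  }
  r_ins_local <- total_secretion_rate(c_gluc, 0, c_oxy, kin)   # per tissue volume
  src <- r_ins_local * ft
  c_ins <- as.numeric(Matrix::solve(-ops$ins$A, src))
  c_insL <- ifelse(ft > 0, c_ins + r_ins_local / kin$k_insL, 0)
  st <- new_species_fields(
    mesh, c_oxy, c_gluc, c_ins, c_insL,
    extra = list(secretion_total = sum(src * vol),
                 iterations = it, converged = converged,
                 glucose_in = glucose_in, oxygen_in = oxygen_in))
  st$outflux <- outflow_insulin_flux(st, flow, mesh)
  st
}

transport_operators <- function(mesh, flow, dset) {
  list(oxy = assemble_transport(mesh, flow, species_cell_diffusivity(mesh, dset, "oxy")),
       gluc = assemble_transport(mesh, flow, species_cell_diffusivity(mesh, dset, "gluc")),
       ins = assemble_transport(mesh, flow, species_cell_diffusivity(mesh, dset, "ins")),
       insL = assemble_transport(mesh, flow, species_cell_diffusivity(mesh, dset, "insL")))
}

#' Initial state for a transient perifusion run
#'
#' Steady solution of the full system at the protocol's t = 0 inflow values
#' (baseline glucose, incoming oxygen, zero inflow insulin); starting
#' transients from it removes numerical startup artifacts from the readout.
#'
#' @inheritParams steady_perifusion
#' @param prot A [protocol()].
#' @return A `species_fields` object.
#' @export
initial_state <- function(mesh, flow, kin, dset, prot, ops = NULL) {
  st <- steady_perifusion(mesh, flow, kin, dset,
                          glucose_in = glucose_inflow(0, prot),
                          oxygen_in = prot$oxygen_in, ops = ops)
  if (!st$converged)
    stop("steady initial state did not converge; residual change above tolerance",
         call. = FALSE)
  st
}

# vectorized semi-implicit consumption substeps (positivity preserving)
react_consume <- function(c_gluc, c_oxy, ft, kin, dt, n_sub = 3L) {
  Kg <- kin$gluc_consumption$c_half; Rg <- abs(kin$gluc_consumption$r_max)
  Ko <- kin$oxy_consumption$c_half; Ro <- abs(kin$oxy_consumption$r_max)
  h <- dt / n_sub
  for (s in seq_len(n_sub)) {
    delta <- necrosis_factor(c_oxy, kin)
    phi <- glucose_metabolic_factor(c_gluc, kin)
    c_oxy <- c_oxy / (1 + h * Ro * phi * delta / (c_oxy + Ko) * ft)
    c_gluc <- c_gluc / (1 + h * Rg * delta / (c_gluc + Kg) * ft)
  }
  list(c_gluc = c_gluc, c_oxy = c_oxy)
}

#' Transient simulation of a perifusion protocol
#'
#' Advances the four coupled species with an operator-split scheme: implicit
#' (backward Euler) transport for every species with the constant-matrix
#' factorization reused across steps, the linear local/released insulin
#' exchange solved implicitly as one coupled block (so insulin is conserved
#' between the compartments to machine precision), and the stiff
#' Michaelis-Menten consumption terms integrated with vectorized
#' semi-implicit substeps. First-phase secretion senses the local glucose
#' time-derivative of the previous accepted step (backward difference,
#' floored at zero). The step size is fixed at `dt_max` (default 0.5 s) so
#' inflow steps are never overstepped.
#'
#' @inheritParams initial_state
#' @param dt_max Time step (s), at most 0.5 when the protocol contains steps.
#' @param init Optional initial `species_fields` (default: [initial_state()]).
#' @param snapshot_times Times (s) at which full field snapshots are kept.
#' @param record_every Record the outflow trace every this many steps.
#' @return A `perifusion_result`: list with the outflow `trace` tibble
#'   (time_s, gluc_in_mM, pO2_in_mmHg, insulin_outflux_mol_per_s,
#'   insulin_out_conc_mM), optional `snapshots`, the final `state`, and
#'   solver `diagnostics` (negativity clip audit).
#' @export
simulate_perifusion <- function(mesh, flow, kin = kinetics_config(),
                                dset = diffusion_set(), prot = protocol(),
                                dt_max = 0.5, init = NULL,
                                snapshot_times = numeric(), record_every = 1L,
                                ops = NULL) {
  if (nrow(prot$steps) && dt_max > 0.5)
    stop("`dt_max` must be <= 0.5 s for protocols with inflow steps",
         call. = FALSE)
  if (is.null(ops)) ops <- transport_operators(mesh, flow, dset)
  if (is.null(init)) init <- initial_state(mesh, flow, kin, dset, prot, ops = ops)
  n <- mesh$n_cells
  ft <- as.numeric(mesh$frac_tissue)
  vol <- ops$gluc$vol
  dt <- dt_max
  nt <- ceiling(prot$duration / dt)
  I_n <- Matrix::Diagonal(n)
  lu_g <- Matrix::lu(I_n / dt - ops$gluc$A)
  lu_o <- Matrix::lu(I_n / dt - ops$oxy$A)
  Kd <- Matrix::Diagonal(x = kin$k_insL * ft)
  pairM <- rbind(
    cbind(I_n / dt - ops$insL$A + Kd, -Kd),
    cbind(-Kd, I_n / dt - ops$ins$A + Kd))
  lu_pair <- Matrix::lu(pairM)

  c_gluc <- init$c_gluc; c_oxy <- init$c_oxy
  c_ins <- init$c_ins; c_insL <- init$c_insL
  dcdt <- rep(0, n)
  n_rec <- base::length(seq.int(1L, nt, by = record_every))
  trace <- matrix(NA_real_, n_rec, 5L)
  rec <- 0L
  clip_count <- 0L; clip_max <- 0
  snapshots <- list()
  snap_steps <- if (base::length(snapshot_times))
    pmin(pmax(round(snapshot_times / dt), 1L), nt) else integer()
  oxy_b <- ops$oxy$b_unit * prot$oxygen_in
  inflow_area <- sum(flow$u[1L, ] * mesh$dy)
  cum <- c(gluc_in = 0, gluc_out = 0, oxy_in = 0, oxy_out = 0,
           ins_out = 0, insL_out = 0, secreted = 0)
  oc <- ops$gluc$outlet_cells
  for (s in seq_len(nt)) {
    t_new <- s * dt
    g_in <- glucose_inflow(t_new, prot)
    g_prev <- c_gluc
    c_gluc <- as.numeric(Matrix::solve(lu_g, g_prev / dt + ops$gluc$b_unit * g_in))
    c_oxy <- as.numeric(Matrix::solve(lu_o, c_oxy / dt + oxy_b))
    r_ins <- total_secretion_rate(c_gluc, dcdt, c_oxy, kin) * ft
    pair_sol <- as.numeric(Matrix::solve(
      lu_pair, c(c_insL / dt + r_ins, c_ins / dt)))
    c_insL <- pair_sol[1:n]; c_ins <- pair_sol[n + 1:n]
    cum <- cum + dt * c(
      g_in * inflow_area,
      sum(ops$gluc$outflux_w * c_gluc[oc]),
      prot$oxygen_in * inflow_area,
      sum(ops$oxy$outflux_w * c_oxy[oc]),
      sum(ops$ins$outflux_w * c_ins[oc]),
      sum(ops$insL$outflux_w * c_insL[oc]),
      sum(r_ins * vol))
    reac <- react_consume(c_gluc, c_oxy, ft, kin, dt)
    c_gluc <- reac$c_gluc; c_oxy <- reac$c_oxy
    dcdt <- (c_gluc - g_prev) / dt
    neg <- c(c_gluc[c_gluc < 0], c_oxy[c_oxy < 0], c_ins[c_ins < 0],
             c_insL[c_insL < 0])
    if (base::length(neg)) {
      clip_count <- clip_count + base::length(neg)
      clip_max <- max(clip_max, -min(neg))
      c_gluc <- pmax(c_gluc, 0); c_oxy <- pmax(c_oxy, 0)
      c_ins <- pmax(c_ins, 0); c_insL <- pmax(c_insL, 0)
    }
    if ((s - 1L) %% record_every == 0L) {
      rec <- rec + 1L
      outflux <- sum(ops$ins$outflux_w * c_ins[ops$ins$outlet_cells])
      trace[rec, ] <- c(t_new, g_in, conc_to_po2(prot$oxygen_in, kin),
                        outflux, outflux / max(flow$flux_out, 1e-300))
    }
    if (s %in% snap_steps) {
      snapshots[[base::length(snapshots) + 1L]] <- new_species_fields(
        mesh, c_oxy, c_gluc, c_ins, c_insL, time = t_new)
    }
  }
  trace <- trace[seq_len(rec), , drop = FALSE]
  colnames(trace) <- c("time_s", "gluc_in_mM", "pO2_in_mmHg",
                       "insulin_outflux_mol_per_s", "insulin_out_conc_mM")
  structure(list(
    trace = tibble::as_tibble(as.data.frame(trace)),
    snapshots = snapshots,
    state = new_species_fields(mesh, c_oxy, c_gluc, c_ins, c_insL,
                               time = nt * dt),
    init = init,
    diagnostics = list(dt = dt, n_steps = nt, clip_count = clip_count,
                       clip_max = clip_max, cumulative = cum),
    protocol = prot
  ), class = "perifusion_result")
}

#' Domain totals of a state (mol per m depth)
#'
#' @param state A `species_fields` object.
#' @param mesh The matching mesh.
#' @return Named vector of species totals.
#' @export
domain_totals <- function(state, mesh) {
  vol <- as.numeric(outer(mesh$dx, mesh$dy))
  c(oxy = sum(state$c_oxy * vol), gluc = sum(state$c_gluc * vol),
    ins = sum(state$c_ins * vol), insL = sum(state$c_insL * vol))
}
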