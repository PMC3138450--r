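# Spherically symmetric reduced model: one islet (optionally encapsulated)
# surrounded by a shell of stagnant medium with Dirichlet far-field
# concentrations. Shares every rate law with the 2D solver and serves as a
# fast surrogate and as a cross-solver oracle.

radial_cell_diffusivity <- function(radial, dset, species) {
  if (species == "insL") return(rep(dset$insL, radial$n_cells))
  d <- dset[[species]]
  out <- numeric(radial$n_cells)
  out[radial$subdomain == "tissue"] <- d[["tissue"]]
  out[radial$subdomain == "capsule"] <- d[["capsule"]]
  out[radial$subdomain == "medium"] <- d[["water"]]
  out
}

# dc/dt = A c + b_unit * c_far (pure diffusion, Dirichlet outer boundary,
# no-flux at the center)
assemble_radial <- function(radial, D_cells) {
  n <- radial$n_cells
  r <- radial$r; rc <- radial$rc; vol <- radial$vol
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (n > 1L) {
    k <- 1:(n - 1L)
    rf <- r[k + 1L]
    g <- 4 * pi * rf^2 / ((rf - rc[k]) / D_cells[k] + (rc[k + 1L] - rf) / D_cells[k + 1L])
    ii <- c(k, k, k + 1L, k + 1L)
    jj <- c(k, k + 1L, k + 1L, k)
    xx <- c(-g / vol[k], g / vol[k], -g / vol[k + 1L], g / vol[k + 1L])
  }
  g_out <- 4 * pi * radial$r_outer^2 * D_cells[n] / (radial$r_outer - rc[n])
  ii <- c(ii, n); jj <- c(jj, n); xx <- c(xx, -g_out / vol[n])
  b_unit <- numeric(n); b_unit[n] <- g_out / vol[n]
  list(A = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)),
       b_unit = b_unit, vol = vol)
}

radial_operators <- function(radial, dset) {
  list(oxy = assemble_radial(radial, radial_cell_diffusivity(radial, dset, "oxy")),
       gluc = assemble_radial(radial, radial_cell_diffusivity(radial, dset, "gluc")),
       ins = assemble_radial(radial, radial_cell_diffusivity(radial, dset, "ins")),
       insL = assemble_radial(radial, radial_cell_diffusivity(radial, dset, "insL")))
}

#' Steady state of the spherically symmetric reduced model
#'
#' Solves the steady reaction-diffusion system (no convection) for a single
#' islet with Dirichlet far-field concentrations at the outer radius, using
#' the same quasi-linearized fixed-point iteration as [steady_perifusion()].
#'
#' @param radial A [radial_grid()] mesh.
#' @param kin A [kinetics_config()].
#' @param dset A [diffusion_set()].
#' @param glucose_far,oxygen_far Far-field concentrations (mol m-3).
#' @param oxygen_source Optional override of the oxygen reaction: a
#'   `function(c_oxy, c_gluc)` returning the volumetric rate in tissue
#'   (mol m-3 s-1, signed). Used for validation against closed-form
#'   zeroth-order consumption profiles.
#' @param tol,max_iter,relax Fixed-point controls.
#' @return A `radial_fields` object with radial profiles, `secretion_total`
#'   (mol s-1 for the whole sphere) and convergence diagnostics.
#' @export
steady_radial <- function(radial, kin = kinetics_config(),
                          dset = diffusion_set(), glucose_far = 15,
                          oxygen_far = 0.200, oxygen_source = NULL,
                          tol = 1e-10, max_iter = 500L, relax = 0.7) {
  ops <- radial_operators(radial, dset)
  ft <- as.numeric(radial$subdomain == "tissue")
  n <- radial$n_cells
  c_gluc <- rep(glucose_far, n); c_oxy <- rep(oxygen_far, n)
  Kg <- kin$gluc_consumption$c_half; Rg <- abs(kin$gluc_consumption$r_max)
  Ko <- kin$oxy_consumption$c_half; Ro <- abs(kin$oxy_consumption$r_max)
  converged <- FALSE; it <- 0L
  delta_s <- rep(1, n)     # damped necrosis field, as in steady_perifusion()
  ch_prev <- Inf
  for (it in seq_len(max_iter)) {
    delta_s <- 0.5 * necrosis_factor(c_oxy, kin) + 0.5 * delta_s
    k_g <- Rg * delta_s / (c_gluc + Kg) * ft
    g_new <- as.numeric(Matrix::solve(
      Matrix::Diagonal(x = k_g) - ops$gluc$A, ops$gluc$b_unit * glucose_far))
    if (is.null(oxygen_source)) {
      phi <- glucose_metabolic_factor(g_new, kin)
      k_o <- Ro * phi * delta_s / (c_oxy + Ko) * ft
      o_new <- as.numeric(Matrix::solve(
        Matrix::Diagonal(x = k_o) - ops$oxy$A, ops$oxy$b_unit * oxygen_far))
    } else {
      src <- oxygen_source(c_oxy, g_new) * ft
      o_new <- as.numeric(Matrix::solve(-ops$oxy$A,
                                        ops$oxy$b_unit * oxygen_far + src))
    }
    g_new <- pmax(g_new, 0); o_new <- pmax(o_new, 0)
    ch <- max(max(abs(g_new - c_gluc)) / max(glucose_far, 1e-12),
              max(abs(o_new - c_oxy)) / max(oxygen_far, 1e-12))
    c_gluc <- relax * g_new + (1 - relax) * c_gluc
    c_oxy <- relax * o_new + (1 - relax) * c_oxy
    if (ch < tol) { converged <- TRUE; break }
    if (it %% 50L == 0L && ch > 0.5 * ch_prev) relax <- max(relax * 0.6, 0.05)
    if (it %% 50L == 0L) ch_prev <- ch
  }
  r_ins_local <- total_secretion_rate(c_gluc, 0, c_oxy, kin)
  src <- r_ins_local * ft
  c_ins <- as.numeric(Matrix::solve(-ops$ins$A, src))
  c_insL <- ifelse(ft > 0, c_ins + r_ins_local / kin$k_insL, 0)
  structure(list(
    c_oxy = c_oxy, c_gluc = c_gluc, c_ins = c_ins, c_insL = c_insL,
    radial = radial, secretion_total = sum(src * radial$vol),
    iterations = it, converged = converged,
    glucose_far = glucose_far, oxygen_far = oxygen_far
  ), class = "radial_fields")
}

#' Transient simulation of the spherically symmetric reduced model
#'
#' Same operator-split time stepping as [simulate_perifusion()], in spherical
#' coordinates without convection. The far-field glucose follows the
#' protocol's smoothed-step schedule; far-field oxygen is the protocol's
#' incoming value; far-field insulin is zero.
#'
#' @inheritParams steady_radial
#' @param prot A [protocol()] interpreted as the far-field schedule.
#' @param dt_max Time step (s).
#' @param init Optional initial `radial_fields` (default: steady state at the
#'   t = 0 far-field values).
#' @return A `radial_result` with a `trace` tibble (time_s, gluc_far_mM,
#'   secretion_mol_per_s, insL_total_mol, ins_total_mol) and the final state.
#' @export
simulate_radial <- function(radial, kin = kinetics_config(),
                            dset = diffusion_set(), prot = protocol(),
                            dt_max = 0.5, init = NULL) {
  ops <- radial_operators(radial, dset)
  n <- radial$n_cells
  ft <- as.numeric(radial$subdomain == "tissue")
  vol <- radial$vol
  if (is.null(init))
    init <- steady_radial(radial, kin, dset,
                          glucose_far = glucose_inflow(0, prot),
                          oxygen_far = prot$oxygen_in)
  dt <- dt_max
  nt <- ceiling(prot$duration / dt)
  I_n <- Matrix::Diagonal(n)
  lu_g <- Matrix::lu(I_n / dt - ops$gluc$A)
  lu_o <- Matrix::lu(I_n / dt - ops$oxy$A)
  Kd <- Matrix::Diagonal(x = kin$k_insL * ft)
  lu_pair <- Matrix::lu(rbind(
    cbind(I_n / dt - ops$insL$A + Kd, -Kd),
    cbind(-Kd, I_n / dt - ops$ins$A + Kd)))
  c_gluc <- init$c_gluc; c_oxy <- init$c_oxy
  c_ins <- init$c_ins; c_insL <- init$c_insL
  dcdt <- rep(0, n)
  trace <- matrix(NA_real_, nt, 5L)
  for (s in seq_len(nt)) {
    t_new <- s * dt
    g_far <- glucose_inflow(t_new, prot)
    g_prev <- c_gluc
    c_gluc <- as.numeric(Matrix::solve(lu_g, g_prev / dt + ops$gluc$b_unit * g_far))
    c_oxy <- as.numeric(Matrix::solve(
      lu_o, c_oxy / dt + ops$oxy$b_unit * prot$oxygen_in))
    r_ins <- total_secretion_rate(c_gluc, dcdt, c_oxy, kin) * ft
    pair_sol <- as.numeric(Matrix::solve(
      lu_pair, c(c_insL / dt + r_ins, c_ins / dt)))
    c_insL <- pair_sol[1:n]; c_ins <- pair_sol[n + 1:n]
    reac <- react_consume(c_gluc, c_oxy, ft, kin, dt)
    c_gluc <- reac$c_gluc; c_oxy <- reac$c_oxy
    dcdt <- (c_gluc - g_prev) / dt
    r_now <- total_secretion_rate(c_gluc, dcdt, c_oxy, kin) * ft
    trace[s, ] <- c(t_new, g_far, sum(r_now * vol),
                    sum(c_insL * vol * ft), sum(c_ins * vol))
  }
  colnames(trace) <- c("time_s", "gluc_far_mM", "secretion_mol_per_s",
                       "insL_total_mol", "ins_total_mol")
  structure(list(
    trace = tibble::as_tibble(as.data.frame(trace)),
    state = structure(list(c_oxy = c_oxy, c_gluc = c_gluc, c_ins = c_ins,
                           c_insL = c_insL, radial = radial),
                      class = "radial_fields"),
    protocol = prot
  ), class = "radial_result")
}
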