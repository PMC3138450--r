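#' Flow parameters of the perifusing medium
#'
#' Aqueous medium at body temperature driven at a 0.1 mL/min-scale flow:
#' density 993 kg m-3, viscosity 0.7e-3 Pa s, inflow peak speed 1e-4 m s-1.
#'
#' @param density Fluid density (kg m-3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param v_in Peak inflow speed of the parabolic inlet profile (m s-1).
#' @param body_force Volume force (N m-3; default 0).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(density = 993, viscosity = 0.7e-3, v_in = 1e-4,
                        body_force = 0) {
  if (density <= 0 || viscosity <= 0 || v_in <= 0)
    stop("`density`, `viscosity` and `v_in` must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity, v_in = v_in,
                 body_force = body_force), class = "flow_params")
}

#' Parabolic inlet velocity profile
#'
#' `4 v_in s (1 - s)` along the inlet: zero at the walls, `v_in` at the
#' midline, mean `(2/3) v_in`.
#'
#' @param s Normalized boundary coordinate(s) in `[0, 1]`.
#' @param params A [flow_params()].
#' @return Inflow speed(s), m s-1.
#' @export
inlet_profile <- function(s, params = flow_params()) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("`s` must lie in [0, 1]", call. = FALSE)
  4 * params$v_in * s * (1 - s)
}

# linear indices on the staggered (MAC) grid
mac_indices <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  nu <- (nx + 1L) * ny; nv <- nx * (ny + 1L); np <- nx * ny
  list(
    nu = nu, nv = nv, np = np, n = nu + nv + np,
    iu = function(i, j) (j - 1L) * (nx + 1L) + i,
    iv = function(i, j) nu + (j - 1L) * nx + i,
    ip = function(i, j) nu + nv + (j - 1L) * nx + i
  )
}

#' Solve the steady creeping flow in the chamber
#'
#' Steady incompressible flow on a staggered (marker-and-cell) grid:
#' momentum balance with no-slip on the walls and on all solid (tissue,
#' capsule) cells, the parabolic inlet profile, and a zero-pressure,
#' no-viscous-stress outlet. At the operating Reynolds number (~0.6) the
#' default is the Stokes system; `method = "navier-stokes"` adds the
#' convective term by Picard iteration and gives near-identical results.
#' Face velocities in solid subdomains are exactly zero by construction and
#' the discrete divergence of every fluid cell vanishes to solver precision.
#'
#' @param mesh A [mesh_geometry()] result.
#' @param params A [flow_params()].
#' @param method `"stokes"` (default) or `"navier-stokes"`.
#' @param picard_tol,picard_max Convergence control of the Picard loop.
#' @return An object of class `velocity_field` with face velocities `u`
#'   ((nx+1) x ny) and `v` (nx x (ny+1)), pressure `p`, cell-center
#'   velocities `uc`, `vc`, Reynolds number and flux/divergence diagnostics.
#' @export
solve_steady_flow <- function(mesh, params = flow_params(),
                              method = c("stokes", "navier-stokes"),
                              picard_tol = 1e-10, picard_max = 25L) {
  method <- match.arg(method)
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx; dy <- mesh$dy; xc <- mesh$xc; yc <- mesh$yc
  eta <- params$viscosity
  idx <- mac_indices(mesh)
  iu <- idx$iu; iv <- idx$iv; ip <- idx$ip

  cell_solid <- mesh$frac_lumen < 0.5
  u_solid <- matrix(FALSE, nx + 1L, ny)
  u_solid[2:nx, ] <- cell_solid[1:(nx - 1L), ] | cell_solid[2:nx, ]
  v_solid <- matrix(FALSE, nx, ny + 1L)
  if (ny > 1L) v_solid[, 2:ny] <- cell_solid[, 1:(ny - 1L)] | cell_solid[, 2:ny]

  est <- 8L * idx$n
  ti <- integer(est); tj <- integer(est); tx <- numeric(est); nz <- 0L
  b <- numeric(idx$n)
  add <- function(r, c, v) {
    k <- nz + seq_along(v)
    ti[k] <<- r; tj[k] <<- c; tx[k] <<- v; nz <<- nz + base::length(v)
  }

  u_inlet <- inlet_profile(yc / mesh$y[base::length(mesh$y)], params)

  # --- u momentum -----------------------------------------------------------
  for (j in seq_len(ny)) {
    # vertical neighbor distances for u-faces in row j
    d_n <- if (j < ny) yc[j + 1] - yc[j] else dy[j] / 2   # to wall ghost above
    d_s <- if (j > 1L) yc[j] - yc[j - 1] else dy[j] / 2
    for (i in seq_len(nx + 1L)) {
      r <- iu(i, j)
      if (i == 1L) { add(r, r, 1); b[r] <- u_inlet[j]; next }
      if (u_solid[i, j]) { add(r, r, 1); next }
      dxu <- if (i <= nx) xc[i] - xc[i - 1] else dx[nx] / 2
      diag_val <- 0
      # east viscous flux
      if (i <= nx) {
        ce <- eta * dy[j] / dx[i]
        add(r, iu(i + 1L, j), -ce); diag_val <- diag_val + ce
      }                                        # outlet face: du/dx = 0 ghost
      # west viscous flux
      cw <- eta * dy[j] / dx[i - 1L]
      add(r, iu(i - 1L, j), -cw); diag_val <- diag_val + cw
      # north / south viscous fluxes (wall ghost: u = 0 at dy/2)
      cn <- eta * dxu / d_n
      if (j < ny) add(r, iu(i, j + 1L), -cn)
      diag_val <- diag_val + cn
      cs <- eta * dxu / d_s
      if (j > 1L) add(r, iu(i, j - 1L), -cs)
      diag_val <- diag_val + cs
      add(r, r, diag_val)
      # pressure gradient
      if (i <= nx) {
        add(r, ip(i, j), dy[j]); add(r, ip(i - 1L, j), -dy[j])
      } else {
        add(r, ip(nx, j), -dy[j])              # outlet ghost pressure = 0
      }
      b[r] <- b[r] + params$body_force * dxu * dy[j]
    }
  }

  # --- v momentum -----------------------------------------------------------
  for (j in seq_len(ny + 1L)) {
    for (i in seq_len(nx)) {
      r <- iv(i, j)
      if (j == 1L || j == ny + 1L || v_solid[i, j]) { add(r, r, 1); next }
      dyv <- yc[j] - yc[j - 1]
      diag_val <- 0
      # east / west viscous fluxes (inlet ghost v = 0, outlet dv/dx = 0)
      if (i < nx) {
        ce <- eta * dyv / (xc[i + 1] - xc[i])
        add(r, iv(i + 1L, j), -ce); diag_val <- diag_val + ce
      }
      if (i > 1L) {
        cw <- eta * dyv / (xc[i] - xc[i - 1])
        add(r, iv(i - 1L, j), -cw); diag_val <- diag_val + cw
      } else {
        diag_val <- diag_val + eta * dyv / (dx[1] / 2)
      }
      # north / south
      cn <- eta * dx[i] / dy[j]
      if (j < ny) add(r, iv(i, j + 1L), -cn)   # j = ny: wall face above is 0
      diag_val <- diag_val + cn
      cs <- eta * dx[i] / dy[j - 1L]
      if (j > 2L) add(r, iv(i, j - 1L), -cs)   # j = 2: wall face below is 0
      diag_val <- diag_val + cs
      add(r, r, diag_val)
      add(r, ip(i, j), dx[i]); add(r, ip(i, j - 1L), -dx[i])
    }
  }

  # --- continuity -----------------------------------------------------------
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    r <- ip(i, j)
    if (cell_solid[i, j]) { add(r, r, 1); next }
    add(r, iu(i + 1L, j), dy[j]); add(r, iu(i, j), -dy[j])
    add(r, iv(i, j + 1L), dx[i]); add(r, iv(i, j), -dx[i])
  }

  A0 <- Matrix::sparseMatrix(i = ti[1:nz], j = tj[1:nz], x = tx[1:nz],
                             dims = c(idx$n, idx$n))
  sol <- as.numeric(Matrix::solve(A0, b))

  if (method == "navier-stokes") {
    rho <- params$density
    for (it in seq_len(picard_max)) {
      u_m <- matrix(sol[1:idx$nu], nx + 1L, ny)
      v_m <- matrix(sol[idx$nu + 1:idx$nv], nx, ny + 1L)
      ci <- integer(0); cj <- integer(0); cx <- numeric(0)
      cadd <- function(r, c, v) {
        ci <<- c(ci, r); cj <<- c(cj, c); cx <<- c(cx, v)
      }
      # upwind convection for u momentum (interior fluid faces only)
      for (j in seq_len(ny)) for (i in 2:nx) {
        if (u_solid[i, j]) next
        r <- iu(i, j)
        dxu <- xc[i] - xc[i - 1]
        ue <- 0.5 * (u_m[i, j] + u_m[i + 1L, j])
        uw <- 0.5 * (u_m[i - 1L, j] + u_m[i, j])
        vn <- 0.5 * (v_m[i - 1L, j + 1L] + v_m[i, j + 1L])
        vs <- 0.5 * (v_m[i - 1L, j] + v_m[i, j])
        fe <- rho * ue * dy[j]; fw <- rho * uw * dy[j]
        fn <- rho * vn * dxu;   fs <- rho * vs * dxu
        cadd(r, if (fe > 0) iu(i, j) else iu(i + 1L, j), fe)
        cadd(r, if (fw > 0) iu(i - 1L, j) else iu(i, j), -fw)
        if (j < ny) cadd(r, if (fn > 0) iu(i, j) else iu(i, j + 1L), fn)
        else if (fn > 0) cadd(r, iu(i, j), fn)
        if (j > 1L) cadd(r, if (fs > 0) iu(i, j - 1L) else iu(i, j), -fs)
        else if (fs < 0) cadd(r, iu(i, j), -fs)
      }
      # upwind convection for v momentum
      for (j in 2:ny) for (i in seq_len(nx)) {
        if (v_solid[i, j]) next
        r <- iv(i, j)
        dyv <- yc[j] - yc[j - 1]
        ue <- 0.5 * (u_m[i + 1L, j - 1L] + u_m[i + 1L, j])
        uw <- 0.5 * (u_m[i, j - 1L] + u_m[i, j])
        vn <- 0.5 * (v_m[i, j] + v_m[i, j + 1L])
        vs <- 0.5 * (v_m[i, j - 1L] + v_m[i, j])
        fe <- rho * ue * dyv; fw <- rho * uw * dyv
        fn <- rho * vn * dx[i]; fs <- rho * vs * dx[i]
        if (i < nx) cadd(r, if (fe > 0) iv(i, j) else iv(i + 1L, j), fe)
        else if (fe > 0) cadd(r, iv(i, j), fe)
        if (i > 1L) cadd(r, if (fw > 0) iv(i - 1L, j) else iv(i, j), -fw)
        else if (fw < 0) cadd(r, iv(i, j), -fw)
        cadd(r, if (fn > 0) iv(i, j) else iv(i, j + 1L), fn)
        cadd(r, if (fs > 0) iv(i, j - 1L) else iv(i, j), -fs)
      }
      A <- A0
      if (base::length(ci)) {
        A <- A0 + Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                                       dims = c(idx$n, idx$n))
      }
      sol_new <- as.numeric(Matrix::solve(A, b))
      delta <- max(abs(sol_new - sol)) / max(abs(sol_new), 1e-300)
      sol <- sol_new
      if (delta < picard_tol) break
    }
  }

  u <- matrix(sol[1:idx$nu], nx + 1L, ny)
  v <- matrix(sol[idx$nu + 1:idx$nv], nx, ny + 1L)
  p <- matrix(sol[idx$nu + idx$nv + 1:idx$np], nx, ny)
  u[u_solid] <- 0; v[v_solid] <- 0
  div <- (u[-1, , drop = FALSE] - u[-(nx + 1L), , drop = FALSE]) * rep(dy, each = nx) +
    (v[, -1, drop = FALSE] - v[, -(ny + 1L), drop = FALSE]) * rep(dx, ny)
  flux_in <- sum(u[1, ] * dy)
  flux_out <- sum(u[nx + 1L, ] * dy)
  structure(list(
    u = u, v = v, p = p,
    uc = (u[-1, , drop = FALSE] + u[-(nx + 1L), , drop = FALSE]) / 2,
    vc = (v[, -1, drop = FALSE] + v[, -(ny + 1L), drop = FALSE]) / 2,
    cell_solid = cell_solid, u_solid = u_solid, v_solid = v_solid,
    flux_in = flux_in, flux_out = flux_out,
    div_max = max(abs(div)), div_scale = abs(flux_in),
    reynolds = params$density * params$v_in *
      mesh$y[base::length(mesh$y)] / params$viscosity,
    params = params, method = method
  ), class = "velocity_field")
}
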