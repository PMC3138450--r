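# broom-style tidiers, autoplot methods and print methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hill fit
#'
#' @param x A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (term, estimate, fixed).
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_max", "c_half", "n"),
    estimate = c(x$r_max, x$c_half, x$n),
    fixed = c(FALSE, FALSE, x$restricted))
}

#' One-row summary of a Hill fit
#'
#' @inheritParams tidy.hill_fit
#' @return Tibble with the estimates, residual norm and fit metadata.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r_max = x$r_max, c_half = x$c_half, n = x$n,
                 restricted = x$restricted, rss = x$rss,
                 residual_norm = x$residual_norm, n_points = x$n_points)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit%s: r_max = %.4g, c_half = %.4g, n = %.3g (RSS %.3g, %d points)\n",
    if (x$restricted) " (n fixed)" else "", x$r_max, x$c_half, x$n, x$rss,
    x$n_points))
  invisible(x)
}

#' Tidy the outflow trace of a perifusion run
#'
#' @param x A `perifusion_result`.
#' @param ... Unused.
#' @return The trace tibble.
#' @method tidy perifusion_result
#' @export
tidy.perifusion_result <- function(x, ...) x$trace

#' One-row summary of a perifusion run
#'
#' @inheritParams tidy.perifusion_result
#' @return Tibble with step count, step size, cumulative secretion and the
#'   negativity-clip audit.
#' @method glance perifusion_result
#' @export
glance.perifusion_result <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n_steps = d$n_steps, dt_s = d$dt, duration_s = x$protocol$duration,
    secreted_mol = unname(d$cumulative["secreted"]),
    insulin_out_mol = unname(d$cumulative["ins_out"]),
    clip_count = d$clip_count, clip_max = d$clip_max)
}

#' @export
print.perifusion_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Perifusion run: %d steps of %.3g s (%.1f min); secreted %.3g mol/m depth, %.3g mol left through the outlet\n",
    g$n_steps, g$dt_s, g$duration_s / 60, g$secreted_mol, g$insulin_out_mol))
  invisible(x)
}

#' Plot the insulin outflow trace
#'
#' Outflow insulin flux versus time with the inflow glucose schedule on a
#' scaled secondary axis.
#'
#' @param object A `perifusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perifusion_result
#' @export
autoplot.perifusion_result <- function(object, ...) {
  tr <- object$trace
  scale <- max(tr$insulin_outflux_mol_per_s) /
    max(max(tr$gluc_in_mM), 1e-300)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s / 60)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gluc_in_mM * scale),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$insulin_outflux_mol_per_s),
                       colour = "#B2182B") +
    ggplot2::scale_y_continuous(
      name = "insulin outflow (mol/s per m depth)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "inflow glucose (mM)")) +
    ggplot2::labs(x = "time (min)") +
    ggplot2::theme_minimal()
}

#' Plot an oxygen sweep
#'
#' Fraction of the normoxic second-phase secretion versus incoming pO2, with
#' the interpolated half-maximal pressure marked.
#'
#' @param object An `oxygen_sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxygen_sweep_result
#' @export
autoplot.oxygen_sweep_result <- function(object, ...) {
  hm <- attr(object, "half_max_po2")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$po2_mmHg, y = .data$fraction)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::geom_point(colour = "#B2182B") +
    ggplot2::labs(x = "incoming pO2 (mmHg)",
                  y = "fraction of normoxic secretion") +
    ggplot2::theme_minimal()
  if (is.finite(hm))
    p <- p + ggplot2::geom_vline(xintercept = hm, linetype = "dotted")
  p
}

#' Plot a Hill fit with its data
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble::tibble(conc = seq(0, max(object$data$conc), length.out = 200))
  grid$resp <- object$r_max * grid$conc^object$n /
    (grid$conc^object$n + object$c_half^object$n)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$resp)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166AC") +
    ggplot2::labs(x = "concentration (mM)", y = "response") +
    ggplot2::theme_minimal()
}

#' Plot radial steady-state profiles
#'
#' Oxygen and glucose concentration profiles of the spherically symmetric
#' reduced model.
#'
#' @param object A `radial_fields` object from [steady_radial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radial_fields
#' @export
autoplot.radial_fields <- function(object, ...) {
  rad <- object$radial
  tbl <- tibble::tibble(
    r_um = rep(rad$rc * 1e6, 2L),
    species = rep(c("oxygen", "glucose"), each = rad$n_cells),
    value = c(object$c_oxy / max(object$c_oxy),
              object$c_gluc / max(object$c_gluc)))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$r_um, y = .data$value,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = rad$islet_radius * 1e6,
                        linetype = "dotted") +
    ggplot2::labs(x = "radius (um)", y = "concentration / far-field") +
    ggplot2::theme_minimal()
}

#' @export
print.oxygen_sweep_result <- function(x, ...) {
  cat(sprintf("Oxygen sweep (%g mM glucose): half-maximal incoming pO2 %.1f mmHg\n",
              attr(x, "glucose_mM"), attr(x, "half_max_po2")))
  NextMethod()
}

#' @export
print.encapsulation_comparison <- function(x, ...) {
  cat(sprintf("Free vs encapsulated islets at %g mM glucose (pO2 %g / %g mmHg)\n",
              x$glucose_mM, x$po2_mmHg[1], x$po2_mmHg[2]))
  print(x$ratios)
  invisible(x)
}

#' @importFrom rlang .data
NULL
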