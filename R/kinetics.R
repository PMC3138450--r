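#' Hill rate-law parameters
#'
#' Container for the three parameters of the generalized Hill (sigmoid)
#' rate law `r_max * c^n / (c^n + c_half^n)`, the common functional form for
#' all consumption and secretion kinetics in this model. With `n = 1` it
#' reduces to Michaelis-Menten kinetics.
#'
#' @param r_max Maximum rate (mol m-3 s-1; signed, negative for consumption;
#'   use 1 for a dimensionless modulating fraction).
#' @param c_half Concentration (or rate, for gradient-sensing terms) of
#'   half-maximal response; must be positive.
#' @param n Hill slope (dimensionless, positive).
#' @return An object of class `hill_params`.
#' @examples
#' p <- hill_params(r_max = 3e-5, c_half = 7, n = 2.5)
#' hill(7, p) # half-maximal
#' @export
hill_params <- function(r_max, c_half, n) {
  if (!is.numeric(r_max) || length(r_max) != 1L || !is.finite(r_max))
    stop("`r_max` must be a single finite number", call. = FALSE)
  if (!is.numeric(c_half) || length(c_half) != 1L || !is.finite(c_half) || c_half <= 0)
    stop("`c_half` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("`n` must be a single positive number", call. = FALSE)
  structure(list(r_max = r_max, c_half = c_half, n = n), class = "hill_params")
}

#' Evaluate the Hill rate law
#'
#' Computes `r_max * c^n / (c^n + c_half^n)`. The function is 0 at `c = 0`,
#' exactly `r_max / 2` at `c = c_half`, and saturates at `r_max` for large
#' `c`. Small negative inputs (numerical undershoot from a transport solver)
#' are clipped to zero.
#'
#' @param c Nonnegative concentration(s), vectorized.
#' @param p A [hill_params()] object.
#' @return Rate(s), same length as `c`; sign follows `p$r_max`.
#' @export
hill <- function(c, p) {
  if (!inherits(p, "hill_params")) stop("`p` must be a `hill_params` object", call. = FALSE)
  if (!is.numeric(c) || any(!is.finite(c))) stop("`c` must be finite numeric", call. = FALSE)
  c <- pmax(c, 0)
  p$r_max * hill_fraction(c, p$c_half, p$n)
}

# dimensionless saturation fraction c^n/(c^n + c_half^n), numerically safe at 0
hill_fraction <- function(c, c_half, n) {
  c <- pmax(c, 0)
  # work with (c/c_half)^n to avoid overflow for large n or c
  x <- (c / c_half)^n
  x / (x + 1)
}

#' Smoothed Heaviside step
#'
#' Quintic smoothstep ramp used for the necrosis cut-off and for smoothed
#' inflow glucose staircases: 0 for `x <= -scale`, 1 for `x >= scale`, and a
#' polynomial ramp with continuous first derivative and no overshoot in
#' between; `smoothed_step(0, s) == 0.5`.
#'
#' @param x Signed argument(s), vectorized.
#' @param scale Half-width of the ramp (positive).
#' @return Value(s) in `[0, 1]`.
#' @export
smoothed_step <- function(x, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
  t <- pmin(pmax((x + scale) / (2 * scale), 0), 1)
  t * t * t * (t * (6 * t - 15) + 10)
}

#' Kinetic parameter set for the islet secretion model
#'
#' Assembles all cellular-level rate-law constants with defaults equal to the
#' model's calibrated values: Michaelis-Menten oxygen consumption
#' (`r_max = -0.034 mol m-3 s-1`, half-max 1 uM) modulated by glucose via a
#' metabolic-demand factor; Michaelis-Menten glucose consumption
#' (`-0.028 mol m-3 s-1`, half-max 10 uM); second-phase insulin secretion as a
#' Hill function of local glucose (n = 2.5, half-max 7 mM,
#' `3e-5 mol m-3 s-1`); first-phase secretion as a Hill function of the local
#' glucose time-derivative (n = 2, half-max 0.03 mM/s, `21e-5 mol m-3 s-1`)
#' shaped by a bump centered at 5 mM glucose; abrupt oxygen limitation of
#' secretion (n = 3, half-max 3 uM); a necrosis cut-off below 0.1 uM oxygen;
#' and first-order release from the cell-local insulin compartment
#' (`k_insL = 0.003 s-1`, half-life about 4 min).
#'
#' Concentrations are in mol m-3 (numerically identical to mM); partial
#' oxygen pressures convert linearly at 700 mmHg per mol m-3 (0.200 mol m-3 is
#' about 140 mmHg).
#'
#' @param oxy_consumption,gluc_consumption,ins_phase2,ins_phase1,ins_oxy_mod
#'   [hill_params()] objects for the individual rate laws.
#' @param phi_base,phi_metab Base and metabolic fractions of the oxygen
#'   consumption rate (defaults 0.5 each; they sum to 1).
#' @param phi_scale Scale factor of the glucose-modulation of oxygen
#'   consumption, chosen so the modulated rate at 3 mM glucose equals the
#'   unmodulated base rate (default 1.8).
#' @param c_crit_oxy Critical oxygen concentration below which tissue is
#'   treated as necrotic (mol m-3; default 1e-4).
#' @param step_scale Half-width of the smoothed necrosis step (mol m-3).
#' @param k_insL First-order release rate of the local insulin compartment
#'   (s-1).
#' @param c_mid_sigma Glucose concentration of maximal first-phase
#'   (gradient) sensitivity (mol m-3; default 5).
#' @param sigma_steepness Steepness (per mM) of the logistic underlying the
#'   gradient-modulation bump; the default makes the bump decay to 0.3 at
#'   10 mM glucose.
#' @param po2_per_conc Henry-type conversion factor, mmHg per mol m-3.
#' @param insulin_molar_mass Insulin monomer molar mass (g/mol).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(
    oxy_consumption  = hill_params(-0.034, 1e-3, 1),
    gluc_consumption = hill_params(-0.028, 1e-2, 1),
    ins_phase2       = hill_params(3.0e-5, 7, 2.5),
    ins_phase1       = hill_params(21.0e-5, 0.03, 2),
    ins_oxy_mod      = hill_params(1, 3e-3, 3),
    phi_base = 0.5, phi_metab = 0.5, phi_scale = 1.8,
    c_crit_oxy = 1.0e-4, step_scale = 0.5e-4,
    k_insL = 0.003, c_mid_sigma = 5,
    sigma_steepness = log((1 + sqrt(0.7)) / (1 - sqrt(0.7))) / 5,
    po2_per_conc = 700, insulin_molar_mass = 5808) {
  for (nm in c("oxy_consumption", "gluc_consumption", "ins_phase2",
               "ins_phase1", "ins_oxy_mod")) {
    if (!inherits(get(nm), "hill_params"))
      stop(sprintf("`%s` must be a `hill_params` object", nm), call. = FALSE)
  }
  scalars <- c(phi_base = phi_base, phi_metab = phi_metab, phi_scale = phi_scale,
               c_crit_oxy = c_crit_oxy, step_scale = step_scale, k_insL = k_insL,
               c_mid_sigma = c_mid_sigma, sigma_steepness = sigma_steepness,
               po2_per_conc = po2_per_conc, insulin_molar_mass = insulin_molar_mass)
  if (any(!is.finite(scalars)) || any(scalars < 0))
    stop("kinetic constants must be finite and nonnegative", call. = FALSE)
  if (step_scale <= 0 || k_insL <= 0 || po2_per_conc <= 0)
    stop("`step_scale`, `k_insL` and `po2_per_conc` must be positive", call. = FALSE)
  structure(list(
    oxy_consumption = oxy_consumption, gluc_consumption = gluc_consumption,
    ins_phase2 = ins_phase2, ins_phase1 = ins_phase1, ins_oxy_mod = ins_oxy_mod,
    phi_base = phi_base, phi_metab = phi_metab, phi_scale = phi_scale,
    c_crit_oxy = c_crit_oxy, step_scale = step_scale, k_insL = k_insL,
    c_mid_sigma = c_mid_sigma, sigma_steepness = sigma_steepness,
    po2_per_conc = po2_per_conc, insulin_molar_mass = insulin_molar_mass
  ), class = "kinetics_config")
}

#' Necrosis cut-off
#'
#' Smoothed step that is ~0 where local oxygen is below the critical
#' viability concentration and 1 in viable tissue. Applied to oxygen
#' consumption and, for physical consistency, also to glucose consumption and
#' insulin secretion (necrotic tissue neither consumes nor secretes).
#'
#' @param c_oxy Local oxygen concentration(s), mol m-3.
#' @param cfg A [kinetics_config()].
#' @return Viability fraction(s) in `[0, 1]`.
#' @export
necrosis_factor <- function(c_oxy, cfg = kinetics_config()) {
  smoothed_step(c_oxy - cfg$c_crit_oxy, cfg$step_scale)
}

#' Glucose-dependence of oxygen consumption
#'
#' Metabolic-demand modulation of the oxygen consumption rate:
#' `phi_scale * (phi_base + phi_metab * f(c_gluc))` where `f` is the Hill
#' saturation fraction of the second-phase secretion law (n = 2.5, half-max
#' 7 mM). With the default calibration the factor is ~1 at resting (3 mM)
#' glucose and the consumption rate rises about 70% from 3 to 15 mM.
#'
#' @param c_gluc Glucose concentration(s), mol m-3.
#' @param cfg A [kinetics_config()].
#' @return Dimensionless factor(s) in `[phi_scale*phi_base, phi_scale]`.
#' @export
glucose_metabolic_factor <- function(c_gluc, cfg = kinetics_config()) {
  f <- hill_fraction(c_gluc, cfg$ins_phase2$c_half, cfg$ins_phase2$n)
  cfg$phi_scale * (cfg$phi_base + cfg$phi_metab * f)
}

#' Local oxygen consumption rate
#'
#' Michaelis-Menten consumption of oxygen, scaled by the glucose-dependent
#' metabolic factor and cut to zero in necrotic (oxygen-starved) tissue.
#' Always nonpositive; tends to 0 as oxygen vanishes.
#'
#' @inheritParams glucose_metabolic_factor
#' @param c_oxy Oxygen concentration(s), mol m-3.
#' @return Rate(s), mol m-3 s-1 (<= 0).
#' @export
oxygen_consumption_rate <- function(c_oxy, c_gluc, cfg = kinetics_config()) {
  hill(c_oxy, cfg$oxy_consumption) *
    glucose_metabolic_factor(c_gluc, cfg) *
    necrosis_factor(c_oxy, cfg)
}

#' Local glucose consumption rate
#'
#' Michaelis-Menten glucose consumption (half-max 10 uM, so effectively
#' saturated at physiological glucose), zeroed in necrotic tissue.
#'
#' @inheritParams oxygen_consumption_rate
#' @return Rate(s), mol m-3 s-1 (<= 0).
#' @export
glucose_consumption_rate <- function(c_gluc, c_oxy, cfg = kinetics_config()) {
  hill(c_gluc, cfg$gluc_consumption) * necrosis_factor(c_oxy, cfg)
}

#' Second-phase insulin secretion rate
#'
#' Sigmoid (Hill, n = 2.5, half-max 7 mM) dependence of the sustained
#' secretion rate on local glucose: essentially no release at low glucose, a
#' plateau at high glucose.
#'
#' @inheritParams glucose_metabolic_factor
#' @return Rate(s), mol m-3 s-1 (>= 0).
#' @export
secretion_rate_phase2 <- function(c_gluc, cfg = kinetics_config()) {
  hill(c_gluc, cfg$ins_phase2)
}

#' Glucose-level modulation of the first-phase response
#'
#' Unimodal bump (a normalized derivative of a logistic sigmoid,
#' `4 h (1 - h)`) that maximizes gradient-driven first-phase secretion around
#' the glucose level of highest islet sensitivity (5 mM) and damps it where
#' the islet is already running an elevated second-phase rate, or at very low
#' glucose.
#'
#' @inheritParams glucose_metabolic_factor
#' @return Dimensionless value(s) in `(0, 1]`, equal to 1 at `c_mid_sigma`.
#' @export
gradient_modulation <- function(c_gluc, cfg = kinetics_config()) {
  h <- 1 / (1 + exp(-cfg$sigma_steepness * (pmax(c_gluc, 0) - cfg$c_mid_sigma)))
  4 * h * (1 - h)
}

#' First-phase insulin secretion rate
#'
#' Hill response (n = 2, half-max 0.03 mM/s) to the *rate of increase* of
#' local glucose, active only while glucose is rising, shaped by
#' [gradient_modulation()].
#'
#' @inheritParams glucose_metabolic_factor
#' @param dcdt Local glucose time-derivative(s), mol m-3 s-1 (any sign).
#' @return Rate(s), mol m-3 s-1 (>= 0); zero when `dcdt <= 0`.
#' @export
secretion_rate_phase1 <- function(c_gluc, dcdt, cfg = kinetics_config()) {
  pos <- pmax(dcdt, 0)
  hill(pos, cfg$ins_phase1) * gradient_modulation(c_gluc, cfg)
}

#' Oxygen limitation of insulin secretion
#'
#' Abrupt Hill-type factor (n = 3, half-max 3 uM) through which low local
#' oxygen shuts down secretion; secretion starts becoming limited below
#' roughly 6 uM oxygen (~4 mmHg).
#'
#' @inheritParams oxygen_consumption_rate
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @export
oxygen_secretion_modulation <- function(c_oxy, cfg = kinetics_config()) {
  hill_fraction(c_oxy, cfg$ins_oxy_mod$c_half, cfg$ins_oxy_mod$n)
}

#' Total local insulin secretion rate
#'
#' Sum of first- and second-phase secretion, limited by local oxygen
#' availability and zeroed in necrotic tissue.
#'
#' @inheritParams secretion_rate_phase1
#' @param c_oxy Oxygen concentration(s), mol m-3.
#' @return Rate(s), mol m-3 s-1 (>= 0).
#' @export
total_secretion_rate <- function(c_gluc, dcdt, c_oxy, cfg = kinetics_config()) {
  (secretion_rate_phase1(c_gluc, dcdt, cfg) + secretion_rate_phase2(c_gluc, cfg)) *
    oxygen_secretion_modulation(c_oxy, cfg) * necrosis_factor(c_oxy, cfg)
}

#' Exchange between the local and released insulin compartments
#'
#' Secreted insulin first enters a cell-local compartment (standing in for
#' the readily releasable granule pool) and is released to the surrounding
#' medium by first-order kinetics:
#' `d c_insL/dt = R_ins - k_insL (c_insL - c_ins)`, the transferred amount
#' appearing as a source for released insulin. The two returned source terms
#' always sum to `r_ins` (conservation).
#'
#' @param c_insL Local-compartment insulin concentration(s), mol m-3.
#' @param c_ins Released insulin concentration(s), mol m-3.
#' @param r_ins Total secretion rate(s) from [total_secretion_rate()].
#' @param cfg A [kinetics_config()].
#' @return List with components `d_insL` and `d_ins` (mol m-3 s-1).
#' @export
local_insulin_exchange <- function(c_insL, c_ins, r_ins, cfg = kinetics_config()) {
  transfer <- cfg$k_insL * (c_insL - c_ins)
  list(d_insL = r_ins - transfer, d_ins = transfer)
}

#' Convert between oxygen partial pressure and dissolved concentration
#'
#' Linear (Henry-type) conversion at 700 mmHg per mol m-3, so 140 mmHg
#' corresponds to 0.200 mol m-3 and 0.7 mmHg to 1 uM.
#'
#' @param p Partial pressure(s), mmHg (nonnegative).
#' @param c Concentration(s), mol m-3 (nonnegative).
#' @param cfg A [kinetics_config()].
#' @return The converted value(s).
#' @export
po2_to_conc <- function(p, cfg = kinetics_config()) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("partial pressure must be finite and nonnegative", call. = FALSE)
  p / cfg$po2_per_conc
}

#' @rdname po2_to_conc
#' @export
conc_to_po2 <- function(c, cfg = kinetics_config()) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentration must be finite and nonnegative", call. = FALSE)
  c * cfg$po2_per_conc
}

#' Maximum second-phase secretion expressed per islet equivalent
#'
#' Converts a volumetric secretion rate (default: the second-phase maximum
#' `r_max`) to pg of insulin per islet equivalent (IEQ, a 150-um-diameter
#' sphere) per minute, using the insulin monomer molar mass.
#'
#' @param rate Volumetric secretion rate, mol m-3 s-1.
#' @param cfg A [kinetics_config()].
#' @return Rate in pg/IEQ/min.
#' @export
secretion_pg_per_ieq_min <- function(rate = kinetics_config()$ins_phase2$r_max,
                                     cfg = kinetics_config()) {
  v_ieq <- pi / 6 * (150e-6)^3                 # m^3, standard islet volume
  rate * v_ieq * cfg$insulin_molar_mass * 1e12 * 60
}
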