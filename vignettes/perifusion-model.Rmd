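---
title: "Modelling glucose-stimulated insulin release in perifused islets"
author: "isletsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose-stimulated insulin release in perifused islets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletsim)
```

## The model

Isolated pancreatic islets are avascular: every molecule of glucose and
oxygen that reaches a beta cell, and every molecule of insulin that leaves
it, moves by diffusion through up to ~75 um of tissue and then through the
surrounding medium. `isletsim` models dynamic glucose-stimulated insulin
release (GSIR) of islets in a perifusion chamber at the level of *local*
concentrations: four species fields — oxygen `c_oxy`, glucose `c_gluc`,
released insulin `c_ins` and a cell-local insulin pool `c_insL` — obey the
convection-diffusion-reaction equation

$$\frac{\partial c}{\partial t} = \nabla\cdot(D \nabla c) -
  \mathbf{u}\cdot\nabla c + R(c_\mathrm{oxy}, c_\mathrm{gluc}, \ldots),$$

with subdomain-dependent diffusivities (medium / islet tissue / hydrogel
capsule) and reaction terms active only in tissue. The velocity field
$\mathbf{u}$ solves the steady incompressible (creeping) flow problem in the
chamber lumen once per geometry; the Reynolds number of the default
configuration is about 0.6, so the Stokes system is the default and the full
Navier-Stokes option changes the solution by well under 1%.

All cellular rate laws are Hill functions
$R_\mathrm{max}\, c^n / (c^n + C_{Hf}^n)$:

| rate | argument | $C_{Hf}$ | $n$ | $R_\mathrm{max}$ |
|---|---|---|---|---|
| oxygen consumption | `c_oxy` | 1 uM | 1 | -0.034 mol m$^{-3}$ s$^{-1}$ |
| glucose consumption | `c_gluc` | 10 uM | 1 | -0.028 mol m$^{-3}$ s$^{-1}$ |
| second-phase secretion | `c_gluc` | 7 mM | 2.5 | 3.0e-5 mol m$^{-3}$ s$^{-1}$ |
| first-phase secretion | $\partial c_\mathrm{gluc}/\partial t$ | 0.03 mM/s | 2 | 21e-5 mol m$^{-3}$ s$^{-1}$ |
| oxygen limit on secretion | `c_oxy` | 3 uM | 3 | 1 (modulator) |

Oxygen consumption carries a metabolic-demand factor
$\varphi_{o,g} = \Phi_{sc}(\varphi_\mathrm{base} + \varphi_\mathrm{metab}
f_{2.5,7}(c_\mathrm{gluc}))$ with
$\varphi_\mathrm{base}=\varphi_\mathrm{metab}=0.5$ and $\Phi_{sc}=1.8$, so
the modulated rate equals the base rate at resting (3 mM) glucose and rises
about 70% between 3 and 15 mM:

```{r phi}
100 * (glucose_metabolic_factor(15) / glucose_metabolic_factor(3) - 1)
```

Tissue whose oxygen falls below the critical concentration
$C_{cr}$ = 0.1 uM is treated as necrotic through a smoothed step
$\delta$ = `smoothed_step(c_oxy - 1e-4, 0.5e-4)` (a quintic ramp with
continuous first derivative and no overshoot). The cut is stated for oxygen
consumption; we apply it to glucose consumption and secretion as well — dead
tissue neither consumes nor secretes — which is numerically negligible
because the oxygen limit on secretion is already ~4e-5 at the cut. The cut
is instantaneous in the current oxygen field (no necrosis memory); users
modelling recovery from deep hypoxia should be aware that tissue here
"revives" if oxygen returns.

First-phase secretion responds to the *rise* of local glucose (zero for
falling glucose) and is shaped by a bump $\sigma_{i1,g}(c_\mathrm{gluc}) =
4h(1-h)$, $h$ a logistic centered at $C_m$ = 5 mM. The exact printed form of
this modulator is not recoverable from the source text beyond "a derivative
of a sigmoid" peaking at 5 mM, so the logistic-derivative normalized to 1 at
$C_m$ is used, with the steepness exposed as `sigma_steepness`; the default
makes $\sigma(10\,\mathrm{mM}) = 0.3$, consistent with the modulator's
purpose of damping the gradient response in islets already running a high
second-phase rate.

Secreted insulin first fills the local compartment `c_insL` (a stand-in for
the readily releasable granule pool) and drains into free insulin with rate
$k_\mathrm{insL} = 0.003\ \mathrm{s^{-1}}$, a half-life of
`r round(log(2) / 0.003 / 60, 2)` min. This single linear stage is what
gives the computed first-phase peak its ~5-10 min decay; without it the
response dies in under a minute. `c_insL` is carried as a regular transported
field with diffusivity 1e-16 m$^2$ s$^{-1}$, i.e. immobile.

Total secretion is
$(R_{ph1} + R_{ph2})\,\varphi_{i,o}(c_\mathrm{oxy})\,\delta(c_\mathrm{oxy})$;
we multiply *both* phases by the oxygen modulator $\varphi_{i,o}$ (the
source text's sum-then-modulate reading). Partial oxygen pressures convert
to dissolved concentration linearly at 700 mmHg per mol m$^{-3}$
(140 mmHg = 0.200 mM).

## Geometry and discretization

The chamber is a planar 2D cross-section of the perifusion tube: a rectangle
4 mm high containing two representative islets of 100 and 150 um diameter
(most islets are ~100 um; most islet *mass* sits near 150 um, the standard
IEQ). The tube length is not stated in the source material; we use 12 mm
(3x the height) with the islets 1 mm apart at mid-height and mid-length, so
inlet and outlet effects are far from the islets. Capsules add a 150-um
hydrogel annulus with its own diffusivities.

No unstructured-mesh generator or FEM library is available in this package's
dependency footprint, so the spatial discretization is a boundary-adapted
rectilinear finite-volume scheme built in-package: a graded tensor grid,
spacing `resolution` near the islets (default 16 um, which meshes the
default chamber into 5,000-10,000 cells, the reference discretization
density) and geometrically coarsening away from them. Circular interfaces
are represented by per-cell coverage fractions, computed by midpoint
subsampling at ~1 um, so subdomain areas are recovered to ~0.1%; cell
diffusivities are fraction-weighted, face conductances harmonic, and
reaction terms scale with the tissue fraction. Mesh construction is fully
deterministic; the configuration seed only affects stochastic analysis
steps (fit multi-starts, synthetic noise).

Flow is solved on the staggered (MAC) arrangement of the same grid —
momentum on faces, continuity per cell — with the parabolic inlet profile
$4 v_\mathrm{in} s(1-s)$, no-slip walls, a zero-pressure outlet, and
Dirichlet zero velocity on every face touching a majority-solid cell, so
velocities inside islets and capsules are exactly zero and the discrete
divergence vanishes to solver precision. Transport uses first-order upwind
convection with those face velocities (implicit, hence positivity
preserving), an advective inward-flux inlet, convective outflow, and
insulated walls.

Time integration is operator-split per 0.5-s step (the imposed maximum so
inflow steps are never overstepped): implicit transport with a factorization
reused across steps; the local/released insulin exchange solved as one
implicit 2N block so the pair conserves insulin to machine precision; and
the stiff Michaelis-Menten consumption terms advanced by semi-implicit
substeps that keep concentrations nonnegative. The glucose time-derivative
driving first-phase secretion is the backward difference over the previous
accepted step, floored at zero. Negative undershoots are clipped at zero
with a logged audit (`diagnostics$clip_count`); in practice the count is
zero. Steady readouts (dose-response plateaus, oxygen sweeps, encapsulation
ratios) use a damped fixed-point steady solver on the same discrete
operators — quasi-linearized consumption, with the necrosis field damped
separately because an undamped iteration can flip cells between dead and
alive indefinitely — which reproduces long-run transient plateaus at a
fraction of the cost (the two agree to well under 2% in the test suite).
Transient runs start from the steady state at the protocol's t = 0 inflow,
removing startup artifacts from the readout.

A spherically symmetric reduced solver (`steady_radial()`,
`simulate_radial()`) treats one islet (plus optional capsule) surrounded by
a stagnant medium shell with Dirichlet far-field values, sharing every rate
law and numerical device with the 2D solver. It is validated against the
closed-form zeroth-order consumption profile
$c(r) = c_s - \frac{R_0}{6D}(a^2 - r^2)$ to 0.01% and serves as the fast
surrogate for islet-level sweeps.

## What the simulated experiments emulate — and what they do not

The protocol drivers reproduce the canonical perifusion experiments:
stepwise glucose staircases (G1 up to G30), single G1-G15-G1 steps,
incoming-oxygen sweeps at high glucose, and free-versus-encapsulated
comparisons. Inflow steps are smoothed over `tau` = 30 s (half-width),
emulating apparatus switching and mixing; the exact smoothing width of the
reference setup is not printed, and 1-min ramps are typical of perifusion
hardware. Staircase fixtures use plateaus of 30 min, with the levels
1, 3, 5, 7, 10, 15, 30 mM.

Because the measured insulin outflow amplitude scales with the (unknown)
functional islet mass, all quantitative comparisons in the package are made
on normalized quantities — fractions of a reference plateau, per-IEQ rates,
or half-maximal positions; absolute mol/s values are reported per metre of
chamber depth (planar 2D) and are not comparable to experimental amplitudes.

One genuine representation limit deserves emphasis. A planar 2D
cross-section turns spherical islets into infinite cylinders, and at the
perifusion Peclet number (~2) the unstirred-layer oxygen deficit around a
cylinder is roughly twice that around a sphere of the same radius. The
package therefore offers both representations, and they bracket the
physiological behaviour: at 15 mM glucose the planar chamber puts the
half-maximal incoming pO2 of the two-islet configuration near 38 mmHg and
encapsulated islets at 45 mmHg near 36% of their normoxic rate, while the
spherical surrogate (stagnant shell 300 um, far field at the incoming
values) puts the half-max near 17 mmHg with encapsulation nearly neutral
(capsule oxygen diffusivity, 2.5e-9 m$^2$ s$^{-1}$, is close to water, so
in a stagnant-shell picture a capsule barely changes oxygen supply — its
real effect in the chamber is to displace *convecting* fluid). Calibrated
experimental curves for whole islets (half-max ~25 mmHg, encapsulated ~50%
at 45 mmHg) fall between the two, as expected for 3D objects in a flow.
Sweep-style questions about oxygen limitation are best asked of the
spherical surrogate; questions about chamber hydrodynamics, washout and
trace shape are best asked of the 2D chamber.

Not modelled, by design: subcellular granule-pool dynamics, time-dependent
potentiation or inhibition, GLP-1-class amplification, interspecies
differences, islet swelling or growth, persistent necrosis, and 3D
geometry.

## Numerical choices at a glance

* Steady fixed point: relative-change tolerance 1e-9 (2D) / 1e-10 (radial),
  under-relaxation 0.7 with automatic back-off, necrosis field damped at 0.5.
* Transient step: fixed 0.5 s (protocol contract); 3 semi-implicit reaction
  substeps; trace recorded every accepted step.
* Hill fitting: Levenberg-Marquardt over a deterministic multi-start grid
  (slopes 0.5-4, half-max at data quartiles); `fix_n` restricts the slope.
* Half-maximal pO2: monotone piecewise-linear interpolation of the
  normalized sweep.
* Plateau readouts: mean of the final 2 min with a <1% drift audit.
* Problem sizes: unit tests run a 3 x 1.2 mm single-islet chamber at 30 um
  and the reference chamber at 25-30 um; these reproduce the default-mesh
  plateaus to within 2% (tested), which is why the defaults are not needed
  for routine property checks.

## Reproducing the reference checkpoints

`scripts/acceptance.R` recomputes the model's printed checkpoints from
scratch (consumption rise 3-15 mM, compartment half-life, outer-third
volume fraction, pg/IEQ/min conversion, diffusion times, the oxygen
half-max, and the encapsulated hypoxic fraction) and writes them as JSON;
see the README for usage.
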