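# isletsim

Local-concentration modelling of glucose-stimulated insulin release (GSIR)
in perifused pancreatic islets.

Isolated and encapsulated islets are avascular, so their function is set by
what diffusion and slow perifusion flow deliver to — and carry away from —
each beta cell. `isletsim` simulates a perifusion experiment end to end:
four species (oxygen, glucose, released insulin and a cell-local insulin
pool) are transported by convection-diffusion over a steady creeping-flow
field in a 2D chamber cross-section containing free or hydrogel-encapsulated
islets, with all cellular kinetics written as Hill laws
*R*<sub>max</sub>·*c*<sup>*n*</sup>/(*c*<sup>*n*</sup> + *C*<sub>Hf</sub><sup>*n*</sup>):

* oxygen consumption (*n* = 1, *C*<sub>Hf</sub> = 1 uM,
  *R*<sub>max</sub> = −0.034 mol m⁻³ s⁻¹), scaled by a glucose-dependent
  metabolic-demand factor and cut to zero in necrotic tissue
  (*c*<sub>oxy</sub> < 0.1 uM);
* glucose consumption (*n* = 1, *C*<sub>Hf</sub> = 10 uM);
* second-phase (sustained) secretion from local glucose (*n* = 2.5,
  *C*<sub>Hf</sub> = 7 mM, *R*<sub>max</sub> = 3·10⁻⁵ mol m⁻³ s⁻¹);
* first-phase (transient) secretion from the local glucose *rise*
  ∂*c*<sub>gluc</sub>/∂*t* (*n* = 2, *C*<sub>Hf</sub> = 0.03 mM s⁻¹,
  *R*<sub>max</sub> = 21·10⁻⁵ mol m⁻³ s⁻¹), peaked around 5 mM glucose;
* an abrupt oxygen limit on secretion (*n* = 3, *C*<sub>Hf</sub> = 3 uM).

Secretion fills a local compartment that releases insulin with first-order
rate *k*<sub>insL</sub> = 0.003 s⁻¹ (half-life ≈ 4 min), which gives the
biphasic outflow trace its experimental time scale. A spherically symmetric
reduced solver handles single-islet questions (dose-response curves, oxygen
sweeps) in seconds. The methods vignette
(`vignettes/perifusion-model.Rmd`) documents the model, the finite-volume
discretization, and the planar-vs-spherical representation trade-off.

## Worked example

Steady second-phase dose-response of a single 100-um islet under ample
oxygen, fitted with the Hill equation, then an incoming-oxygen sweep of the
reference two-islet pair (100 + 150 um) at high glucose:

```r
library(isletsim)

dr  <- dose_response_radial(diameter = 100e-6, oxygen_mmHg = 140)
fit <- fit_hill(dr[, c("glucose_mM", "secretion")])
fit
#> Hill fit: r_max = 1.57e-17, c_half = 7.035, n = 2.52 (RSS 1.34e-40, 10 points)

sw <- oxygen_sweep_radial(po2_mmHg = c(140, 80, 50, 40, 30, 25, 20, 15, 10))
sw
#> Oxygen sweep (15 mM glucose): half-maximal incoming pO2 16.9 mmHg
#> # A tibble: 9 x 3
#>   po2_mmHg secretion fraction
#>      <dbl>     <dbl>    <dbl>
#> 1       10  1.04e-17    0.175
#> 2       15  2.54e-17    0.425
#> 3       20  3.72e-17    0.623
#> # i 6 more rows
```

The fitted `c_half` ≈ 7.0 mM and slope `n` ≈ 2.5 show that a small,
well-oxygenated islet transmits the cellular secretion law almost
undistorted, while the sweep shows total secretion holding near the
normoxic rate down to ~40-50 mmHg and collapsing below ~20 mmHg — the
diffusion-limited core of the larger islet shuts down first
(`autoplot(sw)` draws the curve). Full-chamber experiments run the same
way: `run_staircase()`, `run_single_step()`, `oxygen_sweep()`,
`encapsulation_compare()`, each returning tibbles with `tidy()`, `glance()`
and `autoplot()` methods; `write_timeseries()` emits the outflow trace CSV.
A command-line wrapper with the same drivers lives at
`inst/cli/isletsim.R`, and YAML configurations with unit-suffixed keys
(`diameter_um`, `oxygen_mmHg`, `t_min`, ...) are read by `load_config()`
and emitted by `make_fixture()` / `write_config()`.

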