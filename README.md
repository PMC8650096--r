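# spherochip

Flow and drug-transport simulation for spheroid-on-a-chip microfluidic
devices, with full-factorial design-space screening.

Multicellular tumour spheroids (~100 um aggregates) are cultured in
cylindrical microwells coupled to one or two perfusion channels by small
rectangular "infusion" connectors. Whether a drug reaches the spheroid
mostly by **advection** (flow through the porous aggregate) or by
**diffusion** (gradients across it) depends jointly on chamber radius,
connector dimensions, channel topology (single vs double supply channel),
spheroid porosity and flow rates — too many combinations to prototype in
the lab. `spherochip` simulates every combination of an 8-factor design
table (the reference table gives 19,200 design/flow scenarios) and distils
each design into five volume-averaged metrics over the spheroid for
clustered "design heatmap" selection.

## The model

* **Flow** — steady, inertia-free incompressible flow (Re ~ 1e-2) on a
  staggered finite-volume voxel grid. One Brinkman-penalized field covers
  channels, connectors, well and spheroid: momentum is
  `-mu lap(u) + (mu/kappa) u + grad p = 0` with `div u = 0`, where the drag
  term is active inside the spheroid with Kozeny-Carman permeability
  `kappa = d_g^2 eps^3 / (180 (1-eps)^2)` (`d_g` = 15 um). Inlets carry
  fully developed rectangular-duct profiles; the 50-well serpentine supply
  row is condensed into a resistor-ladder network whose cross-channel
  pressure difference drives through-flow across the well. The
  saddle-point system is solved by augmented-Lagrangian Uzawa iteration
  with one sparse Cholesky factorization.
* **Transport** — advection-diffusion of the drug on the frozen flow
  field, `dc/dt + div(u c - D grad c) = 0`, with Bruggeman-corrected
  diffusivity `D_eff = eps^1.5 D` inside the spheroid, Dirichlet inlet
  concentration, implicit upwind finite volumes (monotone; discrete
  maximum principle holds by construction). Defaults model 10 uM
  doxorubicin (`D = 1.6e-10 m^2/s`) over 120 min.
* **Metrics and heatmaps** — volume averages over the spheroid of
  concentration, speed, shear rate `sqrt(2 D:D)`, advective flux `|u c|`
  and diffusive flux `|D grad c|`; dominant-mode classification (a mode
  "dominates" at a 10x flux ratio, boundary inclusive); min-max
  normalization; complete-linkage (farthest-point) hierarchical clustering
  on Euclidean distances; CSV/PNG heatmap export.
* **Sweep runner** — embarrassingly parallel, resumable, deterministic:
  identical results for any worker count.

See the methods vignette (`vignettes/spherochip-methods.Rmd`) for the
governing equations, the serpentine-row boundary-condition model, all
defaults with units, and known limitations.

## Worked example

Simulate the reference double-supply-channel design (porosity 0.5, chamber
radius 120 um, all connectors 60 um) at 0.01 ml/h per channel for 20 min:

```r
library(spherochip)
d   <- design_point(phi = 0.5, radius = 120, wr = 60, hr = 60,
                    wl = 60, hl = 60, q1 = 0.01, q2 = 0.01)
rec <- simulate_design(d, spacing = 10, t_end = 1200, dt = 60)
print(rec)
#> Design record: P5.Wr6.R12.Hr6.Wl6.Hl6 (Q1 0.01, Q2 0.01 ml/h) -> ADVECTION_DOMINANT
#> Design metrics at t = 1200 s (volume averages over spheroid)
#>   concentration   0.01
#>   velocity        5.47924e-08
#>   shear_rate      0.0644802
#>   advective_flux  5.47925e-10
#>   diffusive_flux  1.50149e-14
#>   total_flux      5.47914e-10
#>   mode: ADVECTION_DOMINANT
```

Reading the output: after 20 min the spheroid is already equilibrated at
the 10 uM inlet concentration (`concentration` = 1e-2 mol/m^3). Interior
velocities are ~55 nm/s — the wide connectors let the wells short-circuit
the two supply channels along the row, so the cross-well pressure
difference is small (~0.05 Pa) and the porous aggregate screens what
through-flow remains (well speed 0.006 mm/s against 0.14 mm/s in the
channels). Transport into the spheroid is classified advection-dominated
because concentration gradients — and with them the diffusive flux — have
already collapsed at equilibrium.

A design sweep over a reduced factor table, collected into a clustered
heatmap:

```r
cfg   <- sweep_config(factors = tiny <- factor_table(
           q1 = c(0.01, 0.02), q2 = 0.01, wl = c(0.1, 60), wr = 60,
           hl = 60, hr = 60, radius = 80, phi = c(0.2, 0.9)),
         out_root = "store", spacing = 20, t_end = 1200, dt = 60,
         workers = 4)
store <- run_sweep(cfg)
dm    <- collect_results(store, "equal")
heatmap_export(dm, cluster_designs(dm), "store/heatmap_equal")
```

A command-line front end with `simulate`, `sweep`, `collect`, `cluster`,
`validate` and `config --dump` subcommands ships in
`inst/cli/spherochip.R`.

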