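---
title: "Modelling flow and drug transport in spheroid-on-a-chip devices"
author: "spherochip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow and drug transport in spheroid-on-a-chip devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spherochip)
```

# The system being modelled

Array-type microfluidic chips culture multicellular tumour spheroids (MCTS,
~100 um aggregates of cancer cells) in cylindrical microwells beside one or
two perfusion channels. Medium, and later drug, is pumped through the supply
channel(s); small rectangular "infusion" connectors couple each well to the
channel(s). Device geometry — chamber radius, connector width and height on
either side, one or two supply channels — together with the spheroid's
porosity and the flow rates determines how much drug reaches the spheroid
and by which mechanism (advection through the porous aggregate versus
diffusion down concentration gradients).

`spherochip` simulates one *unit cell* of such a device (one well, its
connectors, and one pitch of each supply channel) and sweeps the
full-factorial design space: an 8-factor table (two flow rates, four
connector dimensions, chamber radius, porosity) whose reference levels give
2x2x5x4x5x4x3x4 = 19,200 design/flow combinations. Each design is reduced
to five volume-averaged metrics over the spheroid — concentration, velocity
magnitude, shear rate, advective-flux magnitude, diffusive-flux magnitude —
evaluated after a 120-minute perfusion, classified by dominant transport
mode, min-max normalized, and assembled into hierarchically clustered
design heatmaps for design selection.

# Governing equations and discretization

## Flow

Flow is steady, incompressible and inertia-free: at 0.01-0.02 ml/h in
100-200 um ducts the Reynolds number is ~1e-2, so the unsteady and
convective terms of the momentum balance are negligible and the problem is
linear (a property the test suite verifies field-wise by scaling the inlet
rates). One velocity/pressure field covers all open regions through
Brinkman penalization: inside the spheroid a drag term mu/kappa u is added
to the Stokes momentum balance, which reduces to Darcy's law where drag
dominates; solid walls are excluded from the unknowns with no-slip faces
(the kappa -> 0 limit).

The spheroid's permeability follows the Kozeny-Carman law

    kappa(eps) = d_g^2 eps^3 / (180 (1 - eps)^2)

with grain diameter `d_g = 15` um (a typical epithelial cell size). This is
the leading free modelling choice — no permeability law or value is
available for real tumour-spheroid aggregates — and it is config-overridable
(`spheroid_properties(permeability = ...)`).

Discretization is a staggered (MAC) finite-volume scheme on an isotropic
voxel grid: face-normal velocities, cell pressures, 7-point viscous
stencils with no-slip walls entering tangentially through ghost reflection.
Inlets carry the classical Fourier-series fully developed rectangular-duct
profile scaled so the discrete face sum reproduces the prescribed flow rate
exactly; outlets hold a ghost reference pressure.

The saddle-point system is solved by augmented-Lagrangian Uzawa iteration:
the momentum block plus a grad-div augmentation (factor `gamma0 = 1e6`
relative to viscosity) is factorized once with a sparse Cholesky
(CHOLMOD via the Matrix package), after which each pressure update contracts
the continuity residual by ~4 orders of magnitude. Iterations stop once the
relative residual has dropped below `tol = 1e-4` (it typically reaches
1e-10 within two or three iterations); the residual history is stored on
the returned field. Discrete divergence and the global inflow/outflow
balance are then at round-off, comfortably inside the 0.5% conservation
contract asserted by the tests.

## The serpentine-row boundary condition

The unit cell cannot be simulated in isolation without deciding what the
rest of the 50-well supply row does, and this decision dominates the
physics. With both channel outlets at the same reference pressure and
co-current flow, a symmetric double-supply-channel (DSC) cell has zero
cross-well pressure difference: the only motion in the well is shear-driven
recirculation leaking through the connector, which our solves show is 3-5
orders of magnitude slower than the channel flow. Measurable advection
inside wells and spheroids requires a cross-channel pressure difference.

We therefore model the row the way the chip is actually plumbed: the two
channels of a DSC pair are counter-current branches of a serpentine, and by
Stokes linearity the 50-well row is a resistor-ladder network — channel
segments of one pitch between well nodes, and at every node a cross-well
resistor (the two connectors in series plus the well cavity, from the
rectangular-duct resistance series). Solving the ladder yields the
channel-pressure profiles *including* the short-circuiting of the channels
through the wells, which self-consistently caps the cross-pressure: wells
with wide connectors equalize the channels locally and see small
differences, wells with narrow connectors preserve the end-to-end contrast.

The signed cross-pressure is antisymmetric along the row under equal flow
rates (the exact mid-row well sees zero), so no single position represents
the row. The default unit cell therefore applies the row *mean* of the
absolute cross-pressure, exposed as the left channel's outlet reference.
`flow_bc(row_fraction = ...)` selects a specific well position instead, and
`arrangement = "co"` restores the co-current, zero-cross-flow configuration
(used by the mirror-symmetry property tests). Single-supply-channel (SSC)
designs have a dead-end well regardless: with the left connector closed
there is no through-path, and well velocities are purely shear-driven.

## Transport

Drug transport solves the advection-diffusion equation on the frozen flow
field: no reaction, no internal sources, drug entering solely as a
Dirichlet inlet concentration from t = 0+. Defaults model doxorubicin
perfusion: free diffusivity `D = 1.6e-10` m^2/s (small-molecule value in
aqueous media), inlet concentration 10 uM = 1e-2 mol/m^3. Inside the
spheroid the effective diffusivity follows the Bruggeman correction
`D_eff = eps^1.5 D` — below the free value, increasing in porosity, and
config-overridable (`transport_properties(bruggeman_exponent = ...)`).

The scheme is cell-centered finite volume with first-order upwind advection
on the staggered face velocities, harmonic-mean face diffusivities at the
spheroid interface, advective outflow at outlets and zero wall flux, and
implicit (backward Euler) time stepping with the operator factorized once
and reused across steps. Upwinding plus implicit stepping make the scheme
monotone: concentrations provably respect the discrete maximum principle,
asserted by the tests. Boundary fluxes are accumulated with the same
discrete coefficients each step, so the global mass balance closes to
round-off by construction and the 0.5% report threshold is a genuine audit
of solver health rather than of modelling error.

Default horizon and step are 120 min at `dt = 30` s with checkpoints every
10 min; the implicit scheme is unconditionally stable, so `dt` trades only
temporal accuracy, which the tests check by halving.

# What the oracles cover

Three closed-form solutions gate the numerics (all generated
programmatically, none stored):

* rectangular-duct Poiseuille flow (Fourier series) — inlet profile,
  interior profile within 2% and cross-section flow rate within 1% at 5 um
  spacing;
* Darcy flow through a uniform porous slab spanning a duct — pressure drop
  within 5% of `mu L U / kappa`;
* diffusion into a sphere with clamped surface — center concentration
  within 3% of the classical series (compared at the voxelized sphere's
  effective radius, which removes the leading discretization bias).

Property-style tests add: Stokes linearity under flow-rate scaling, mirror
symmetry of co-current symmetric cells, the discrete maximum principle,
long-time saturation at the inlet level, exhaustive round-tripping of the
design-name codec over all 4,800 geometries, enumeration against a
nested-loop oracle on random factor tables, complete-linkage merge heights
against a brute-force O(n^3) agglomerative oracle, and bit-identical sweep
outputs for 1 versus 4 workers.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| channel width x height | 200 x 100 | um | typical droplet-array supply duct; sets channel speed 0.139 mm/s at 0.01 ml/h |
| connector length | 100 | um | wall thickness between channel and well; controls well-channel coupling |
| well depth | 100 | um | well spans the chip height |
| spheroid diameter | 100 | um | MCTS size; fixed across the sweep |
| unit-cell pitch | 400 | um | well-to-well spacing; sets channel segment resistance |
| wells per row | 50 | - | row length of the ladder network |
| grain diameter | 15 | um | Kozeny-Carman permeability scale |
| D (free) | 1.6e-10 | m^2/s | small-molecule doxorubicin in water |
| Bruggeman exponent | 1.5 | - | porosity correction of D_eff |
| resolution | 10 (5 for oracles) | um | voxel size; open connectors must span >= 2 voxels |
| tol | 1e-4 | - | relative residual drop (4 orders) |
| evaluation time | 7200 | s | heatmap metric horizon |

The unit-cell dimensions are explicit assumptions: fabricated chips of this
class rarely publish every internal dimension, so all of them live in
`geometry_config()` and the YAML config rather than in code, and should be
set to the measured geometry of whatever device is being modelled.

# Design decisions taken where the design was open

* **Evaluation state and saturation.** With zero reaction and aqueous
  diffusivity, designs with wide (60 um) connectors saturate the well and
  spheroid at the inlet concentration well before the 120-minute
  evaluation time. Past saturation the diffusive flux decays toward
  numerical zero, so advective/diffusive flux *ratios* of such designs are
  extreme and sensitive only to the advective side. Experimental spheroid
  perfusion commonly shows pronounced core concentration deficits even
  after hours, which a source-free advection-diffusion model with aqueous
  diffusivity cannot produce at these length scales; capturing that would
  require a retention mechanism (binding, partitioning, adsorption) that
  is deliberately outside this model's scope. We report what the stated
  physics yields rather than introducing such a mechanism implicitly.
* **Constant-column normalization maps to 0** (not 0.5): deterministic,
  and matches the convention that every non-constant column attains 0.
* **Clustering tie-breaks** inherit the deterministic input (enumeration)
  order, making leaf orders bit-reproducible.
* **The two heatmap scenarios** are stored as separate matrices keyed
  `equal` (Q1 = Q2 = 0.01 ml/h) and `unequal` (Q1 = 0.02, Q2 = 0.01 ml/h).
* **No randomness anywhere in the pipeline**: sweep results are
  worker-count invariant by isolation, and `seed` exists in the config
  only as a reserved key.

# Problem sizes

The suite and the acceptance script run everything at desk scale: 10 um
voxels for unit cells (20 um for sweep smoke tests), 5 um for the analytic
oracles, 120-minute horizons at 60-120 s implicit steps. A unit-cell flow
solve is ~20-35k voxels and takes seconds; the full 19,200-design sweep at
these settings is a cluster-scale job and is exercised here only through
reduced factor tables (the `subset` selector schedules slices of the full
enumeration for such campaigns).

# Known limitations

* The unit-cell geometry is a reconstruction; absolute velocity levels in
  wells (and everything downstream of them) depend on the unknown true
  connector length, channel cross-section and row plumbing. Ratios and
  orderings are more trustworthy than absolute magnitudes.
* SSC wells are dead-ended in this geometry, so their interior velocities
  are shear-driven and 3-5 orders of magnitude below channel speeds.
  Devices whose wells exhibit only a ~10x velocity deficit relative to the
  channel (as some chamber-type chips do) must couple well and channel far
  more openly than a single side connector; model such devices with a
  different geometry, not by tuning connector dimensions.
* First-order upwinding adds numerical diffusion ~u h/2; front positions
  are accurate (tested), front widths are smeared at coarse resolution.
* The Brinkman penalization smears the spheroid surface over one voxel;
  permeability contrasts across the surface converge only linearly in
  spacing.
* No uptake, binding, metabolism, spheroid growth or deformation; single
  species; Newtonian fluid; rigid geometry.
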