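Package: spherochip
Title: Flow and Drug Transport Simulation for Spheroid-on-a-Chip Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Full-factorial design-space exploration of microfluidic
    spheroid-on-a-chip devices. Solves steady Stokes-Brinkman flow through a
    voxelized unit cell (supply channels, infusion connectors, cylindrical
    microwell, porous tumour spheroid) on a staggered finite-volume grid, then
    time-dependent advection-diffusion drug transport on the frozen flow
    field. Reduces each device design to five volume-averaged metrics
    (concentration, velocity, shear rate, advective flux, diffusive flux)
    over the spheroid, classifies the dominant transport mode, and builds
    hierarchically clustered design heatmaps for design selection. Includes a
    resumable parallel sweep runner over the factorial design space and
    analytic-oracle validation cases (rectangular-duct flow, Darcy slab,
    diffusion into a sphere).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    parallel,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
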