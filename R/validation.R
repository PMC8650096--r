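## Analytic-oracle fixtures: simple grids and fields with closed-form
## solutions, used by the validation suite and the tests.

#' Straight rectangular-duct validation grid
#'
#' A duct of the given cross-section along x, optionally with a porous slab
#' (labeled as spheroid material) spanning the full cross-section over an
#' x-interval — the configuration of the duct-flow and Darcy pressure-drop
#' oracles.
#'
#' @param width_um,height_um duct cross-section (um).
#' @param length_um duct length (um).
#' @param spacing voxel size (um).
#' @param porosity porosity attached to the grid's design (sets the porous
#'   slab material and the effective diffusivity).
#' @param slab_x optional `c(from, to)` x-interval (um) of the porous slab.
#' @return A `domain_grid` whose open cells are channel (label `CHANNEL_R`)
#'   or porous slab (label `SPHEROID`).
#' @export
make_duct_grid <- function(width_um = 200, height_um = 100, length_um = 200,
                           spacing = 5, porosity = 0.5, slab_x = NULL) {
  h <- spacing
  nx <- as.integer(round(length_um / h))
  ny <- as.integer(round(width_um / h))
  nz <- as.integer(round(height_um / h))
  lab <- array(REGIONS[["CHANNEL_R"]], c(nx, ny, nz))
  if (!is.null(slab_x)) {
    xc <- (seq_len(nx) - 0.5) * h
    lab[xc > slab_x[1] & xc <= slab_x[2], , ] <- REGIONS[["SPHEROID"]]
  }
  design <- design_point(phi = porosity, radius = 80, wr = 60, hr = 60,
                         wl = CLOSED_LEVEL, hl = CLOSED_LEVEL, q1 = 0)
  structure(list(spacing = h * 1e-6, shape = c(nx, ny, nz), labels = lab,
                 origin = c(0, 0, 0), design = design,
                 geom = geometry_config(channel_width = width_um,
                                        channel_height = height_um,
                                        well_depth = height_um,
                                        unit_cell_pitch = length_um),
                 extent_um = c(length_um, width_um, height_um)),
            class = "domain_grid")
}

#' Sphere-in-a-box validation grid
#'
#' A porous sphere (spheroid material) centered in an open box, used by the
#' diffusion-into-a-sphere oracle.
#'
#' @param radius_um sphere radius (um).
#' @param box_um box edge length (um).
#' @param spacing voxel size (um).
#' @param porosity sphere porosity (sets its effective diffusivity).
#' @return A `domain_grid` with the sphere labeled `SPHEROID` inside `WELL`.
#' @export
make_sphere_grid <- function(radius_um = 50, box_um = 140, spacing = 5,
                             porosity = 0.5) {
  h <- spacing
  n <- as.integer(round(box_um / h))
  lab <- array(REGIONS[["WELL"]], c(n, n, n))
  xc <- (seq_len(n) - 0.5) * h - box_um / 2
  r2 <- outer(outer(xc^2, xc^2, "+"), xc^2, "+")
  lab[r2 <= radius_um^2] <- REGIONS[["SPHEROID"]]
  design <- design_point(phi = porosity, radius = 80, wr = 60, hr = 60,
                         wl = CLOSED_LEVEL, hl = CLOSED_LEVEL, q1 = 0)
  structure(list(spacing = h * 1e-6, shape = c(n, n, n), labels = lab,
                 origin = c(0, 0, 0), design = design,
                 geom = geometry_config(),
                 extent_um = rep(box_um, 3)),
            class = "domain_grid")
}

#' Construct a flow field from explicit face velocities
#'
#' Wraps given (or constant) staggered face velocities as a `flow_field`,
#' for analytic test cases (quiescent fluid, plug flow, Couette shear) that
#' bypass the solver.
#'
#' @param grid a `domain_grid`.
#' @param u,v,w face-velocity arrays of dims `(nx+1, ny, nz)`,
#'   `(nx, ny+1, nz)`, `(nx, ny, nz+1)`, or scalars (recycled).
#' @return A `flow_field` (pressure zero, no residual history).
#' @export
as_flow_field <- function(grid, u = 0, v = 0, w = 0) {
  d <- grid$shape
  mk <- function(x, dd) if (length(x) == 1L) array(x, dd) else {
    stopifnot(identical(dim(x), dd)); x
  }
  uarr <- mk(u, c(d[1] + 1L, d[2], d[3]))
  varr <- mk(v, c(d[1], d[2] + 1L, d[3]))
  warr <- mk(w, c(d[1], d[2], d[3] + 1L))
  h <- grid$spacing
  q_in <- sum(pmax(uarr[1, , ], 0)) * h^2
  q_out <- sum(pmax(uarr[d[1] + 1L, , ], 0)) * h^2
  structure(list(u = uarr, v = varr, w = warr,
                 p = array(0, d), grid = grid,
                 residual_history = numeric(0), tol = NA_real_,
                 converged = TRUE, q_in = q_in, q_out = q_out,
                 cross_pressure = 0),
            class = "flow_field")
}

#' Analytic center concentration for diffusion into a sphere
#'
#' Series solution for a sphere of radius `a` with its surface held at `c0`
#' from t = 0, initially empty: c(0, t)/c0 = 1 + 2 sum (-1)^n exp(-n^2 pi^2
#' Fo) with Fo = D t / a^2.
#'
#' @param fo Fourier number D*t/a^2.
#' @param nterms series terms.
#' @return Center concentration as a fraction of the surface value.
#' @export
sphere_center_concentration <- function(fo, nterms = 200) {
  vapply(fo, function(f) {
    n <- seq_len(nterms)
    max(0, 1 + 2 * sum((-1)^n * exp(-n^2 * pi^2 * f)))
  }, 1)
}
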