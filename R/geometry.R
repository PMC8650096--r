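## Voxelized unit-cell geometry: one microwell, its connector(s) and
## supply-channel segment(s), with per-voxel region labels.

#' Region label codes
#'
#' Integer codes used in the `labels` array of a [build_domain()] grid:
#' `SOLID` (0), `CHANNEL_L` (1), `CHANNEL_R` (2), `CONNECTOR_L` (3),
#' `CONNECTOR_R` (4), `WELL` (5), `SPHEROID` (6). Every voxel carries exactly
#' one label; all labels except `SOLID` are open to flow.
#'
#' @format Named integer vector.
#' @export
REGIONS <- c(SOLID = 0L, CHANNEL_L = 1L, CHANNEL_R = 2L, CONNECTOR_L = 3L,
             CONNECTOR_R = 4L, WELL = 5L, SPHEROID = 6L)

#' Fixed unit-cell geometry defaults
#'
#' Device dimensions that are not part of the swept design space. The unit
#' cell is one microwell plus its connector(s) and supply-channel segment(s);
#' coordinates are x along the channel, y across the device, z the chip
#' height, with the origin at the unit-cell corner. Config values are in um;
#' grids store SI units internally.
#'
#' @param channel_width supply-channel width in y (um).
#' @param channel_height supply-channel (and chip) height in z (um).
#' @param connector_length connector length in y between channel and well (um).
#' @param well_depth microwell depth; the well is a vertical-axis cylinder
#'   spanning the chip height (um).
#' @param spheroid_diameter tumour-spheroid diameter (um).
#' @param spheroid_center_offset xyz offset of the spheroid center from the
#'   well center (um).
#' @param unit_cell_pitch periodic well-to-well spacing along the channel (um).
#' @param n_wells_row number of microwells chained in one supply row; used by
#'   the row pressure model, not meshed.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(channel_width = 200, channel_height = 100,
                            connector_length = 100, well_depth = 100,
                            spheroid_diameter = 100,
                            spheroid_center_offset = c(0, 0, 0),
                            unit_cell_pitch = 400, n_wells_row = 50) {
  stopifnot(channel_width > 0, channel_height > 0, connector_length > 0,
            well_depth > 0, spheroid_diameter > 0, unit_cell_pitch > 0,
            n_wells_row >= 1, length(spheroid_center_offset) == 3)
  if (well_depth != channel_height)
    stop("well_depth must equal channel_height: the well cylinder spans ",
         "the chip height")
  structure(list(channel_width = channel_width,
                 channel_height = channel_height,
                 connector_length = connector_length,
                 well_depth = well_depth,
                 spheroid_diameter = spheroid_diameter,
                 spheroid_center_offset = spheroid_center_offset,
                 unit_cell_pitch = unit_cell_pitch,
                 n_wells_row = n_wells_row),
            class = "geometry_config")
}

#' Build the voxelized unit-cell domain for a design
#'
#' Assigns a region label to every voxel of an isotropic grid by geometric
#' membership: rectangular supply channels along x at both y extremes,
#' rectangular connectors (width along x, height along z, centered on the
#' channel mid-height), a cylindrical well of the design's chamber radius
#' spanning the chip height, and a spherical spheroid at the well center.
#' Everything else is `SOLID`. For SSC designs (closed left connector) the
#' left channel and connector are not meshed, so no `CHANNEL_L` or
#' `CONNECTOR_L` voxels exist; the box keeps the same extents so SSC and DSC
#' grids of equal design parameters are congruent.
#'
#' @param design a one-row `design_table` ([design_point()] or a row of
#'   [enumerate_designs()]).
#' @param geom a [geometry_config()].
#' @param spacing isotropic voxel size (um). Every open connector dimension
#'   must span at least 2 voxels, i.e. `spacing <= min(open connector dims)/2`.
#' @return An object of class `domain_grid`: list with `spacing` (m), `shape`
#'   (nx, ny, nz), `labels` (integer array of [REGIONS] codes), `origin` (m),
#'   plus the design and geometry it was built from.
#' @export
build_domain <- function(design, geom = geometry_config(), spacing = 10) {
  stopifnot(inherits(design, "data.frame"), nrow(design) == 1L)
  d <- as.list(design[1, ])
  open_dims <- c(wr = d$wr_um, hr = d$hr_um)
  if (d$topology == "DSC") open_dims <- c(open_dims, wl = d$wl_um, hl = d$hl_um)
  if (spacing > min(open_dims) / 2)
    stop(sprintf(paste0("resolution error: spacing %g um cannot resolve the ",
                        "smallest open connector dimension (%g um); use ",
                        "spacing <= %g um"),
                 spacing, min(open_dims), min(open_dims) / 2))
  h <- spacing
  cw <- geom$channel_width; ch <- geom$channel_height
  lc <- geom$connector_length; R <- d$radius_um
  pitch <- geom$unit_cell_pitch
  Lx <- pitch; Ly <- 2 * (cw + lc + R); Lz <- ch
  nx <- max(1L, as.integer(round(Lx / h)))
  ny <- max(1L, as.integer(round(Ly / h)))
  nz <- max(1L, as.integer(round(Lz / h)))
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  lab <- array(REGIONS[["SOLID"]], c(nx, ny, nz))

  ssc <- d$topology == "SSC"
  ## channels
  if (!ssc) lab[, yc <= cw, zc <= ch] <- REGIONS[["CHANNEL_L"]]
  lab[, yc > Ly - cw, zc <= ch] <- REGIONS[["CHANNEL_R"]]
  ## connectors: width along x centered at pitch/2, height about z = ch/2.
  ## edges snap to the nearest voxel face and the duct spans round(W/h)
  ## voxels, so its hydraulic dimensions are preserved even when the exact
  ## edges fall mid-voxel
  zmid <- ch / 2
  inb <- function(x, c0, width) {
    n <- max(1L, as.integer(round(width / h)))
    i0 <- as.integer(floor((c0 - width / 2) / h + 0.5))
    ix <- as.integer(round(x / h + 0.5))   # voxel index of each center
    ix > i0 & ix <= i0 + n
  }
  if (!ssc) {
    xin <- inb(xc, pitch / 2, d$wl_um)
    zin <- inb(zc, zmid, d$hl_um)
    yin <- yc > cw & yc <= cw + lc
    lab[xin, yin, zin] <- REGIONS[["CONNECTOR_L"]]
  }
  xin <- inb(xc, pitch / 2, d$wr_um)
  zin <- inb(zc, zmid, d$hr_um)
  yin <- yc > cw + lc + 2 * R & yc <= cw + 2 * lc + 2 * R
  lab[xin, yin, zin] <- REGIONS[["CONNECTOR_R"]]
  ## well cylinder (vertical axis, spans chip height)
  wc <- c(pitch / 2, cw + lc + R)
  r2 <- outer((xc - wc[1])^2, (yc - wc[2])^2, "+")
  well2d <- r2 <= R^2
  lab[array(well2d, c(nx, ny, nz))] <- REGIONS[["WELL"]]
  ## spheroid sphere at well center (+ optional offset)
  sc <- c(wc, ch / 2) + geom$spheroid_center_offset
  rs <- geom$spheroid_diameter / 2
  s2 <- outer(outer((xc - sc[1])^2, (yc - sc[2])^2, "+"), (zc - sc[3])^2, "+")
  lab[s2 <= rs^2] <- REGIONS[["SPHEROID"]]

  structure(list(spacing = h * 1e-6, shape = c(nx, ny, nz), labels = lab,
                 origin = c(0, 0, 0), design = design, geom = geom,
                 extent_um = c(Lx, Ly, Lz)),
            class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  n <- x$shape
  cat(sprintf("Unit-cell domain grid: %d x %d x %d voxels at %.3g um\n",
              n[1], n[2], n[3], x$spacing * 1e6))
  tab <- table(factor(x$labels, levels = REGIONS, labels = names(REGIONS)))
  for (r in names(tab)) if (tab[[r]] > 0)
    cat(sprintf("  %-12s %8d voxels (%.3g nL)\n", r, tab[[r]],
                tab[[r]] * (x$spacing)^3 * 1e12))
  invisible(x)
}

#' Measure the volume of a labeled region
#'
#' Voxel count times voxel volume; zero for regions absent from the grid.
#'
#' @param grid a [build_domain()] grid.
#' @param label a region name from [REGIONS] (e.g. `"SPHEROID"`).
#' @return Volume in m^3.
#' @export
region_measure <- function(grid, label) {
  if (!label %in% names(REGIONS))
    stop("unknown region label '", label, "'; expected one of: ",
         paste(names(REGIONS), collapse = ", "))
  sum(grid$labels == REGIONS[[label]]) * grid$spacing^3
}

## logical mask of open (non-solid) voxels
open_mask <- function(grid) grid$labels != REGIONS[["SOLID"]]

## voxel-center coordinates (m) along each axis
grid_axes <- function(grid) {
  h <- grid$spacing
  lapply(seq_len(3), function(a) (seq_len(grid$shape[a]) - 0.5) * h)
}
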