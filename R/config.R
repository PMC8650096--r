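## Structured configuration: one YAML file with sections
## factors/geometry/fluid/drug/solver/sweep; every default dumpable.

#' Default configuration of the simulation pipeline
#'
#' Returns the full nested default configuration: the reference factor
#' table, unit-cell geometry, fluid and drug properties, solver settings and
#' sweep settings. The `sweep$seed` key is reserved for interface stability;
#' the pipeline contains no random number generation and never reads it.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  ft <- default_factor_table()
  geom <- geometry_config()
  list(
    factors = lapply(unclass(ft), as.numeric),
    geometry = unclass(geom)[names(unclass(geom)) != "class"],
    fluid = list(density = 1000, viscosity = 1e-3),
    drug = list(diffusivity = 1.6e-10, inlet_concentration = 1e-2,
                bruggeman_exponent = 1.5, grain_diameter_um = 15),
    solver = list(resolution_um = 10, tol = 1e-4, maxit = 50,
                  gamma0 = 1e6, arrangement = "counter",
                  row_fraction = NULL),
    sweep = list(t_end_s = 7200, dt_s = 30, evaluation_time_s = 7200,
                 checkpoint_interval_s = 600, workers = 1, subset = NULL,
                 out_root = "spherochip_results", seed = NULL)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a configuration file
#'
#' YAML with any subset of the sections/keys of [default_config()]; missing
#' entries fall back to the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

#' Dump a configuration as YAML text
#'
#' @param cfg a configuration list (default: all defaults).
#' @return YAML character string.
#' @export
config_dump <- function(cfg = default_config()) {
  yaml::as.yaml(cfg)
}

#' Build a [sweep_config()] from a configuration list
#'
#' @param cfg nested configuration list ([read_config()]).
#' @param out_root output directory (overrides `cfg$sweep$out_root`).
#' @return A [sweep_config()].
#' @export
sweep_config_from <- function(cfg, out_root = NULL) {
  g <- cfg$geometry
  sweep_config(
    factors = do.call(factor_table, cfg$factors),
    geom = geometry_config(channel_width = g$channel_width,
                           channel_height = g$channel_height,
                           connector_length = g$connector_length,
                           well_depth = g$well_depth,
                           spheroid_diameter = g$spheroid_diameter,
                           spheroid_center_offset = g$spheroid_center_offset,
                           unit_cell_pitch = g$unit_cell_pitch,
                           n_wells_row = g$n_wells_row),
    out_root = if (is.null(out_root)) cfg$sweep$out_root else out_root,
    spacing = cfg$solver$resolution_um,
    t_end = cfg$sweep$t_end_s, dt = cfg$sweep$dt_s,
    evaluation_time = cfg$sweep$evaluation_time_s,
    workers = cfg$sweep$workers, subset = cfg$sweep$subset,
    fluid = fluid_properties(cfg$fluid$density, cfg$fluid$viscosity),
    props = transport_properties(cfg$drug$diffusivity,
                                 cfg$drug$inlet_concentration,
                                 cfg$drug$bruggeman_exponent),
    arrangement = cfg$solver$arrangement,
    row_fraction = cfg$solver$row_fraction,
    grain_diameter_um = cfg$drug$grain_diameter_um,
    tol = cfg$solver$tol)
}
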