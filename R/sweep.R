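## Sweep orchestration: run designs across parallel workers, persist
## per-design records, resume interrupted sweeps, assemble design matrices.

#' Simulate one device design end to end
#'
#' Builds the voxel domain, solves steady flow, runs the drug-transport
#' simulation and extracts the five design metrics at the evaluation time.
#' This is the unit of work of the design sweep; it is deterministic (no
#' random number generation anywhere in the pipeline).
#'
#' @param design one-row `design_table` (its `q1_ml_h`/`q2_ml_h` columns set
#'   the flow scenario; `q1` is ignored for SSC designs).
#' @param geom a [geometry_config()].
#' @param spacing voxel size (um).
#' @param fluid a [fluid_properties()].
#' @param props a [transport_properties()].
#' @param t_end,dt transport horizon and step (s).
#' @param evaluation_time metric evaluation time (s); defaults to `t_end`.
#' @param checkpoints checkpoint times (s); the evaluation time is always
#'   included.
#' @param probes named list of probe points (um); defaults to the spheroid
#'   core (well center).
#' @param arrangement,row_fraction see [flow_bc()].
#' @param grain_diameter_um permeability-law grain size (um).
#' @param tol flow-solver tolerance.
#' @return A list of class `design_record`: `design`, `metrics`, `mode`,
#'   `probe_traces`, `diagnostics`.
#' @export
simulate_design <- function(design, geom = geometry_config(), spacing = 10,
                            fluid = fluid_properties(),
                            props = transport_properties(),
                            t_end = 7200, dt = 30,
                            evaluation_time = t_end, checkpoints = NULL,
                            probes = NULL,
                            arrangement = "counter", row_fraction = NULL,
                            grain_diameter_um = 15, tol = 1e-4) {
  d <- design[1, ]
  grid <- build_domain(d, geom, spacing)
  if (is.null(probes)) {
    ctr <- c(geom$unit_cell_pitch / 2,
             geom$channel_width + geom$connector_length + d$radius_um,
             geom$channel_height / 2)
    probes <- list(core = ctr)
  }
  sph <- spheroid_properties(d$phi, grain_diameter_um)
  q1 <- if (d$topology == "SSC") NA_real_ else d$q1_ml_h
  bc <- flow_bc(q1, d$q2_ml_h, arrangement = arrangement,
                row_fraction = row_fraction)
  flow <- solve_flow(grid, fluid, sph, bc, tol = tol)
  cks <- sort(unique(c(checkpoints, evaluation_time)))
  hist <- solve_transport(grid, flow, props, t_end = t_end, dt = dt,
                          checkpoints = cks, probes = probes)
  met <- compute_metrics(flow, hist, evaluation_time)
  structure(list(design = d, metrics = met,
                 mode = classify_transport_mode(met),
                 probe_traces = hist$probe_traces,
                 history = hist, flow = flow,
                 diagnostics = list(
                   residual_history = flow$residual_history,
                   mass_balance = mass_balance_report(hist),
                   cfl = hist$cfl,
                   cells = prod(grid$shape),
                   open_cells = sum(open_mask(grid)))),
            class = "design_record")
}

#' @export
print.design_record <- function(x, ...) {
  cat(sprintf("Design record: %s (Q1 %s, Q2 %g ml/h) -> %s\n",
              x$design$name,
              ifelse(x$design$topology == "SSC", "-", x$design$q1_ml_h),
              x$design$q2_ml_h, x$mode))
  print(x$metrics)
  invisible(x)
}

#' Sweep configuration
#'
#' @param factors a [factor_table()].
#' @param geom a [geometry_config()].
#' @param out_root output directory for per-design records.
#' @param spacing voxel size (um).
#' @param t_end,dt,evaluation_time transport settings (s).
#' @param workers number of parallel worker processes.
#' @param subset optional integer range `c(from, to)` into the enumeration
#'   (1-based, inclusive) to run a slice of the design list.
#' @param fluid,props,arrangement,row_fraction,grain_diameter_um,tol
#'   passed through to [simulate_design()].
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(factors = default_factor_table(),
                         geom = geometry_config(), out_root,
                         spacing = 10, t_end = 7200, dt = 30,
                         evaluation_time = t_end, workers = 1L,
                         subset = NULL, fluid = fluid_properties(),
                         props = transport_properties(),
                         arrangement = "counter", row_fraction = NULL,
                         grain_diameter_um = 15, tol = 1e-4) {
  stopifnot(workers >= 1)
  designs <- enumerate_designs(factors)
  if (!is.null(subset)) {
    stopifnot(length(subset) == 2, subset[1] >= 1,
              subset[2] <= nrow(designs), subset[1] <= subset[2])
  }
  structure(list(factors = factors, geom = geom, out_root = out_root,
                 spacing = spacing, t_end = t_end, dt = dt,
                 evaluation_time = evaluation_time, workers = workers,
                 subset = subset, fluid = fluid, props = props,
                 arrangement = arrangement, row_fraction = row_fraction,
                 grain_diameter_um = grain_diameter_um, tol = tol,
                 designs = designs),
            class = "sweep_config")
}

record_dir <- function(root, design) {
  file.path(root, sprintf("%s.Q1_%g.Q2_%g", design$name,
                          design$q1_ml_h, design$q2_ml_h))
}

record_complete <- function(dir) {
  f <- file.path(dir, "status")
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], "COMPLETE")
}

write_record <- function(dir, rec, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- rec$metrics
  row <- cbind(as.data.frame(rec$design),
               as.data.frame(as.list(unclass(m))),
               total_flux = attr(m, "total_flux"), mode = rec$mode,
               evaluation_time_s = config$evaluation_time)
  utils::write.csv(row, file.path(dir, "metrics.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(rec$probe_traces, file.path(dir, "probes.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("residual: %s",
                       paste(signif(rec$diagnostics$residual_history, 4),
                             collapse = " ")),
               sprintf("mass_balance: %.4g", rec$diagnostics$mass_balance),
               sprintf("open_cells: %d", rec$diagnostics$open_cells)),
             file.path(dir, "solve.log"))
  writeLines("COMPLETE", file.path(dir, "status"))
}

#' Run a (subset of a) full-factorial design sweep
#'
#' Every design in the configured subset is simulated independently
#' (embarrassingly parallel across worker processes) and persisted to its
#' own record directory under `out_root`, keyed by design name plus flow
#' scenario. Completed records are immutable: re-running a finished sweep is
#' a no-op unless `force = TRUE`, and an interrupted sweep resumes with only
#' the pending designs. Per-design solver failures are recorded in the
#' design's directory and summarized, not fatal.
#'
#' @param config a [sweep_config()].
#' @param force re-run designs that already have complete records.
#' @return An object of class `result_store`: the store directory, the sweep
#'   manifest (design, status) and the config. The manifest is also written
#'   to `<out_root>/manifest.csv`.
#' @export
run_sweep <- function(config, force = FALSE) {
  designs <- config$designs
  idx <- seq_len(nrow(designs))
  if (!is.null(config$subset))
    idx <- seq(config$subset[1], config$subset[2])
  dir.create(config$out_root, recursive = TRUE, showWarnings = FALSE)

  run_one <- function(i) {
    dsg <- designs[i, ]
    dir <- record_dir(config$out_root, dsg)
    if (!force && record_complete(dir)) return("COMPLETE")
    rec <- tryCatch(
      simulate_design(dsg, geom = config$geom, spacing = config$spacing,
                      fluid = config$fluid, props = config$props,
                      t_end = config$t_end, dt = config$dt,
                      evaluation_time = config$evaluation_time,
                      arrangement = config$arrangement,
                      row_fraction = config$row_fraction,
                      grain_diameter_um = config$grain_diameter_um,
                      tol = config$tol),
      error = function(e) e)
    if (inherits(rec, "error")) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(c("FAILED", conditionMessage(rec)),
                 file.path(dir, "status"))
      return(paste("FAILED:", conditionMessage(rec)))
    }
    write_record(dir, rec, config)
    "COMPLETE"
  }
  status <- if (config$workers > 1L) {
    unlist(parallel::mclapply(idx, run_one, mc.cores = config$workers,
                              mc.preschedule = FALSE))
  } else {
    vapply(idx, run_one, character(1))
  }
  manifest <- cbind(as.data.frame(designs[idx, ]), status = status)
  utils::write.csv(manifest, file.path(config$out_root, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  fails <- sum(startsWith(status, "FAILED"))
  if (fails)
    warning(fails, " design(s) failed; see their status files under ",
            config$out_root)
  structure(list(root = config$out_root, manifest = manifest,
                 config = config),
            class = "result_store")
}

#' @export
print.result_store <- function(x, ...) {
  cat(sprintf("Result store %s: %d records (%d complete, %d failed)\n",
              x$root, nrow(x$manifest),
              sum(x$manifest$status == "COMPLETE"),
              sum(startsWith(x$manifest$status, "FAILED"))))
  invisible(x)
}

#' Assemble a design matrix from a result store
#'
#' Gathers the per-design metric records of one flow-rate scenario, in
#' enumeration order, into a [design_matrix()]. The two scenarios mirror the
#' clustered heatmap pair: `"equal"` keeps designs with Q1 = Q2 at the base
#' flow rate (SSC designs are keyed by Q2 alone), `"unequal"` designs with
#' Q1 = 2 Q2.
#'
#' @param store a [run_sweep()] result store, or its directory path.
#' @param scenario `"equal"` or `"unequal"`.
#' @param base_q base flow rate (ml/h) defining the scenario pair.
#' @return A [design_matrix()] with rownames the design names; raw rows also
#'   carried as data frame attribute `records` (including mode labels).
#'   Designs without a complete record are reported via attribute `missing`.
#' @export
collect_results <- function(store, scenario = c("equal", "unequal"),
                            base_q = 0.01) {
  scenario <- match.arg(scenario)
  root <- if (inherits(store, "result_store")) store$root else store
  mf <- file.path(root, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest at ", root)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  q1_want <- if (scenario == "equal") base_q else 2 * base_q
  sel <- manifest$q2_ml_h == base_q & manifest$q1_ml_h == q1_want
  manifest <- manifest[sel, , drop = FALSE]
  if (!nrow(manifest)) stop("no designs of scenario '", scenario,
                            "' in the manifest")
  rows <- list(); missing <- character(0)
  for (i in seq_len(nrow(manifest))) {
    dir <- record_dir(root, manifest[i, ])
    if (!record_complete(dir)) {
      missing <- c(missing, manifest$name[i]); next
    }
    rows[[length(rows) + 1L]] <-
      utils::read.csv(file.path(dir, "metrics.csv"),
                      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no complete records for scenario '", scenario, "'")
  rec <- do.call(rbind, rows)
  raw <- as.matrix(rec[, METRIC_NAMES])
  rownames(raw) <- rec$name
  dm <- design_matrix(raw, evaluation_time = rec$evaluation_time_s[1],
                      scenario = scenario)
  attr(dm, "records") <- rec
  attr(dm, "missing") <- missing
  if (length(missing))
    message(length(missing), " design(s) lack complete records: ",
            paste(utils::head(missing, 5), collapse = ", "))
  dm
}
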