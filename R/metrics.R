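## Five volume-averaged design metrics over the spheroid, transport-mode
## classification, min-max normalization and clustered design heatmaps.

METRIC_NAMES <- c("concentration", "velocity", "shear_rate",
                  "advective_flux", "diffusive_flux")

#' Volume average of a field over a labeled region
#'
#' sum(field * voxel volume) / sum(voxel volume) over the voxels carrying the
#' region label. The grid is isotropic, so this reduces to the arithmetic
#' mean over the region's voxels.
#'
#' @param field cell array congruent with the grid.
#' @param grid a [build_domain()] grid.
#' @param label a region name from [REGIONS].
#' @return The volume-averaged value.
#' @export
volume_average <- function(field, grid, label) {
  if (!label %in% names(REGIONS))
    stop("unknown region label '", label, "'")
  if (!identical(dim(field), dim(grid$labels)))
    stop("field and grid are not congruent")
  m <- grid$labels == REGIONS[[label]]
  if (!any(m)) stop("region '", label, "' is empty in this grid")
  mean(field[m])
}

#' Extract the five design metrics of a simulated design
#'
#' Volume averages over the spheroid region at the evaluation time:
#' concentration, velocity magnitude, shear rate, and the magnitudes of the
#' advective and diffusive flux vectors.
#'
#' @param flow the converged [solve_flow()] field.
#' @param history the [solve_transport()] history (must hold a checkpoint at
#'   `evaluation_time`).
#' @param evaluation_time metric evaluation time (s).
#' @return An object of class `metric_vector`: named numeric of length 5,
#'   with the total-flux volume average attached as attribute `total_flux`.
#' @export
compute_metrics <- function(flow, history, evaluation_time) {
  grid <- flow$grid
  conc <- checkpoint_field(history, evaluation_time)
  fl <- flux_fields(conc, flow, history$props)
  cz <- conc; cz[is.na(cz)] <- 0
  m <- c(concentration = volume_average(cz, grid, "SPHEROID"),
         velocity = volume_average(cell_velocity(flow)$speed, grid,
                                   "SPHEROID"),
         shear_rate = volume_average(shear_rate_field(flow), grid,
                                     "SPHEROID"),
         advective_flux = volume_average(fl$adv_mag, grid, "SPHEROID"),
         diffusive_flux = volume_average(fl$dif_mag, grid, "SPHEROID"))
  if (any(!is.finite(m)) || any(m < 0))
    stop("metric extraction produced non-finite or negative values")
  structure(m, total_flux = volume_average(fl$tot_mag, grid, "SPHEROID"),
            evaluation_time = evaluation_time, class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("Design metrics at t = %g s (volume averages over spheroid)\n",
              attr(x, "evaluation_time")))
  for (n in METRIC_NAMES) cat(sprintf("  %-15s %.6g\n", n, x[[n]]))
  cat(sprintf("  %-15s %.6g\n", "total_flux", attr(x, "total_flux")))
  cat(sprintf("  mode: %s\n", classify_transport_mode(x)))
  invisible(x)
}

#' Classify the dominant transport mode
#'
#' A mode is dominant when its volume-averaged flux is at least 10x the
#' other mode's (boundary inclusive); otherwise the design is mixed-mode.
#'
#' @param metrics a [compute_metrics()] vector, or any numeric with
#'   `advective_flux` and `diffusive_flux` entries.
#' @param ratio_threshold dominance threshold (default 10).
#' @return `"ADVECTION_DOMINANT"`, `"DIFFUSION_DOMINANT"` or `"MIXED"`.
#' @export
classify_transport_mode <- function(metrics, ratio_threshold = 10) {
  adv <- metrics[["advective_flux"]]; dif <- metrics[["diffusive_flux"]]
  if (adv < 0 || dif < 0) stop("flux metrics must be non-negative")
  if (adv == 0 && dif == 0)
    stop("undefined transport mode: both fluxes are zero")
  r <- max(adv, dif) / min(adv, dif)
  if (is.infinite(r) || r >= ratio_threshold) {
    if (adv >= dif) "ADVECTION_DOMINANT" else "DIFFUSION_DOMINANT"
  } else "MIXED"
}

#' Min-max normalize metric columns to [0, 1]
#'
#' Per column: (x - min) / (max - min). A constant column maps to all zeros
#' (the deterministic convention used for the design heatmaps).
#'
#' @param mat numeric matrix (designs x metrics).
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1L) stop("need at least one row")
  out <- apply(mat, 2, function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat))
  dimnames(out) <- dimnames(mat)
  out
}

#' Assemble a design matrix from raw metric rows
#'
#' @param raw numeric matrix or data frame (designs x 5 metrics), rownames =
#'   design names.
#' @param evaluation_time metric evaluation time (s).
#' @param scenario flow-rate scenario label (e.g. `"equal"`, `"unequal"`).
#' @return An object of class `design_matrix` with `raw` and `normalized`
#'   member matrices.
#' @export
design_matrix <- function(raw, evaluation_time = NA_real_,
                          scenario = NA_character_) {
  raw <- as.matrix(raw)
  structure(list(raw = raw, normalized = minmax_normalize(raw),
                 evaluation_time = evaluation_time, scenario = scenario),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d designs x %d metrics (scenario %s, t = %g s)\n",
              nrow(x$raw), ncol(x$raw), x$scenario, x$evaluation_time))
  print(utils::head(signif(x$normalized, 3)))
  if (nrow(x$raw) > 6) cat("  ...\n")
  invisible(x)
}

#' Hierarchically cluster designs (complete linkage, Euclidean)
#'
#' Agglomerative clustering of the normalized metric rows with the
#' farthest-point (complete) linkage rule on Euclidean distances, as used
#' for the clustered design heatmaps. Tie handling is deterministic (input
#' row order), so leaf orders are bit-reproducible across runs.
#'
#' @param dm a [design_matrix()] (its normalized matrix is clustered) or a
#'   plain numeric matrix with at least 2 rows.
#' @return An object of class `design_linkage`: the merge list
#'   (`merge`, `height` as in [stats::hclust()]), the leaf `order`, and the
#'   row labels.
#' @export
cluster_designs <- function(dm) {
  mat <- if (inherits(dm, "design_matrix")) dm$normalized else as.matrix(dm)
  if (nrow(mat) < 2L) stop("need at least 2 designs to cluster")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = rownames(mat), hclust = hc),
            class = "design_linkage")
}

#' @export
print.design_linkage <- function(x, ...) {
  cat(sprintf("Design linkage tree: %d leaves, %d merges (complete linkage)\n",
              length(x$order), length(x$height)))
  cat(sprintf("  merge heights: %s\n",
              paste(signif(x$height, 3), collapse = ", ")))
  invisible(x)
}

## simple perceptually ordered color ramp for the heatmap raster
heat_ramp <- grDevices::colorRamp(c("#440154", "#31688E", "#35B779",
                                    "#FDE725"))

#' Export a clustered design heatmap
#'
#' Writes (a) the normalized matrix as CSV in clustered row order (values at
#' 17 significant digits, so re-reading reproduces them bit-exactly), (b)
#' the merge list as CSV (`step,left,right,height,size`; negative left/right
#' are leaf indices as in [stats::hclust()]), and (c) a raster heatmap PNG
#' whose pixel dimensions scale with the matrix shape.
#'
#' @param dm a [design_matrix()].
#' @param tree the matching [cluster_designs()] linkage.
#' @param prefix output path prefix; writes `<prefix>_matrix.csv`,
#'   `<prefix>_merges.csv`, `<prefix>_heatmap.png`.
#' @param cell_px pixels per matrix cell in the raster.
#' @return Named character vector of the three paths, invisibly.
#' @export
heatmap_export <- function(dm, tree, prefix, cell_px = 8L) {
  stopifnot(inherits(dm, "design_matrix"), inherits(tree, "design_linkage"))
  ord <- tree$order
  mat <- dm$normalized[ord, , drop = FALSE]
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_mat <- paste0(prefix, "_matrix.csv")
  p_mrg <- paste0(prefix, "_merges.csv")
  p_png <- paste0(prefix, "_heatmap.png")

  df <- data.frame(name = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat)))
    df[[colnames(mat)[j]]] <- formatC(mat[, j], digits = 17, format = "g")
  ok <- tryCatch({
    utils::write.csv(df, p_mat, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write heatmap matrix CSV to ", p_mat)

  sizes <- integer(length(tree$height))
  csize <- function(k) if (k < 0) 1L else sizes[k]
  for (s in seq_along(tree$height))
    sizes[s] <- csize(tree$merge[s, 1]) + csize(tree$merge[s, 2])
  utils::write.csv(data.frame(step = seq_along(tree$height),
                              left = tree$merge[, 1],
                              right = tree$merge[, 2],
                              height = tree$height, size = sizes),
                   p_mrg, row.names = FALSE, quote = FALSE)

  rgb <- heat_ramp(as.vector(t(mat))) / 255   # row-major over matrix
  img <- array(0, c(nrow(mat), ncol(mat), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[, ch], nrow(mat), ncol(mat), byrow = TRUE)
  big <- img[rep(seq_len(nrow(mat)), each = cell_px),
             rep(seq_len(ncol(mat)), each = cell_px), , drop = FALSE]
  png::writePNG(big, p_png)
  invisible(c(matrix = p_mat, merges = p_mrg, heatmap = p_png))
}

#' Query designs whose metric responds to the flow-rate ratio alone
#'
#' Finds geometries for which a chosen metric changes by at least
#' `min_factor` between the equal (`Q1 = Q2`) and unequal (`Q1 = 2 Q2`) flow
#' scenarios while every other metric stays within `max_other_factor` — the
#' design-selection pattern of the clustered heatmaps (e.g. a geometry that
#' achieves both low and high shear by changing the flow-rate ratio only).
#'
#' @param equal,unequal matrices of raw metrics (same rownames: geometry
#'   names; same metric columns) for the two flow scenarios.
#' @param metric the metric column to screen (e.g. `"shear_rate"`).
#' @param min_factor required fold change of `metric` (>= 1).
#' @param max_other_factor allowed fold change of every other metric (>= 1).
#' @return Character vector of matching geometry names (possibly empty).
#' @export
design_query <- function(equal, unequal, metric, min_factor,
                         max_other_factor = 1.2) {
  stopifnot(min_factor >= 1, max_other_factor >= 1)
  common <- intersect(rownames(equal), rownames(unequal))
  eq <- as.matrix(equal)[common, , drop = FALSE]
  un <- as.matrix(unequal)[common, , drop = FALSE]
  if (!metric %in% colnames(eq)) stop("unknown metric '", metric, "'")
  fold <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    ifelse(lo == 0, ifelse(hi == 0, 1, Inf), hi / lo)
  }
  f <- fold(eq[, metric], un[, metric])
  others <- setdiff(colnames(eq), metric)
  ok_other <- rep(TRUE, length(common))
  for (m in others) ok_other <- ok_other & fold(eq[, m], un[, m]) <= max_other_factor
  common[f >= min_factor & ok_other]
}
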