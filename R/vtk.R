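## Export of voxel fields to the legacy VTK ImageData (structured points)
## format, readable by ParaView and friends. ASCII, cell data.

#' Write grid fields to a legacy VTK structured-points file
#'
#' Writes the unit-cell grid with any number of cell fields: scalar fields
#' as arrays congruent with the grid, vector fields as lists of three such
#' arrays. The region labels are always included as an integer scalar field
#' `region`.
#'
#' @param grid a [build_domain()] grid.
#' @param path output `.vtk` path.
#' @param fields named list of cell fields (array, or list of 3 arrays for a
#'   vector field). `NA` values are written as 0.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(grid, path, fields = list()) {
  n <- grid$shape; h <- grid$spacing
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("spherochip unit-cell fields")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d %d", n[1] + 1L, n[2] + 1L, n[3] + 1L)
  wl("ORIGIN %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3])
  wl("SPACING %g %g %g", h, h, h)
  wl("CELL_DATA %d", prod(n))
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(paste(as.integer(grid$labels), collapse = " "), con)
  num <- function(a) {
    a[is.na(a)] <- 0
    paste(formatC(as.vector(a), format = "g", digits = 9), collapse = " ")
  }
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {
      stopifnot(length(f) == 3)
      wl("VECTORS %s double", nm)
      v <- cbind(as.vector(f[[1]]), as.vector(f[[2]]), as.vector(f[[3]]))
      v[is.na(v)] <- 0
      writeLines(paste(apply(v, 1, function(r)
        paste(formatC(r, format = "g", digits = 9), collapse = " ")),
        collapse = "\n"), con)
    } else {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(num(f), con)
    }
  }
  invisible(path)
}

#' Export a solved flow field to VTK
#'
#' Cell-centered velocity vector, pressure and shear rate.
#'
#' @param flow a [solve_flow()] field.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_flow <- function(flow, path) {
  cv <- cell_velocity(flow)
  write_vtk_image(flow$grid, path,
                  fields = list(velocity = list(cv$ux, cv$uy, cv$uz),
                                pressure = flow$p,
                                shear_rate = shear_rate_field(flow)))
}
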