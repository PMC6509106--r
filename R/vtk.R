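#' Export grid fields as a legacy VTK structured-points file
#'
#' Writes one or more cell fields (theta, h, concentration, WUD, ...) of a
#' `soil_grid` as an ASCII VTK `STRUCTURED_POINTS` dataset with cell data,
#' readable by ParaView and pyvista. Out-of-mask cells carry -9999.
#'
#' @param grid a `soil_grid`.
#' @param fields named list of 3-d arrays on the grid.
#' @param path output file path.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(grid, fields, path, title = "rootflux fields") {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  dx <- grid$dx
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    title,
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", grid$nx + 1, grid$ny + 1, grid$nz + 1),
    sprintf("ORIGIN %g %g %g", -grid$nx * dx / 2, -grid$ny * dx / 2,
            -grid$height),
    sprintf("SPACING %g %g %g", dx, dx, dx),
    sprintf("CELL_DATA %d", grid$nx * grid$ny * grid$nz)
  ), con)
  for (nm in names(fields)) {
    a <- fields[[nm]]
    a[is.na(a)] <- -9999
    # VTK expects x fastest, z slowest, with z increasing upward:
    # our layer 1 is the top, so reverse the z order
    a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(formatC(as.vector(a), format = "g", digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export a grid field as a long CSV (one row per masked voxel)
#'
#' @param grid a `soil_grid`.
#' @param fields named list of 3-d arrays.
#' @param path output file.
#' @export
write_field_csv <- function(grid, fields, path) {
  idx <- which(grid$mask)
  ijk <- arrayInd(idx, dim(grid$mask))
  out <- tibble(x_cm = grid$xc[ijk[, 1]], y_cm = grid$yc[ijk[, 2]],
                z_cm = grid$zc[ijk[, 3]])
  for (nm in names(fields)) out[[nm]] <- fields[[nm]][idx]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
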