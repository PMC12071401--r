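#' Write run diagnostics as tidy CSV
#'
#' One row per output time, SI units throughout (heights m, masses kg,
#' temperatures K, pressure Pa).
#'
#' @param run a `bake_run`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_diagnostics_csv <- function(run, path) {
  utils::write.csv(run$diagnostics, path, row.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as legacy ASCII VTK
#'
#' Structured axisymmetric (r, z) grid with the deformed column heights;
#' cell data: temperature, dry-basis moisture, porosity, pore-opening
#' fraction, gas pressure and effective conductivity. Readable by ParaView
#' and meshio.
#'
#' @param snap one element of `run$snapshots`.
#' @param grid the run's final `bake_grid` (supplies the radial layout).
#' @param path output `.vtk` file.
#' @return the path, invisibly.
#' @export
write_vtk_snapshot <- function(snap, grid, path) {
  nr <- grid$nr; nz <- grid$nz
  h <- snap$h
  # node heights per column boundary: average adjacent columns' cumulative z
  zc <- rbind(0, apply(h, 1, cumsum))            # (nz+1) x nr, per column
  zn <- matrix(0, nz + 1L, nr + 1L)
  zn[, 1] <- zc[, 1]; zn[, nr + 1L] <- zc[, nr]
  if (nr > 1L) for (i in 2:nr) zn[, i] <- 0.5 * (zc[, i - 1L] + zc[, i])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "crumbsim snapshot", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nr + 1L, nz + 1L),
               sprintf("POINTS %d float", (nr + 1L) * (nz + 1L))), con)
  for (k in seq_len(nz + 1L))
    for (i in seq_len(nr + 1L))
      writeLines(sprintf("%g %g 0", grid$r_face[i], zn[k, i]), con)
  writeLines(sprintf("CELL_DATA %d", nr * nz), con)
  fields <- list(temperature_K = snap$T, moisture_drybasis = snap$W,
                 porosity = snap$f_vg, pore_open = snap$alpha,
                 gas_pressure_Pa = snap$P_g,
                 conductivity_W_mK = snap$lambda_eff)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", as.vector(fields[[nm]])), con)  # column-major = r fastest
  }
  invisible(path)
}
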