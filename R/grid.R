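#' Axisymmetric column grid
#'
#' Structured cell-centred finite-volume grid for a cylindrical dough in a
#' mold: `nr` annular columns (uniform in radius) each carrying `nz` cells of
#' individual height. Because the mold blocks radial displacement, mesh
#' motion is vertical and column-wise (each cell is a material slab whose
#' height evolves with the local volumetric strain rate), which makes the
#' grid its own ALE map: cell masses are conserved identically under motion.
#' The reduced 1-D axial mode is the `nr = 1` special case.
#'
#' Boundary tags are implicit in the structure: `k = 1` faces the mold
#' bottom, `k = nz` the oven air, `i = 1` the symmetry axis (zero radial
#' flux), `i = nr` the mold side wall.
#'
#' @param mode `"axisym2d"` or `"axial1d"`.
#' @param nr,nz cell counts (radial, axial); `nr` is forced to 1 in 1-D mode.
#' @param radius mold inner radius, m.
#' @param height initial dough height, m.
#' @param mold_height mold height, m; columns cannot grow beyond it.
#' @return object of class `bake_grid`.
#' @export
make_grid <- function(mode = c("axisym2d", "axial1d"), nr = 10, nz = 20,
                      radius = 0.05, height = 0.020, mold_height = 0.100) {
  mode <- match.arg(mode)
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  if (mode == "axial1d") nr <- 1L
  nr <- as.integer(nr); nz <- as.integer(nz)
  if (nr < 1L || nz < 2L) stop("need nr >= 1 and nz >= 2")
  r_face <- seq(0, radius, length.out = nr + 1L)
  r <- 0.5 * (r_face[-1] + r_face[-(nr + 1L)])
  A_z <- pi * (r_face[-1]^2 - r_face[-(nr + 1L)]^2)   # annulus areas, m^2
  h <- matrix(height / nz, nr, nz)
  structure(list(
    mode = mode, nr = nr, nz = nz, radius = radius,
    height0 = height, mold_height = mold_height,
    r = r, r_face = r_face, dr = radius / nr, A_z = A_z,
    h = h, dz0 = height / nz
  ), class = "bake_grid")
}

#' Cell volumes of a column grid
#' @param grid a [make_grid()] object.
#' @return `nr x nz` matrix of volumes, m^3.
#' @export
cell_volumes <- function(grid) {
  grid$A_z * grid$h   # A_z recycles down columns (nr x nz)
}

#' Column heights (free-surface position per column)
#' @param grid a [make_grid()] object.
#' @return numeric vector of length `nr`, m.
#' @export
column_heights <- function(grid) rowSums(grid$h)

#' @export
print.bake_grid <- function(x, ...) {
  cat(sprintf("<bake_grid> %s, %d x %d cells, R = %g m, height %s m (initial %g)\n",
              x$mode, x$nr, x$nz, x$radius,
              paste(signif(range(column_heights(x)), 4), collapse = ".."),
              x$height0))
  invisible(x)
}

# Vertical face distances between cell centres within each column:
# nr x (nz-1) matrix.
vertical_spacing <- function(grid) {
  h <- grid$h
  0.5 * (h[, -grid$nz, drop = FALSE] + h[, -1, drop = FALSE])
}

# Lateral face area between column i and i+1 at layer k, using the mean of
# the two cell heights: (nr-1) x nz matrix. Zero-row matrix when nr = 1.
radial_face_areas <- function(grid) {
  if (grid$nr < 2L) return(matrix(0, 0, grid$nz))
  rf <- grid$r_face[2:grid$nr]
  hm <- 0.5 * (grid$h[-grid$nr, , drop = FALSE] + grid$h[-1, , drop = FALSE])
  2 * pi * rf * hm
}

# Outer side-wall area per layer of the outermost column (length nz).
side_wall_areas <- function(grid) 2 * pi * grid$radius * grid$h[grid$nr, ]
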