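# Phantom geometry and voxel rendering.

#' Phantom specification
#'
#' A contrast sphere fixed in a water-filled insert, oscillating along the
#' superior-inferior (SI) axis.  The sphere's T1-weighted signal is
#' `contrast_ratio` times the surrounding water, emulating a contrast-filled
#' lesion in healthy tissue.
#'
#' @param sphere_diameter_mm Sphere diameter in mm (default 30).
#' @param contrast_ratio Sphere-to-background intensity ratio (> 1,
#'   default 1.5).
#' @param background_level Water signal level in arbitrary units.
#' @param sphere_center_rest_mm Rest position of the sphere centre, mm
#'   triplet in volume axes (x, y, slice).
#' @param bath_diameter_mm Extent of the water bath used by the MR forward
#'   model (the signal-producing region around the sphere), mm.  Voxel
#'   rendering treats the background as uniform unless `bath = TRUE` is
#'   requested in [render_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(sphere_diameter_mm = 30, contrast_ratio = 1.5,
                         background_level = 1.0,
                         sphere_center_rest_mm = c(0, 0, 0),
                         bath_diameter_mm = 80) {
  if (sphere_diameter_mm <= 0) stop("sphere diameter must be > 0",
                                    call. = FALSE)
  if (contrast_ratio <= 1) stop("contrast ratio must exceed 1",
                                call. = FALSE)
  structure(list(sphere_diameter_mm = sphere_diameter_mm,
                 contrast_ratio = contrast_ratio,
                 background_level = background_level,
                 sphere_center_rest_mm = sphere_center_rest_mm,
                 bath_diameter_mm = bath_diameter_mm,
                 motion_axis = "SI"),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %g mm sphere, contrast %g:1, background %g, SI motion\n",
    x$sphere_diameter_mm, x$contrast_ratio, x$background_level))
  invisible(x)
}

#' Image grid geometry
#'
#' In-plane voxel centres sit at `(i - 0.5) * voxel - fov/2`; slice centres
#' at `(p - 0.5) * thickness - slab/2`.  The SI axis is the in-plane row
#' axis (dim 2) for coronal volumes and the slice axis (dim 3) for axial
#' volumes.
#'
#' @param matrix In-plane matrix size (power of two).
#' @param fov_mm In-plane field of view, mm.
#' @param n_slices Number of slices.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param orientation `"axial"` or `"coronal"`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(matrix = 128, fov_mm = 300, n_slices = 30,
                       slice_thickness_mm = 3,
                       orientation = c("axial", "coronal")) {
  orientation <- match.arg(orientation)
  if (bitwAnd(matrix, matrix - 1L) != 0L || matrix < 8L) {
    stop("`matrix` must be a power of two (>= 8)", call. = FALSE)
  }
  if (slice_thickness_mm <= 0) stop("slice thickness must be > 0",
                                    call. = FALSE)
  vox <- fov_mm / matrix
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 n_slices = as.integer(n_slices),
                 slice_thickness_mm = slice_thickness_mm,
                 slab_mm = n_slices * slice_thickness_mm,
                 voxel_mm = c(vox, vox, slice_thickness_mm),
                 orientation = orientation),
            class = "image_grid")
}

# voxel centre coordinates (mm) along each volume axis
grid_axes <- function(grid) {
  N <- grid$matrix
  P <- grid$n_slices
  vox <- grid$voxel_mm
  list(x = (seq_len(N) - 0.5) * vox[1L] - grid$fov_mm / 2,
       y = (seq_len(N) - 0.5) * vox[2L] - grid$fov_mm / 2,
       z = (seq_len(P) - 0.5) * vox[3L] - grid$slab_mm / 2)
}

# which volume axis is superior-inferior
si_axis <- function(orientation) {
  if (orientation == "coronal") 2L else 3L
}

# partial-volume fraction of each voxel inside a sphere.  Interior and
# exterior voxels are classified by centre distance; voxels straddling the
# surface are supersampled on an s^3 sub-grid.
sphere_pv <- function(grid, center_mm, radius_mm, s = 5L) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center_mm[1L])^2
  dy2 <- (ax$y - center_mm[2L])^2
  dz2 <- (ax$z - center_mm[3L])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  half_diag <- sqrt(sum(grid$voxel_mm^2)) / 2
  pv <- (d2 <= radius_mm^2) * 1.0
  band <- which(abs(sqrt(d2) - radius_mm) <= half_diag)
  if (length(band)) {
    dims <- dim(d2)
    idx <- arrayInd(band, dims)
    cx <- ax$x[idx[, 1L]] - center_mm[1L]
    cy <- ax$y[idx[, 2L]] - center_mm[2L]
    cz <- ax$z[idx[, 3L]] - center_mm[3L]
    off <- ((seq_len(s) - 0.5) / s - 0.5)
    frac <- numeric(length(band))
    r2 <- radius_mm^2
    for (ox in off) for (oy in off) for (oz in off) {
      frac <- frac + ((cx + ox * grid$voxel_mm[1L])^2 +
                      (cy + oy * grid$voxel_mm[2L])^2 +
                      (cz + oz * grid$voxel_mm[3L])^2 <= r2)
    }
    pv[band] <- frac / s^3
  }
  pv
}

#' Render the phantom at a given SI displacement
#'
#' Produces a 3D intensity volume: uniform water background plus the
#' contrast-sphere excess, with partial-volume anti-aliasing at the sphere
#' surface (boundary voxels are supersampled against the analytic sphere).
#'
#' @param position_mm SI displacement of the sphere from its rest centre,
#'   mm.
#' @param spec A [phantom_spec()].
#' @param grid An [image_grid()].
#' @param bath If `TRUE`, the background is rendered as the finite water
#'   bath sphere of `spec$bath_diameter_mm` (the object the MR forward
#'   model sees) instead of a uniform background.
#' @return A 3D array `matrix x matrix x n_slices`.
#' @export
render_phantom <- function(position_mm, spec, grid, bath = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "image_grid"))
  R <- spec$sphere_diameter_mm / 2
  center <- spec$sphere_center_rest_mm
  center[si_axis(grid$orientation)] <-
    center[si_axis(grid$orientation)] + position_mm
  ext <- c(grid$fov_mm / 2, grid$fov_mm / 2, grid$slab_mm / 2)
  if (any(abs(center) + R > ext)) {
    stop("out of field: sphere leaves the imaging volume", call. = FALSE)
  }
  excess <- (spec$contrast_ratio - 1) * spec$background_level
  pv <- sphere_pv(grid, center, R)
  if (bath && is.finite(spec$bath_diameter_mm)) {
    bg_pv <- sphere_pv(grid, spec$sphere_center_rest_mm,
                       spec$bath_diameter_mm / 2)
    vol <- spec$background_level * bg_pv + excess * pv
  } else {
    vol <- spec$background_level + excess * pv
  }
  vol
}
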