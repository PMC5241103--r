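#' Regular 3D grid geometry
#'
#' A `volume_grid` describes the geometry shared by all volumes in a plan:
#' the number of voxels per axis, the physical voxel spacing in mm, and the
#' world coordinate (mm) of the *center* of voxel `(0, 0, 0)`. Voxel indices
#' are 0-based; world coordinates are right-handed with axes aligned to the
#' grid (a fixed RAS-like convention enforced on load).
#'
#' @param shape Integer vector of length 3: voxels per axis (each >= 1).
#' @param spacing Numeric vector of length 3: mm per voxel along each axis
#'   (each > 0).
#' @param origin Numeric vector of length 3: world mm of the center of voxel
#'   (0,0,0). Default `c(0, 0, 0)`.
#' @return A `volume_grid` object.
#' @examples
#' g <- volume_grid(c(10, 10, 10), c(4.4, 4.4, 5.6))
#' voxel_volume_cm3(g)
#' @export
volume_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("grid shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         orientation = "RAS"),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid in cubic centimeters
#'
#' @param grid A [volume_grid()].
#' @return `prod(spacing) / 1000`, in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$spacing) / 1000
}

#' World coordinates of voxel centers along one axis
#'
#' @param grid A [volume_grid()].
#' @param axis Axis index 1, 2 or 3.
#' @return Numeric vector of world mm positions of voxel centers.
#' @export
grid_axis_mm <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' World extent of a grid
#'
#' Returns the world-mm bounding box spanned by voxel centers.
#'
#' @param grid A [volume_grid()].
#' @return A 2 x 3 matrix with rows `min`, `max`.
#' @export
grid_extent_mm <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  m <- rbind(min = lo, max = hi)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Test whether two grids share geometry
#'
#' @param a,b [volume_grid()] objects.
#' @param tol Absolute tolerance in mm for spacing/origin comparison.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "operation") {
  if (!same_grid(grid_of(a), grid_of(b)))
    stop(sprintf("%s requires both volumes on the same grid; resample explicitly first", what))
  invisible(TRUE)
}

#' Voxel-center world coordinates for all voxels of a grid
#'
#' Returns coordinates in array (column-major) order, matching the storage
#' order of `scalar_map` and `smri_mask` values.
#'
#' @param grid A [volume_grid()].
#' @return An n x 3 matrix of world mm coordinates.
#' @export
grid_coordinates_mm <- function(grid) {
  xs <- grid_axis_mm(grid, 1)
  ys <- grid_axis_mm(grid, 2)
  zs <- grid_axis_mm(grid, 3)
  n <- prod(grid$shape)
  cbind(
    x = rep(xs, times = n / grid$shape[1]),
    y = rep(rep(ys, each = grid$shape[1]), times = grid$shape[3]),
    z = rep(zs, each = grid$shape[1] * grid$shape[2])
  )
}
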