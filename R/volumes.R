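#' Scalar field on a 3D grid
#'
#' A `scalar_map` couples a 3D numeric array with its [volume_grid()] and a
#' unit tag. Invalid voxels (outside the acquisition support, failed fits,
#' division guards) are flagged in an explicit companion logical array
#' `valid`, never encoded as sentinel values: statistics over reference
#' regions must exclude them, not dilute them. Values at invalid voxels are
#' stored as `NA`.
#'
#' @param values Numeric 3D array (dimensions must equal `grid$shape`).
#' @param grid A [volume_grid()].
#' @param unit Unit tag: `"arbitrary"` (raw signal), `"fold-normal"`, or
#'   `"Gy"`.
#' @param valid Optional logical array of the same shape; defaults to
#'   `is.finite(values)`.
#' @return A `scalar_map` object.
#' @export
scalar_map <- function(values, grid,
                       unit = c("arbitrary", "fold-normal", "Gy"),
                       valid = NULL) {
  unit <- match.arg(unit)
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("scalar_map values must be a 3D array")
  if (is.null(dim(values)) || !all(dim(values) == grid$shape))
    stop("scalar_map values dimensions must match grid shape")
  storage.mode(values) <- "double"
  if (is.null(valid)) {
    valid <- is.finite(values)
  } else {
    valid <- as.array(valid)
    if (!all(dim(valid) == grid$shape))
      stop("validity mask dimensions must match grid shape")
    storage.mode(valid) <- "logical"
    valid <- valid & is.finite(values)
  }
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, grid = grid, unit = unit),
            class = "scalar_map")
}

#' Binary region on a 3D grid
#'
#' @param membership Logical 3D array (dimensions equal to `grid$shape`).
#'   Numeric 0/1 arrays are accepted and coerced.
#' @param grid A [volume_grid()].
#' @param label Name of the structure (e.g. `"GTV2"`, `"brainstem"`).
#' @return An `smri_mask` object.
#' @export
smri_mask <- function(membership, grid, label = "") {
  stopifnot(inherits(grid, "volume_grid"))
  membership <- as.array(membership)
  if (length(dim(membership)) != 3L)
    stop("mask membership must be a 3D array")
  if (!all(dim(membership) == grid$shape))
    stop("mask dimensions must match grid shape")
  if (is.numeric(membership)) {
    u <- unique(as.vector(membership))
    if (!all(u %in% c(0, 1)))
      stop("numeric mask content must be 0/1")
  }
  storage.mode(membership) <- "logical"
  membership[is.na(membership)] <- FALSE
  structure(list(membership = membership, grid = grid,
                 label = as.character(label)),
            class = "smri_mask")
}

grid_of <- function(x) {
  if (inherits(x, "volume_grid")) return(x)
  x$grid
}

#' @export
print.scalar_map <- function(x, ...) {
  rng <- if (any(x$valid)) range(x$values[x$valid]) else c(NA, NA)
  cat(sprintf("<scalar_map> unit '%s', %d/%d valid voxels, range [%.4g, %.4g]\n",
              x$unit, sum(x$valid), length(x$valid), rng[1], rng[2]))
  print(x$grid)
  invisible(x)
}

#' @export
print.smri_mask <- function(x, ...) {
  cat(sprintf("<smri_mask> '%s', %d member voxels, %.3f cm^3\n",
              x$label, sum(x$membership), volume_cm3(x)))
  print(x$grid)
  invisible(x)
}

#' Set algebra on masks
#'
#' Union, intersection and set difference of masks sharing a grid. No
#' implicit resampling is performed: a grid mismatch is an error.
#'
#' @param a,b `smri_mask` objects on the same grid.
#' @param label Label for the result.
#' @return An `smri_mask`.
#' @export
mask_union <- function(a, b, label = a$label) {
  stop_if_grid_mismatch(a, b, "mask_union")
  smri_mask(a$membership | b$membership, a$grid, label)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b, label = a$label) {
  stop_if_grid_mismatch(a, b, "mask_intersect")
  smri_mask(a$membership & b$membership, a$grid, label)
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b, label = a$label) {
  stop_if_grid_mismatch(a, b, "mask_difference")
  smri_mask(a$membership & !b$membership, a$grid, label)
}

#' Test whether one mask is contained in another
#'
#' @param a,b `smri_mask` objects on the same grid.
#' @return Logical scalar: `TRUE` if every member voxel of `a` is in `b`.
#' @export
mask_subset <- function(a, b) {
  stop_if_grid_mismatch(a, b, "mask_subset")
  !any(a$membership & !b$membership)
}
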