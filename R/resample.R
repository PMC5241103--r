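#' Trilinear resampling between grids
#'
#' Resamples a scalar map onto a destination grid by trilinear
#' interpolation in world coordinates: each destination voxel center is
#' located in the source grid and interpolated from the 8 surrounding
#' source voxel centers. This is the operation that carries metabolite maps
#' from the coarse spectroscopic grid into the fine clinical planning grid.
#'
#' Destination voxels falling outside the source support, or whose
#' interpolation stencil touches an invalid source voxel, are flagged
#' invalid in the output. Interpolation is exact on affine fields and the
#' result is always bounded by the min/max of the 8 stencil values.
#'
#' @param src A [scalar_map()].
#' @param dst_grid Destination [volume_grid()].
#' @return A [scalar_map()] on `dst_grid` with the same unit tag. If the
#'   grids share no world-space overlap the output is all-invalid and a
#'   warning is raised.
#' @export
resample_trilinear <- function(src, dst_grid) {
  stopifnot(inherits(src, "scalar_map"), inherits(dst_grid, "volume_grid"))
  sg <- src$grid
  ns <- sg$shape
  nd <- dst_grid$shape

  # fractional source index of destination voxel centers, per axis
  u <- lapply(1:3, function(a)
    (grid_axis_mm(dst_grid, a) - sg$origin[a]) / sg$spacing[a])
  in_support <- lapply(1:3, function(a) u[[a]] >= 0 & u[[a]] <= ns[a] - 1)

  if (!any(in_support[[1]]) || !any(in_support[[2]]) || !any(in_support[[3]])) {
    warning("destination grid lies entirely outside the source support")
    vals <- array(NA_real_, nd)
    return(scalar_map(vals, dst_grid, unit = src$unit,
                      valid = array(FALSE, nd)))
  }

  i0 <- lapply(1:3, function(a) pmin(pmax(floor(u[[a]]), 0), ns[a] - 2))
  tfr <- lapply(1:3, function(a) u[[a]] - i0[[a]])

  rep3 <- function(vs, axis) {
    if (axis == 1) rep(vs, times = nd[2] * nd[3])
    else if (axis == 2) rep(rep(vs, each = nd[1]), times = nd[3])
    else rep(vs, each = nd[1] * nd[2])
  }
  ix <- rep3(i0[[1]], 1); iy <- rep3(i0[[2]], 2); iz <- rep3(i0[[3]], 3)
  tx <- rep3(tfr[[1]], 1); ty <- rep3(tfr[[2]], 2); tz <- rep3(tfr[[3]], 3)
  ok <- rep3(in_support[[1]], 1) & rep3(in_support[[2]], 2) &
    rep3(in_support[[3]], 3)

  sv <- src$values
  sv[!src$valid] <- NA_real_
  corner <- function(dx, dy, dz) {
    idx <- (ix + dx) + ns[1] * ((iy + dy) + ns[2] * (iz + dz)) + 1
    sv[idx]
  }
  wx0 <- 1 - tx; wy0 <- 1 - ty; wz0 <- 1 - tz
  val <-
    corner(0, 0, 0) * wx0 * wy0 * wz0 + corner(1, 0, 0) * tx * wy0 * wz0 +
    corner(0, 1, 0) * wx0 * ty * wz0 + corner(1, 1, 0) * tx * ty * wz0 +
    corner(0, 0, 1) * wx0 * wy0 * tz + corner(1, 0, 1) * tx * wy0 * tz +
    corner(0, 1, 1) * wx0 * ty * tz + corner(1, 1, 1) * tx * ty * tz
  valid <- ok & is.finite(val)
  val[!valid] <- NA_real_
  scalar_map(array(val, nd), dst_grid, unit = src$unit,
             valid = array(valid, nd))
}
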