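#' Planar-contour structure sets
#'
#' A `structure_set` holds named regions as stacked closed planar polygons
#' (vertices in world mm), grouped by axial slice position — the geometry
#' carried by clinical RT structure files. The on-disk form is a documented
#' JSON dialect (see [write_structures()]); rasterization into a grid uses
#' voxel-center inclusion with the even–odd rule, so nested polygons
#' subtract (holes).
#'
#' @param structures A named list. Each element is a list of slices; each
#'   slice is a `list(z = <slice world mm>, polygons = <list of n x 2
#'   vertex matrices>)` with every polygon having at least 3 vertices.
#' @return A `structure_set` object.
#' @export
structure_set <- function(structures = list()) {
  stopifnot(is.list(structures))
  for (nm in names(structures)) {
    for (sl in structures[[nm]]) {
      stopifnot(is.numeric(sl$z), is.list(sl$polygons))
      for (p in sl$polygons) {
        p <- as.matrix(p)
        if (ncol(p) != 2 || nrow(p) < 3)
          stop("each polygon needs >= 3 (x, y) vertices (structure '", nm, "')")
      }
    }
  }
  structure(list(structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structure(s): %s\n",
              length(x$structures),
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

# even-odd (crossing number) point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Rasterize a structure set into a grid
#'
#' A voxel is a member iff its center lies inside the slice's polygons under
#' the even–odd rule, so a polygon nested inside another subtracts a hole.
#' Every polygon must lie on a slice plane of the target grid (within
#' `z_tol` mm); a non-coplanar polygon is an error, not silently snapped.
#'
#' @param s A [structure_set()].
#' @param grid Target [volume_grid()].
#' @param z_tol Max |z - slice center| in mm for coplanarity (default 1e-3).
#' @return A named list of [smri_mask()] objects, one per structure. An
#'   empty structure set yields an empty list.
#' @export
rasterize_structure <- function(s, grid, z_tol = 1e-3) {
  stopifnot(inherits(s, "structure_set"), inherits(grid, "volume_grid"))
  xs <- grid_axis_mm(grid, 1)
  ys <- grid_axis_mm(grid, 2)
  zs <- grid_axis_mm(grid, 3)
  px <- rep(xs, times = grid$shape[2])
  py <- rep(ys, each = grid$shape[1])
  out <- list()
  for (nm in names(s$structures)) {
    mem <- array(FALSE, grid$shape)
    for (sl in s$structures[[nm]]) {
      k <- which(abs(zs - sl$z) <= z_tol)
      if (length(k) != 1L)
        stop(sprintf(
          "polygon of '%s' at z = %.4f mm is not coplanar with a unique grid slice",
          nm, sl$z))
      parity <- logical(length(px))
      for (p in sl$polygons)
        parity <- xor(parity, points_in_polygon(px, py, as.matrix(p)))
      mem[, , k] <- mem[, , k] | array(parity, grid$shape[1:2])
    }
    out[[nm]] <- smri_mask(mem, grid, label = nm)
  }
  out
}

#' Extract planar contours from a mask
#'
#' Traces iso-contours of the membership indicator at level 0.5 on each
#' axial slice (marching squares via [grDevices::contourLines()]), giving
#' closed polygons in world mm. Rasterizing the result back onto the mask's
#' grid reproduces the mask with Dice >= 0.99 for masks whose smallest
#' feature spans at least ~3 voxels.
#'
#' @param m An [smri_mask()].
#' @return A [structure_set()] with one structure named after the mask's
#'   label (or `"structure"` if unlabelled). An empty mask yields an empty
#'   structure set.
#' @export
extract_contours <- function(m) {
  stopifnot(inherits(m, "smri_mask"))
  if (!any(m$membership)) return(structure_set())
  nm <- if (nzchar(m$label)) m$label else "structure"
  g <- m$grid
  xs <- grid_axis_mm(g, 1)
  ys <- grid_axis_mm(g, 2)
  zs <- grid_axis_mm(g, 3)
  # pad with a zero border so contours around boundary-touching regions close
  xpad <- c(xs[1] - g$spacing[1], xs, xs[g$shape[1]] + g$spacing[1])
  ypad <- c(ys[1] - g$spacing[2], ys, ys[g$shape[2]] + g$spacing[2])
  slices <- list()
  for (k in seq_len(g$shape[3])) {
    sl <- m$membership[, , k]
    if (!any(sl)) next
    mat <- matrix(0, length(xpad), length(ypad))
    mat[2:(g$shape[1] + 1), 2:(g$shape[2] + 1)] <- as.numeric(sl)
    cl <- grDevices::contourLines(xpad, ypad, mat, levels = 0.5)
    polys <- lapply(cl, function(cc) cbind(cc$x, cc$y))
    polys <- polys[vapply(polys, nrow, 1L) >= 3L]
    if (length(polys))
      slices[[length(slices) + 1L]] <- list(z = zs[k], polygons = polys)
  }
  st <- list()
  st[[nm]] <- slices
  structure_set(st)
}

#' Read and write structure sets as JSON
#'
#' The dialect is
#' `{"structures": [{"name": ..., "slices": [{"z": ..., "polygons":`
#' `[[[x, y], ...], ...]}]}]}` with all coordinates in world mm.
#'
#' @param s A [structure_set()].
#' @param path File path.
#' @return `write_structures()` returns `path` invisibly;
#'   `read_structures()` returns a [structure_set()].
#' @export
write_structures <- function(s, path) {
  stopifnot(inherits(s, "structure_set"))
  obj <- list(structures = lapply(names(s$structures), function(nm) {
    list(
      name = nm,
      slices = lapply(s$structures[[nm]], function(sl) {
        list(z = sl$z,
             polygons = lapply(sl$polygons, function(p) {
               p <- as.matrix(p)
               lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
             }))
      })
    )
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structures
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)
  st <- list()
  for (s in obj$structures) {
    slices <- lapply(s$slices, function(sl) {
      list(z = as.numeric(sl$z),
           polygons = lapply(sl$polygons, function(p) {
             do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
           }))
    })
    st[[s$name]] <- slices
  }
  structure_set(st)
}
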