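#' Read a NIfTI volume as a scalar map or mask
#'
#' Reads a 3D NIfTI-1 volume (`.nii` / `.nii.gz`) whose affine encodes voxel
#' spacing and origin. Only axis-aligned affines are supported; axis flips
#' and permutations are normalized on load to the package's fixed
#' right-handed, grid-aligned convention, so all downstream geometry is
#' orientation-safe. Oblique (rotated) affines are rejected.
#'
#' Mask content is detected automatically (all stored values in \{0, 1\}) or
#' forced with `as`.
#'
#' @param path Path to a NIfTI file.
#' @param as `"auto"` (detect masks by 0/1 content), `"mask"`, or
#'   `"scalar"`.
#' @param unit Unit tag attached when reading a scalar map.
#' @param label Label attached when reading a mask.
#' @return A [scalar_map()] or [smri_mask()].
#' @export
read_volume <- function(path, as = c("auto", "mask", "scalar"),
                        unit = "arbitrary", label = "") {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions: ", path)
  aff <- unclass(RNifti::xform(img))[1:3, , drop = FALSE]
  geo <- normalize_affine(aff, dim(arr), path)
  if (!is.null(geo$flip) || !is.null(geo$perm)) {
    for (j in which(geo$flipped)) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[j]] <- rev(seq_len(dim(arr)[j]))
      arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
    if (!identical(geo$perm, 1:3)) arr <- aperm(arr, geo$perm)
  }
  grid <- volume_grid(dim(arr), geo$spacing, geo$origin)
  vals <- as.vector(arr)
  is_binary <- all(vals[is.finite(vals)] %in% c(0, 1)) && any(is.finite(vals))
  if (as == "mask" || (as == "auto" && is_binary)) {
    if (!is_binary) stop("requested a mask but file content is not 0/1: ", path)
    m <- array(vals, dim(arr))
    m[!is.finite(m)] <- 0
    smri_mask(m != 0, grid, label)
  } else {
    scalar_map(array(vals, dim(arr)), grid, unit = unit)
  }
}

# Decompose an axis-aligned 3x4 affine into permutation/flips/spacing/origin.
normalize_affine <- function(aff, dims, path, tol = 1e-4) {
  A <- aff[, 1:3, drop = FALSE]
  t <- aff[, 4]
  perm <- integer(3)   # perm[i] = data axis feeding world axis i
  flipped <- logical(3)
  spacing <- numeric(3)
  for (i in 1:3) {
    nz <- which(abs(A[i, ]) > tol)
    if (length(nz) != 1L)
      stop("oblique or degenerate affine in ", path,
           "; only axis-aligned volumes are supported")
    perm[i] <- nz
    spacing[i] <- abs(A[i, nz])
    flipped[nz] <- A[i, nz] < 0
  }
  if (anyDuplicated(perm))
    stop("degenerate affine (repeated axis) in ", path)
  # world coordinate of the voxel that becomes index (0,0,0) after flips
  v0 <- ifelse(flipped, dims - 1, 0)
  origin <- as.vector(A %*% v0 + t)
  list(perm = perm, flipped = flipped, spacing = spacing, origin = origin)
}

#' Write a scalar map or mask as NIfTI
#'
#' The affine written is diagonal with the grid spacing on the diagonal and
#' the grid origin in the translation column; spacing and origin round-trip
#' through [read_volume()] to within float precision. Masks are stored as
#' 8-bit 0/1 volumes, scalar maps as 64-bit floats (invalid voxels as NaN).
#'
#' @param v A [scalar_map()] or [smri_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "smri_mask")) {
    arr <- array(as.integer(v$membership), v$grid$shape)
    dtype <- "uint8"
  } else if (inherits(v, "scalar_map")) {
    arr <- v$values
    arr[!v$valid] <- NaN
    dtype <- "double"
  } else stop("write_volume expects a scalar_map or smri_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- v$grid$spacing
  aff <- rbind(cbind(diag(v$grid$spacing), v$grid$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = dtype)
    TRUE
  }, error = function(e) {
    stop("cannot write NIfTI to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
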