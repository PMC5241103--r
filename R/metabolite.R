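#' Voxelwise Cho/NAA ratio map
#'
#' Divides a choline map by an NAA map on a shared grid. Voxels where
#' either input is invalid, or where NAA is at or below `naa_floor`, are
#' flagged invalid — never clipped to a large number, so downstream
#' statistics exclude them.
#'
#' @param cho,naa [scalar_map()] objects on the same grid.
#' @param naa_floor Denominator floor (default `1e-6`).
#' @return A [scalar_map()] (unit `"arbitrary"`).
#' @export
ratio_map <- function(cho, naa, naa_floor = 1e-6) {
  stopifnot(inherits(cho, "scalar_map"), inherits(naa, "scalar_map"))
  stop_if_grid_mismatch(cho, naa, "ratio_map")
  ok <- cho$valid & naa$valid & !is.na(naa$values) & naa$values > naa_floor
  vals <- cho$values / naa$values
  vals[!ok] <- NA_real_
  scalar_map(vals, cho$grid, unit = "arbitrary", valid = ok)
}

#' Segment contralateral normal-appearing white matter
#'
#' The normalization reference region: voxels whose white-matter
#' probability reaches `p_min`, on the hemisphere opposite the tumor, with
#' tumor-related structures (typically GTV1) excluded after a safety
#' dilation. A reference smaller than `min_volume_cm3` is refused — too
#' small a region signals an unusable normalization.
#'
#' @param wm_prob [scalar_map()] of white-matter probability on the
#'   clinical grid.
#' @param hemispheres [scalar_map()] of hemisphere labels (1 = left,
#'   2 = right).
#' @param tumor_side `"left"` or `"right"` — the hemisphere containing the
#'   tumor; the *other* one is used.
#' @param exclusions List of [smri_mask()] to exclude (each dilated by
#'   `exclusion_margin_mm` first).
#' @param p_min WM probability cutoff (default 0.9).
#' @param exclusion_margin_mm Safety dilation of exclusions in mm
#'   (default 10).
#' @param min_volume_cm3 Minimum acceptable NAWM volume (default 10 cm^3).
#' @return An [smri_mask()] labelled `"NAWM"`.
#' @export
segment_nawm <- function(wm_prob, hemispheres, tumor_side = c("right", "left"),
                         exclusions = list(), p_min = 0.9,
                         exclusion_margin_mm = 10, min_volume_cm3 = 10) {
  tumor_side <- match.arg(tumor_side)
  stopifnot(inherits(wm_prob, "scalar_map"), inherits(hemispheres, "scalar_map"))
  stop_if_grid_mismatch(wm_prob, hemispheres, "segment_nawm")
  contra <- if (tumor_side == "right") 1 else 2
  mem <- wm_prob$valid & !is.na(wm_prob$values) & wm_prob$values >= p_min &
    hemispheres$values == contra
  mem[is.na(mem)] <- FALSE
  mem <- array(mem, wm_prob$grid$shape)
  for (ex in exclusions) {
    stop_if_grid_mismatch(wm_prob, ex, "segment_nawm")
    exd <- expand_margin(ex, exclusion_margin_mm)
    mem <- mem & !exd$membership
  }
  out <- smri_mask(mem, wm_prob$grid, "NAWM")
  if (volume_cm3(out) < min_volume_cm3)
    stop(sprintf(
      "NAWM reference region too small (%.2f cm^3 < %.2f cm^3); refusing to normalize",
      volume_cm3(out), min_volume_cm3))
  out
}

#' Fold-normalize a map by its NAWM mean
#'
#' Scales a map by the mean of its valid values over the NAWM reference
#' region, yielding fold-normal units in which NAWM averages exactly 1. The
#' reference mean is recorded on the result (`attr(., "reference_mean")`)
#' for provenance. At least 95% of the reference region must be valid.
#'
#' @param m A [scalar_map()].
#' @param nawm The NAWM [smri_mask()] on the same grid.
#' @return A [scalar_map()] with unit `"fold-normal"` and class `fold_map`
#'   prepended; attributes `reference_mean` and `reference_label`.
#' @export
normalize_fold <- function(m, nawm) {
  stopifnot(inherits(m, "scalar_map"), inherits(nawm, "smri_mask"))
  stop_if_grid_mismatch(m, nawm, "normalize_fold")
  nv <- sum(nawm$membership)
  if (nv == 0) stop("empty NAWM reference region")
  ok <- nawm$membership & m$valid
  if (sum(ok) < 0.95 * nv)
    stop("map is valid on less than 95% of the NAWM reference region")
  ref <- mean(m$values[ok])
  if (!is.finite(ref) || ref <= 0)
    stop("NAWM reference mean is not positive; cannot fold-normalize")
  out <- scalar_map(m$values / ref, m$grid, unit = "fold-normal",
                    valid = m$valid)
  class(out) <- c("fold_map", class(out))
  attr(out, "reference_mean") <- ref
  attr(out, "reference_label") <- nawm$label
  out
}

#' Threshold a fold-normal map into a metabolic abnormality mask
#'
#' Voxels at or above `level` (closed comparison, the conservative larger-
#' target convention), inside the brain and valid. By default no connected-
#' component filtering is applied; `components = "touching"` keeps only
#' components intersecting a reference mask (typically GTV2), discarding
#' remote islands.
#'
#' @param f A fold-normal [scalar_map()].
#' @param level Fold threshold (> 0), e.g. 1.5, 1.75, 2.0.
#' @param brain Brain [smri_mask()] on the same grid.
#' @param components `"all"` (default) or `"touching"`.
#' @param reference Reference [smri_mask()] for `components = "touching"`.
#' @return An [smri_mask()] labelled `sprintf("choNAA_fold%g", level)`.
#' @export
threshold_segmentation <- function(f, level, brain,
                                   components = c("all", "touching"),
                                   reference = NULL) {
  components <- match.arg(components)
  stopifnot(inherits(f, "scalar_map"), level > 0)
  stop_if_grid_mismatch(f, brain, "threshold_segmentation")
  mem <- f$valid & !is.na(f$values) & f$values >= level & brain$membership
  mem[is.na(mem)] <- FALSE
  mem <- array(mem, f$grid$shape)
  if (components == "touching") {
    if (is.null(reference))
      stop("components = \"touching\" requires a reference mask")
    stop_if_grid_mismatch(f, reference, "threshold_segmentation")
    lab <- label_components_cpp(mem, f$grid$shape)
    keep <- unique(lab[reference$membership & mem])
    keep <- keep[keep > 0]
    mem <- array(lab %in% keep, f$grid$shape)
  }
  smri_mask(mem, f$grid, sprintf("choNAA_fold%g", level))
}
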