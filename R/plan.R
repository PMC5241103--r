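#' Planning configuration
#'
#' Margins, fold thresholds, prescriptions, and organ-at-risk limits used
#' throughout plan construction and evaluation. Defaults follow standard
#' glioblastoma chemoradiation practice: CTV1 = GTV1 + 7 mm, CTV2 = GTV2 +
#' 5 mm (both limited to brain), PTV = CTV + 3 mm (unclipped, setup
#' uncertainty), PTV1 prescribed 51 Gy (54 Gy variant allowed) and PTV2
#' 60 Gy in 30 fractions; brainstem/optic soft maximum 54 Gy with a hard
#' brainstem ceiling of 60 Gy; the planning goal is 100% of the dose
#' covering 95% of the target, with PTV2 coverage down to 90% allowable
#' near the brainstem.
#'
#' @param ctv1_margin_mm,ctv2_margin_mm,ptv_margin_mm Margins in mm.
#' @param thresholds Strictly increasing Cho/NAA fold thresholds.
#' @param rx_ptv1_gy,rx_ptv2_gy Prescription doses in Gy.
#' @param fractions Number of fractions.
#' @param oar_soft_max_gy Brainstem/optic soft maximum (Gy).
#' @param brainstem_hard_max_gy Brainstem hard point-maximum (Gy).
#' @param coverage_goal_pct Percent of target to cover at prescription.
#' @param relaxed_ptv2_pct Allowable PTV2 coverage floor (percent).
#' @return A `plan_config` object.
#' @export
plan_config <- function(ctv1_margin_mm = 7, ctv2_margin_mm = 5,
                        ptv_margin_mm = 3,
                        thresholds = c(1.5, 1.75, 2.0),
                        rx_ptv1_gy = 51, rx_ptv2_gy = 60, fractions = 30,
                        oar_soft_max_gy = 54, brainstem_hard_max_gy = 60,
                        coverage_goal_pct = 95, relaxed_ptv2_pct = 90) {
  if (any(c(ctv1_margin_mm, ctv2_margin_mm, ptv_margin_mm) < 0))
    stop("margins must be >= 0")
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  if (rx_ptv1_gy <= 0 || rx_ptv2_gy <= 0) stop("prescriptions must be positive")
  structure(list(
    ctv1_margin_mm = ctv1_margin_mm, ctv2_margin_mm = ctv2_margin_mm,
    ptv_margin_mm = ptv_margin_mm, thresholds = thresholds,
    rx_ptv1_gy = rx_ptv1_gy, rx_ptv2_gy = rx_ptv2_gy, fractions = fractions,
    oar_soft_max_gy = oar_soft_max_gy,
    brainstem_hard_max_gy = brainstem_hard_max_gy,
    coverage_goal_pct = coverage_goal_pct,
    relaxed_ptv2_pct = relaxed_ptv2_pct
  ), class = "plan_config")
}

#' Expand a mask by a metric margin
#'
#' Euclidean margin expansion honoring anisotropic voxel spacing: the
#' result contains every voxel whose center lies within `margin_mm` (world
#' mm) of some member voxel center, computed with an exact separable
#' distance transform — not a structuring-element dilation, which is wrong
#' by up to a slice on thick-slice grids. Optionally intersected with an
#' anatomic barrier (e.g. the brain external contour). A zero margin is the
#' identity.
#'
#' @param m An [smri_mask()].
#' @param margin_mm Margin in mm (>= 0).
#' @param barrier Optional [smri_mask()] to clip the result to.
#' @return An [smri_mask()].
#' @export
expand_margin <- function(m, margin_mm, barrier = NULL) {
  stopifnot(inherits(m, "smri_mask"), margin_mm >= 0)
  if (margin_mm == 0 || !any(m$membership)) {
    out <- m
  } else {
    d2 <- edt_squared_cpp(m$membership, m$grid$shape, m$grid$spacing)
    out <- smri_mask(array(d2 <= margin_mm^2, m$grid$shape), m$grid, m$label)
  }
  if (!is.null(barrier)) {
    stop_if_grid_mismatch(m, barrier, "expand_margin")
    out <- smri_mask(out$membership & barrier$membership, m$grid, m$label)
  }
  out
}

#' Construct conventional GTV/CTV/PTV target volumes
#'
#' CTV1 and CTV2 expand the FLAIR (GTV1) and enhancing/cavity (GTV2) gross
#' volumes by their metric margins, clipped to the brain external contour;
#' PTVs add the setup margin without anatomic clipping. Enhancement
#' exceeding the FLAIR volume is pathological but possible and only raises
#' a warning.
#'
#' @param gtv1,gtv2 Gross target [smri_mask()]s (FLAIR; enhancement +
#'   cavity).
#' @param brain Brain [smri_mask()] used as the CTV barrier.
#' @param cfg A [plan_config()].
#' @return A `plan_volumes` list with masks `gtv1`, `gtv2`, `ctv1`, `ctv2`,
#'   `ptv1`, `ptv2`, the `brain` barrier, `cfg`, and a `provenance` log of
#'   construction steps.
#' @export
build_conventional <- function(gtv1, gtv2, brain, cfg = plan_config()) {
  stopifnot(inherits(cfg, "plan_config"))
  for (m in list(gtv1, gtv2, brain)) stopifnot(inherits(m, "smri_mask"))
  stop_if_grid_mismatch(gtv1, gtv2, "build_conventional")
  stop_if_grid_mismatch(gtv1, brain, "build_conventional")
  if (!any(gtv1$membership) || !any(gtv2$membership))
    stop("empty GTV")
  if (!mask_subset(gtv2, gtv1))
    warning("GTV2 (enhancement) extends beyond GTV1 (FLAIR); proceeding")
  prov <- list()
  step <- function(name, what) prov[[name]] <<- what
  ctv1 <- expand_margin(gtv1, cfg$ctv1_margin_mm, barrier = brain)
  ctv1$label <- "CTV1"
  step("CTV1", sprintf("GTV1 + %g mm, clipped to brain", cfg$ctv1_margin_mm))
  ctv2 <- expand_margin(gtv2, cfg$ctv2_margin_mm, barrier = brain)
  ctv2$label <- "CTV2"
  step("CTV2", sprintf("GTV2 + %g mm, clipped to brain", cfg$ctv2_margin_mm))
  ptv1 <- expand_margin(ctv1, cfg$ptv_margin_mm)
  ptv1$label <- "PTV1"
  step("PTV1", sprintf("CTV1 + %g mm, unclipped", cfg$ptv_margin_mm))
  ptv2 <- expand_margin(ctv2, cfg$ptv_margin_mm)
  ptv2$label <- "PTV2"
  step("PTV2", sprintf("CTV2 + %g mm, unclipped", cfg$ptv_margin_mm))
  structure(list(gtv1 = gtv1, gtv2 = gtv2, ctv1 = ctv1, ctv2 = ctv2,
                 ptv1 = ptv1, ptv2 = ptv2, brain = brain, cfg = cfg,
                 provenance = prov),
            class = "plan_volumes")
}

#' Merge a Cho/NAA segmentation into the target volumes
#'
#' The metabolic abnormality is merged with CTV2 to form `sMRI_CTV2`
#' (never removing a conventionally targeted voxel), expanded by the setup
#' margin to `sMRI_PTV2`; `sMRI_CTV1` is the union of `sMRI_CTV2` with
#' CTV1, again expanded to `sMRI_PTV1`.
#'
#' @param pv A `plan_volumes` from [build_conventional()].
#' @param choNAA_seg The threshold segmentation [smri_mask()].
#' @param cfg A [plan_config()] (defaults to the one stored in `pv`).
#' @return `pv` augmented with `seg`, `smri_ctv2`, `smri_ptv2`,
#'   `smri_ctv1`, `smri_ptv1` and extended provenance.
#' @export
build_smri <- function(pv, choNAA_seg, cfg = pv$cfg) {
  stopifnot(inherits(pv, "plan_volumes"), inherits(choNAA_seg, "smri_mask"))
  stop_if_grid_mismatch(pv$ctv2, choNAA_seg, "build_smri")
  smri_ctv2 <- mask_union(pv$ctv2, choNAA_seg, label = "sMRI_CTV2")
  smri_ptv2 <- expand_margin(smri_ctv2, cfg$ptv_margin_mm)
  smri_ptv2$label <- "sMRI_PTV2"
  smri_ctv1 <- mask_union(smri_ctv2, pv$ctv1, label = "sMRI_CTV1")
  smri_ptv1 <- expand_margin(smri_ctv1, cfg$ptv_margin_mm)
  smri_ptv1$label <- "sMRI_PTV1"
  pv$seg <- choNAA_seg
  pv$smri_ctv2 <- smri_ctv2
  pv$smri_ptv2 <- smri_ptv2
  pv$smri_ctv1 <- smri_ctv1
  pv$smri_ptv1 <- smri_ptv1
  pv$provenance$sMRI_CTV2 <-
    sprintf("CTV2 union %s", choNAA_seg$label)
  pv$provenance$sMRI_PTV2 <-
    sprintf("sMRI_CTV2 + %g mm, unclipped", cfg$ptv_margin_mm)
  pv$provenance$sMRI_CTV1 <- "sMRI_CTV2 union CTV1"
  pv$provenance$sMRI_PTV1 <-
    sprintf("sMRI_CTV1 + %g mm, unclipped", cfg$ptv_margin_mm)
  pv
}

#' @export
print.plan_volumes <- function(x, ...) {
  nm <- intersect(c("gtv1", "gtv2", "ctv1", "ctv2", "ptv1", "ptv2",
                    "seg", "smri_ctv2", "smri_ptv2", "smri_ctv1",
                    "smri_ptv1"), names(x))
  cat("<plan_volumes>\n")
  for (n in nm)
    cat(sprintf("  %-10s %8.2f cm^3\n", x[[n]]$label, volume_cm3(x[[n]])))
  invisible(x)
}
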