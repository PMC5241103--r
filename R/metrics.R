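#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` for two masks on the same grid. Two empty masks
#' are defined as perfect agreement (Dice 1.0) and a message is logged.
#'
#' @param a,b [smri_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "dice")
  na <- sum(a$membership); nb <- sum(b$membership)
  if (na + nb == 0) {
    message("dice: both masks empty; returning 1.0 by convention")
    return(1.0)
  }
  2 * sum(a$membership & b$membership) / (na + nb)
}

#' Mask volume in cubic centimeters
#'
#' Member voxel count times the voxel volume.
#'
#' @param m An [smri_mask()].
#' @return Volume in cm^3.
#' @export
volume_cm3 <- function(m) {
  stopifnot(inherits(m, "smri_mask"))
  sum(m$membership) * voxel_volume_cm3(m$grid)
}

#' Percent volume increase from a base mask to a new mask
#'
#' @param base,new [smri_mask()] objects; `base` must be nonempty.
#' @return `100 * (vol(new) - vol(base)) / vol(base)`.
#' @export
percent_increase <- function(base, new) {
  vb <- volume_cm3(base)
  if (vb <= 0) stop("percent_increase: base mask is empty")
  100 * (volume_cm3(new) - vb) / vb
}

#' Isodose mask
#'
#' Voxels receiving at least `level_gy` (closed comparison): the voxel form
#' of the 100% prescription isodose line.
#'
#' @param dose A [scalar_map()] in Gy.
#' @param level_gy Dose level in Gy.
#' @return An [smri_mask()] labelled `sprintf("IDL%g", level_gy)`.
#' @export
isodose_mask <- function(dose, level_gy) {
  stopifnot(inherits(dose, "scalar_map"))
  mem <- dose$valid & !is.na(dose$values) & dose$values >= level_gy
  mem[is.na(mem)] <- FALSE
  smri_mask(array(mem, dose$grid$shape), dose$grid,
            sprintf("IDL%g", level_gy))
}

#' Volume of a segmentation outside a region
#'
#' @param seg,region [smri_mask()] objects on the same grid.
#' @return A list with `cm3` (volume of `seg` outside `region`) and `pct`
#'   (percent of `seg` outside). An empty `seg` gives `(0, 0)` with a
#'   warning.
#' @export
volume_outside <- function(seg, region) {
  stop_if_grid_mismatch(seg, region, "volume_outside")
  ns <- sum(seg$membership)
  if (ns == 0) {
    warning("volume_outside: empty segmentation")
    return(list(cm3 = 0, pct = 0))
  }
  nout <- sum(seg$membership & !region$membership)
  list(cm3 = nout * voxel_volume_cm3(seg$grid), pct = 100 * nout / ns)
}

#' Percent of a target covered at a dose level
#'
#' @param target Nonempty [smri_mask()].
#' @param dose [scalar_map()] in Gy on the same grid.
#' @param level_gy Dose level in Gy.
#' @return `100 * |target ∩ {dose >= level}| / |target|`.
#' @export
coverage_percent <- function(target, dose, level_gy) {
  stopifnot(inherits(target, "smri_mask"), inherits(dose, "scalar_map"))
  stop_if_grid_mismatch(target, dose, "coverage_percent")
  nt <- sum(target$membership)
  if (nt == 0) stop("coverage_percent: empty target")
  dv <- dose$values
  dv[is.na(dv)] <- -Inf
  100 * sum(target$membership & dv >= level_gy) / nt
}

#' Maximum dose within an organ
#'
#' Point-maximum over organ voxel values (no volume-of-interest smoothing).
#'
#' @param organ Nonempty [smri_mask()].
#' @param dose [scalar_map()] in Gy on the same grid.
#' @return Maximum dose in Gy.
#' @export
max_dose_in <- function(organ, dose) {
  stopifnot(inherits(organ, "smri_mask"), inherits(dose, "scalar_map"))
  stop_if_grid_mismatch(organ, dose, "max_dose_in")
  if (!any(organ$membership)) stop("max_dose_in: empty organ")
  max(dose$values[organ$membership], na.rm = TRUE)
}

#' Recurrence coverage by a target volume
#'
#' Percent of the recurrent tumor contained in a target mask.
#'
#' @param rec Nonempty recurrence [smri_mask()].
#' @param ctv Target [smri_mask()] on the same grid.
#' @return Coverage percent in `[0, 100]`.
#' @export
recurrence_coverage <- function(rec, ctv) {
  stop_if_grid_mismatch(rec, ctv, "recurrence_coverage")
  nr <- sum(rec$membership)
  if (nr == 0) stop("recurrence_coverage: empty recurrence mask")
  100 * sum(rec$membership & ctv$membership) / nr
}

#' Evaluate a plan into a one-row comparison record
#'
#' Computes the full set of volumetric, spatial, dosimetric and recurrence
#' quantities for one patient/threshold: target volumes, the percent
#' increase of `sMRI_CTV2` over CTV2 and their Dice overlap, the volume and
#' percent of the Cho/NAA segmentation outside CTV1/CTV2 and outside the
#' 100% prescription isodose regions, target coverage at prescription,
#' brainstem point-maximum dose, constraint flags (coverage goal, soft
#' 54 Gy / hard 60 Gy brainstem limits), and — when a recurrence mask is
#' given — recurrence coverage by the conventional and sMRI CTVs and by
#' the 57 and 60 Gy isodose regions.
#'
#' For sMRI-augmented plans coverage is reported for the sMRI PTVs against
#' `dose` (the plan being evaluated, typically replanned), while the
#' where-does-the-abnormality-escape analysis (`seg_outside_idl*`) is
#' scored against the isodose regions of `ref_dose` — by default the same
#' dose, but normally the *conventional* plan's dose, since the question
#' is how much metabolic abnormality conventional planning leaves
#' undertreated.
#'
#' @param pv A `plan_volumes` (conventional or sMRI-augmented).
#' @param dose [scalar_map()] in Gy on the same grid.
#' @param organs Named list of organ [smri_mask()]s; `brainstem` is used
#'   for the constraint flags if present.
#' @param rec Optional recurrence [smri_mask()].
#' @param cfg A [plan_config()] (defaults to the one stored in `pv`).
#' @param patient_id Identifier copied into the record.
#' @param ref_dose Reference [scalar_map()] whose isodose regions the
#'   segmentation is compared against (default `dose`).
#' @return A one-row [tibble::tibble()].
#' @export
evaluate_plan <- function(pv, dose, organs = list(), rec = NULL,
                          cfg = pv$cfg, patient_id = NA_character_,
                          ref_dose = dose) {
  stopifnot(inherits(pv, "plan_volumes"), inherits(dose, "scalar_map"))
  has_smri <- !is.null(pv$smri_ctv2)
  threshold <- if (has_smri)
    as.numeric(sub("^choNAA_fold", "", pv$seg$label)) else NA_real_

  idl1 <- isodose_mask(ref_dose, cfg$rx_ptv1_gy)
  idl2 <- isodose_mask(ref_dose, cfg$rx_ptv2_gy)

  ptv1 <- if (has_smri) pv$smri_ptv1 else pv$ptv1
  ptv2 <- if (has_smri) pv$smri_ptv2 else pv$ptv2
  cov1 <- coverage_percent(ptv1, dose, cfg$rx_ptv1_gy)
  cov2 <- coverage_percent(ptv2, dose, cfg$rx_ptv2_gy)

  bs_max <- bs_over_soft <- NA_real_
  if (!is.null(organs$brainstem)) {
    bs_max <- max_dose_in(organs$brainstem, dose)
    bs_over_soft <- coverage_percent(organs$brainstem, dose,
                                     cfg$oar_soft_max_gy)
  }

  seg_out <- function(region) {
    if (has_smri) volume_outside(pv$seg, region) else list(cm3 = NA_real_,
                                                           pct = NA_real_)
  }
  o_ctv1 <- seg_out(pv$ctv1); o_ctv2 <- seg_out(pv$ctv2)
  o_idl1 <- seg_out(idl1); o_idl2 <- seg_out(idl2)

  rec_ctv2 <- rec_smri <- rec_57 <- rec_60 <- NA_real_
  if (!is.null(rec) && any(rec$membership)) {
    rec_ctv2 <- recurrence_coverage(rec, pv$ctv2)
    if (has_smri) rec_smri <- recurrence_coverage(rec, pv$smri_ctv2)
    rec_57 <- recurrence_coverage(rec, isodose_mask(dose, 57))
    rec_60 <- recurrence_coverage(rec, isodose_mask(dose, 60))
  }

  cov_ok <- cov1 >= cfg$coverage_goal_pct &&
    cov2 >= cfg$relaxed_ptv2_pct
  bs_soft_ok <- is.na(bs_max) || bs_max < cfg$oar_soft_max_gy
  # hard constraint: point max < 60 Gy and no more than 10% of the
  # brainstem above the 54 Gy soft level
  bs_hard_ok <- is.na(bs_max) ||
    (bs_max < cfg$brainstem_hard_max_gy && bs_over_soft <= 10)

  tibble::tibble(
    patient_id = patient_id,
    plan = if (has_smri) "sMRI" else "conventional",
    threshold = threshold,
    vol_ctv2_cm3 = volume_cm3(pv$ctv2),
    vol_smri_ctv2_cm3 = if (has_smri) volume_cm3(pv$smri_ctv2) else NA_real_,
    vol_seg_cm3 = if (has_smri) volume_cm3(pv$seg) else NA_real_,
    pct_increase_ctv2 = if (has_smri)
      percent_increase(pv$ctv2, pv$smri_ctv2) else NA_real_,
    dice_ctv2 = if (has_smri) dice(pv$ctv2, pv$smri_ctv2) else NA_real_,
    seg_outside_ctv1_cm3 = o_ctv1$cm3, seg_outside_ctv1_pct = o_ctv1$pct,
    seg_outside_ctv2_cm3 = o_ctv2$cm3, seg_outside_ctv2_pct = o_ctv2$pct,
    seg_outside_idl1_cm3 = o_idl1$cm3, seg_outside_idl1_pct = o_idl1$pct,
    seg_outside_idl2_cm3 = o_idl2$cm3, seg_outside_idl2_pct = o_idl2$pct,
    coverage_ptv1_pct = cov1,
    coverage_ptv2_pct = cov2,
    brainstem_max_gy = bs_max,
    brainstem_over54_pct = bs_over_soft,
    coverage_goal_met = cov_ok,
    brainstem_soft_ok = bs_soft_ok,
    brainstem_hard_ok = bs_hard_ok,
    rec_coverage_ctv2_pct = rec_ctv2,
    rec_coverage_smri_ctv2_pct = rec_smri,
    rec_coverage_57gy_pct = rec_57,
    rec_coverage_60gy_pct = rec_60
  )
}
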