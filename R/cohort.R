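#' Process one synthetic patient through the full pipeline
#'
#' Runs the complete analysis chain for a single phantom: Cho/NAA ratio on
#' the spectroscopic grid, trilinear upsampling into the clinical grid,
#' contralateral NAWM segmentation and fold-normalization, conventional
#' target construction, conformal dose simulation, recurrence simulation,
#' then — per fold threshold — metabolic segmentation, sMRI-augmented
#' volumes, replanned (or conventional) dose, and a full comparison record.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param cfg A [plan_config()].
#' @param penumbra_mm Dose falloff scale for [generate_dose()].
#' @param recurrence_volume_cm3,recurrence_mixing,recurrence_seed Passed to
#'   [generate_recurrence()].
#' @param evaluate_smri_against `"replanned"` (regenerate dose on the sMRI
#'   PTVs) or `"conventional"` (score sMRI volumes against the conventional
#'   dose — the uncovered-abnormality analysis).
#' @param patient_id Identifier copied into the records.
#' @return A tibble with one conventional row and one row per threshold.
#' @export
run_patient <- function(truth, cfg = plan_config(), penumbra_mm = 5,
                        recurrence_volume_cm3 = 2, recurrence_mixing = 1,
                        recurrence_seed = truth$params$seed,
                        evaluate_smri_against = c("replanned",
                                                  "conventional"),
                        patient_id = "patient") {
  evaluate_smri_against <- match.arg(evaluate_smri_against)
  stopifnot(inherits(truth, "phantom_truth"))
  cg <- truth$clinical_grid

  ratio_s <- ratio_map(truth$cho, truth$naa)
  ratio_c <- resample_trilinear(ratio_s, cg)
  nawm <- segment_nawm(truth$wm_prob, truth$hemispheres, truth$tumor_side,
                       exclusions = list(truth$gtv1))
  fold <- normalize_fold(ratio_c, nawm)

  pv <- build_conventional(truth$gtv1, truth$gtv2, truth$brain, cfg)
  conv_dose <- generate_dose(
    list(list(mask = pv$ptv1, prescription = cfg$rx_ptv1_gy),
         list(mask = pv$ptv2, prescription = cfg$rx_ptv2_gy)),
    cg, penumbra_mm)
  rec <- generate_recurrence(truth, recurrence_volume_cm3,
                             recurrence_mixing, recurrence_seed)
  if (!any(rec$membership)) rec <- NULL
  organs <- list(brainstem = truth$brainstem)

  rows <- list(evaluate_plan(pv, conv_dose, organs, rec, cfg, patient_id))
  for (L in cfg$thresholds) {
    seg <- threshold_segmentation(fold, L, truth$brain)
    pvs <- build_smri(pv, seg, cfg)
    dose_s <- if (evaluate_smri_against == "replanned") {
      generate_dose(
        list(list(mask = pvs$smri_ptv1, prescription = cfg$rx_ptv1_gy),
             list(mask = pvs$smri_ptv2, prescription = cfg$rx_ptv2_gy)),
        cg, penumbra_mm)
    } else conv_dose
    # the abnormality-escape analysis is always scored against the
    # conventional plan's isodose regions
    rows[[length(rows) + 1L]] <-
      evaluate_plan(pvs, dose_s, organs, rec, cfg, patient_id,
                    ref_dose = conv_dose)
  }
  dplyr::bind_rows(rows)
}

# per-patient randomized phantom parameters for a cohort
draw_patient_params <- function(base, patient_seed) {
  run_seeded(patient_seed, {
    core <- stats::runif(1, 12, 18)
    flair <- core + stats::runif(1, 8, 14)
    cavity <- min(core - 2, stats::runif(1, 5, 9))
    sigma <- stats::runif(1, 9, 15)
    side <- sample(c("left", "right"), 1)
    geo0 <- phantom_geometry(base)
    sgn <- if (side == "right") 1 else -1
    jitter <- stats::runif(3, -8, 8)
    center <- geo0$center +
      c(sgn * 0.4 * geo0$semi[1], 0.1 * geo0$semi[2], 0) + jitter
    phantom_params(
      clinical_shape = base$clinical_shape,
      clinical_spacing = base$clinical_spacing,
      smri_spacing = base$smri_spacing,
      tumor_side = side, tumor_center = center,
      cavity_radius = cavity, core_radius = core, flair_radius = flair,
      sigma_inf = sigma, amplitude = base$amplitude,
      baseline = base$baseline, cho_nawm = base$cho_nawm,
      noise_cv = base$noise_cv, seed = patient_seed)
  })
}

#' Run a synthetic cohort end to end
#'
#' Generates `n_patients` randomized phantoms (tumor side, location, radii
#' and infiltration length vary patient to patient), processes each through
#' [run_patient()], assembles the per-patient comparison records, and
#' computes the cohort statistics table. Per-patient failures are isolated:
#' the cohort completes and failures are reported in `$errors`. The run is
#' deterministic under a fixed `seed`.
#'
#' @param n_patients Number of phantoms.
#' @param params Base [phantom_params()] (geometry/noise template).
#' @param cfg A [plan_config()].
#' @param seed Master seed; all per-patient seeds derive from it.
#' @param patient_params Optional list of fully specified
#'   [phantom_params()], one per patient, overriding the randomized
#'   per-patient draws (its length then defines the cohort size).
#' @param out_dir Optional directory; when given, `records.csv`,
#'   `stats.csv` and `manifest.json` are written there.
#' @inheritParams run_patient
#' @return A `smrirt_cohort` list with `records` (tibble), `stats`
#'   (tibble), `manifest`, `errors` (tibble).
#' @export
run_cohort <- function(n_patients = 3, params = phantom_params(),
                       cfg = plan_config(), seed = 1L,
                       penumbra_mm = 5,
                       recurrence_volume_cm3 = 2, recurrence_mixing = 1,
                       evaluate_smri_against = c("replanned",
                                                 "conventional"),
                       patient_params = NULL, out_dir = NULL) {
  evaluate_smri_against <- match.arg(evaluate_smri_against)
  if (!is.null(patient_params)) n_patients <- length(patient_params)
  patient_seeds <- run_seeded(seed,
                              sample.int(.Machine$integer.max - 1L,
                                         n_patients))
  records <- list()
  errors <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("phantom_%02d", i)
    res <- tryCatch({
      pp <- if (is.null(patient_params)) {
        draw_patient_params(params, patient_seeds[i])
      } else patient_params[[i]]
      truth <- generate_phantom(pp)
      run_patient(truth, cfg, penumbra_mm, recurrence_volume_cm3,
                  recurrence_mixing, patient_seeds[i],
                  evaluate_smri_against, pid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        tibble::tibble(patient_id = pid, error = conditionMessage(res))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  records <- dplyr::bind_rows(records)
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(patient_id = character(), error = character())
  stats_tbl <- cohort_stats(records)
  manifest <- list(seed = seed, n_patients = n_patients,
                   patient_seeds = patient_seeds,
                   thresholds = cfg$thresholds,
                   evaluate_smri_against = evaluate_smri_against,
                   recurrence_mixing = recurrence_mixing,
                   recurrence_volume_cm3 = recurrence_volume_cm3,
                   penumbra_mm = penumbra_mm)
  out <- structure(list(records = records, stats = stats_tbl,
                        manifest = manifest, errors = errors),
                   class = "smrirt_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tbl, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Cohort statistics table
#'
#' Per fold threshold: a one-sided paired t test of sMRI_CTV2 vs CTV2
#' volume (greater), a one-sided one-sample t test of Dice against 1.0
#' (less), a one-sided paired t test of recurrence coverage by sMRI_CTV2
#' vs CTV2 (greater), and a one-sided one-sample t test of percent
#' abnormality beyond the 60 Gy isodose region against 0 (greater); plus
#' one-way ANOVAs of PTV2 coverage and brainstem maximum dose across plan
#' groups. Tests that are undefined on the data at hand (zero variance,
#' n < 2) are reported with `NA` and the reason.
#'
#' @param records The `records` tibble from [run_cohort()].
#' @return A tibble, one row per test.
#' @export
cohort_stats <- function(records) {
  if (nrow(records) == 0)
    return(tibble::tibble(test = character(), threshold = numeric(),
                          statistic = numeric(), df1 = numeric(),
                          df2 = numeric(), p.value = numeric(),
                          estimate = numeric(), n = integer(),
                          note = character()))
  conv <- dplyr::filter(records, .data$plan == "conventional")
  rows <- list()
  add <- function(test, threshold, expr) {
    res <- tryCatch(expr, error = function(e) e)
    rows[[length(rows) + 1L]] <<- if (inherits(res, "error")) {
      tibble::tibble(test = test, threshold = threshold,
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p.value = NA_real_, estimate = NA_real_,
                     n = NA_integer_, note = conditionMessage(res))
    } else {
      td <- tidy(res)
      tibble::tibble(test = test, threshold = threshold,
                     statistic = td$statistic, df1 = td$df1, df2 = td$df2,
                     p.value = td$p.value, estimate = td$estimate,
                     n = td$n, note = "")
    }
  }
  for (L in sort(unique(stats::na.omit(records$threshold)))) {
    sm <- dplyr::filter(records, .data$plan == "sMRI",
                        .data$threshold == L)
    sm <- sm[match(conv$patient_id, sm$patient_id), ]
    add("smri_ctv2_vs_ctv2_volume", L,
        paired_t_one_sided(sm$vol_smri_ctv2_cm3, sm$vol_ctv2_cm3,
                           "greater"))
    add("dice_vs_unity", L,
        one_sample_t_vs_unity(sm$dice_ctv2, "less"))
    ok <- !is.na(sm$rec_coverage_smri_ctv2_pct) &
      !is.na(sm$rec_coverage_ctv2_pct)
    add("recurrence_coverage_smri_vs_ctv2", L,
        paired_t_one_sided(sm$rec_coverage_smri_ctv2_pct[ok],
                           sm$rec_coverage_ctv2_pct[ok], "greater"))
    add("seg_outside_idl60_vs_zero", L,
        one_sample_t_vs_unity(sm$seg_outside_idl2_pct, "greater", mu = 0))
  }
  groups_cov <- c(list(conv$coverage_ptv2_pct),
                  lapply(sort(unique(stats::na.omit(records$threshold))),
                         function(L) {
                           dplyr::filter(records, .data$plan == "sMRI",
                                         .data$threshold == L)$coverage_ptv2_pct
                         }))
  add("anova_ptv2_coverage", NA_real_, one_way_anova(groups_cov))
  groups_bs <- c(list(conv$brainstem_max_gy),
                 lapply(sort(unique(stats::na.omit(records$threshold))),
                        function(L) {
                          dplyr::filter(records, .data$plan == "sMRI",
                                        .data$threshold == L)$brainstem_max_gy
                        }))
  add("anova_brainstem_max", NA_real_, one_way_anova(groups_bs))
  dplyr::bind_rows(rows)
}

#' @export
print.smrirt_cohort <- function(x, ...) {
  cat(sprintf("<smrirt_cohort> %d patient(s), %d record(s), %d error(s)\n",
              length(unique(x$records$patient_id)), nrow(x$records),
              nrow(x$errors)))
  means <- dplyr::summarise(
    dplyr::group_by(x$records, .data$plan, .data$threshold),
    pct_increase = mean(.data$pct_increase_ctv2),
    dice = mean(.data$dice_ctv2),
    .groups = "drop")
  print(means)
  invisible(x)
}
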