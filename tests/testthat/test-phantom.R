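test_that("phantom parameters are validated", {
  expect_error(small_phantom_params(cavity_radius = 16), "cavity < core")
  expect_error(small_phantom_params(sigma_inf = 0), "sigma_inf")
  expect_error(small_phantom_params(amplitude = -1), "amplitude")
  expect_error(small_phantom_params(noise_cv = -0.1), "noise_cv")
  expect_error(
    generate_phantom(small_phantom_params(tumor_center = c(1e3, 1e3, 1e3))),
    "outside the brain")
})

test_that("noiseless ratio field follows the closed form", {
  tr <- small_truth()  # CV = 0, A = 2, baseline 0.6
  p <- tr$params
  pts <- grid_coordinates_mm(tr$smri_grid)
  d <- sqrt((pts[, 1] - tr$tumor_center[1])^2 +
            (pts[, 2] - tr$tumor_center[2])^2 +
            (pts[, 3] - tr$tumor_center[3])^2)
  core <- d <= p$core_radius & tr$cho_naa$valid
  expect_gt(sum(core), 0)
  # inside the core (the boundary closure of f = A): ratio = baseline * (1 + A)
  expect_equal(unname(tr$cho_naa$values[core]),
               rep(p$baseline * (1 + p$amplitude), sum(core)),
               tolerance = 1e-12)
  # far field: ratio = baseline where the infiltration has fully decayed
  far <- d > p$core_radius + 6 * p$sigma_inf & tr$cho_naa$valid
  expect_gt(sum(far), 0)
  expect_equal(unname(tr$cho_naa$values[far]),
               rep(p$baseline, sum(far)), tolerance = 1e-9)
  # Cho and NAA individually reproduce the same quotient
  q <- tr$cho$values / tr$naa$values
  expect_equal(q[tr$cho_naa$valid], tr$cho_naa$values[tr$cho_naa$valid],
               tolerance = 1e-12)
})

test_that("phantom anatomy nests and maps are valid only in the brain", {
  tr <- small_truth()
  expect_true(mask_subset(tr$cavity, tr$gtv2))
  expect_true(mask_subset(tr$gtv2, tr$gtv1))
  expect_true(mask_subset(tr$gtv1, tr$brain))
  expect_identical(tr$cho$valid, tr$brain_smri$membership)
  # hemispheres partition the grid along the midsagittal plane
  expect_setequal(unique(as.vector(tr$hemispheres$values)), c(1, 2))
})

test_that("identical seeds give bit-identical phantoms", {
  p <- small_phantom_params(noise_cv = 0.1, seed = 99L)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$cho$values, b$cho$values)
  expect_identical(a$naa$values, b$naa$values)
  c2 <- generate_phantom(small_phantom_params(noise_cv = 0.1, seed = 100L))
  expect_false(identical(a$cho$values, c2$cho$values))
})

test_that("thresholding the noiseless fold field recovers the analytic region", {
  tr <- small_truth()
  fold <- scalar_map(tr$cho_naa$values / tr$params$baseline, tr$smri_grid,
                     unit = "fold-normal", valid = tr$cho_naa$valid)
  for (L in c(1.5, 1.75, 2.0)) {
    seg <- threshold_segmentation(fold, L, tr$brain_smri)
    an <- analytic_abnormality(tr, L, tr$smri_grid)
    expect_gte(dice(seg, an), 0.95)
  }
})

test_that("dose surrogate honors prescriptions, falloff and the max rule", {
  g <- volume_grid(c(21, 21, 21), c(1, 1, 1))
  tgt <- ball_mask(g, c(10, 10, 10), 4, "PTV")
  dose <- generate_dose(list(list(mask = tgt, prescription = 60)), g,
                        penumbra_mm = 5)
  # inside the target: exactly the prescription
  expect_equal(unname(dose$values[tgt$membership]),
               rep(60, sum(tgt$membership)), tolerance = 1e-12)
  # at distance d the dose is prescription * 2 / (1 + exp(2 d / penumbra));
  # voxel (20,10,10) is 6 mm outside the 4 mm ball surface... measure from
  # member voxel centers: nearest member center is (14,10,10), d = 6 mm
  expect_equal(dose$values[21, 11, 11], 60 * 2 / (1 + exp(2 * 6 / 5)),
               tolerance = 1e-12)
  # monotone non-increasing with distance along a ray
  ray <- dose$values[11:21, 11, 11]
  expect_true(all(diff(ray) <= 1e-12))

  # nested boost: PTV2 at 60 inside PTV1 at 51 -> PTV2 voxels receive 60
  ptv1 <- ball_mask(g, c(10, 10, 10), 8, "PTV1")
  both <- generate_dose(list(list(mask = ptv1, prescription = 51),
                             list(mask = tgt, prescription = 60)), g, 5)
  expect_true(all(both$values[tgt$membership] >= 60 - 1e-12))
  expect_true(all(both$values[ptv1$membership] >= 51 - 1e-12))
  expect_error(generate_dose(list(), g), "at least one target")
})

test_that("generated plans cover every target at prescription", {
  tr <- small_truth()
  pv <- build_conventional(tr$gtv1, tr$gtv2, tr$brain, plan_config())
  dose <- generate_dose(list(list(mask = pv$ptv1, prescription = 51),
                             list(mask = pv$ptv2, prescription = 60)),
                        tr$clinical_grid)
  expect_gte(coverage_percent(pv$ptv1, dose, 51), 99)
  expect_gte(coverage_percent(pv$ptv2, dose, 60), 99)
})

test_that("recurrence volume, determinism and null setting behave", {
  tr <- small_truth()
  vox <- voxel_volume_cm3(tr$clinical_grid)
  rec <- generate_recurrence(tr, volume_cm3 = 2, mixing = 0, seed = 5)
  expect_equal(sum(rec$membership), round(2 / vox))
  rec2 <- generate_recurrence(tr, volume_cm3 = 2, mixing = 0, seed = 5)
  expect_identical(rec$membership, rec2$membership)
  expect_equal(sum(generate_recurrence(tr, 0, 1, 1)$membership), 0L)
})

test_that("infiltration-weighted recurrence concentrates at the core boundary", {
  # small decay length so the weight is sharply peaked outside the core
  p <- small_phantom_params(sigma_inf = 4, seed = 21L)
  tr <- generate_phantom(p)
  pts <- grid_coordinates_mm(tr$clinical_grid)
  hits <- 0L
  nrep <- 100L
  for (s in seq_len(nrep)) {
    rec <- generate_recurrence(tr, volume_cm3 = 1, mixing = 1, seed = s)
    cen <- colMeans(pts[which(rec$membership), , drop = FALSE])
    d <- sqrt(sum((cen - tr$tumor_center)^2))
    if (abs(d - p$core_radius) <= 2 * p$sigma_inf) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * nrep)
})
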