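gridm <- volume_grid(c(10, 10, 10), c(1, 1, 1))

test_that("dice handles identity, disjointness and the small worked case", {
  set.seed(12)
  a <- random_mask(gridm, 0.3, "a")
  expect_equal(dice(a, a), 1.0)
  b <- smri_mask(!a$membership, gridm, "b")
  expect_equal(dice(a, b), 0.0)
  # |a| = |b| = 2 with overlap 1 -> 2*1/4
  m1 <- smri_mask(array(FALSE, gridm$shape), gridm)
  m2 <- smri_mask(array(FALSE, gridm$shape), gridm)
  m1$membership[c(1, 2)] <- TRUE
  m2$membership[c(2, 3)] <- TRUE
  expect_equal(dice(m1, m2), 0.5)
  empty <- smri_mask(array(FALSE, gridm$shape), gridm)
  expect_message(d <- dice(empty, empty), "both masks empty")
  expect_equal(d, 1.0)
  other <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  expect_error(dice(a, random_mask(other)), "same grid")
})

test_that("volumes and percent increase follow the definitions", {
  expect_equal(volume_cm3(smri_mask(array(FALSE, gridm$shape), gridm)), 0)
  ga <- volume_grid(c(10, 10, 10), c(4.4, 4.4, 5.6))
  m7 <- smri_mask(array(FALSE, ga$shape), ga)
  m7$membership[1:7] <- TRUE
  expect_equal(volume_cm3(m7), 7 * 0.108416, tolerance = 1e-9)

  base <- smri_mask(array(FALSE, gridm$shape), gridm)
  base$membership[1:100] <- TRUE
  expect_equal(percent_increase(base, base), 0)
  dbl <- smri_mask(array(FALSE, gridm$shape), gridm)
  dbl$membership[1:200] <- TRUE
  expect_equal(percent_increase(base, dbl), 100)
  # 40 cm^3 -> 69.64 cm^3 is a 74.1% increase
  expect_equal(100 * (69.64 - 40) / 40, 74.1, tolerance = 1e-9)
  expect_error(percent_increase(smri_mask(array(FALSE, gridm$shape), gridm),
                                base), "empty")
})

test_that("isodose masks use a closed threshold", {
  d <- scalar_map(array(60, gridm$shape), gridm, unit = "Gy")
  expect_true(all(isodose_mask(d, 60)$membership))
  expect_false(any(isodose_mask(d, 60.001)$membership))
})

test_that("volume outside a region partitions the segmentation", {
  seg <- smri_mask(array(FALSE, gridm$shape), gridm)
  seg$membership[1:100] <- TRUE            # 0.1 cm^3
  region <- smri_mask(array(FALSE, gridm$shape), gridm)
  region$membership[1:60] <- TRUE
  out <- volume_outside(seg, region)
  expect_equal(out$cm3, 0.04)
  expect_equal(out$pct, 40)
  expect_equal(volume_outside(seg, seg), list(cm3 = 0, pct = 0))
  none <- smri_mask(array(FALSE, gridm$shape), gridm)
  none$membership[900:1000] <- TRUE
  expect_equal(volume_outside(seg, none)$pct, 100)
  expect_warning(ve <- volume_outside(none_empty <- smri_mask(
    array(FALSE, gridm$shape), gridm), region), "empty")
  expect_equal(ve, list(cm3 = 0, pct = 0))
  # additivity: outside + inside = total, exactly
  expect_equal(out$cm3 + 0.06, volume_cm3(seg))
})

test_that("coverage and max dose behave on constructed fixtures", {
  target <- smri_mask(array(FALSE, gridm$shape), gridm)
  target$membership[1:100] <- TRUE
  dv <- array(0, gridm$shape)
  dv[1:82] <- 60
  dose <- scalar_map(dv, gridm, unit = "Gy")
  expect_equal(coverage_percent(target, dose, 60), 82.0)
  expect_equal(coverage_percent(target, dose, 0), 100)
  full <- scalar_map(array(61, gridm$shape), gridm, unit = "Gy")
  expect_equal(coverage_percent(target, full, 60), 100)
  expect_error(coverage_percent(smri_mask(array(FALSE, gridm$shape), gridm),
                                dose, 60), "empty")
  # coverage monotone non-increasing in level
  set.seed(13)
  rd <- random_dose(gridm)
  covs <- vapply(seq(0, 70, by = 5),
                 function(L) coverage_percent(target, rd, L), 1.0)
  expect_true(all(diff(covs) <= 0))

  organ <- smri_mask(array(FALSE, gridm$shape), gridm)
  organ$membership[200:260] <- TRUE
  cv <- array(53.9, gridm$shape)
  expect_equal(max_dose_in(organ, scalar_map(cv, gridm, unit = "Gy")), 53.9)
  cv[230] <- 59.9
  expect_equal(max_dose_in(organ, scalar_map(cv, gridm, unit = "Gy")), 59.9)
  expect_error(max_dose_in(smri_mask(array(FALSE, gridm$shape), gridm),
                           dose), "empty")
})

test_that("recurrence coverage is monotone under target union", {
  set.seed(14)
  for (rep in 1:20) {
    rec <- random_mask(gridm, 0.2, "rec")
    if (!any(rec$membership)) next
    ctv <- random_mask(gridm, 0.3, "ctv")
    seg <- random_mask(gridm, 0.2, "seg")
    up <- mask_union(ctv, seg)
    expect_gte(recurrence_coverage(rec, up), recurrence_coverage(rec, ctv))
  }
  half <- smri_mask(array(FALSE, gridm$shape), gridm)
  half$membership[1:100] <- TRUE
  ctv <- smri_mask(array(FALSE, gridm$shape), gridm)
  ctv$membership[51:150] <- TRUE
  expect_equal(recurrence_coverage(half, ctv), 50)
})

test_that("evaluate_plan populates the record and flags violations", {
  tr <- small_truth()
  cfg <- plan_config()
  pv <- build_conventional(tr$gtv1, tr$gtv2, tr$brain, cfg)
  dose <- generate_dose(list(list(mask = pv$ptv1, prescription = 51),
                             list(mask = pv$ptv2, prescription = 60)),
                        tr$clinical_grid)
  rec <- evaluate_plan(pv, dose, list(brainstem = tr$brainstem),
                       cfg = cfg, patient_id = "p")
  expect_equal(nrow(rec), 1)
  expect_gte(rec$coverage_ptv1_pct, 95)
  expect_gte(rec$coverage_ptv2_pct, 95)
  expect_true(rec$coverage_goal_met)
  expect_true(rec$brainstem_hard_ok)

  # halved dose: no voxel reaches prescription, violation flagged
  half <- scalar_map(dose$values * 0.5, tr$clinical_grid, unit = "Gy")
  rec2 <- evaluate_plan(pv, half, list(brainstem = tr$brainstem),
                        cfg = cfg, patient_id = "p")
  expect_equal(rec2$coverage_ptv2_pct, 0)
  expect_false(rec2$coverage_goal_met)

  # organ overlapping PTV2 receives the full boost dose
  hot <- evaluate_plan(pv, dose, list(brainstem = pv$ptv2), cfg = cfg)
  expect_equal(hot$brainstem_max_gy, 60, tolerance = 1e-9)
  expect_false(hot$brainstem_soft_ok)
})

test_that("metrics equal index-set oracles on random instances", {
  set.seed(15)
  for (rep in 1:25) {
    shp <- sample(5:20, 3, replace = TRUE)
    sp <- runif(3, 0.8, 6)
    g <- volume_grid(shp, sp)
    a <- random_mask(g, runif(1, 0.1, 0.6), "a")
    b <- random_mask(g, runif(1, 0.1, 0.6), "b")
    d <- random_dose(g)
    lv <- runif(1, 0, 70)
    expect_identical(dice(a, b), bf_dice(a, b))
    expect_identical(volume_outside(a, b), bf_volume_outside(a, b))
    if (any(a$membership)) {
      expect_identical(coverage_percent(a, d, lv), bf_coverage(a, d, lv))
      expect_identical(max_dose_in(a, d), bf_max_dose(a, d))
    }
  }
})
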