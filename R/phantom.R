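#' Parameters for the synthetic brain-tumor phantom
#'
#' The phantom emulates the data a pre-treatment glioblastoma planning
#' session produces: a fine "clinical" grid carrying anatomy and contours,
#' and a coarse spectroscopic grid (nominal 4.4 x 4.4 x 5.6 mm voxels)
#' carrying metabolite maps. The tumor has a resection cavity nested in an
#' enhancing core nested in a FLAIR abnormality, and an infiltration
#' gradient extending beyond the enhancing core:
#' `f(x) = A * exp(-d(x)^2 / sigma_inf^2)` where `d(x)` is the Euclidean
#' distance outside the core surface (`f = A` inside the core, 0 outside the
#' brain). The Cho/NAA ratio is `baseline * (1 + f(x)) * eps(x)` with
#' multiplicative lognormal noise `eps` of the stated coefficient of
#' variation, sampled at spectroscopic voxel centers; Cho is raised and NAA
#' suppressed toward the core so that their quotient equals this field.
#'
#' Default geometry is a reduced-size head (120^3 voxels at 1.5 mm) chosen
#' for fast iteration; radii are typical of a post-resection glioblastoma
#' (core ~3 cm diameter) and the NAWM absolute Cho/NAA baseline of 0.6
#' makes the 1.5-/1.75-/2.0-fold thresholds correspond to absolute ratios
#' of 0.9-1.2.
#'
#' @param clinical_shape,clinical_spacing Clinical grid voxels and mm
#'   spacing.
#' @param smri_spacing Spectroscopic grid mm spacing (default
#'   `c(4.4, 4.4, 5.6)`).
#' @param tumor_side `"left"` or `"right"` hemisphere.
#' @param tumor_center Optional world-mm tumor center; defaults to a
#'   plausible deep-hemisphere location. Must lie inside the brain.
#' @param cavity_radius,core_radius,flair_radius Nested radii in mm
#'   (strictly increasing).
#' @param sigma_inf Infiltration decay length in mm (> 0).
#' @param amplitude Peak fold-elevation `A` of Cho/NAA at the core
#'   boundary (> 0).
#' @param baseline Absolute NAWM Cho/NAA ratio.
#' @param cho_nawm Absolute NAWM Cho level (arbitrary signal units).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on the ratio (>= 0).
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   phantoms.
#' @return A `phantom_params` object.
#' @export
phantom_params <- function(clinical_shape = c(120, 120, 120),
                           clinical_spacing = c(1.5, 1.5, 1.5),
                           smri_spacing = c(4.4, 4.4, 5.6),
                           tumor_side = c("right", "left"),
                           tumor_center = NULL,
                           cavity_radius = 8,
                           core_radius = 15,
                           flair_radius = 25,
                           sigma_inf = 12,
                           amplitude = 2,
                           baseline = 0.6,
                           cho_nawm = 1.2,
                           noise_cv = 0.1,
                           seed = 1L) {
  tumor_side <- match.arg(tumor_side)
  if (!(cavity_radius < core_radius && core_radius < flair_radius))
    stop("radii must satisfy cavity < core < FLAIR, strictly")
  if (sigma_inf <= 0) stop("sigma_inf must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (baseline <= 0 || cho_nawm <= 0) stop("baseline levels must be > 0")
  p <- list(
    clinical_shape = as.integer(clinical_shape),
    clinical_spacing = as.double(clinical_spacing),
    smri_spacing = as.double(smri_spacing),
    tumor_side = tumor_side,
    tumor_center = tumor_center,
    cavity_radius = cavity_radius, core_radius = core_radius,
    flair_radius = flair_radius,
    sigma_inf = sigma_inf, amplitude = amplitude,
    baseline = baseline, cho_nawm = cho_nawm,
    noise_cv = noise_cv, seed = as.integer(seed)
  )
  class(p) <- "phantom_params"
  p
}

# geometry derived from params: grids, brain ellipsoid, default tumor center
phantom_geometry <- function(p) {
  cg <- volume_grid(p$clinical_shape, p$clinical_spacing)
  world <- p$clinical_shape * p$clinical_spacing
  smri_shape <- pmax(2L, as.integer(ceiling(
    (p$clinical_shape - 1) * p$clinical_spacing / p$smri_spacing)) + 1L)
  sg <- volume_grid(smri_shape, p$smri_spacing)
  center <- (p$clinical_shape - 1) * p$clinical_spacing / 2
  semi <- 0.45 * world
  tc <- p$tumor_center
  if (is.null(tc)) {
    sgn <- if (p$tumor_side == "right") 1 else -1
    tc <- center + c(sgn * 0.4 * semi[1], 0.1 * semi[2], 0)
  }
  list(clinical_grid = cg, smri_grid = sg, center = center, semi = semi,
       tumor_center = as.double(tc))
}

ellipsoid_rho <- function(pts, center, semi) {
  sqrt(((pts[, 1] - center[1]) / semi[1])^2 +
       ((pts[, 2] - center[2]) / semi[2])^2 +
       ((pts[, 3] - center[3]) / semi[3])^2)
}

# continuous infiltration fold-elevation field at world points (mm)
infiltration_field <- function(pts, p, geo) {
  d <- sqrt((pts[, 1] - geo$tumor_center[1])^2 +
            (pts[, 2] - geo$tumor_center[2])^2 +
            (pts[, 3] - geo$tumor_center[3])^2)
  dout <- pmax(0, d - p$core_radius)
  f <- p$amplitude * exp(-(dout / p$sigma_inf)^2)
  f[ellipsoid_rho(pts, geo$center, geo$semi) > 1] <- 0
  f
}

run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a complete synthetic patient
#'
#' Builds every input the planning pipeline needs, with known ground truth:
#' a smooth ellipsoidal brain split into hemispheres by the midsagittal
#' plane, a white-matter probability map high in a deep-brain shell,
#' FLAIR (GTV1) and enhancing-core (GTV2) masks on the clinical grid, the
#' continuous infiltration field, and Cho / NAA / Cho-NAA-ratio maps
#' sampled on the coarse spectroscopic grid (valid only inside the brain).
#'
#' @param p A [phantom_params()].
#' @return A `phantom_truth` list with elements `params`, `clinical_grid`,
#'   `smri_grid`, `brain`, `hemispheres`, `wm_prob`, `gtv1`, `gtv2`,
#'   `cavity`, `brainstem` (a central-inferior organ-at-risk surrogate),
#'   `infiltration` (clinical grid), `cho`, `naa`, `cho_naa`
#'   (spectroscopic grid), `tumor_side`, `tumor_center`.
#' @export
generate_phantom <- function(p) {
  stopifnot(inherits(p, "phantom_params"))
  geo <- phantom_geometry(p)
  cg <- geo$clinical_grid; sg <- geo$smri_grid

  if (ellipsoid_rho(matrix(geo$tumor_center, 1), geo$center, geo$semi) > 1)
    stop("tumor center lies outside the brain")

  pts_c <- grid_coordinates_mm(cg)
  rho_c <- ellipsoid_rho(pts_c, geo$center, geo$semi)
  brain_c <- array(rho_c <= 1, cg$shape)
  hemi <- array(ifelse(pts_c[, 1] < geo$center[1], 1, 2), cg$shape)
  wm <- pmin(1, pmax(0, (0.85 - rho_c) / 0.1)) *
    pmin(1, pmax(0, (rho_c - 0.25) / 0.1))
  wm <- array(wm, cg$shape)

  dist_c <- sqrt((pts_c[, 1] - geo$tumor_center[1])^2 +
                 (pts_c[, 2] - geo$tumor_center[2])^2 +
                 (pts_c[, 3] - geo$tumor_center[3])^2)
  gtv2 <- array(dist_c <= p$core_radius, cg$shape) & brain_c
  gtv1 <- array(dist_c <= p$flair_radius, cg$shape) & brain_c
  cavity <- array(dist_c <= p$cavity_radius, cg$shape) & brain_c
  f_c <- array(infiltration_field(pts_c, p, geo), cg$shape)

  # brainstem surrogate: small central-inferior ball, clipped to brain
  bs_center <- geo$center + c(0, 0, -0.45 * geo$semi[3])
  bs <- array(sqrt((pts_c[, 1] - bs_center[1])^2 +
                   (pts_c[, 2] - bs_center[2])^2 +
                   (pts_c[, 3] - bs_center[3])^2) <= 8, cg$shape) & brain_c

  pts_s <- grid_coordinates_mm(sg)
  brain_s <- ellipsoid_rho(pts_s, geo$center, geo$semi) <= 1
  f_s <- infiltration_field(pts_s, p, geo)
  eps <- run_seeded(p$seed, {
    if (p$noise_cv > 0) {
      sdlog <- sqrt(log(1 + p$noise_cv^2))
      stats::rlnorm(nrow(pts_s), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(pts_s))
  })
  cho_v <- p$cho_nawm * sqrt(1 + f_s) * sqrt(eps)
  naa_v <- (p$cho_nawm / p$baseline) / (sqrt(1 + f_s) * sqrt(eps))
  ratio_v <- p$baseline * (1 + f_s) * eps
  valid_s <- array(brain_s, sg$shape)
  to_map <- function(v) {
    v[!brain_s] <- NA_real_
    scalar_map(array(v, sg$shape), sg, unit = "arbitrary", valid = valid_s)
  }

  structure(list(
    params = p,
    clinical_grid = cg, smri_grid = sg,
    brain = smri_mask(brain_c, cg, "brain"),
    brain_smri = smri_mask(valid_s, sg, "brain"),
    hemispheres = scalar_map(hemi, cg, unit = "arbitrary"),
    wm_prob = scalar_map(wm, cg, unit = "arbitrary"),
    gtv1 = smri_mask(gtv1, cg, "GTV1"),
    gtv2 = smri_mask(gtv2, cg, "GTV2"),
    cavity = smri_mask(cavity, cg, "cavity"),
    brainstem = smri_mask(bs, cg, "brainstem"),
    infiltration = scalar_map(f_c, cg, unit = "arbitrary"),
    cho = to_map(cho_v),
    naa = to_map(naa_v),
    cho_naa = to_map(ratio_v),
    tumor_side = p$tumor_side,
    tumor_center = geo$tumor_center
  ), class = "phantom_truth")
}

#' Analytic infiltration region of a phantom
#'
#' Closed-form region where the true fold-elevation field satisfies
#' `1 + f(x) >= level`, i.e. the ball of radius
#' `core_radius + sigma_inf * sqrt(log(A / (level - 1)))` intersected with
#' the brain. This is the ground truth against which threshold
#' segmentations of the generated maps are scored.
#'
#' @param truth A `phantom_truth`.
#' @param level Fold threshold (> 1 for a finite region).
#' @param grid Grid to rasterize onto (default the clinical grid).
#' @return An [smri_mask()].
#' @export
analytic_abnormality <- function(truth, level, grid = truth$clinical_grid) {
  p <- truth$params
  geo <- phantom_geometry(p)
  pts <- grid_coordinates_mm(grid)
  brain <- ellipsoid_rho(pts, geo$center, geo$semi) <= 1
  if (level - 1 > p$amplitude) {
    return(smri_mask(array(FALSE, grid$shape), grid,
                     sprintf("abnormality_%g", level)))
  }
  if (level <= 1) {
    return(smri_mask(array(brain, grid$shape), grid,
                     sprintf("abnormality_%g", level)))
  }
  radius <- p$core_radius + p$sigma_inf * sqrt(log(p$amplitude / (level - 1)))
  d <- sqrt((pts[, 1] - geo$tumor_center[1])^2 +
            (pts[, 2] - geo$tumor_center[2])^2 +
            (pts[, 3] - geo$tumor_center[3])^2)
  smri_mask(array(d <= radius & brain, grid$shape), grid,
            sprintf("abnormality_%g", level))
}

#' Logistic dose falloff profile
#'
#' The conformal dose surrogate assigns, for each target, its prescription
#' inside the target and `prescription * dose_falloff(d, penumbra_mm)` at
#' Euclidean distance `d` mm outside it, where
#' `dose_falloff(d, p) = 2 / (1 + exp(2 d / p))` — equal to 1 at the target
#' surface and monotonically decreasing with distance.
#'
#' @param d Distance outside the target in mm (>= 0).
#' @param penumbra_mm Falloff scale in mm.
#' @return Fraction of prescription in (0, 1].
#' @export
dose_falloff <- function(d, penumbra_mm) {
  2 / (1 + exp(2 * pmax(d, 0) / penumbra_mm))
}

#' Simulate a conformal dose distribution
#'
#' Parametric surrogate for inverse-planned conformal dose: each voxel
#' receives the maximum over targets of
#' `prescription * dose_falloff(d, penumbra_mm)`, with `d` the Euclidean
#' distance (anisotropic-exact) outside the target. Voxels inside a target
#' receive at least its prescription, and dose is monotonically
#' non-increasing with distance from each target.
#'
#' @param targets A list of `list(mask = <smri_mask>, prescription = <Gy>)`.
#' @param grid The dose grid (must match the target masks).
#' @param penumbra_mm Logistic falloff scale in mm (default 5).
#' @return A [scalar_map()] in Gy.
#' @export
generate_dose <- function(targets, grid, penumbra_mm = 5) {
  if (length(targets) == 0) stop("at least one target is required")
  vals <- array(0, grid$shape)
  for (tg in targets) {
    stopifnot(inherits(tg$mask, "smri_mask"), is.numeric(tg$prescription))
    if (!same_grid(tg$mask$grid, grid))
      stop("target mask grid does not match the dose grid")
    if (!any(tg$mask$membership)) stop("empty target mask")
    d <- sqrt(edt_squared_cpp(tg$mask$membership, grid$shape, grid$spacing))
    dose_t <- tg$prescription * ifelse(d <= 0, 1, dose_falloff(d, penumbra_mm))
    vals <- pmax(vals, dose_t)
  }
  scalar_map(array(vals, grid$shape), grid, unit = "Gy")
}

#' Simulate a recurrence mask
#'
#' Emulates post-treatment recurrent contrast enhancement: a connected blob
#' seeded at a voxel drawn (outside the enhancing core) with probability
#' proportional to `mixing * f(x) + (1 - mixing)`, where `f` is the true
#' infiltration field — so at `mixing = 1` recurrence arises preferentially
#' where pre-treatment Cho/NAA was elevated, and at `mixing = 0` the seed is
#' uniform over the brain. The blob is grown to the requested volume by
#' taking the nearest brain voxels around the seed.
#'
#' @param truth A `phantom_truth`.
#' @param volume_cm3 Requested recurrence volume (cm^3); 0 gives an empty
#'   mask.
#' @param mixing Infiltration bias in `[0, 1]`.
#' @param seed RNG seed.
#' @return An [smri_mask()] on the clinical grid, labelled `"recurrence"`.
#' @export
generate_recurrence <- function(truth, volume_cm3 = 2, mixing = 1,
                                seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"),
            mixing >= 0, mixing <= 1, volume_cm3 >= 0)
  cg <- truth$clinical_grid
  n_req <- round(volume_cm3 / voxel_volume_cm3(cg))
  if (n_req == 0)
    return(smri_mask(array(FALSE, cg$shape), cg, "recurrence"))
  region <- truth$brain$membership & !truth$gtv2$membership
  idx <- which(region)
  f <- as.vector(truth$infiltration$values)[idx]
  w <- mixing * f + (1 - mixing)
  if (sum(w) <= 0) w <- rep(1, length(idx))
  seed_idx <- run_seeded(seed, sample(idx, 1, prob = w))
  pts <- grid_coordinates_mm(cg)
  seed_pt <- pts[seed_idx, ]
  brain_idx <- which(truth$brain$membership)
  d2 <- (pts[brain_idx, 1] - seed_pt[1])^2 +
        (pts[brain_idx, 2] - seed_pt[2])^2 +
        (pts[brain_idx, 3] - seed_pt[3])^2
  n_take <- min(n_req, length(brain_idx))
  sel <- brain_idx[order(d2)[seq_len(n_take)]]
  mem <- array(FALSE, cg$shape)
  mem[sel] <- TRUE
  smri_mask(mem, cg, "recurrence")
}
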