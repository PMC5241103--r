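# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use index-set primitives (which/intersect/setdiff,
# explicit loops) rather than the package's vectorized logical arithmetic.

bf_dice <- function(a, b) {
  ia <- which(a$membership); ib <- which(b$membership)
  if (length(ia) + length(ib) == 0) return(1.0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

bf_volume_outside <- function(seg, region) {
  is <- which(seg$membership); ir <- which(region$membership)
  nout <- length(setdiff(is, ir))
  list(cm3 = nout * (prod(seg$grid$spacing) / 1000),
       pct = if (length(is)) 100 * nout / length(is) else 0)
}

# Minkowski-sum enumeration: union of lattice offset balls around members.
# Independent of the EDT path; exact for center-to-center semantics.
bf_minkowski_expand <- function(m, margin_mm) {
  g <- m$grid
  no <- floor(margin_mm / g$spacing)
  offs <- as.matrix(expand.grid(x = -no[1]:no[1], y = -no[2]:no[2],
                                z = -no[3]:no[3]))
  keep <- (offs[, 1] * g$spacing[1])^2 + (offs[, 2] * g$spacing[2])^2 +
    (offs[, 3] * g$spacing[3])^2 <= margin_mm^2
  offs <- offs[keep, , drop = FALSE]
  idx <- which(m$membership, arr.ind = TRUE)
  mem <- array(FALSE, g$shape)
  for (r in seq_len(nrow(offs))) {
    sh <- cbind(idx[, 1] + offs[r, 1], idx[, 2] + offs[r, 2],
                idx[, 3] + offs[r, 3])
    ok <- sh[, 1] >= 1 & sh[, 1] <= g$shape[1] &
      sh[, 2] >= 1 & sh[, 2] <= g$shape[2] &
      sh[, 3] >= 1 & sh[, 3] <= g$shape[3]
    mem[sh[ok, , drop = FALSE]] <- TRUE
  }
  smri_mask(mem, g, m$label)
}

bf_coverage <- function(target, dose, level) {
  it <- which(target$membership)
  hot <- which(dose$values >= level)
  100 * length(intersect(it, hot)) / length(it)
}

bf_max_dose <- function(organ, dose) {
  mx <- -Inf
  for (i in which(organ$membership)) mx <- max(mx, dose$values[i])
  mx
}

# all-pairs distance-threshold expansion (exact oracle for expand_margin)
bf_expand <- function(m, margin_mm) {
  pts <- grid_coordinates_mm(m$grid)
  src <- pts[which(m$membership), , drop = FALSE]
  mem <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (pts[i, 1] - src[, 1])^2 + (pts[i, 2] - src[, 2])^2 +
      (pts[i, 3] - src[, 3])^2
    any(sqrt(d2) <= margin_mm)
  }, TRUE)
  smri_mask(array(mem, m$grid$shape), m$grid, m$label)
}

random_mask <- function(grid, p = 0.2, label = "m") {
  smri_mask(array(stats::runif(prod(grid$shape)) < p, grid$shape),
            grid, label)
}

random_dose <- function(grid, max_gy = 70) {
  scalar_map(array(stats::runif(prod(grid$shape), 0, max_gy), grid$shape),
             grid, unit = "Gy")
}

# a small, fast phantom configuration used throughout the unit tests
small_phantom_params <- function(..., noise_cv = 0, seed = 11L) {
  phantom_params(clinical_shape = c(60, 60, 50),
                 clinical_spacing = c(3, 3, 3),
                 noise_cv = noise_cv, seed = seed, ...)
}

# noiseless small phantom, built once per test run
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_phantom_params())
    cache
  }
})

ball_mask <- function(grid, center, radius, label = "ball") {
  pts <- grid_coordinates_mm(grid)
  d <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
            (pts[, 3] - center[3])^2)
  smri_mask(array(d <= radius, grid$shape), grid, label)
}
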