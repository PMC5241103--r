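test_that("grid construction validates geometry and voxel volume", {
  g <- volume_grid(c(10, 10, 10), c(4.4, 4.4, 5.6))
  expect_equal(voxel_volume_cm3(g), 4.4 * 4.4 * 5.6 / 1000)
  expect_error(volume_grid(c(0, 10, 10), c(1, 1, 1)), ">= 1")
  expect_error(volume_grid(c(5, 5, 5), c(1, -1, 1)), "positive")
})

test_that("mask write/read round-trips membership and grid exactly", {
  g <- volume_grid(c(10, 10, 10), c(1, 1, 1), origin = c(-5, 3, 12))
  set.seed(1)
  m <- random_mask(g, 0.3, "roundtrip")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  m2 <- read_volume(f, as = "mask")
  expect_identical(m2$membership, m$membership)
  expect_equal(m2$grid$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(m2$grid$origin, g$origin, tolerance = 1e-4)
  # 1000 true voxels at 1 mm isotropic occupy exactly 1 cm^3
  mem <- array(FALSE, g$shape); mem[seq_len(1000)] <- TRUE
  expect_equal(volume_cm3(smri_mask(mem, g)), 1.0)
})

test_that("single anisotropic voxel has the analytic volume", {
  g <- volume_grid(c(3, 3, 3), c(4.4, 4.4, 5.6))
  mem <- array(FALSE, g$shape); mem[2, 2, 2] <- TRUE
  expect_equal(volume_cm3(smri_mask(mem, g)), 0.108416, tolerance = 1e-9)
})

test_that("scalar write/read preserves values, validity and spacing", {
  g <- volume_grid(c(8, 7, 6), c(4.4, 4.4, 5.6))
  set.seed(2)
  vals <- array(runif(prod(g$shape), 0.5, 3), g$shape)
  vals[1, 1, 1] <- NA  # invalid voxel
  s <- scalar_map(vals, g, unit = "fold-normal")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(s, f)
  s2 <- read_volume(f, as = "scalar", unit = "fold-normal")
  expect_lt(max(abs(s2$values[s$valid] - s$values[s$valid])), 1e-6)
  expect_identical(s2$valid, s$valid)
  expect_equal(s2$grid$spacing, c(4.4, 4.4, 5.6), tolerance = 1e-4)
  # a mask read back as scalar holds only 0/1
  m <- smri_mask(array(vals > 1.5, g$shape), g)
  write_volume(m, f)
  sm <- read_volume(f, as = "scalar")
  expect_true(all(sm$values %in% c(0, 1)))
})

test_that("flipped axis-aligned affines are normalized on load", {
  g <- volume_grid(c(6, 5, 4), c(2, 3, 4), origin = c(1, 2, 3))
  set.seed(3)
  m <- random_mask(g, 0.4)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  # write with a flipped x-axis: same voxels, LAS-style header
  arr <- array(as.integer(m$membership), g$shape)
  arr_fl <- arr[rev(seq_len(g$shape[1])), , , drop = FALSE]
  img <- RNifti::asNifti(arr_fl)
  RNifti::pixdim(img) <- g$spacing
  o_fl <- g$origin + c((g$shape[1] - 1) * g$spacing[1], 0, 0)
  aff <- rbind(cbind(diag(c(-1, 1, 1) * g$spacing), o_fl), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, f, datatype = "uint8")
  m2 <- read_volume(f, as = "mask")
  expect_identical(m2$membership, m$membership)
  expect_equal(m2$grid$origin, g$origin, tolerance = 1e-4)
})

test_that("missing files and non-3D content are rejected", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")),
               "not found")
})

test_that("rasterization follows voxel-center even-odd inclusion", {
  g <- volume_grid(c(30, 30, 5), c(1, 1, 1))
  # axis-aligned 10 x 10 mm square: centers 5.5..14.5 strictly inside
  sq <- rbind(c(5, 5), c(15, 5), c(15, 15), c(5, 15))
  ss <- structure_set(list(box = list(list(z = 2, polygons = list(sq)))))
  masks <- rasterize_structure(ss, g)
  expect_equal(sum(masks$box$membership), 100L)
  expect_true(all(which(apply(masks$box$membership, 3, any)) == 3L))

  # nested polygon subtracts a hole
  hole <- rbind(c(8, 8), c(12, 8), c(12, 12), c(8, 12))
  ss2 <- structure_set(list(donut = list(
    list(z = 2, polygons = list(sq, hole)))))
  donut <- rasterize_structure(ss2, g)$donut
  expect_equal(sum(donut$membership), 100L - 16L)

  # empty structure set -> no masks
  expect_length(rasterize_structure(structure_set(), g), 0)

  # non-coplanar polygon is an error
  ss3 <- structure_set(list(bad = list(list(z = 2.37, polygons = list(sq)))))
  expect_error(rasterize_structure(ss3, g), "coplanar")
})

test_that("rasterized circle area matches the analytic value within 2%", {
  g <- volume_grid(c(60, 60, 3), c(1, 1, 1))
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(29.5 + 20 * cos(th), 29.5 + 20 * sin(th))
  ss <- structure_set(list(c20 = list(list(z = 1, polygons = list(circ)))))
  n <- sum(rasterize_structure(ss, g)$c20$membership)
  expect_lt(abs(n - pi * 20^2) / (pi * 20^2), 0.02)
})

test_that("contour extraction round-trips smooth masks with Dice >= 0.99", {
  g <- volume_grid(c(26, 26, 26), c(1, 1, 1))
  sph <- ball_mask(g, c(12.5, 12.5, 12.5), 10, "sphere")
  ss <- extract_contours(sph)
  back <- rasterize_structure(ss, g)$sphere
  expect_gte(dice(sph, back), 0.99)

  # empty mask -> empty structure set, not an error
  empty <- smri_mask(array(FALSE, g$shape), g)
  expect_length(extract_contours(empty)$structures, 0)

  # single-slice rectangle -> one polygon whose bounding box matches
  mem <- array(FALSE, g$shape); mem[6:15, 9:20, 12] <- TRUE
  rect <- smri_mask(mem, g, "rect")
  sr <- extract_contours(rect)
  slices <- sr$structures$rect
  expect_length(slices, 1)
  expect_length(slices[[1]]$polygons, 1)
  rt <- rasterize_structure(sr, g)$rect
  expect_identical(rt$membership, rect$membership)

  # two disjoint blobs -> two polygons on shared slices
  mem2 <- array(FALSE, g$shape)
  mem2[3:7, 3:7, 10:12] <- TRUE
  mem2[15:20, 15:20, 10:12] <- TRUE
  blobs <- smri_mask(mem2, g, "blobs")
  sb <- extract_contours(blobs)
  npoly <- vapply(sb$structures$blobs, function(sl) length(sl$polygons), 1L)
  expect_true(all(npoly == 2L))
})

test_that("structure sets round-trip through the JSON dialect", {
  sq <- rbind(c(5, 5), c(15, 5), c(15, 15), c(5, 15))
  ss <- structure_set(list(a = list(list(z = 2, polygons = list(sq))),
                           b = list(list(z = 4, polygons = list(sq + 1)))))
  f <- withr::local_tempfile(fileext = ".json")
  write_structures(ss, f)
  ss2 <- read_structures(f)
  expect_equal(names(ss2$structures), c("a", "b"))
  expect_equal(ss2$structures$a[[1]]$z, 2)
  expect_equal(unname(ss2$structures$b[[1]]$polygons[[1]]), unname(sq + 1))
})

test_that("trilinear resampling is node-exact, affine-exact and bounded", {
  src_g <- volume_grid(c(12, 11, 10), c(4.4, 4.4, 5.6))
  dst_g <- volume_grid(c(40, 40, 40), c(1, 1, 1), origin = c(2, 2, 2))

  # constant field stays constant inside support
  const <- scalar_map(array(2, src_g$shape), src_g)
  rc <- resample_trilinear(const, dst_g)
  expect_true(all(abs(rc$values[rc$valid] - 2) < 1e-12))

  # destination grid coincident with source nodes reproduces values
  set.seed(4)
  vals <- array(runif(prod(src_g$shape)), src_g$shape)
  s <- scalar_map(vals, src_g)
  node_g <- volume_grid(c(5, 5, 5), src_g$spacing,
                        origin = src_g$spacing * 2)
  rn <- resample_trilinear(s, node_g)
  expect_equal(rn$values, vals[3:7, 3:7, 3:7], tolerance = 1e-12)

  # linear ramp f(x) = x reproduced exactly inside support
  pts <- grid_coordinates_mm(src_g)
  ramp <- scalar_map(array(pts[, 1], src_g$shape), src_g)
  rr <- resample_trilinear(ramp, dst_g)
  xs <- grid_axis_mm(dst_g, 1)
  expected <- array(rep(xs, times = prod(dst_g$shape[2:3])), dst_g$shape)
  expect_lt(max(abs(rr$values[rr$valid] - expected[rr$valid])), 1e-6)

  # interpolation bounded by source range
  rs <- resample_trilinear(s, dst_g)
  expect_true(all(rs$values[rs$valid] >= min(vals) - 1e-12))
  expect_true(all(rs$values[rs$valid] <= max(vals) + 1e-12))

  # disjoint grids: all-invalid with a warning
  far_g <- volume_grid(c(5, 5, 5), c(1, 1, 1), origin = c(1e4, 1e4, 1e4))
  expect_warning(rf <- resample_trilinear(s, far_g), "outside")
  expect_false(any(rf$valid))
})

test_that("invalid source voxels poison only their interpolation stencils", {
  src_g <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  vals <- array(1, src_g$shape)
  valid <- array(TRUE, src_g$shape)
  valid[5, 5, 5] <- FALSE
  s <- scalar_map(vals, src_g, valid = valid)
  dst_g <- volume_grid(c(19, 19, 19), c(1, 1, 1))
  r <- resample_trilinear(s, dst_g)
  expect_false(all(r$valid))
  # voxels far from the invalid node are untouched
  expect_true(r$valid[1, 1, 1] && abs(r$values[1, 1, 1] - 1) < 1e-12)
})
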