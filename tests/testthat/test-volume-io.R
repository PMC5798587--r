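test_that("volumes round-trip bit-exactly through every supported format", {
  ramp <- volume3d(array(as.numeric(1:120), c(4, 5, 6)), voxel_size = 5,
                   origin = c(10, 20, 30))
  for (ext in c("nrrd", "mha", "raw")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_volume(ramp, f)
    back <- read_volume(f)
    expect_identical(back$data, ramp$data, label = ext)
    expect_equal(back$voxel_size, 5)
    expect_equal(back$origin, c(10, 20, 30))
  }
  # TIFF: integer data in 0..65535 round-trips exactly; no origin in TIFF
  f <- tempfile(fileext = ".tif")
  write_volume(ramp, f)
  back <- read_volume(f, voxel_size_um = 5)
  expect_equal(back$data, ramp$data)
  expect_equal(back$voxel_size, 5)
})

test_that("TIFF stacks map slices to increasing z and demand a voxel size", {
  slices <- list(matrix(c(1, 2, 3, 4), 2, 2), matrix(c(5, 6, 7, 8), 2, 2),
                 matrix(c(9, 10, 11, 12), 2, 2))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(slices, function(m) m / 65535), f, bits.per.sample = 16L)
  v <- read_volume(f, voxel_size_um = 2.2)
  expect_equal(dim(v$data), c(2, 2, 3))
  # slice k of the stack is plane z = k
  expect_equal(v$data[, , 2], slices[[2]])
  expect_equal(v$data[1, 2, 3], slices[[3]][1, 2])
  expect_error(read_volume(f), "voxel size")
})

test_that("a malformed stack names the offending slice", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 2)),
                  f, bits.per.sample = 16L)
  expect_error(read_volume(f, voxel_size_um = 5), "slice 2")
})

test_that("volume3d validates its invariants", {
  expect_error(volume3d(matrix(0, 2, 2), 5), "3D")
  expect_error(volume3d(array(0, c(2, 2, 2)), -1), "positive")
  v <- volume3d(array(0, c(2, 3, 4)), 5, origin = c(1, 2, 3))
  expect_equal(dim(v), c(2, 3, 4))
  # voxel-center physical convention
  expect_equal(as.numeric(physis:::voxel_to_um(v, c(2, 2, 2))), c(6, 7, 8))
})

test_that("median filter removes impulses, keeps constants, defaults to kernel 2", {
  v <- volume3d(array(7, c(5, 5, 5)), 5)
  expect_equal(median_filter_3d(v)$data, v$data)
  v$data[3, 3, 3] <- 255
  f <- median_filter_3d(v)
  expect_equal(f$data[3, 3, 3], 7)
  expect_true(all(f$data %in% c(7, 255)))  # range subset of input
  expect_identical(formals(median_filter_3d)$kernel, 2)
  # kernel 2 means a 3x3x3 window: a 3-voxel solid line survives, a point does not
  expect_error(median_filter_3d(v, kernel = 0), "integer")
})

test_that("median filter reaches a fixed point quickly on sparse binary noise", {
  set.seed(7)
  for (case in 1:3) {
    v <- volume3d(array(as.numeric(stats::runif(32^3) < 0.2), c(32, 32, 32)), 5)
    reached <- FALSE
    for (it in 1:5) {
      f <- median_filter_3d(v)
      if (identical(f$data, v$data)) { reached <- TRUE; break }
      v <- f
    }
    expect_true(reached, label = sprintf("case %d fixed point within 5 sweeps", case))
    expect_true(all(f$data %in% c(0, 1)))  # binary in, binary out
  }
})

test_that("identity alignment is the identity map", {
  set.seed(3)
  v <- volume3d(array(stats::runif(1000), c(10, 10, 10)), 5)
  out <- align_volume(v, rigid_alignment())
  expect_identical(out$data, v$data)
})

test_that("auto alignment brings a cylinder axis onto +z within 2 degrees", {
  arr <- array(0, c(41, 41, 41))
  for (i in 6:36) arr[i, 19:23, 19:23] <- 200  # rod along +x
  v <- volume3d(arr, 5)
  mask <- volume3d(array(arr > 100, dim(arr)), 5)
  al <- align_volume(v, "auto", mask = mask)
  aligned_mask <- align_volume(mask, attr(al, "alignment"), interp = "nearest")
  idx <- which(aligned_mask$data != 0, arr.ind = TRUE)
  axis <- eigen(stats::cov(idx), symmetric = TRUE)$vectors[, 1]
  angle <- acos(abs(axis[3])) * 180 / pi
  expect_lt(angle, 2)
})

test_that("auto alignment rejects isotropic objects", {
  arr <- array(0, c(21, 21, 21))
  arr[8:14, 8:14, 8:14] <- 1  # cube: degenerate principal axes
  mask <- volume3d(arr, 5)
  expect_error(align_volume(volume3d(arr * 200, 5), "auto", mask = mask),
               "degenerate")
})

test_that("a 90-degree rotation and its inverse recover the volume", {
  set.seed(1)
  v <- volume3d(array(round(stats::runif(30^3) * 255), c(30, 30, 30)), 5)
  R90 <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  fwd <- align_volume(v, rigid_alignment(R90))
  back <- align_volume(fwd, rigid_alignment(t(R90)))
  core <- 5:26  # away from edges, where rotation maps outside the grid
  expect_lte(max(abs(back$data[core, core, core] - v$data[core, core, core])), 1)
})

test_that("rigid_alignment rejects non-rotations", {
  expect_error(rigid_alignment(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_alignment(matrix(1, 3, 3)), "orthonormal")
})
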