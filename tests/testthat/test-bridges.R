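# two plates with a gap; `columns` is a list of (x, y, radius) cylinders
# spanning the gap, `spurs` of (x, y, radius, from) stubs touching one side
plate_phantom_mask <- function(d = c(40, 40, 24), gap = c(9, 14),
                               columns = list(), spurs = list()) {
  arr <- array(FALSE, d)
  arr[, , 3:(gap[1] - 1)] <- TRUE
  arr[, , (gap[2] + 1):(d[3] - 2)] <- TRUE
  disc <- function(cx, cy, r) {
    ij <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
    ij[(ij[, 1] - cx)^2 + (ij[, 2] - cy)^2 <= r^2, , drop = FALSE]
  }
  for (cl in columns)
    for (k in gap[1]:gap[2])
      arr[cbind(disc(cl[1], cl[2], cl[3]), k)] <- TRUE
  for (sp in spurs) {
    zr <- if (sp[4] == 2) gap[1]:(gap[1] + 1) else (gap[2] - 1):gap[2]
    for (k in zr) arr[cbind(disc(sp[1], sp[2], sp[3]), k)] <- TRUE
  }
  volume3d(arr, 5)
}

test_that("spanning components are detected; spurs and one-sided stubs are not", {
  mask <- plate_phantom_mask(
    columns = list(c(8, 8, 2), c(20, 20, 3), c(32, 10, 2)),
    spurs = list(c(10, 30, 2, 2), c(30, 30, 2, 1)))
  lab <- label_compartments(mask)
  bs <- find_candidate_bridges(lab, mask)
  expect_equal(nrow(bs), 3)
  expect_true(all(bs$touches_epi & bs$touches_met))
  # ids ordered deterministically by bbox minimum
  expect_equal(bs$id, seq_len(3))

  # two cylinders merging into a Y inside the band are one bridge
  maskY <- plate_phantom_mask(columns = list(c(18, 20, 3), c(23, 20, 3)))
  labY <- label_compartments(maskY)
  bsY <- find_candidate_bridges(labY, maskY)
  expect_equal(nrow(bsY), 1)
})

test_that("bridge detection matches a brute-force label-and-test oracle", {
  set.seed(21)
  for (conn in c(6, 26)) {
    for (case in 1:3) {
      d <- c(24, 24, 16)
      arr <- array(FALSE, d)
      arr[, , 1:4] <- TRUE
      arr[, , 13:16] <- TRUE
      # random mineral in the band
      band <- 5:12
      arr[, , band] <- stats::runif(d[1] * d[2] * length(band)) < 0.06
      mask <- volume3d(arr, 5)
      lab <- label_compartments(mask, gp_band = c(5, 12))
      bs <- find_candidate_bridges(lab, mask, connectivity = conn)
      # oracle: label band voxels, keep components adjacent to both plates
      bandm <- array(FALSE, d); bandm[, , band] <- arr[, , band]
      lo <- bf_label(bandm, conn)
      off <- nb_offsets(conn)
      spanning <- 0L
      total_vox <- integer()
      for (cid in seq_len(max(lo))) {
        vox <- which(lo == cid, arr.ind = TRUE)
        te <- tm <- FALSE
        for (r in seq_len(nrow(vox)))
          for (o in seq_len(nrow(off))) {
            q <- vox[r, ] + off[o, ]
            if (any(q < 1) || any(q > d)) next
            l <- lab$data[matrix(q, 1)]
            if (l == 1L) te <- TRUE
            if (l == 2L) tm <- TRUE
          }
        if (te && tm) {
          spanning <- spanning + 1L
          total_vox <- c(total_vox, nrow(vox))
        }
      }
      expect_equal(nrow(bs), spanning, label = sprintf("conn %d case %d", conn, case))
      expect_equal(sort(bs$voxel_count), sort(total_vox))
    }
  }
})

test_that("manual seed selection restricts detection to clicked components", {
  mask <- plate_phantom_mask(columns = list(c(8, 8, 2), c(20, 20, 3), c(32, 10, 2)))
  lab <- label_compartments(mask)
  bs <- find_candidate_bridges(lab, mask, seeds = matrix(c(8, 8, 11), 1))
  expect_equal(nrow(bs), 1)
  expect_equal(bs$voxel_count,
               find_candidate_bridges(lab, mask)$voxel_count[1])
})

test_that("the minimum-volume filter keeps >= 125 and drops smaller bridges", {
  gen <- sweep_bridge_volumes(c(124, 125), gap_thickness = 5)
  labd <- gen$truth$labels$data
  mask <- volume3d(array(labd %in% c(1L, 2L, 4L), dim(labd)), 5)
  lab <- label_compartments(mask, gp_band = gen$truth$band)
  bs <- find_candidate_bridges(lab, mask)
  expect_equal(sort(bs$voxel_count), c(124L, 125L))
  kept <- filter_by_volume(bs)  # default min_voxels = 125
  expect_equal(kept$voxel_count, 125L)

  # empty set stays empty; min_voxels = 1 is the identity
  empty <- kept[0, ]
  class(empty) <- class(kept)
  expect_equal(nrow(filter_by_volume(kept, 1)), 1)
  expect_identical(filter_by_volume(bs, 1)$voxel_count, bs$voxel_count)

  # idempotent and monotone
  expect_identical(filter_by_volume(kept)$voxel_count, kept$voxel_count)
  for (m in c(1, 50, 125, 200))
    expect_lte(nrow(filter_by_volume(bs, m + 10)), nrow(filter_by_volume(bs, m)))
})

test_that("bridge voxel counts never exceed the band's mineral content", {
  mask <- plate_phantom_mask(
    columns = list(c(8, 8, 2), c(20, 20, 3)),
    spurs = list(c(30, 30, 3, 1)))
  lab <- label_compartments(mask)
  bs <- find_candidate_bridges(lab, mask)
  band_mineral <- sum(lab$data == 4L)
  expect_lte(sum(bs$voxel_count), band_mineral)
})

test_that("bridge centers lie inside their component", {
  # straight axis-aligned cylinder: center within 1 voxel of the midpoint
  mask <- plate_phantom_mask(d = c(24, 24, 32), gap = c(7, 26),
                             columns = list(c(12, 12, 3)))
  lab <- label_compartments(mask, gp_band = c(7, 26))
  bs <- bridge_centers(find_candidate_bridges(lab, mask))
  mid_z <- (mean(c(7, 26)) - 1) * 5
  expect_lte(abs(bs$cz_um - mid_z) / 5, 1)
  expect_lte(abs(bs$cx_um / 5 + 1 - 12), 1)

  # L-shaped component: skeleton center inside, raw centroid outside
  d <- c(26, 26, 14)
  arr <- array(FALSE, d)
  arr[, , 1:3] <- TRUE; arr[, , 12:14] <- TRUE
  arr[3:24, 3:6, 4:11] <- TRUE   # vertical-ish slab spanning the band
  arr[3:6, 3:24, 4:11] <- TRUE
  # make it span: the slab touches both plates across z 4..11
  mask <- volume3d(arr, 5)
  lab <- label_compartments(mask, gp_band = c(4, 11))
  bs <- find_candidate_bridges(lab, mask)
  expect_equal(nrow(bs), 1)
  cent <- bridge_centers(bs, method = "centroid")
  skel <- bridge_centers(bs, method = "skeleton")
  at <- function(b) {
    v <- round(c(b$cx_um, b$cy_um, b$cz_um) / 5) + 1
    arr[matrix(v, 1)]
  }
  expect_false(at(cent))  # centroid of the L falls outside the arms
  expect_true(at(skel))

  # single-voxel bridge: center is that voxel
  d2 <- c(10, 10, 9)
  arr2 <- array(FALSE, d2)
  arr2[, , 1:4] <- TRUE; arr2[, , 6:9] <- TRUE
  arr2[5, 5, 5] <- TRUE
  mask2 <- volume3d(arr2, 5)
  lab2 <- label_compartments(mask2, gp_band = c(5, 5))
  suppressMessages(bs2 <- bridge_centers(find_candidate_bridges(lab2, mask2)))
  expect_equal(c(bs2$cx_um, bs2$cy_um, bs2$cz_um), c(4, 4, 4) * 5)
})

test_that("an empty band or missing compartments raise errors", {
  solid <- volume3d(array(TRUE, c(8, 8, 8)), 5)
  lab <- label_compartments(solid, gp_band = c(4, 5))
  # no epiphysis/metaphysis separation problem: band given, still works
  expect_s3_class(find_candidate_bridges(lab, solid), "bridge_set")
})
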