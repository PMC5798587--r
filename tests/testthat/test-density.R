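# a bridge_set-like object with given centers, for projection tests
fake_bridges <- function(centers_um, voxel_size = 5) {
  bs <- tibble::tibble(
    id = seq_len(nrow(centers_um)),
    voxel_count = 1L, volume_um3 = voxel_size^3,
    cx_um = centers_um[, 1], cy_um = centers_um[, 2], cz_um = centers_um[, 3],
    touches_epi = TRUE, touches_met = TRUE,
    x0 = 1L, x1 = 1L, y0 = 1L, y1 = 1L, z0 = 1L, z1 = 1L)
  attr(bs, "voxel_size") <- voxel_size
  attr(bs, "origin") <- c(0, 0, 0)
  attr(bs, "label_map") <- array(0L, c(1, 1, 1))
  attr(bs, "gp_band") <- c(1L, 1L)
  attr(bs, "provenance") <- list()
  class(bs) <- c("bridge_set", class(bs))
  bs
}

flat_surface <- function(nx = 20, ny = 20, z_um = 200, voxel_size = 5) {
  structure(list(height_um = matrix(z_um, nx, ny),
                 footprint = matrix(TRUE, nx, ny),
                 voxel_size = voxel_size, origin = c(0, 0, 0)),
            class = "joint_surface")
}

test_that("projection carries centers straight up to the surface", {
  surf <- flat_surface(z_um = 200)
  bs <- fake_bridges(rbind(c(30, 40, 50)))
  pts <- project_to_surface(bs, surf)
  expect_equal(pts$status, "projected")
  expect_equal(pts$surface_z_um, 200)
  expect_equal(c(pts$x_um, pts$y_um), c(30, 40))

  # undulating surface: projected height matches the analytic generator height
  spec <- small_phantom_spec(5, seed = 13)
  gen <- generate_phantom(spec)
  mask <- segment_phantom(gen$volume)
  lab <- label_compartments(mask)
  surf2 <- extract_joint_surface(lab, mask)
  bs2 <- bridge_centers(find_candidate_bridges(lab, mask))
  pts2 <- project_to_surface(bs2, surf2)
  expect_true(all(pts2$status == "projected"))
  vs <- gen$volume$voxel_size
  for (r in seq_len(nrow(pts2))) {
    iv <- pts2$x_um[r] / vs + 1
    jv <- pts2$y_um[r] / vs + 1
    truth_h <- gen$truth$height_um[round(iv), round(jv)]
    expect_lte(abs(pts2$surface_z_um[r] - truth_h), vs)
  }

  # a center outside the footprint is reported as missed, not dropped
  surf3 <- flat_surface(nx = 10, ny = 10)
  bs3 <- fake_bridges(rbind(c(20, 20, 10), c(200, 20, 10)))  # x=200 um: column 41
  pts3 <- project_to_surface(bs3, surf3)
  expect_equal(pts3$status, c("projected", "missed"))
  expect_equal(nrow(pts3), 2)
})

test_that("windowed counts match brute-force counting and conserve points", {
  set.seed(5)
  n <- 50
  pts <- tibble::tibble(
    bridge_id = 1:n,
    x_um = stats::runif(n, 0, 1500), y_um = stats::runif(n, 0, 1500),
    surface_z_um = 100, status = "projected")
  dm <- areal_density(pts, window_um = 256)
  expect_equal(sum(dm$windows$n_bridges), n)
  oracle <- bf_window_counts(pts$x_um, pts$y_um, dm$grid_anchor, 256)
  got <- dm$windows[order(dm$windows$ix, dm$windows$iy), ]
  o <- order(oracle$cells[, 1], oracle$cells[, 2])
  expect_equal(cbind(got$ix, got$iy), unname(oracle$cells[o, , drop = FALSE]))
  expect_equal(got$n_bridges, oracle$counts[o])
  # window centers are consistent with their grid indices
  expect_equal(got$x_center_um, dm$grid_anchor[1] + (got$ix + 0.5) * 256)
  expect_equal(got$y_center_um, dm$grid_anchor[2] + (got$iy + 0.5) * 256)
  # per-bridge density equals its window count
  for (r in seq_len(nrow(dm$per_bridge))) {
    w <- dm$windows$n_bridges[dm$windows$ix == dm$per_bridge$ix[r] &
                                dm$windows$iy == dm$per_bridge$iy[r]]
    expect_equal(dm$per_bridge$density[r], w)
  }
  expect_true(all(dm$per_bridge$density >= 1))
})

test_that("one point gives one occupied window; close pairs share a density of 2", {
  one <- tibble::tibble(bridge_id = 1L, x_um = 300, y_um = 300,
                        surface_z_um = 0, status = "projected")
  dm <- areal_density(one)
  expect_equal(nrow(dm$windows), 1)
  expect_equal(dm$windows$n_bridges, 1L)

  two <- tibble::tibble(bridge_id = 1:2, x_um = c(300, 400), y_um = c(300, 300),
                        surface_z_um = 0, status = "projected")
  dm2 <- areal_density(two)  # 100 um apart, inside one 256-um window
  expect_equal(dm2$per_bridge$density, c(2L, 2L))
})

test_that("density is translation-equivariant and monotone under window doubling", {
  set.seed(9)
  pts <- tibble::tibble(
    bridge_id = 1:30,
    x_um = stats::runif(30, 0, 2000), y_um = stats::runif(30, 0, 2000),
    surface_z_um = 0, status = "projected")
  dm <- areal_density(pts, 256, grid_anchor = c(0, 0))
  shift <- c(137, -401)
  pts2 <- pts
  pts2$x_um <- pts2$x_um + shift[1]
  pts2$y_um <- pts2$y_um + shift[2]
  dm2 <- areal_density(pts2, 256, grid_anchor = shift)
  expect_equal(dm$windows$n_bridges, dm2$windows$n_bridges)
  expect_equal(dm$per_bridge$density, dm2$per_bridge$density)

  prev <- 0
  for (w in 256 * 2^(0:3)) {
    mx <- max(areal_density(pts, w, grid_anchor = c(0, 0))$per_bridge$density)
    expect_gte(mx, prev)
    prev <- mx
  }
})

test_that("half-open windows count boundary points exactly once", {
  pts <- tibble::tibble(bridge_id = 1:3,
                        x_um = c(0, 256, 512), y_um = c(0, 0, 0),
                        surface_z_um = 0, status = "projected")
  dm <- areal_density(pts, 256, grid_anchor = c(0, 0))
  expect_equal(sum(dm$windows$n_bridges), 3)
  expect_equal(dm$windows$n_bridges, c(1L, 1L, 1L))  # each on its own window
})

test_that("overlay rendering is deterministic and locates the density maximum", {
  surf <- flat_surface(nx = 60, ny = 60)
  bs <- fake_bridges(rbind(c(150, 150, 10)))
  pts <- project_to_surface(bs, surf)
  dm <- areal_density(pts, window_um = 100, grid_anchor = c(0, 0))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  p1 <- tempfile(fileext = ".ply")
  render_overlay(dm, surf, png_path = f1, ply_path = p1)
  render_overlay(dm, surf, png_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(file.size(p1) > 0)
  # the occupied window is the one containing the bridge
  expect_equal(dm$windows$ix, 1L)
  expect_equal(dm$windows$iy, 1L)

  # empty density map still renders a footprint-only overlay
  empty <- areal_density(pts[0, ], window_um = 100, grid_anchor = c(0, 0))
  f3 <- tempfile(fileext = ".png")
  render_overlay(empty, surf, png_path = f3)
  expect_true(file.exists(f3))
})
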