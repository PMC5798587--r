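bone <- function() material_model(17000, 0.3)
gp <- function() material_model(6, 0.49)

block_mesh <- function(d, voxel_um = 10, label = 1L) {
  mesh_from_labels(volume3d(array(label, d), voxel_um))
}

test_that("voxel meshing gives 5 tets per voxel with exact volume", {
  m <- block_mesh(c(1, 1, 1))
  expect_equal(nrow(m$elems), 5)
  v1 <- m$nodes[m$elems[, 2], ] - m$nodes[m$elems[, 1], ]
  v2 <- m$nodes[m$elems[, 3], ] - m$nodes[m$elems[, 1], ]
  v3 <- m$nodes[m$elems[, 4], ] - m$nodes[m$elems[, 1], ]
  vols <- (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
           v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
           v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  expect_true(all(vols > 0))
  expect_equal(sum(vols), m$h_mm^3)

  # 2x2x2 block: 40 tets, every interior face shared by exactly two tets
  m2 <- block_mesh(c(2, 2, 2))
  expect_equal(nrow(m2$elems), 40)
  e <- m2$elems
  faces <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)], e[, c(1, 3, 4)], e[, c(2, 3, 4)])
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true(all(table(key) %in% c(1, 2)))
  # mesh volume equals voxel volume
  expect_equal(sum(physis:::cpp_fem_assemble(m2$nodes, m2$elems - 1L,
                                             rep(1, 40), rep(0, 40))$vol),
               8 * m2$h_mm^3)

  expect_error(mesh_from_labels(volume3d(array(0L, c(2, 2, 2)), 10)), "empty")
  expect_error(mesh_from_labels(volume3d(array(1L, c(2, 2, 2)), 10), 0), "bin_factor")
})

test_that("binning takes the majority label per block", {
  arr <- array(1L, c(4, 4, 4))
  arr[1:2, 1:2, 1:2] <- 3L          # one octant cartilage
  arr[3:4, 3:4, 3:4] <- 0L          # one octant background
  m <- mesh_from_labels(volume3d(arr, 10), bin_factor = 2)
  # 8 blocks -> 7 retained voxels (one pure-background block dropped)
  expect_equal(nrow(m$elems), 7 * 5)
  expect_equal(sum(m$material_id == 2L), 5)  # the cartilage block
})

test_that("zero load with valid restraints gives zero displacement", {
  m <- block_mesh(c(2, 2, 4))
  lc <- load_case(m, total_force = 0)
  fe <- assemble_and_solve(m, list(bone()), lc)
  expect_lt(max(abs(fe$u)), 1e-15)
})

test_that("the patch test is exact for both tissue materials", {
  for (mat in list(bone(), gp())) {
    m <- block_mesh(c(3, 3, 3))
    A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -2e-3, 5e-4, 1e-4, 2e-4, 1.5e-3),
                3, 3, byrow = TRUE)
    bnodes <- unique(sort(as.vector(physis:::boundary_faces(m))))
    ub <- m$nodes[bnodes, ] %*% t(A)
    lc <- list(fixed = tibble::tibble(node = rep(bnodes, 3),
                                      dof = rep(1:3, each = length(bnodes)),
                                      value = as.numeric(ub)),
               forces = tibble::tibble(node = integer(), dof = integer(),
                                       value = numeric()))
    fe <- assemble_and_solve(m, list(mat, mat), lc)
    eps <- (A + t(A)) / 2
    lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
    mu <- mat$E / (2 * (1 + mat$nu))
    sig <- lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
    expect_vm <- c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[2, 3], sig[3, 1])
    relerr <- max(abs(sweep(fe$stress, 2, expect_vm))) / max(abs(expect_vm))
    expect_lt(relerr, 1e-8)
    # interior displacements reproduce the linear field exactly
    uex <- m$nodes %*% t(A)
    expect_lt(max(abs(fe$u - uex)), 1e-12 * max(abs(uex)))
  }
})

test_that("a uniform column matches the F*L/(E*A) bar solution", {
  h <- 0.01  # mm
  m <- block_mesh(c(4, 4, 20))
  lc <- load_case(m, total_force = 1, split = "consistent", regions = "all")
  fe <- assemble_and_solve(m, list(material_model(17000, 0)), lc)
  A <- (4 * h)^2; L <- 20 * h
  exact <- -1 * L / (17000 * A)
  top <- which(m$nodes[, 3] >= max(m$nodes[, 3]) - 1e-12)
  expect_lt(abs(mean(fe$u[top, 3]) - exact) / abs(exact), 0.005)
})

test_that("a bone-on-cartilage column matches the series-spring solution", {
  h <- 0.01
  arr <- array(2L, c(4, 4, 20))
  arr[, , 11:20] <- 3L  # growth-plate layer on top
  m <- mesh_from_labels(volume3d(arr, 10))
  lc <- load_case(m, total_force = 1, split = "consistent", regions = "all")
  fe <- assemble_and_solve(m, list(material_model(17000, 0), material_model(6, 0)), lc)
  A <- (4 * h)^2
  exact <- -1 * (10 * h / 17000 + 10 * h / 6) / A
  top <- which(m$nodes[, 3] >= max(m$nodes[, 3]) - 1e-12)
  expect_lt(abs(mean(fe$u[top, 3]) - exact) / abs(exact), 0.01)
})

test_that("reactions balance applied loads and the residual is tiny", {
  m <- block_mesh(c(3, 3, 6))
  lc <- load_case(m, total_force = 1)  # default medial/lateral equal split
  expect_equal(sum(lc$forces$value[lc$forces$dof == 3]), -1)
  fe <- assemble_and_solve(m, list(bone()), lc)
  expect_lt(fe$residual, 1e-8)
  for (d in 1:3) {
    applied <- sum(lc$forces$value[lc$forces$dof == d])
    reacted <- sum(fe$reactions$value[fe$reactions$dof == d])
    expect_lt(abs(applied + reacted), 1e-9)
  }
})

test_that("insufficient restraints are diagnosed", {
  m <- block_mesh(c(2, 2, 2))
  lc <- list(fixed = tibble::tibble(node = 1L, dof = 3L, value = 0),
             forces = tibble::tibble(node = 8L, dof = 3L, value = -1))
  expect_error(assemble_and_solve(m, list(bone()), lc), "rigid-body")
})

test_that("von Mises has its closed-form values and is rotation-invariant", {
  expect_equal(von_mises(diag(c(10, 0, 0))), 10)
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- 5
  expect_equal(von_mises(sh), 5 * sqrt(3))
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)), "symmetric")

  set.seed(31)
  S <- matrix(stats::rnorm(9), 3, 3); S <- (S + t(S)) / 2
  v0 <- von_mises(S)
  for (rep in 1:5) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_lt(abs(von_mises(Q %*% S %*% t(Q)) - v0), 1e-10 * max(1, v0))
  }
})

test_that("mesh sensitivity picks the first mesh inside the 5% band", {
  counts <- c(1000, 5000, 20000, 80000, 320000)
  metrics <- c(10, 6, 5.2, 5.05, 5.0)
  chosen <- mesh_sensitivity(counts, metrics)
  expect_equal(as.integer(chosen), 20000)  # |5.2 - 5|/5 = 4% <= 5%
  tab <- attr(chosen, "table")
  expect_equal(nrow(tab), 5)

  # all equal: the coarsest wins
  expect_equal(as.integer(mesh_sensitivity(counts, rep(2, 5))), 1000)
  expect_error(mesh_sensitivity(c(10, 20), c(1, 1)), "at least 3")
  expect_error(mesh_sensitivity(counts, c(10, 9, 8, 30, 5.0)), "band")
})

test_that("VTK export writes a well-formed unstructured grid", {
  m <- block_mesh(c(2, 2, 3))
  fe <- assemble_and_solve(m, list(bone()), load_case(m, 1))
  f <- tempfile(fileext = ".vtk")
  write_vtk(fe, f)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("von_mises", lines)))
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(npts, nrow(m$nodes))
})

test_that("tidy and glance summarize an FE result", {
  m <- block_mesh(c(2, 2, 4))
  fe <- assemble_and_solve(m, list(bone()), load_case(m, 1))
  td <- tidy(fe)
  expect_equal(nrow(td), nrow(m$elems))
  expect_true(all(c("von_mises", "material_id", "sxx") %in% names(td)))
  gl <- glance(fe)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total_reaction_z_n, 1, tolerance = 1e-9)
})
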