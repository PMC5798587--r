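#' Specify a synthetic growth-plate phantom
#'
#' Describes a microCT-like test object: two mineralized plates (epiphysis
#' above, metaphysis below) separated by a low-intensity cartilage gap, with
#' a configurable set of cylindrical bridges spanning the gap, optional
#' sinusoidal undulation of the joint surface, and Gaussian gray-level noise.
#' The gray-level model is deliberately simple (tissue means + noise, no
#' beam hardening or ring artifacts): the pipeline, not the scanner, is
#' under test. Gray separations must be at least 4 standard deviations of
#' the noise so that segmentation is well-posed by construction.
#'
#' @param shape integer 3-vector, voxel dimensions `(nx, ny, nz)`.
#' @param voxel_size voxel edge length, micrometres.
#' @param plate_thickness integer 2-vector `c(epiphysis, metaphysis)` in
#'   voxels.
#' @param gap_thickness growth-plate gap in voxels (>= 1).
#' @param bridges list of `list(center_xy = c(i, j), radius_vox, tilt_deg)`;
#'   cylinders spanning the full gap, tilt (about y, toward +x) up to 30
#'   degrees.
#' @param undulation `list(amplitude_vox, period_vox)` for the joint-surface
#'   sinusoid along x (amplitude 0 disables it).
#' @param gray_levels `list(bone_mean, cartilage_mean, background_mean,
#'   noise_sd)`.
#' @param z_margin background slices below/above the plates.
#' @param seed RNG seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), voxel_size = 5,
                         plate_thickness = c(25, 25), gap_thickness = 10,
                         bridges = list(),
                         undulation = list(amplitude_vox = 0, period_vox = 32),
                         gray_levels = list(bone_mean = 200, cartilage_mean = 60,
                                            background_mean = 20, noise_sd = 5),
                         z_margin = 3, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_size > 0,
            length(plate_thickness) == 2, all(plate_thickness >= 1),
            gap_thickness >= 1)
  gl <- gray_levels
  seps <- c(gl$bone_mean - gl$cartilage_mean, gl$cartilage_mean - gl$background_mean)
  if (gl$noise_sd > 0 && any(seps < 4 * gl$noise_sd))
    stop("gray-level separations must be >= 4 * noise_sd")
  for (b in bridges) {
    if (is.null(b$radius_vox) || b$radius_vox < 1) stop("bridge radii must be >= 1")
    if (is.null(b$tilt_deg)) b$tilt_deg <- 0
    if (abs(b$tilt_deg) > 30) stop("bridge tilt must be <= 30 degrees")
  }
  need_z <- z_margin * 2 + sum(plate_thickness) + gap_thickness +
    undulation$amplitude_vox
  if (shape[3] < need_z)
    stop("shape[3] too small for plates + gap + undulation + margins")
  structure(list(shape = shape, voxel_size = voxel_size,
                 plate_thickness = as.integer(plate_thickness),
                 gap_thickness = as.integer(gap_thickness),
                 bridges = bridges, undulation = undulation,
                 gray_levels = gray_levels, z_margin = as.integer(z_margin),
                 seed = seed),
            class = "phantom_spec")
}

#' Randomly place well-separated bridges for a phantom
#'
#' Draws `k` bridge centers uniformly over the cross-section, rejecting
#' candidates closer than `min_sep` voxels to an accepted center or to the
#' volume margin. Deterministic for a fixed seed.
#'
#' @param k number of bridges.
#' @param shape phantom voxel dimensions.
#' @param radius_vox cylinder radius (voxels).
#' @param tilt_deg maximum absolute tilt; each bridge gets a tilt drawn
#'   uniformly in `[-tilt_deg, tilt_deg]`.
#' @param min_sep minimum center-to-center spacing (voxels).
#' @param margin keep-out border in x and y (voxels).
#' @param seed RNG seed.
#' @return A list of bridge descriptions for [phantom_spec()].
#' @export
random_bridge_layout <- function(k, shape = c(128, 128, 128), radius_vox = 3,
                                 tilt_deg = 0, min_sep = 4 * radius_vox + 4,
                                 margin = 12, seed = 1) {
  if (k == 0) return(list())
  set.seed(seed)
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < k) {
    tries <- tries + 1
    if (tries > 10000) stop("could not place ", k, " non-overlapping bridges")
    p <- c(stats::runif(1, margin, shape[1] - margin),
           stats::runif(1, margin, shape[2] - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, p, "-")^2))) >= min_sep)
      centers <- rbind(centers, p)
  }
  tilts <- if (tilt_deg > 0) stats::runif(k, -tilt_deg, tilt_deg) else rep(0, k)
  lapply(seq_len(k), function(i)
    list(center_xy = round(centers[i, ]), radius_vox = radius_vox,
         tilt_deg = tilts[i]))
}

#' Generate a phantom volume with exact ground truth
#'
#' Rasterizes the geometry described by a [phantom_spec()] into a noiseless
#' label volume (the ground truth) and a noisy grayscale volume. Bridges are
#' checked for pairwise overlap during rasterization. The generator is
#' deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (grayscale [volume3d]) and `truth`:
#'   `labels` (label [volume3d], codes as in [label_compartments()], with the
#'   `gp_band` attribute set), `bridge_map` (integer array of bridge ids),
#'   `bridges` (tibble: `id`, `voxel_count`, true centroid `cx_um`, `cy_um`,
#'   `cz_um`, geometry columns), `height_um` / `footprint` (analytic joint
#'   surface), `band` (z-interval of the gap, 1-based slices).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  vs <- spec$voxel_size
  zm <- spec$z_margin
  met0 <- zm + 1
  met1 <- zm + spec$plate_thickness[2]
  gap0 <- met1 + 1
  gap1 <- met1 + spec$gap_thickness
  epi0 <- gap1 + 1
  ztop0 <- epi0 + spec$plate_thickness[1] - 1

  und <- spec$undulation
  xs <- seq_len(d[1])
  dz <- if (und$amplitude_vox > 0)
    round(und$amplitude_vox * sin(2 * pi * (xs - 1) / und$period_vox))
  else rep(0L, d[1])
  ztop <- matrix(ztop0 + dz, d[1], d[2])  # undulation along x
  if (max(ztop) > d[3]) stop("undulation exceeds the volume top")
  if (min(ztop) < epi0) stop("undulation amplitude exceeds the epiphyseal plate thickness")

  lab <- array(0L, d)
  for (k in met0:met1) lab[, , k] <- 2L
  for (k in gap0:gap1) lab[, , k] <- 3L
  for (k in epi0:max(ztop)) lab[, , k][k <= ztop] <- 1L

  bridge_map <- array(0L, d)
  nb <- length(spec$bridges)
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    br <- spec$bridges[[b]]
    tilt <- if (is.null(br$tilt_deg)) 0 else br$tilt_deg
    r <- br$radius_vox
    for (k in gap0:gap1) {
      cx <- br$center_xy[1] + (k - gap0) * tan(tilt * pi / 180)
      cy <- br$center_xy[2]
      xr <- max(1, floor(cx - r)):min(d[1], ceiling(cx + r))
      yr <- max(1, floor(cy - r)):min(d[2], ceiling(cy + r))
      inside <- outer((xr - cx)^2, (yr - cy)^2, "+") <= r^2
      ij <- which(inside, arr.ind = TRUE)
      if (nrow(ij) == 0) next
      xi <- xr[ij[, 1]]; yj <- yr[ij[, 2]]
      prev <- bridge_map[cbind(xi, yj, k)]
      clash <- prev != 0 & prev != b
      if (any(clash))
        stop(sprintf("bridges %d and %d overlap at slice z=%d",
                     prev[clash][1], b, k))
      bridge_map[cbind(xi, yj, k)] <- b
      counts[b] <- counts[b] + nrow(ij)
    }
  }
  lab[bridge_map > 0] <- 4L

  gl <- spec$gray_levels
  means <- c(gl$background_mean, gl$bone_mean, gl$bone_mean,
             gl$cartilage_mean, gl$bone_mean)
  gray <- array(means[lab + 1L], d)
  if (gl$noise_sd > 0) {
    set.seed(spec$seed)
    gray <- gray + array(stats::rnorm(prod(d), 0, gl$noise_sd), d)
  }

  bridges <- tibble::tibble(
    id = seq_len(nb),
    voxel_count = counts,
    cx_um = NA_real_, cy_um = NA_real_, cz_um = NA_real_,
    center_x_vox = vapply(spec$bridges, function(b) b$center_xy[1], 0),
    center_y_vox = vapply(spec$bridges, function(b) b$center_xy[2], 0),
    radius_vox = vapply(spec$bridges, function(b) b$radius_vox, 0),
    tilt_deg = vapply(spec$bridges, function(b)
      if (is.null(b$tilt_deg)) 0 else b$tilt_deg, 0)
  )
  if (nb > 0) {
    idx <- which(bridge_map > 0, arr.ind = TRUE)
    ids <- bridge_map[bridge_map > 0]
    for (b in seq_len(nb)) {
      cen <- colMeans(idx[ids == b, , drop = FALSE])
      bridges[b, c("cx_um", "cy_um", "cz_um")] <- as.list((cen - 1) * vs)
    }
  }

  labels <- volume3d(lab, vs)
  attr(labels, "gp_band") <- c(gap0, gap1)
  truth <- list(labels = labels, bridge_map = bridge_map, bridges = bridges,
                height_um = (ztop - 1) * vs,
                footprint = matrix(TRUE, d[1], d[2]),
                band = c(gap0, gap1))
  list(volume = volume3d(gray, vs), truth = truth)
}

#' Sweep phantom: one spanning component per requested voxel volume
#'
#' Builds a phantom whose growth-plate gap is crossed by isolated components
#' with exactly the requested integer voxel counts, constructed by direct
#' voxel placement (full 1x1 columns through the gap, extra voxels filling a
#' compact box column by column). Used to characterize volume-threshold
#' filters: a component of `v` voxels survives a `min_voxels` filter iff
#' `v >= min_voxels`.
#'
#' @param volumes integer vector of requested voxel counts, each >= the gap
#'   thickness (a smaller component cannot span the gap).
#' @param gap_thickness gap in voxels (default 5).
#' @param plate_thickness plate thickness in voxels (both plates).
#' @param voxel_size micrometres per voxel.
#' @param gray_levels as in [phantom_spec()]; default noiseless.
#' @return As [generate_phantom()]: list with `volume` and `truth` (the
#'   `bridges` tibble lists the requested counts).
#' @export
sweep_bridge_volumes <- function(volumes, gap_thickness = 5,
                                 plate_thickness = 3, voxel_size = 5,
                                 gray_levels = list(bone_mean = 200,
                                                    cartilage_mean = 60,
                                                    background_mean = 20,
                                                    noise_sd = 0)) {
  volumes <- as.integer(volumes)
  g <- as.integer(gap_thickness)
  if (any(volumes < g))
    stop("requested volume ", min(volumes),
         " cannot span a gap of ", g, " voxels")
  n <- length(volumes)
  w <- max(1L, ceiling(sqrt(max(volumes) / g)))
  pitch <- w + 3L
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  margin <- 4L
  zm <- 2L
  d <- c(margin * 2L + ncols * pitch, margin * 2L + nrows * pitch,
         2L * zm + 2L * plate_thickness + g)
  met0 <- zm + 1L; met1 <- zm + plate_thickness
  gap0 <- met1 + 1L; gap1 <- met1 + g
  epi0 <- gap1 + 1L; epi1 <- gap1 + plate_thickness

  lab <- array(0L, d)
  for (k in met0:met1) lab[, , k] <- 2L
  for (k in gap0:gap1) lab[, , k] <- 3L
  for (k in epi0:epi1) lab[, , k] <- 1L

  # snake order over the w x w box: adjacent positions are face neighbors
  box <- do.call(rbind, lapply(seq_len(w), function(j) {
    xs <- if (j %% 2 == 1) seq_len(w) else rev(seq_len(w))
    cbind(xs, j)
  }))

  bridge_map <- array(0L, d)
  for (i in seq_len(n)) {
    gx <- (i - 1) %% ncols
    gy <- (i - 1) %/% ncols
    x0 <- margin + gx * pitch
    y0 <- margin + gy * pitch
    v <- volumes[i]
    full_cols <- v %/% g
    rem <- v %% g
    if (full_cols > nrow(box)) stop("internal: sweep box too small")
    for (cidx in seq_len(full_cols)) {
      p <- box[cidx, ]
      bridge_map[x0 + p[1], y0 + p[2], gap0:gap1] <- i
    }
    if (rem > 0) {
      p <- box[full_cols + 1, ]
      bridge_map[x0 + p[1], y0 + p[2], gap0:(gap0 + rem - 1)] <- i
    }
  }
  lab[bridge_map > 0] <- 4L

  gl <- gray_levels
  means <- c(gl$background_mean, gl$bone_mean, gl$bone_mean,
             gl$cartilage_mean, gl$bone_mean)
  gray <- array(means[lab + 1L], d)
  if (!is.null(gl$noise_sd) && gl$noise_sd > 0)
    gray <- gray + array(stats::rnorm(prod(d), 0, gl$noise_sd), d)

  labels <- volume3d(lab, voxel_size)
  attr(labels, "gp_band") <- c(gap0, gap1)
  truth <- list(labels = labels, bridge_map = bridge_map,
                bridges = tibble::tibble(id = seq_len(n), voxel_count = volumes),
                height_um = matrix((epi1 - 1) * voxel_size, d[1], d[2]),
                footprint = matrix(TRUE, d[1], d[2]),
                band = c(gap0, gap1))
  list(volume = volume3d(gray, voxel_size), truth = truth)
}
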