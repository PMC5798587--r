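#' Seed-based region-growing segmentation
#'
#' Starting from one or more seed voxels, selects every voxel connected to a
#' seed (under the chosen connectivity) whose gray value lies in the closed
#' tolerance interval `[lo, hi]`. This is the standard region-growing
#' segmentation used to extract mineralized tissue from microCT volumes. The
#' result is exactly the union of connected components of the thresholded
#' set that contain a seed, and is deterministic.
#'
#' @param vol a [volume3d].
#' @param seeds integer matrix (n x 3) or vector of length 3; 1-based voxel
#'   indices `(i, j, k)`.
#' @param tolerance numeric `c(lo, hi)`, closed gray-value interval.
#' @param connectivity 26 (default; includes face, edge and corner neighbors
#'   — thin oblique structures stay connected) or 6 (faces only).
#' @return A [volume3d] with logical data (the mask).
#' @export
region_grow <- function(vol, seeds, tolerance, connectivity = 26) {
  stopifnot(inherits(vol, "volume3d"))
  seeds <- rbind(seeds)
  storage.mode(seeds) <- "integer"
  if (ncol(seeds) != 3L) stop("`seeds` must be (i,j,k) voxel index triples")
  d <- dim(vol$data)
  if (any(seeds < 1L) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed outside volume bounds")
  if (length(tolerance) != 2L || tolerance[1] > tolerance[2])
    stop("`tolerance` must be c(lo, hi) with lo <= hi")
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26")
  gv <- vol$data[seeds]
  bad <- which(gv < tolerance[1] | gv > tolerance[2])
  if (length(bad))
    stop(sprintf("seed (%d,%d,%d) has gray value %.6g outside tolerance [%.6g, %.6g]",
                 seeds[bad[1], 1], seeds[bad[1], 2], seeds[bad[1], 3],
                 gv[bad[1]], tolerance[1], tolerance[2]))
  m <- cpp_region_grow(as.numeric(vol$data), d, seeds - 1L,
                       tolerance[1], tolerance[2], as.integer(connectivity))
  volume3d(array(m, d), vol$voxel_size, vol$origin)
}

#' Label the compartments around the growth plate
#'
#' Splits a mineralized mask into epiphysis (above the growth-plate band) and
#' metaphysis (below it), and labels the band itself. The growth-plate band
#' is the z-interval of minimal mineralized cross-sectional area between the
#' two bone compartments: the per-slice area profile is smoothed with a
#' 5-slice moving average, the interior minimum located, and the band taken
#' as the contiguous run of slices around it whose raw area stays below a
#' quarter-height threshold between the minimum and maximum profile values.
#' An explicit `gp_band` overrides auto-location (it is honored verbatim).
#'
#' Label codes: 0 background, 1 epiphysis, 2 metaphysis, 3 growth-plate
#' cartilage (non-mineralized voxels inside the band), 4 bridge candidate
#' (mineralized voxels inside the band).
#'
#' @param bone_mask a [volume3d] with logical data (mineralized voxels).
#' @param gp_band optional integer `c(z_lo, z_hi)` (1-based slice indices)
#'   bounding the growth-plate gap.
#' @return A [volume3d] with integer label data and attribute `"gp_band"`.
#' @export
label_compartments <- function(bone_mask, gp_band = NULL) {
  stopifnot(inherits(bone_mask, "volume3d"))
  m <- bone_mask$data != 0
  if (!any(m)) stop("bone mask is empty")
  d <- dim(m)
  if (is.null(gp_band)) {
    area <- apply(m, 3, sum)
    sm <- stats::filter(area, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- area[is.na(sm)]
    zin <- range(which(area > 0))
    if (zin[2] - zin[1] < 4) stop("volume too thin to locate a growth-plate band")
    # candidate slices whose smoothing window lies fully inside the
    # mineralized z-range (edge windows are biased low by empty slices);
    # ties in the smoothed profile are broken by the raw area, so a gap
    # thinner than the smoothing window is still pinpointed
    interior <- seq(zin[1] + 2, zin[2] - 2)
    zmin <- interior[order(sm[interior], area[interior])[1]]
    thr <- min(area[interior]) + 0.25 * (max(area) - min(area[interior]))
    if (area[zmin] >= thr)
      stop("no interior minimum in the mineralized area profile; ",
           "supply `gp_band` explicitly")
    lo <- zmin; hi <- zmin
    while (lo - 1 >= zin[1] && area[lo - 1] < thr) lo <- lo - 1
    while (hi + 1 <= zin[2] && area[hi + 1] < thr) hi <- hi + 1
    if (lo <= zin[1] || hi >= zin[2])
      stop("area profile is monotone (no compartment on one side); ",
           "supply `gp_band` explicitly")
    gp_band <- c(lo, hi)
  } else {
    if (length(gp_band) != 2L || gp_band[1] > gp_band[2] ||
        gp_band[1] < 1 || gp_band[2] > d[3])
      stop("`gp_band` must be c(z_lo, z_hi) inside the volume")
  }
  z <- rep(seq_len(d[3]), each = d[1] * d[2])
  dim(z) <- d
  lab <- array(0L, d)
  lab[m & z > gp_band[2]] <- 1L
  lab[m & z < gp_band[1]] <- 2L
  inband <- z >= gp_band[1] & z <= gp_band[2]
  lab[!m & inband] <- 3L
  lab[m & inband] <- 4L
  out <- volume3d(lab, bone_mask$voxel_size, bone_mask$origin)
  attr(out, "gp_band") <- as.integer(gp_band)
  out
}

#' Extract the joint (plateau) surface as a height map
#'
#' For every (x, y) column that intersects the epiphysis, the surface height
#' is the physical z (micrometres) of the topmost mineralized voxel in that
#' column; the footprint marks the columns where the surface exists. This is
#' the surface onto which bridge centers are projected along +z.
#'
#' @param labeled a labeled [volume3d] from [label_compartments()].
#' @param bone_mask the mineralized mask the labels came from.
#' @return An object of class `joint_surface`: list with `height_um` (nx x ny
#'   matrix, `NA` off the footprint), `footprint` (logical matrix),
#'   `voxel_size`, `origin`.
#' @export
extract_joint_surface <- function(labeled, bone_mask) {
  stopifnot(inherits(labeled, "volume3d"), inherits(bone_mask, "volume3d"))
  assert_same_geometry(labeled, bone_mask)
  epi <- labeled$data == 1L
  if (!any(epi)) stop("epiphysis label is empty")
  d <- dim(epi)
  footprint <- apply(epi, c(1, 2), any)
  topz <- apply(bone_mask$data != 0, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  height <- labeled$origin[3] + (topz - 1) * labeled$voxel_size
  height[!footprint] <- NA_real_
  structure(list(height_um = height, footprint = footprint,
                 voxel_size = labeled$voxel_size, origin = labeled$origin),
            class = "joint_surface")
}

#' @exportS3Method base::print
print.joint_surface <- function(x, ...) {
  cat(sprintf("<joint_surface> %d x %d columns, %d on footprint, z range %.4g .. %.4g um\n",
              nrow(x$footprint), ncol(x$footprint), sum(x$footprint),
              min(x$height_um, na.rm = TRUE), max(x$height_um, na.rm = TRUE)))
  invisible(x)
}
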