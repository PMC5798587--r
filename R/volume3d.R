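#' 3D image volume with physical metadata
#'
#' The basic container for a microCT scan or a mask derived from it: a 3D
#' array of gray values (or logicals / integer labels) plus an isotropic
#' voxel edge length in micrometres and a physical origin. By convention +z
#' points from the metaphysis toward the joint surface (the shaft axis after
#' alignment), and the physical coordinate of voxel `(i, j, k)` (1-based R
#' indices, voxel-center convention) is `origin + voxel_size * (c(i,j,k) - 1)`.
#'
#' @param data 3D array (numeric, integer or logical).
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param origin physical coordinate (micrometres) of voxel `(1,1,1)`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), voxel_size = 5)
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop("every dimension of `data` must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  if (length(origin) != 3L || !is.numeric(origin))
    stop("`origin` must be a numeric 3-vector (micrometres)")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @exportS3Method base::print
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.4g um/voxel (%s)\n",
              d[1], d[2], d[3], x$voxel_size, typeof(x$data)))
  cat(sprintf("  origin (um): %.4g %.4g %.4g | gray range: %.4g .. %.4g\n",
              x$origin[1], x$origin[2], x$origin[3],
              suppressWarnings(min(x$data)), suppressWarnings(max(x$data))))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

# physical coordinates (um) of 1-based voxel indices; ijk: n x 3 matrix
voxel_to_um <- function(vol, ijk) {
  ijk <- rbind(ijk)
  sweep((ijk - 1) * vol$voxel_size, 2, vol$origin, "+")
}

um_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz, 2, vol$origin, "-") / vol$voxel_size + 1
}

assert_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes have different shapes")
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("volumes have different voxel sizes")
  invisible(TRUE)
}
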