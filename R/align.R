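#' Rigid alignment (rotation + translation)
#'
#' Describes the rigid map applied by [align_volume()]: physical coordinates
#' are transformed as `x' = R (x - c) + c + t`, where `c` is the physical
#' center of the volume (rotating about the center keeps the object in the
#' field of view) and `t` is a translation in micrometres.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector, micrometres.
#' @return An object of class `rigid_alignment`.
#' @export
rigid_alignment <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)))
    stop("`rotation` must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("`rotation` must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("`rotation` must have determinant +1 (no reflections)")
  if (length(translation) != 3L || !is.numeric(translation))
    stop("`translation` must be a numeric 3-vector")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_alignment")
}

#' Align a volume so +z is the shaft axis
#'
#' Applies a rigid transform and resamples onto the original grid. With an
#' explicit [rigid_alignment()] the transform is applied as given; with
#' `"auto"` the principal axis of the supplied mineralized mask (largest
#' principal component of the voxel coordinates) is rotated onto +z, which
#' replaces the manual alignment step of an interactive workstation.
#'
#' Grayscale volumes are resampled trilinearly; label or mask volumes must be
#' resampled with `interp = "nearest"` so labels are never blended. An exact
#' identity alignment returns the input unchanged, voxel for voxel.
#'
#' @param vol a [volume3d].
#' @param alignment a [rigid_alignment()] or `"auto"`.
#' @param mask for `"auto"`: a [volume3d] (logical data) of mineralized
#'   voxels used to compute the principal axis.
#' @param interp `"trilinear"` (grayscale) or `"nearest"` (labels/masks).
#' @param fill gray value for voxels mapped from outside the input grid.
#' @return The aligned [volume3d]. The fitted alignment is attached as
#'   attribute `"alignment"`.
#' @export
align_volume <- function(vol, alignment = "auto", mask = NULL,
                         interp = c("trilinear", "nearest"), fill = 0) {
  stopifnot(inherits(vol, "volume3d"))
  interp <- match.arg(interp)
  if (identical(alignment, "auto")) {
    if (is.null(mask))
      stop("alignment = \"auto\" needs a mineralized `mask` to compute a principal axis")
    alignment <- principal_axis_alignment(mask)
  }
  stopifnot(inherits(alignment, "rigid_alignment"))
  R <- alignment$rotation
  t <- alignment$translation
  if (max(abs(R - diag(3))) == 0 && all(t == 0)) {
    attr(vol, "alignment") <- alignment
    return(vol)
  }
  d <- dim(vol$data)
  vs <- vol$voxel_size
  ctr <- vol$origin + vs * (d - 1) / 2
  # source voxel (0-based) for output voxel v: s = R^T v + b
  b <- (crossprod(R, vol$origin - ctr - t) + (ctr - vol$origin)) / vs
  A <- cbind(t(R), as.numeric(b))
  out <- cpp_resample_affine(as.numeric(vol$data), d, d, A,
                             nearest = (interp == "nearest"), fill = fill)
  res <- volume3d(array(out, d), vs, vol$origin)
  attr(res, "alignment") <- alignment
  res
}

# rotation taking the mask's principal axis onto +z
principal_axis_alignment <- function(mask) {
  stopifnot(inherits(mask, "volume3d"))
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("mask too small to estimate a principal axis")
  cov <- stats::cov(idx)
  eg <- eigen(cov, symmetric = TRUE)
  if (eg$values[1] < 1.1 * eg$values[2])
    stop("degenerate principal axes (object nearly isotropic); ",
         "supply an explicit rigid_alignment()")
  v1 <- eg$vectors[, 1]
  if (v1[3] < 0 || (v1[3] == 0 && v1[1] < 0)) v1 <- -v1
  # orthonormal basis {u1, u2, v1}, rows of R, so R %*% v1 = e_z
  ref <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- ref - sum(ref * v1) * v1
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v1[2] * u1[3] - v1[3] * u1[2],
          v1[3] * u1[1] - v1[1] * u1[3],
          v1[1] * u1[2] - v1[2] * u1[1])
  R <- rbind(u1, u2, v1)
  if (det(R) < 0) R[2, ] <- -R[2, ]
  rownames(R) <- NULL
  rigid_alignment(R)
}
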