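#' 3D median filter
#'
#' Removes shot noise from tomographic volumes with minimal blurring. The
#' kernel parameter `k` selects a `(2k-1)^3` cubic window, so the default
#' `k = 2` is a 3x3x3 median — the smallest odd window consistent with a
#' "small" kernel; even-sized median windows are ill-defined. The window is
#' truncated at volume borders.
#'
#' @param vol a [volume3d].
#' @param kernel integer >= 1; window half-width plus one (default 2 gives a
#'   3x3x3 window).
#' @return A filtered [volume3d] of identical shape; the output gray range is
#'   a subset of the input range.
#' @examples
#' v <- volume3d(array(0, c(5, 5, 5)), 5)
#' v$data[3, 3, 3] <- 255  # isolated bright voxel
#' f <- median_filter_3d(v)
#' f$data[3, 3, 3]  # impulse removed
#' @export
median_filter_3d <- function(vol, kernel = 2) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel < 1 ||
      kernel != round(kernel))
    stop("`kernel` must be an integer >= 1")
  out <- cpp_median_filter(as.numeric(vol$data), dim(vol$data), as.integer(kernel))
  volume3d(array(out, dim(vol$data)), vol$voxel_size, vol$origin)
}
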