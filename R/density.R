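#' Project bridge centers onto the joint surface
#'
#' Each bridge center is carried along a straight line in +z to the joint
#' surface: the projected point is `(cx, cy, height(cx, cy))`, with the
#' surface height looked up bilinearly between voxel columns. Centers whose
#' (x, y) falls outside the surface footprint are reported with status
#' `"missed"` — they are excluded from density maps but never silently
#' dropped.
#'
#' @param bs a `bridge_set` with centers populated (see [bridge_centers()]).
#' @param surface a `joint_surface` from [extract_joint_surface()].
#' @return A tibble with columns `bridge_id`, `x_um`, `y_um`, `surface_z_um`,
#'   `status` (`"projected"` or `"missed"`).
#' @export
project_to_surface <- function(bs, surface) {
  stopifnot(inherits(bs, "bridge_set"), inherits(surface, "joint_surface"))
  if (nrow(bs) > 0 && anyNA(bs$cx_um))
    stop("bridge centers not populated; run bridge_centers() first")
  n <- nrow(bs)
  out <- tibble::tibble(
    bridge_id = bs$id,
    x_um = bs$cx_um, y_um = bs$cy_um,
    surface_z_um = NA_real_,
    status = rep("missed", n)
  )
  if (n == 0) return(out)
  vs <- surface$voxel_size
  org <- surface$origin
  H <- surface$height_um
  fp <- surface$footprint
  for (r in seq_len(n)) {
    # fractional column index, 1-based
    fx <- (bs$cx_um[r] - org[1]) / vs + 1
    fy <- (bs$cy_um[r] - org[2]) / vs + 1
    x0 <- floor(fx); y0 <- floor(fy)
    wx <- fx - x0; wy <- fy - y0
    cols <- rbind(c(x0, y0, (1 - wx) * (1 - wy)),
                  c(x0 + 1, y0, wx * (1 - wy)),
                  c(x0, y0 + 1, (1 - wx) * wy),
                  c(x0 + 1, y0 + 1, wx * wy))
    cols <- cols[cols[, 3] > 0, , drop = FALSE]
    ok <- cols[, 1] >= 1 & cols[, 1] <= nrow(fp) &
          cols[, 2] >= 1 & cols[, 2] <= ncol(fp)
    if (!all(ok)) next
    inside <- fp[cbind(cols[, 1], cols[, 2])]
    if (!all(inside)) next
    h <- H[cbind(cols[, 1], cols[, 2])]
    out$surface_z_um[r] <- sum(h * cols[, 3])
    out$status[r] <- "projected"
  }
  out
}

#' Windowed areal number density of bridges
#'
#' Counts projected bridge points in square windows tiling the surface
#' (default 256 um x 256 um), giving the areal number density N_A in
#' bridges/window. Windows are half-open,
#' `[x0 + m*w, x0 + (m+1)*w) x [y0 + n*w, y0 + (n+1)*w)`, so every point is
#' counted exactly once and the window counts always sum to the number of
#' projected points. The grid anchor defaults to the minimum (x, y) corner of
#' the point set (or of the surface footprint when supplied via
#' `grid_anchor`); the anchor used is recorded in the result.
#'
#' @param points tibble from [project_to_surface()]; rows with status
#'   `"missed"` are ignored with a message.
#' @param window_um window side length in micrometres (default 256).
#' @param grid_anchor numeric `c(x, y)` physical anchor of the window grid;
#'   default the floor of the minimum point coordinates.
#' @return A `density_map`: list with `windows` (tibble: `ix`, `iy`,
#'   `x_center_um`, `y_center_um`, `n_bridges`), `per_bridge` (tibble:
#'   `bridge_id`, `ix`, `iy`, `density`), `window_um`, `grid_anchor`.
#' @export
areal_density <- function(points, window_um = 256, grid_anchor = NULL) {
  if (!is.data.frame(points)) stop("`points` must be the projected-point table")
  if (!is.numeric(window_um) || window_um <= 0)
    stop("`window_um` must be > 0")
  missed <- sum(points$status == "missed")
  if (missed > 0)
    message(missed, " bridge(s) missed the surface footprint; excluded from density")
  pts <- points[points$status == "projected", , drop = FALSE]
  if (is.null(grid_anchor)) {
    grid_anchor <- if (nrow(pts)) c(min(pts$x_um), min(pts$y_um)) else c(0, 0)
  }
  ix <- floor((pts$x_um - grid_anchor[1]) / window_um)
  iy <- floor((pts$y_um - grid_anchor[2]) / window_um)
  key <- paste(ix, iy)
  cnt <- table(key)
  per_bridge <- tibble::tibble(
    bridge_id = pts$bridge_id, ix = as.integer(ix), iy = as.integer(iy),
    density = as.integer(cnt[key])
  )
  uk <- !duplicated(key)
  uix <- ix[uk]; uiy <- iy[uk]
  windows <- tibble::tibble(
    ix = as.integer(uix), iy = as.integer(uiy),
    x_center_um = grid_anchor[1] + (uix + 0.5) * window_um,
    y_center_um = grid_anchor[2] + (uiy + 0.5) * window_um,
    n_bridges = as.integer(cnt[key[uk]])
  )
  windows <- windows[order(windows$ix, windows$iy), ]
  structure(list(windows = windows, per_bridge = per_bridge,
                 window_um = window_um, grid_anchor = grid_anchor,
                 n_missed = missed),
            class = "density_map")
}

#' @exportS3Method base::print
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d occupied %g-um windows, %d bridges projected, %d missed\n",
              nrow(x$windows), x$window_um, sum(x$windows$n_bridges), x$n_missed))
  invisible(x)
}

#' Render density overlays
#'
#' Writes (a) a 2D heat map of N_A over the surface footprint as PNG and (b)
#' the joint surface as an ASCII PLY mesh with per-vertex colors encoding the
#' local density. Densities map linearly onto a dark-blue-to-yellow viridis
#' ramp; footprint columns in windows without bridges are drawn at density 0.
#' Output is deterministic for fixed input.
#'
#' @param dm a `density_map`.
#' @param surface the `joint_surface` the bridges were projected onto.
#' @param png_path,ply_path output files (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
render_overlay <- function(dm, surface, png_path = NULL, ply_path = NULL) {
  stopifnot(inherits(dm, "density_map"), inherits(surface, "joint_surface"))
  vs <- surface$voxel_size
  org <- surface$origin
  fp <- surface$footprint
  nx <- nrow(fp); ny <- ncol(fp)
  # density per surface column
  xs <- org[1] + (seq_len(nx) - 1) * vs
  ys <- org[2] + (seq_len(ny) - 1) * vs
  ixm <- matrix(floor((xs - dm$grid_anchor[1]) / dm$window_um), nx, ny)
  iym <- matrix(floor((ys - dm$grid_anchor[2]) / dm$window_um), nx, ny, byrow = TRUE)
  dens <- matrix(0, nx, ny)
  if (nrow(dm$windows)) {
    lut <- dm$windows$n_bridges
    names(lut) <- paste(dm$windows$ix, dm$windows$iy)
    hit <- lut[paste(ixm, iym)]
    hit[is.na(hit)] <- 0
    dens <- matrix(hit, nx, ny)
  }
  dens[!fp] <- NA
  written <- character()
  if (!is.null(png_path)) {
    img <- density_to_rgb(dens)
    # PNG rows are y; transpose so x runs along image width
    png::writePNG(aperm(img, c(2, 1, 3)), png_path)
    written <- c(written, png_path)
  }
  if (!is.null(ply_path)) {
    write_surface_ply(surface, dens, ply_path)
    written <- c(written, ply_path)
  }
  invisible(written)
}

# map densities to RGB (viridis-like 5-stop ramp); NA -> black
density_to_rgb <- function(dens) {
  stops <- matrix(c(
    0.267, 0.005, 0.329,
    0.229, 0.322, 0.546,
    0.128, 0.567, 0.551,
    0.369, 0.789, 0.383,
    0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)
  rng <- range(dens, na.rm = TRUE, finite = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  t <- (dens - rng[1]) / span
  t[is.na(t)] <- -1
  img <- array(0, c(nrow(dens), ncol(dens), 3))
  pos <- pmin(pmax(t, 0), 1) * (nrow(stops) - 1)
  i0 <- pmin(floor(pos), nrow(stops) - 2)
  w <- pos - i0
  for (ch in 1:3) {
    v <- stops[i0 + 1, ch] * (1 - w) + stops[i0 + 2, ch] * w
    v[t < 0] <- 0
    img[, , ch] <- v
  }
  img
}

write_surface_ply <- function(surface, dens, path) {
  fp <- surface$footprint
  nx <- nrow(fp); ny <- ncol(fp)
  vid <- matrix(NA_integer_, nx, ny)
  idx <- which(fp)
  vid[idx] <- seq_along(idx) - 1L  # 0-based PLY vertex ids
  ij <- which(fp, arr.ind = TRUE)
  xs <- surface$origin[1] + (ij[, 1] - 1) * surface$voxel_size
  ys <- surface$origin[2] + (ij[, 2] - 1) * surface$voxel_size
  zs <- surface$height_um[idx]
  col <- density_to_rgb(dens)[cbind(rep(ij[, 1], 3), rep(ij[, 2], 3),
                                    rep(1:3, each = nrow(ij)))]
  col <- matrix(round(col * 255), ncol = 3)
  # quads where all four corners are on the footprint, split into 2 triangles
  faces <- list()
  for (i in seq_len(nx - 1)) {
    ok <- fp[i, -ny] & fp[i + 1, -ny] & fp[i, -1] & fp[i + 1, -1]
    js <- which(ok)
    if (length(js)) {
      a <- vid[cbind(i, js)]; b <- vid[cbind(i + 1, js)]
      c_ <- vid[cbind(i + 1, js + 1)]; d <- vid[cbind(i, js + 1)]
      faces[[length(faces) + 1]] <- cbind(a, b, c_)
      faces[[length(faces) + 1]] <- cbind(a, c_, d)
    }
  }
  faces <- if (length(faces)) do.call(rbind, faces) else matrix(0L, 0, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(ij)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g %d %d %d", xs, ys, zs,
                     col[, 1], col[, 2], col[, 3]), con)
  if (nrow(faces))
    writeLines(sprintf("3 %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}

#' Heat-map plot of an areal density map
#'
#' @param object a `density_map`.
#' @param ... ignored.
#' @return A ggplot object (requires ggplot2).
#' @exportS3Method ggplot2::autoplot
autoplot.density_map <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot()")
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$x_center_um, y = .data$y_center_um,
                                  fill = .data$n_bridges)) +
    ggplot2::geom_tile(width = object$window_um, height = object$window_um) +
    ggplot2::scale_fill_viridis_c(name = expression(N[A])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Bridge areal number density")
}
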