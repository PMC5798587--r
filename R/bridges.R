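#' Find candidate bony bridges spanning the growth plate
#'
#' A bridge is a connected component of mineralized voxels inside the
#' growth-plate band that is adjacent (under the chosen connectivity) to both
#' the epiphyseal and the metaphyseal bone — the topological reading of a
#' bridge "crossing the entire growth plate width". Components touching only
#' one side (spurs) are excluded. Ids are deterministic, ordered by the
#' bounding-box minimum `(z, y, x)`.
#'
#' An optional `seeds` list (voxel index triples, 1-based) restricts the
#' result to components containing a seed, reproducing a manual,
#' observer-clicked identification.
#'
#' @param labeled labeled [volume3d] from [label_compartments()].
#' @param bone_mask mineralized mask the labels came from.
#' @param connectivity 26 (default) or 6.
#' @param seeds optional n x 3 matrix of voxel indices selecting components
#'   manually.
#' @return A `bridge_set`: a [tibble::tibble] with one row per bridge
#'   (columns `id`, `voxel_count`, `volume_um3`, `cx_um`, `cy_um`, `cz_um`,
#'   `touches_epi`, `touches_met`, bbox columns `x0..z1`) and attributes
#'   `voxel_size`, `origin`, `label_map` (per-voxel bridge id array),
#'   `gp_band` and `provenance`.
#' @export
find_candidate_bridges <- function(labeled, bone_mask, connectivity = 26,
                                   seeds = NULL) {
  stopifnot(inherits(labeled, "volume3d"), inherits(bone_mask, "volume3d"))
  assert_same_geometry(labeled, bone_mask)
  band <- attr(labeled, "gp_band")
  if (is.null(band)) stop("labeled volume has no growth-plate band")
  d <- dim(labeled$data)
  if (band[1] > band[2]) stop("empty growth-plate band")
  cand <- bone_mask$data != 0
  zidx <- rep(seq_len(d[3]), each = d[1] * d[2])
  dim(zidx) <- d
  cand <- cand & zidx >= band[1] & zidx <= band[2]
  comp <- array(cpp_label_components(as.vector(cand), d, as.integer(connectivity)), d)
  ncomp <- max(comp)
  empty <- bridge_tibble(labeled, comp * 0L, band, connectivity)
  if (ncomp == 0) return(empty)
  touches <- cpp_touch_labels(as.vector(comp), as.vector(labeled$data), d,
                              ncomp, as.integer(connectivity))
  keep <- which(touches[, 1] & touches[, 2])
  if (!is.null(seeds)) {
    seeds <- rbind(seeds)
    storage.mode(seeds) <- "integer"
    clicked <- unique(comp[seeds])
    keep <- intersect(keep, clicked[clicked > 0])
  }
  if (length(keep) == 0) return(empty)

  idx <- which(comp > 0, arr.ind = TRUE)
  cid <- comp[comp > 0]
  in_keep <- cid %in% keep
  idx <- idx[in_keep, , drop = FALSE]
  cid <- cid[in_keep]
  bbox <- do.call(rbind, lapply(split(seq_along(cid), cid), function(rows) {
    sub <- idx[rows, , drop = FALSE]
    c(range(sub[, 1]), range(sub[, 2]), range(sub[, 3]), length(rows))
  }))
  old_ids <- as.integer(rownames(bbox))
  ord <- order(bbox[, 5], bbox[, 3], bbox[, 1])  # min z, min y, min x
  old_ids <- old_ids[ord]
  bbox <- bbox[ord, , drop = FALSE]

  relab <- integer(ncomp)
  relab[old_ids] <- seq_along(old_ids)
  label_map <- array(0L, d)
  label_map[comp > 0] <- relab[comp[comp > 0]]

  bs <- tibble::tibble(
    id = seq_along(old_ids),
    voxel_count = as.integer(bbox[, 7]),
    volume_um3 = bbox[, 7] * labeled$voxel_size^3,
    cx_um = NA_real_, cy_um = NA_real_, cz_um = NA_real_,
    touches_epi = touches[old_ids, 1],
    touches_met = touches[old_ids, 2],
    x0 = as.integer(bbox[, 1]), x1 = as.integer(bbox[, 2]),
    y0 = as.integer(bbox[, 3]), y1 = as.integer(bbox[, 4]),
    z0 = as.integer(bbox[, 5]), z1 = as.integer(bbox[, 6])
  )
  as_bridge_set(bs, labeled, label_map, band, connectivity)
}

bridge_tibble <- function(labeled, label_map, band, connectivity) {
  bs <- tibble::tibble(
    id = integer(), voxel_count = integer(), volume_um3 = numeric(),
    cx_um = numeric(), cy_um = numeric(), cz_um = numeric(),
    touches_epi = logical(), touches_met = logical(),
    x0 = integer(), x1 = integer(), y0 = integer(), y1 = integer(),
    z0 = integer(), z1 = integer()
  )
  as_bridge_set(bs, labeled, label_map, band, connectivity)
}

as_bridge_set <- function(bs, labeled, label_map, band, connectivity) {
  attr(bs, "voxel_size") <- labeled$voxel_size
  attr(bs, "origin") <- labeled$origin
  attr(bs, "label_map") <- label_map
  attr(bs, "gp_band") <- band
  attr(bs, "provenance") <- list(connectivity = connectivity)
  class(bs) <- c("bridge_set", class(bs))
  bs
}

#' Apply the minimum-volume bridge filter
#'
#' Bridges smaller than `min_voxels` voxels are removed; a bridge of exactly
#' `min_voxels` voxels is retained. The default of 125 voxels discards
#' components too small to distinguish from partial-volume artifacts. Order
#' and ids of the survivors are preserved, so the operation is idempotent and
#' monotone in the threshold.
#'
#' @param bs a `bridge_set`.
#' @param min_voxels integer >= 1 (default 125).
#' @return The filtered `bridge_set`.
#' @export
filter_by_volume <- function(bs, min_voxels = 125) {
  stopifnot(inherits(bs, "bridge_set"))
  if (!is.numeric(min_voxels) || min_voxels < 1 || min_voxels != round(min_voxels))
    stop("`min_voxels` must be an integer >= 1")
  at <- attributes(bs)
  out <- bs[bs$voxel_count >= min_voxels, ]
  for (a in c("voxel_size", "origin", "label_map", "gp_band"))
    attr(out, a) <- at[[a]]
  attr(out, "provenance") <- c(at$provenance, list(min_voxels = min_voxels))
  class(out) <- unique(c("bridge_set", class(out)))
  out
}

#' Extract one center point per bridge
#'
#' With `method = "skeleton"` each bridge is reduced to its medial-axis
#' skeleton by topology-preserving 3D thinning and the center is the skeleton
#' voxel nearest (Euclidean, physical units) to the component centroid —
#' guaranteed to lie inside the component, unlike the raw centroid of a bent
#' bridge. Equidistant skeleton voxels are broken toward the smallest
#' `(z, y, x)` index. `method = "centroid"` uses the arithmetic mean of
#' voxel centers. Single-voxel components fall back to that voxel.
#'
#' @param bs a `bridge_set` (with its `label_map` attribute intact).
#' @param method `"skeleton"` (default) or `"centroid"`.
#' @return The `bridge_set` with `cx_um`, `cy_um`, `cz_um` populated.
#' @export
bridge_centers <- function(bs, method = c("skeleton", "centroid")) {
  stopifnot(inherits(bs, "bridge_set"))
  method <- match.arg(method)
  lm <- attr(bs, "label_map")
  if (is.null(lm)) stop("bridge_set has lost its label_map attribute")
  vs <- attr(bs, "voxel_size")
  org <- attr(bs, "origin")
  for (r in seq_len(nrow(bs))) {
    sub <- lm[bs$x0[r]:bs$x1[r], bs$y0[r]:bs$y1[r], bs$z0[r]:bs$z1[r], drop = FALSE]
    m <- sub == bs$id[r]
    vox <- which(m, arr.ind = TRUE)
    vox <- sweep(vox, 2, c(bs$x0[r], bs$y0[r], bs$z0[r]) - 1L, "+")
    cen_vox <- colMeans(vox)  # 1-based fractional voxel index
    if (method == "centroid" || nrow(vox) == 1L) {
      pick <- cen_vox
      if (method == "skeleton" && nrow(vox) == 1L)
        message("bridge ", bs$id[r], ": single-voxel component, center is that voxel")
    } else {
      sk <- array(cpp_skeletonize(as.vector(m), dim(m)), dim(m))
      skv <- which(sk, arr.ind = TRUE)
      if (nrow(skv) == 0) {
        message("bridge ", bs$id[r],
                ": empty skeleton, falling back to nearest component voxel")
        skv <- which(m, arr.ind = TRUE)
      }
      skv <- sweep(skv, 2, c(bs$x0[r], bs$y0[r], bs$z0[r]) - 1L, "+")
      d2 <- rowSums(sweep(skv, 2, cen_vox, "-")^2)
      best <- which(d2 == min(d2))
      if (length(best) > 1) {
        o <- order(skv[best, 3], skv[best, 2], skv[best, 1])
        best <- best[o[1]]
      }
      pick <- skv[best, ]
    }
    xyz <- org + vs * (pick - 1)
    bs$cx_um[r] <- xyz[1]; bs$cy_um[r] <- xyz[2]; bs$cz_um[r] <- xyz[3]
  }
  prov <- attr(bs, "provenance")
  attr(bs, "provenance") <- c(prov, list(center_method = method))
  bs
}

#' Export a bridge set
#'
#' Writes the tabular bridge data as CSV, the full set with provenance as
#' JSON, and optionally the per-voxel bridge id image as NRRD (each bridge a
#' distinct integer, for colored rendering).
#'
#' @param bs a `bridge_set`.
#' @param csv,json,labels output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_bridges <- function(bs, csv = NULL, json = NULL, labels = NULL) {
  stopifnot(inherits(bs, "bridge_set"))
  written <- character()
  tab <- as.data.frame(bs[, c("id", "voxel_count", "volume_um3",
                              "cx_um", "cy_um", "cz_um",
                              "touches_epi", "touches_met")])
  if (!is.null(csv)) {
    utils::write.csv(tab, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(bridges = tab, provenance = attr(bs, "provenance"),
           voxel_size_um = attr(bs, "voxel_size"),
           gp_band = attr(bs, "gp_band")),
      json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  if (!is.null(labels)) {
    lm <- attr(bs, "label_map")
    keep <- array(0L, dim(lm))
    keep[lm %in% bs$id] <- lm[lm %in% bs$id]
    write_volume(volume3d(keep, attr(bs, "voxel_size"), attr(bs, "origin")), labels)
    written <- c(written, labels)
  }
  invisible(written)
}
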