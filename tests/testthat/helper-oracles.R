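# Brute-force oracles, independent of the package's C++ kernels.

nb_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# plain BFS flood fill over {gray in [lo, hi]} from seeds (n x 3, 1-based)
bf_flood <- function(data, seeds, lo, hi, connectivity) {
  d <- dim(data)
  sel <- array(FALSE, d)
  off <- nb_offsets(connectivity)
  queue <- rbind(seeds)
  sel[queue] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (r in seq_len(nrow(off))) {
      q <- p + off[r, ]
      if (any(q < 1) || any(q > d)) next
      qm <- matrix(q, 1)
      if (!sel[qm] && data[qm] >= lo && data[qm] <= hi) {
        sel[qm] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  sel
}

# connected-component labeling by repeated flood fill
bf_label <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  repeat {
    left <- which(mask & lab == 0L, arr.ind = TRUE)
    if (nrow(left) == 0) break
    nxt <- nxt + 1L
    comp <- bf_flood(array(as.numeric(mask), d), left[1, , drop = FALSE],
                     1, 1, connectivity)
    lab[comp] <- nxt
  }
  lab
}

# double-loop window counting oracle
bf_window_counts <- function(x, y, anchor, w) {
  ix <- floor((x - anchor[1]) / w)
  iy <- floor((y - anchor[2]) / w)
  cells <- unique(cbind(ix, iy))
  counts <- integer(nrow(cells))
  for (i in seq_len(nrow(cells)))
    for (j in seq_along(x))
      if (ix[j] == cells[i, 1] && iy[j] == cells[i, 2])
        counts[i] <- counts[i] + 1L
  list(cells = cells, counts = counts)
}

# small phantom spec used across tests (fast: ~96 x 96 x 80)
small_phantom_spec <- function(k, seed, noise_sd = 5, tilt = 0,
                               undulation = list(amplitude_vox = 4, period_vox = 32)) {
  shape <- c(96, 96, 80)
  phantom_spec(
    shape = shape, plate_thickness = c(18, 18), gap_thickness = 8,
    bridges = random_bridge_layout(k, shape = shape, radius_vox = 3,
                                   tilt_deg = tilt, seed = seed),
    undulation = undulation,
    gray_levels = list(bone_mean = 200, cartilage_mean = 60,
                       background_mean = 20, noise_sd = noise_sd),
    seed = seed)
}

# segmentation driven by the phantom's own gray model; one seed per plate
# (the compartments are disconnected when no bridge crosses the gap)
segment_phantom <- function(vol, spec = NULL) {
  thr <- 130  # midpoint of cartilage (60) and bone (200) means
  cand <- which(vol$data >= thr, arr.ind = TRUE)
  s1 <- cand[which.min(cand[, 3]), ]  # lowest mineralized slice: metaphysis
  s2 <- cand[which.max(cand[, 3]), ]  # highest: epiphysis
  region_grow(vol, rbind(s1, s2), c(thr, Inf))
}

# greedy nearest matching of estimated centers to truth centers
match_centers <- function(est, truth) {
  stopifnot(nrow(est) == nrow(truth))
  used <- logical(nrow(truth))
  idx <- integer(nrow(est))
  for (i in seq_len(nrow(est))) {
    d2 <- (truth$cx_um - est$cx_um[i])^2 + (truth$cy_um - est$cy_um[i])^2 +
      (truth$cz_um - est$cz_um[i])^2
    d2[used] <- Inf
    idx[i] <- which.min(d2)
    used[idx[i]] <- TRUE
  }
  idx
}
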