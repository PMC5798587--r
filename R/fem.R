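#' Isotropic linear-elastic material
#'
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson ratio, dimensionless (-1 < nu < 0.5).
#' @return An object of class `material_model`.
#' @export
material_model <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("E must be > 0 (MPa)")
  if (!is.numeric(nu) || nu <= -1 || nu >= 0.5)
    stop("nu must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "material_model")
}

#' Default tissue materials
#'
#' Mineralized bone E = 17,000 MPa, nu = 0.3; growth-plate cartilage
#' E = 6 MPa, nu = 0.49 (nearly incompressible). Material ids: 1 = bone,
#' 2 = growth plate.
#'
#' @return Named list of [material_model()] objects, indexed by material id.
#' @export
default_materials <- function() {
  list(bone = material_model(17000, 0.3),
       growth_plate = material_model(6, 0.49))
}

#' Tetrahedral mesh from a labeled volume
#'
#' Optionally bins the label volume (majority vote per `bin_factor^3` block,
#' ties toward the smaller label code), then decomposes every retained
#' (non-background) voxel into 5 tetrahedra using the parity-alternating
#' decomposition, which is conforming across shared voxel faces. Nodes are
#' voxel corners in millimetres (micrometre voxel pitch divided by 1000), so
#' Table-style MPa moduli and Newton loads combine without unit scaling.
#' The summed tetrahedron volume equals the retained voxel volume exactly.
#' Element material ids: labels 1, 2, 4 (bone) map to 1; label 3 (growth
#' plate) maps to 2.
#'
#' @param labeled a labeled [volume3d] (codes as in [label_compartments()]).
#' @param bin_factor integer >= 1; voxel down-sampling factor.
#' @return An object of class `tet_mesh`: `nodes` (n x 3, mm), `elems`
#'   (m x 4 node indices, 1-based, positively oriented), `material_id`
#'   (length m), `h_mm` (element edge), `voxel_index` (m-vector mapping
#'   elements to binned-voxel linear indices).
#' @export
mesh_from_labels <- function(labeled, bin_factor = 1) {
  stopifnot(inherits(labeled, "volume3d"))
  if (bin_factor < 1 || bin_factor != round(bin_factor))
    stop("`bin_factor` must be an integer >= 1")
  lab <- labeled$data
  d <- dim(lab)
  if (bin_factor > 1) {
    nb <- d %/% bin_factor
    if (any(nb < 1)) stop("bin_factor larger than the volume")
    sub <- lab[seq_len(nb[1] * bin_factor),
               seq_len(nb[2] * bin_factor),
               seq_len(nb[3] * bin_factor), drop = FALSE]
    lab <- majority_bin(sub, bin_factor)
    d <- nb
  }
  h_mm <- labeled$voxel_size * bin_factor / 1000
  vox <- which(lab != 0L, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("label volume is empty after binning")
  labv <- lab[lab != 0L]
  material_id <- ifelse(labv == 3L, 2L, 1L)

  # voxel corners, 0-based: voxel (i,j,k) (1-based) spans corners (i-1..i, ...)
  corner_bits <- cbind(c(0,1,0,1,0,1,0,1), c(0,0,1,1,0,0,1,1), c(0,0,0,0,1,1,1,1))
  nvox <- nrow(vox)
  corners <- matrix(0L, nvox * 8, 3)
  for (b in 1:8)
    corners[seq.int(b, by = 8, length.out = nvox), ] <-
      t(t(vox) - 1L + corner_bits[b, ])
  ckey <- corners[, 1] + (d[1] + 1) * (corners[, 2] + (d[2] + 1) * corners[, 3])
  uq <- !duplicated(ckey)
  node_key <- ckey[uq]
  node_id <- match(ckey, node_key)           # per corner, 1-based node index
  nodes <- corners[uq, , drop = FALSE] * h_mm
  storage.mode(nodes) <- "double"

  # 5-tet decomposition by local corner index (x + 2y + 4z), parity-alternating
  tets_even <- rbind(c(1,2,4,7), c(0,1,2,4), c(3,1,2,7), c(5,1,4,7), c(6,2,4,7))
  tets_odd  <- rbind(c(0,3,5,6), c(1,0,3,5), c(2,0,3,6), c(4,0,5,6), c(7,3,5,6))
  parity <- (rowSums(vox) - 3L) %% 2L        # 0-based parity of (i-1,j-1,k-1)
  elems <- matrix(0L, nvox * 5, 4)
  for (t in 1:5) {
    rows <- seq.int(t, by = 5, length.out = nvox)
    loc <- matrix(tets_even[t, ], nvox, 4, byrow = TRUE)
    loc_o <- matrix(tets_odd[t, ], nvox, 4, byrow = TRUE)
    odd <- parity == 1L
    loc[odd, ] <- loc_o[odd, ]
    base <- (seq_len(nvox) - 1L) * 8L
    for (c in 1:4) elems[rows, c] <- node_id[base + loc[, c] + 1L]
  }
  # enforce positive orientation
  v1 <- nodes[elems[, 2], ] - nodes[elems[, 1], ]
  v2 <- nodes[elems[, 3], ] - nodes[elems[, 1], ]
  v3 <- nodes[elems[, 4], ] - nodes[elems[, 1], ]
  detv <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  flip <- detv < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]

  structure(list(nodes = nodes, elems = elems,
                 material_id = rep(material_id, each = 5),
                 h_mm = h_mm, dims = d,
                 voxel_index = rep(seq_len(nvox), each = 5),
                 voxel_label = rep(labv, each = 5)),
            class = "tet_mesh")
}

majority_bin <- function(lab, f) {
  d <- dim(lab)
  nb <- d %/% f
  counts <- array(0L, c(nb, 5))  # labels 0..4
  for (l in 0:4) {
    m <- array(as.integer(lab == l), d)
    s <- m
    # sum over f x f x f blocks by successive dimension folding
    s <- apply(array(s, c(f, nb[1], d[2], d[3])), c(2, 3, 4), sum)
    s <- apply(array(s, c(nb[1], f, nb[2], d[3])), c(1, 3, 4), sum)
    s <- apply(array(s, c(nb[1], nb[2], f, nb[3])), c(1, 2, 4), sum)
    counts[, , , l + 1] <- s
  }
  flat <- matrix(counts, ncol = 5)
  win <- max.col(flat, ties.method = "first") - 1L  # tie -> smaller label
  array(as.integer(win), nb)
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d TET4 elements, edge %.4g mm, materials: %s\n",
              nrow(x$nodes), nrow(x$elems), x$h_mm,
              paste(sort(unique(x$material_id)), collapse = ", ")))
  invisible(x)
}

#' Build the static compressive load case
#'
#' Reproduces the loading scenario for a tibia under sustained compression:
#' all nodes on the bottom face have their vertical (z) displacement fixed;
#' rigid-body motion is removed by pinning three deterministic extremal
#' bottom nodes (the minimum-(x,y) node fully fixed, the maximum-x node
#' fixed in x, the maximum-y node fixed in y); the total force (default 1 N,
#' roughly three times the body weight of an adult mouse) is applied in -z,
#' split equally between the medial and lateral halves of the top node set
#' and, within each half, over its nodes (equally, or in proportion to
#' tributary surface area with `split = "consistent"`).
#'
#' @param mesh a `tet_mesh`.
#' @param total_force total applied force, Newtons.
#' @param direction force direction (unit 3-vector, default `c(0, 0, -1)`).
#' @param split `"equal"` (default) or `"consistent"` (tributary-area
#'   weights from the boundary triangulation of the top surface; this is the
#'   work-equivalent loading for a uniform traction).
#' @param regions `"medial_lateral"` (default: half the force on each half of
#'   the top surface) or `"all"` (one node set covering the whole top, e.g.
#'   for uniform-compression verification problems).
#' @return An object of class `load_case`: `fixed` (tibble `node`, `dof`,
#'   `value`) and `forces` (tibble `node`, `dof`, `value`), plus provenance.
#' @export
load_case <- function(mesh, total_force = 1, direction = c(0, 0, -1),
                      split = c("equal", "consistent"),
                      regions = c("medial_lateral", "all")) {
  stopifnot(inherits(mesh, "tet_mesh"))
  split <- match.arg(split)
  regions <- match.arg(regions)
  nd <- mesh$nodes
  tol <- 1e-9 * max(1, max(abs(nd)))
  bottom <- which(nd[, 3] <= min(nd[, 3]) + tol)
  top <- which(nd[, 3] >= max(nd[, 3]) - tol)
  if (length(bottom) < 3) stop("fewer than 3 bottom nodes; cannot restrain rigid-body modes")
  fixed <- tibble::tibble(node = bottom, dof = 3L, value = 0)
  ob <- bottom[order(nd[bottom, 1], nd[bottom, 2])]
  a <- ob[1]
  bx <- bottom[order(-nd[bottom, 1], nd[bottom, 2])][1]
  by <- bottom[order(-nd[bottom, 2], nd[bottom, 1])][1]
  if (length(unique(c(a, bx, by))) < 3)
    stop("degenerate pin-node selection (bottom set too small)")
  fixed <- rbind(fixed,
                 tibble::tibble(node = c(a, a, bx, by),
                                dof = c(1L, 2L, 1L, 2L), value = 0))
  if (regions == "all") {
    forces <- node_forces(mesh, top, total_force, direction, split)
    nmed <- nlat <- NA_integer_
  } else {
    xmid <- mean(range(nd[top, 1]))
    medial <- top[nd[top, 1] <= xmid]
    lateral <- top[nd[top, 1] > xmid]
    if (length(lateral) == 0) lateral <- medial
    forces <- rbind(
      node_forces(mesh, medial, total_force / 2, direction, split),
      node_forces(mesh, lateral, total_force / 2, direction, split)
    )
    nmed <- length(medial); nlat <- length(lateral)
  }
  structure(list(fixed = fixed, forces = forces,
                 provenance = list(total_force = total_force,
                                   direction = direction, split = split,
                                   regions = regions,
                                   n_medial = nmed, n_lateral = nlat)),
            class = "load_case")
}

# distribute `total` * direction over `nodes`
node_forces <- function(mesh, nodes, total, direction, split) {
  w <- if (split == "equal") rep(1, length(nodes)) else {
    tw <- tributary_weights(mesh, nodes)
    if (all(tw == 0)) rep(1, length(nodes)) else tw
  }
  w <- w / sum(w)
  f <- outer(w * total, direction)
  tibble::tibble(node = rep(nodes, 3),
                 dof = rep(1:3, each = length(nodes)),
                 value = as.numeric(f))[as.numeric(f) != 0, ]
}

# area/3 per node over boundary triangles whose vertices all lie in `nodes`
tributary_weights <- function(mesh, nodes) {
  faces <- boundary_faces(mesh)
  inset <- matrix(faces %in% nodes, nrow(faces), 3)
  keep <- rowSums(inset) == 3
  w <- numeric(length(nodes))
  if (!any(keep)) return(w)
  f <- faces[keep, , drop = FALSE]
  p1 <- mesh$nodes[f[, 1], , drop = FALSE]
  p2 <- mesh$nodes[f[, 2], , drop = FALSE]
  p3 <- mesh$nodes[f[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  for (c in 1:3) {
    tab <- tapply(area / 3, f[, c], sum)
    idx <- match(as.integer(names(tab)), nodes)
    w[idx] <- w[idx] + as.numeric(tab)
  }
  w
}

boundary_faces <- function(mesh) {
  e <- mesh$elems
  faces <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)], e[, c(1, 3, 4)], e[, c(2, 3, 4)])
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

#' Assemble and solve the linear elastic system
#'
#' Standard constant-strain TET4 assembly for isotropic linear elasticity:
#' solves `K u = f` with prescribed displacements eliminated, recovers the
#' per-element stress tensor from the constitutive law, and checks global
#' equilibrium (reactions balance applied loads; relative residual on the
#' free equations <= 1e-10).
#'
#' @param mesh a `tet_mesh`.
#' @param materials list of [material_model()] indexed by material id.
#' @param load a [load_case()] (or any list with `fixed` and `forces` tables
#'   of `node`, `dof` (1 = x, 2 = y, 3 = z), `value`).
#' @return An object of class `fe_result`: `u` (n x 3 nodal displacements,
#'   mm), `stress` (m x 6: xx, yy, zz, xy, yz, zx, MPa), `von_mises`
#'   (per element, MPa), `reactions` (tibble at constrained DOFs, N),
#'   `residual` (relative), plus the mesh.
#' @export
assemble_and_solve <- function(mesh, materials = default_materials(), load) {
  stopifnot(inherits(mesh, "tet_mesh"))
  mid <- mesh$material_id
  if (max(mid) > length(materials))
    stop("material id ", max(mid), " has no entry in `materials`")
  E <- vapply(materials, `[[`, 0, "E")[mid]
  nu <- vapply(materials, `[[`, 0, "nu")[mid]
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  trip <- cpp_fem_assemble(mesh$nodes, mesh$elems - 1L, E, nu)
  K <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
                            dims = c(ndof, ndof))
  fixed <- as.data.frame(load$fixed)
  forces <- as.data.frame(load$forces)
  if (any(duplicated(fixed[c("node", "dof")])))
    fixed <- fixed[!duplicated(fixed[c("node", "dof")]), ]
  cdof <- 3L * (fixed$node - 1L) + fixed$dof
  f <- numeric(ndof)
  if (nrow(forces)) {
    fd <- 3L * (forces$node - 1L) + forces$dof
    f[sort(unique(fd))] <- tapply(forces$value, fd, sum)[as.character(sort(unique(fd)))]
  }
  # quick singularity diagnosis: every translation needs a constraint
  for (d in 1:3)
    if (!any(fixed$dof == d))
      stop("singular system: unconstrained rigid-body translation along ",
           c("x", "y", "z")[d])
  free <- setdiff(seq_len(ndof), cdof)
  uc <- fixed$value
  u <- numeric(ndof)
  u[cdof] <- uc
  rhs <- f[free] - as.numeric(K[free, cdof, drop = FALSE] %*% uc)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- tryCatch(as.numeric(Matrix::solve(Kff, rhs)),
                 error = function(e)
                   stop("singular system (insufficient restraints, likely an ",
                        "unconstrained rigid-body rotation): ", conditionMessage(e)))
  u[free] <- uf
  res <- as.numeric(Kff %*% uf) - rhs
  fnorm <- max(sqrt(sum(f^2)), sqrt(sum(rhs^2)), 1e-300)
  residual <- sqrt(sum(res^2)) / fnorm
  if (residual > 1e-8)
    warning(sprintf("solver residual %.3g exceeds 1e-8 of the load norm", residual))
  r_all <- as.numeric(K %*% u) - f
  reactions <- tibble::tibble(node = fixed$node, dof = fixed$dof,
                              value = r_all[cdof])
  S <- cpp_fem_stress(mesh$nodes, mesh$elems - 1L, E, nu, u)
  colnames(S) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 stress = S, von_mises = von_mises(S),
                 reactions = reactions, residual = residual,
                 mesh = mesh, element_volume = trip$vol),
            class = "fe_result")
}

#' von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) + 3 * (s12^2 + s23^2
#' + s31^2))`; zero for hydrostatic states, equal to the axial stress for
#' uniaxial ones.
#'
#' @param stress a symmetric 3x3 stress tensor, or an m x 6 matrix with
#'   columns xx, yy, zz, xy, yz, zx (MPa).
#' @return Non-negative scalar (or m-vector), MPa.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      stop("stress tensor must be symmetric")
    stress <- matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                       stress[1, 2], stress[2, 3], stress[3, 1]), 1)
  }
  s <- stress
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                        (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' @exportS3Method base::print
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> %d nodes, %d elements | max |u| %.4g mm | max von Mises %.4g MPa | residual %.2g\n",
              nrow(x$u), nrow(x$stress), max(abs(x$u)), max(x$von_mises),
              x$residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-element results of a finite-element solve
#'
#' @param x an `fe_result`.
#' @param ... ignored.
#' @return Tibble with one row per element: stress components, von Mises,
#'   material id, element volume.
#' @export
tidy.fe_result <- function(x, ...) {
  tibble::as_tibble(cbind(
    tibble::tibble(element = seq_len(nrow(x$stress)),
                   material_id = x$mesh$material_id,
                   volume_mm3 = x$element_volume),
    as.data.frame(x$stress),
    tibble::tibble(von_mises = x$von_mises)))
}

#' One-row summary of a finite-element solve
#'
#' @param x an `fe_result`.
#' @param ... ignored.
#' @return One-row tibble: sizes, displacement and stress extremes, total
#'   vertical reaction, relative residual.
#' @export
glance.fe_result <- function(x, ...) {
  rz <- sum(x$reactions$value[x$reactions$dof == 3])
  tibble::tibble(n_nodes = nrow(x$u), n_elements = nrow(x$stress),
                 max_abs_u_mm = max(abs(x$u)),
                 max_von_mises_mpa = max(x$von_mises),
                 total_reaction_z_n = rz,
                 residual = x$residual)
}

#' Select the coarsest mesh within tolerance of the asymptote
#'
#' Given a convergence series (element counts and a scalar metric per mesh),
#' estimates the asymptote as the finest-mesh metric and returns the
#' smallest element count whose metric lies within `tol` (default 5%) of it.
#'
#' @param element_counts strictly increasing integer vector (>= 3 entries).
#' @param metrics scalar metric per mesh (same length).
#' @param tol relative tolerance (default 0.05).
#' @return The chosen element count, with the convergence table attached as
#'   attribute `"table"`.
#' @export
mesh_sensitivity <- function(element_counts, metrics, tol = 0.05) {
  if (length(element_counts) < 3) stop("need at least 3 meshes in the series")
  if (length(metrics) != length(element_counts))
    stop("`metrics` and `element_counts` differ in length")
  if (any(diff(element_counts) <= 0))
    stop("element counts must be strictly increasing")
  n <- length(metrics)
  asym <- metrics[n]
  rel <- abs(metrics - asym) / max(abs(asym), 1e-300)
  tab <- tibble::tibble(element_count = element_counts, metric = metrics,
                        rel_error = rel, within_tol = rel <= tol)
  # converged = inside the band and staying there on every finer mesh;
  # the finest mesh itself cannot demonstrate convergence (it defines the
  # asymptote), so a series that only enters the band there has not converged
  stays <- rev(cumprod(rev(rel <= tol))) == 1
  ok <- which(stays[-n])
  if (length(ok) == 0) {
    stop("no mesh enters and stays in the ", 100 * tol,
         "% band of the asymptote; series:\n",
         paste(utils::capture.output(print(as.data.frame(tab))), collapse = "\n"))
  }
  chosen <- element_counts[ok[1]]
  attr(chosen, "table") <- tab
  chosen
}

#' Export a mesh and solution as legacy ASCII VTK
#'
#' Writes an unstructured grid with point displacement vectors and per-cell
#' von Mises stress and material id, readable by ParaView.
#'
#' @param result an `fe_result` (or a bare `tet_mesh` for geometry only).
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(result, path) {
  mesh <- if (inherits(result, "tet_mesh")) result else result$mesh
  con <- file(path, "w")
  on.exit(close(con))
  nd <- mesh$nodes
  el <- mesh$elems
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral mesh with elastic solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.10g %.10g %.10g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * 5), con)
  writeLines(sprintf("4 %d %d %d %d", el[, 1] - 1, el[, 2] - 1,
                     el[, 3] - 1, el[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep("10", nrow(el)), con)
  if (inherits(result, "fe_result")) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(nd)),
                 "VECTORS displacement double"), con)
    writeLines(sprintf("%.10g %.10g %.10g",
                       result$u[, 1], result$u[, 2], result$u[, 3]), con)
    writeLines(c(sprintf("CELL_DATA %d", nrow(el)),
                 "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", result$von_mises), con)
    writeLines(c("SCALARS material int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", mesh$material_id), con)
  }
  invisible(path)
}
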