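#' Tibial plateau landmarks from a segmentation mask
#'
#' Derives, on a re-aligned mask, the tibial plateau footprint (columns whose
#' top surface lies near the plateau level), the plateau z level, the
#' mediolateral split coordinate, the mediolateral extent and the central
#' (spine) slab half-width used for the medial/central/lateral sectors.
#'
#' @param mask A `segmentation_mask` (tibia = label 1), re-aligned so the
#'   limb axis is approximately vertical.
#' @param central_frac Width of the central sector as a fraction of the
#'   mediolateral plateau extent (default 0.2).
#' @param drop_mm Columns whose top surface is more than this far below the
#'   plateau reference level are excluded from the footprint (default 8 mm).
#' @return List: `footprint` (nx x ny logical), `top_z` (nx x ny world z of
#'   the column top, NA off-bone), `z_plateau`, `x0` (split plane), `ml_extent`,
#'   `central_halfwidth`.
#' @export
tibia_landmarks <- function(mask, central_frac = 0.2, drop_mm = 8) {
  lab <- mask$labels == 1L
  if (!any(lab)) stop("missing tibia label in mask")
  d <- dim(lab)
  # top voxel index per (i,j) column
  topk <- apply(lab, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  top_z <- mask$origin[3] + (topk - 1) * mask$spacing[3]
  zref <- stats::quantile(top_z, 0.98, na.rm = TRUE, names = FALSE)
  footprint <- !is.na(top_z) & top_z >= zref - drop_mm
  ij <- which(footprint, arr.ind = TRUE)
  xs <- mask$origin[1] + (ij[, 1] - 1) * mask$spacing[1]
  x0 <- stats::median(xs)
  ml_extent <- diff(range(xs))
  list(footprint = footprint, top_z = top_z,
       z_plateau = mean(top_z[footprint]),
       x0 = x0, ml_extent = ml_extent,
       central_halfwidth = central_frac * ml_extent / 2)
}

#' Crop a mask to the analysis region around the joint
#'
#' Keeps the model between `distal_mm` below and `proximal_mm` above the
#' tibial plateau level. The regional analysis only extends 35 mm below the
#' plateau and the femur acts as a rigid load introducer, so shaft bone far
#' from the joint adds degrees of freedom without affecting the regional
#' fields; the crop planes become the distal/top constraint surfaces.
#'
#' @param mask A re-aligned `segmentation_mask`.
#' @param landmarks A [tibia_landmarks()] result for `mask`.
#' @param distal_mm Extent kept below the plateau (default 55).
#' @param proximal_mm Extent kept above the plateau (default 35).
#' @return The cropped `segmentation_mask`.
#' @export
crop_to_joint <- function(mask, landmarks, distal_mm = 55, proximal_mm = 35) {
  d <- dim(mask$labels)
  z <- mask$origin[3] + (seq_len(d[3]) - 1) * mask$spacing[3]
  drop <- z < landmarks$z_plateau - distal_mm |
    z > landmarks$z_plateau + proximal_mm
  if (any(drop)) mask$labels[, , drop] <- 0L
  if (!any(mask$labels > 0L)) stop("crop removed the whole model")
  mask
}

#' Build a finite-element mesh from a segmentation mask
#'
#' Default mode is `hex_voxel`: a structured grid of 8-node hexahedra at
#' `element_size`, each cell assigned to the majority bone label among 8
#' interior sample points (cells at least half inside a bone are kept). A
#' soft-tissue cylinder spanning the femorotibial gap and enclosing the
#' condyles (radius 1.1 x the mediolateral half-extent) is meshed on the same
#' grid so bone/soft-tissue interfaces share nodes (bonded contact). Mode
#' `tet_quadratic` subdivides each hexahedron into six 10-node quadratic
#' tetrahedra (conforming Freudenthal split) to mirror the quadratic
#' tetrahedral meshes used with commercial solvers and for INP export.
#'
#' @param mask A re-aligned `segmentation_mask` (tibia 1, femur 2, fibula 3).
#' @param element_size Bone element size, mm (>= voxel size).
#' @param mode `"hex_voxel"` or `"tet_quadratic"`.
#' @param landmarks Optional [tibia_landmarks()] result (computed if omitted).
#' @param soft_tissue Logical: include the soft-tissue cylinder (default TRUE).
#' @return An `fe_mesh`: `nodes` (n x 3 mm), `conn` (elements x 8 or x 10),
#'   `type`, `element_domain` (factor tibia/femur/fibula/soft_tissue),
#'   `element_size`, per-element `volumes` and `centroids`, and named
#'   `node_sets` (femur_top, tibia_distal, fibula_distal,
#'   subchondral_surface_medial, subchondral_surface_lateral).
#' @export
build_mesh <- function(mask, element_size,
                       mode = c("hex_voxel", "tet_quadratic"),
                       landmarks = NULL, soft_tissue = TRUE) {
  mode <- match.arg(mode)
  if (element_size < max(mask$spacing))
    stop("element_size must be >= voxel size")
  if (is.null(landmarks)) landmarks <- tibia_landmarks(mask)
  d <- dim(mask$labels)
  lab_vol <- mask_as_volume(mask)

  occ <- which(mask$labels > 0L, arr.ind = TRUE)
  lo <- voxel_to_world(mask, matrix(apply(occ, 2, min), ncol = 3)) -
    mask$spacing / 2
  hi <- voxel_to_world(mask, matrix(apply(occ, 2, max), ncol = 3)) +
    mask$spacing / 2
  h <- element_size
  ncell <- pmax(1L, as.integer(ceiling((hi - lo) / h)))
  cell_ijk <- as.matrix(expand.grid(i = seq_len(ncell[1]),
                                    j = seq_len(ncell[2]),
                                    k = seq_len(ncell[3])))
  centres <- sweep((cell_ijk - 0.5) * h, 2, as.numeric(lo), `+`)

  # occupancy vote over a 3 x 3 x 3 sub-cell lattice per cell; a cell is a
  # bone element when a strict majority of sample points is bone (the odd
  # count avoids ties and keeps the meshed volume unbiased)
  g3 <- c(-1, 0, 1) / 3
  offs <- as.matrix(expand.grid(g3, g3, g3)) * h
  nsamp <- nrow(offs)
  votes <- matrix(0L, nrow(centres), 4)  # labels 1..3 and background (0)
  for (s in seq_len(nsamp)) {
    pts <- sweep(centres, 2, offs[s, ], `+`)
    lv <- as.integer(sample_volume(lab_vol, pts, method = "nearest",
                                   fill = 0))
    lv[lv > 3L] <- 0L   # calibration rods are never meshed
    for (b in 0:3) votes[, b + 1] <- votes[, b + 1] + (lv == b)
  }
  bone_frac <- (nsamp - votes[, 1]) / nsamp
  domain <- ifelse(bone_frac > 0.5,
                   max.col(votes[, 2:4, drop = FALSE],
                           ties.method = "first"), 0L)

  if (soft_tissue) {
    ctr_xy <- c(landmarks$x0, {
      ij <- which(landmarks$footprint, arr.ind = TRUE)
      stats::median(mask$origin[2] + (ij[, 2] - 1) * mask$spacing[2])
    })
    radius <- 1.1 * landmarks$ml_extent / 2
    zp <- landmarks$z_plateau
    in_cyl <- (centres[, 1] - ctr_xy[1])^2 + (centres[, 2] - ctr_xy[2])^2 <=
      radius^2 & centres[, 3] >= zp - 5 & centres[, 3] <= zp + 27
    domain[domain == 0L & in_cyl] <- 4L
  }

  keep <- domain > 0L
  if (!any(keep)) stop("no elements generated")
  cell_ijk <- cell_ijk[keep, , drop = FALSE]
  centres <- centres[keep, , drop = FALSE]
  domain <- domain[keep]

  # corner nodes on the (ncell+1)^3 grid
  nnode_grid <- ncell + 1L
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  gid <- function(ijk) {
    (ijk[, 3] - 1) * nnode_grid[1] * nnode_grid[2] +
      (ijk[, 2] - 1) * nnode_grid[1] + ijk[, 1]
  }
  conn_g <- matrix(0L, nrow(cell_ijk), 8)
  for (c8 in 1:8) {
    conn_g[, c8] <- gid(sweep(cell_ijk, 2, corner_off[c8, ], `+`))
  }
  used <- sort(unique(as.vector(conn_g)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  conn <- matrix(remap[conn_g], nrow(conn_g), 8)
  gk <- (used - 1) %/% (nnode_grid[1] * nnode_grid[2])
  gj <- ((used - 1) %/% nnode_grid[1]) %% nnode_grid[2]
  gi <- (used - 1) %% nnode_grid[1]
  nodes <- cbind(lo[1] + gi * h, lo[2] + gj * h, lo[3] + gk * h)

  dn <- c("tibia", "femur", "fibula", "soft_tissue")
  element_domain <- factor(dn[domain], levels = dn)

  # bones must not touch directly. Stair-casing of the voxel surfaces can
  # make a few femur cells touch tibia cells at a corner or edge across the
  # joint gap: those partial-volume cells are demoted to soft tissue. A
  # substantial shared-node count means the joint gap truly closed -> reject.
  tib_nodes <- unique(as.vector(conn[domain == 1L, , drop = FALSE]))
  fem_nodes <- unique(as.vector(conn[domain == 2L, , drop = FALSE]))
  shared <- intersect(tib_nodes, fem_nodes)
  if (length(shared) > max(10, 0.02 * length(fem_nodes)))
    stop("joint gap is zero: femur and tibia elements share nodes")
  if (length(shared)) {
    touch <- domain == 2L &
      rowSums(matrix(conn %in% shared, nrow(conn), 8)) > 0
    domain[touch] <- 4L
    element_domain <- factor(dn[domain], levels = dn)
    tib_nodes <- unique(as.vector(conn[domain == 1L, , drop = FALSE]))
    fem_nodes <- unique(as.vector(conn[domain == 2L, , drop = FALSE]))
  }

  node_sets <- list()
  if (length(fem_nodes)) {
    zmax <- max(nodes[fem_nodes, 3])
    node_sets$femur_top <- fem_nodes[nodes[fem_nodes, 3] > zmax - h / 2]
  }
  if (length(tib_nodes)) {
    zmin <- min(nodes[tib_nodes, 3])
    node_sets$tibia_distal <- tib_nodes[nodes[tib_nodes, 3] < zmin + h / 2]
  }
  fib_nodes <- unique(as.vector(conn[domain == 3L, , drop = FALSE]))
  if (length(fib_nodes)) {
    zmin <- min(nodes[fib_nodes, 3])
    node_sets$fibula_distal <- fib_nodes[nodes[fib_nodes, 3] < zmin + h / 2]
  }

  # subchondral surface nodes: top faces of tibia cells with no tibia above,
  # restricted to the plateau footprint
  tib_cells <- which(domain == 1L)
  key <- function(ijk) gid(ijk)  # reuse linear cell key on node grid dims
  cell_key <- (cell_ijk[, 3] - 1) * ncell[1] * ncell[2] +
    (cell_ijk[, 2] - 1) * ncell[1] + cell_ijk[, 1]
  tib_keys <- cell_key[tib_cells]
  above_key <- tib_keys + ncell[1] * ncell[2]
  has_above <- above_key %in% cell_key[domain == 1L]
  top_cells <- tib_cells[!has_above]
  # footprint test at cell centres
  fp_idx <- round(world_to_voxel(lab_vol, centres[top_cells, , drop = FALSE]))
  on_fp <- vapply(seq_along(top_cells), function(q) {
    i <- min(max(fp_idx[q, 1], 1), d[1]); j <- min(max(fp_idx[q, 2], 1), d[2])
    landmarks$footprint[i, j]
  }, TRUE)
  near_plateau <- centres[top_cells, 3] >= landmarks$z_plateau - 12
  top_cells <- top_cells[on_fp & near_plateau]
  top_nodes <- unique(as.vector(conn[top_cells, 5:8, drop = FALSE]))
  node_sets$subchondral_surface_medial <-
    top_nodes[nodes[top_nodes, 1] >= landmarks$x0]
  node_sets$subchondral_surface_lateral <-
    top_nodes[nodes[top_nodes, 1] < landmarks$x0]

  cell_key <- (cell_ijk[, 3] - 1) * as.numeric(ncell[1]) * ncell[2] +
    (cell_ijk[, 2] - 1) * ncell[1] + cell_ijk[, 1]
  mesh <- structure(list(nodes = nodes, conn = conn, type = "hex8",
                         element_domain = element_domain,
                         element_size = h,
                         volumes = rep(h^3, nrow(conn)),
                         centroids = centres,
                         node_sets = node_sets,
                         landmarks = landmarks,
                         grid = list(lo = as.numeric(lo), ncell = ncell,
                                     cell_key = cell_key)),
                    class = "fe_mesh")
  if (mode == "tet_quadratic") mesh <- hex_to_tet10(mesh)
  mesh
}

#' @exportS3Method base::print
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d %s elements\n",
              nrow(x$nodes), nrow(x$conn), x$type))
  print(table(x$element_domain))
  invisible(x)
}

# Freudenthal 6-tet split of each hexahedron with quadratic midside nodes.
# Conforming: every cube is split identically relative to the global axes.
hex_to_tet10 <- function(mesh) {
  stopifnot(mesh$type == "hex8")
  # hex corner local coords (VTK order), bitmask xyz
  corner_bits <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                       c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  bit_to_corner <- integer(8)
  for (c8 in 1:8)
    bit_to_corner[1 + corner_bits[c8, 1] + 2 * corner_bits[c8, 2] +
                    4 * corner_bits[c8, 3]] <- c8
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tet_corners <- matrix(0L, 6, 4)
  for (p in seq_len(6)) {
    b <- c(0, 0, 0)
    path <- integer(4)
    path[1] <- bit_to_corner[1]
    for (s in 1:3) {
      b[perms[p, s]] <- 1
      path[s + 1] <- bit_to_corner[1 + b[1] + 2 * b[2] + 4 * b[3]]
    }
    tet_corners[p, ] <- path
  }
  ne <- nrow(mesh$conn)
  tets <- matrix(0L, 6 * ne, 4)
  for (p in 1:6)
    tets[seq.int(p, by = 6, length.out = ne), ] <- mesh$conn[, tet_corners[p, ]]
  dom <- rep(mesh$element_domain, each = 6)

  # orientation: positive volume
  v0 <- mesh$nodes[tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tets[, 2], , drop = FALSE] - v0
  e2 <- mesh$nodes[tets[, 3], , drop = FALSE] - v0
  e3 <- mesh$nodes[tets[, 4], , drop = FALSE] - v0
  det6 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  flip <- det6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  # midside nodes, shared via edge keys
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  nn <- nrow(mesh$nodes)
  a <- matrix(0L, nrow(tets), 6); b <- matrix(0L, nrow(tets), 6)
  for (e in 1:6) {
    a[, e] <- pmin(tets[, edge_pairs[e, 1]], tets[, edge_pairs[e, 2]])
    b[, e] <- pmax(tets[, edge_pairs[e, 1]], tets[, edge_pairs[e, 2]])
  }
  keys <- as.numeric(a) * (nn + 1) + as.numeric(b)
  ukeys <- unique(keys)
  mid_id <- nn + match(keys, ukeys)
  ua <- floor((ukeys - 1e-9) / (nn + 1)); ub <- ukeys - ua * (nn + 1)
  mid_nodes <- (mesh$nodes[ua, , drop = FALSE] +
                  mesh$nodes[ub, , drop = FALSE]) / 2
  conn10 <- cbind(tets, matrix(mid_id, nrow(tets), 6))
  vol6 <- abs(det6) / 6
  ctr <- (mesh$nodes[tets[, 1], ] + mesh$nodes[tets[, 2], ] +
            mesh$nodes[tets[, 3], ] + mesh$nodes[tets[, 4], ]) / 4

  out <- mesh
  out$nodes <- rbind(mesh$nodes, mid_nodes)
  out$conn <- conn10
  out$type <- "tet10"
  out$element_domain <- dom
  out$volumes <- vol6
  out$centroids <- ctr
  # corner-node sets gain the midside nodes of edges internal to the set,
  # so surface constraints also bind the quadratic nodes
  out$node_sets <- lapply(mesh$node_sets, function(set) {
    both <- ua %in% set & ub %in% set
    c(set, nn + which(both))
  })
  out
}
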