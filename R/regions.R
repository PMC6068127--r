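#' The seventeen proximal-tibial region labels
#'
#' Depth-banded regions of the proximal tibia: medial and lateral
#' {peripheral, epiphyseal, metaphyseal, subchondral} cortical and
#' {subchondral, epiphyseal, metaphyseal} trabecular regions, plus the three
#' central (spine) regions.
#'
#' @return Character vector of the 17 region names (a fixed order used by
#'   all tables).
#' @export
region_levels <- function() {
  c("medial peripheral cortical", "medial epiphyseal cortical",
    "medial metaphyseal cortical", "medial subchondral cortical",
    "medial subchondral trabecular", "medial epiphyseal trabecular",
    "medial metaphyseal trabecular",
    "subchondral spine", "epiphyseal central", "metaphyseal central",
    "lateral subchondral cortical", "lateral subchondral trabecular",
    "lateral epiphyseal trabecular", "lateral metaphyseal trabecular",
    "lateral peripheral cortical", "lateral epiphyseal cortical",
    "lateral metaphyseal cortical")
}

#' Depth-from-surface volume for a bone label
#'
#' Exact Euclidean distance from each bone voxel to the nearest non-bone
#' voxel, in mm, on the voxel grid.
#'
#' @param mask A `segmentation_mask`.
#' @param label Bone label (default 1, tibia).
#' @return A `density_volume` whose voxels hold depth in mm (0 outside).
#' @export
depth_volume <- function(mask, label = 1L) {
  m <- mask$labels == label
  if (!any(m)) stop("label not present in mask")
  d2 <- .edt3_sq(m, dim(m), mask$spacing)
  density_volume(array(sqrt(d2), dim = dim(m)), spacing = mask$spacing,
                 origin = mask$origin, orientation = mask$orientation,
                 units = "HU")
}

#' Assign tibial elements to the seventeen anatomical regions
#'
#' Two depth measures drive the assignment: the Euclidean distance from the
#' tibial outer surface (`depth`, 3D EDT) and the vertical depth below the
#' local plateau top surface. Elements whose nearest surface is the outer
#' side cortex (EDT depth clearly smaller than the vertical depth) form the
#' cortical wall: peripheral cortical within 5 mm of the surface in the top
#' 5 mm axial zone, epiphyseal / metaphyseal cortical (surface depth
#' < 2.5 mm) within the 5-15 / 15-35 mm axial extents below the plateau.
#' The remaining plateau/spine column elements are banded by vertical depth:
#' [0, 2.5) mm subchondral cortical, [2.5, 5) subchondral trabecular,
#' [5, 15) epiphyseal, [15, 35] metaphyseal; the central sector (slab of 20%
#' of the mediolateral extent) maps to subchondral spine ([0, 5) mm),
#' epiphyseal central and metaphyseal central. Bands are half-open [lo, hi)
#' with the deepest band closed at 35 mm, so counts are deterministic.
#'
#' @param mesh An `fe_mesh`.
#' @param depth A [depth_volume()] for the tibia on the re-aligned grid.
#' @param landmarks A [tibia_landmarks()] list (plateau footprint and top
#'   surface, plateau z, split coordinate and central half-width).
#' @return A `region_map`: factor `region` per element (17 levels +
#'   `"unassigned"`) and numeric `depth_mm` per element.
#' @export
assign_regions <- function(mesh, depth, landmarks) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (is.null(landmarks$footprint)) stop("missing plateau footprint")
  ne <- nrow(mesh$conn)
  region <- rep("unassigned", ne)
  tib <- which(mesh$element_domain == "tibia")
  ctr <- mesh$centroids[tib, , drop = FALSE]
  d <- sample_volume(depth, ctr, method = "linear", fill = 0)
  fp_idx <- round(world_to_voxel(depth, ctr))
  dm <- dim(depth$data)
  fp_idx[, 1] <- pmin(pmax(fp_idx[, 1], 1), dm[1])
  fp_idx[, 2] <- pmin(pmax(fp_idx[, 2], 1), dm[2])
  on_fp <- landmarks$footprint[cbind(fp_idx[, 1], fp_idx[, 2])]
  top_z <- landmarks$top_z[cbind(fp_idx[, 1], fp_idx[, 2])]
  top_z[is.na(top_z)] <- landmarks$z_plateau
  d_top <- pmax(0, top_z - ctr[, 3])        # vertical depth below top surface
  axial <- landmarks$z_plateau - ctr[, 3]   # axial depth below plateau level
  dx <- ctr[, 1] - landmarks$x0
  sector <- ifelse(abs(dx) <= landmarks$central_halfwidth, "central",
                   ifelse(dx > 0, "medial", "lateral"))

  lab <- rep("unassigned", length(tib))
  band <- function(x, lo, hi, closed = FALSE)
    x >= lo & (if (closed) x <= hi else x < hi)
  # within the wall-cortex shell and clearly nearer the side surface than
  # the plateau top; deep interior elements always belong to the columns
  side_near <- d < 5 & d < d_top - 1
  # plateau / spine columns
  pc <- on_fp & !side_near
  cen <- sector == "central"
  side <- sector  # "medial"/"lateral" for non-central
  put <- function(cond, name) lab[cond] <<- name
  put(pc & !cen & band(d_top, 0, 2.5),
      paste(side[pc & !cen & band(d_top, 0, 2.5)], "subchondral cortical"))
  put(pc & !cen & band(d_top, 2.5, 5),
      paste(side[pc & !cen & band(d_top, 2.5, 5)], "subchondral trabecular"))
  put(pc & !cen & band(d_top, 5, 15),
      paste(side[pc & !cen & band(d_top, 5, 15)], "epiphyseal trabecular"))
  put(pc & !cen & band(d_top, 15, 35, TRUE),
      paste(side[pc & !cen & band(d_top, 15, 35, TRUE)],
            "metaphyseal trabecular"))
  put(pc & cen & band(d_top, 0, 5), "subchondral spine")
  put(pc & cen & band(d_top, 5, 15), "epiphyseal central")
  put(pc & cen & band(d_top, 15, 35, TRUE), "metaphyseal central")
  # outer cortical wall (medial/lateral only)
  wall <- !pc & sector != "central"
  put(wall & d < 5 & band(axial, -2.5, 5),
      paste(side[wall & d < 5 & band(axial, -2.5, 5)],
            "peripheral cortical"))
  put(wall & d < 2.5 & band(axial, 5, 15),
      paste(side[wall & d < 2.5 & band(axial, 5, 15)],
            "epiphyseal cortical"))
  put(wall & d < 2.5 & band(axial, 15, 35, TRUE),
      paste(side[wall & d < 2.5 & band(axial, 15, 35, TRUE)],
            "metaphyseal cortical"))
  region[tib] <- lab
  depth_mm <- rep(NA_real_, ne)
  depth_mm[tib] <- d
  structure(list(region = factor(region,
                                 levels = c(region_levels(), "unassigned")),
                 depth_mm = depth_mm),
            class = "region_map")
}

#' Volume-weighted regional means of the field metrics
#'
#' @param result A `field_result` (usually body-weight scaled).
#' @param map A `region_map` for the same mesh.
#' @return Data frame with one row per region x metric: volume-weighted
#'   `mean`, `n_elements` and `region_volume` (mm^3). Strains are reported
#'   in microstrain. Unassigned elements are excluded.
#' @export
aggregate_regional_metrics <- function(result, map) {
  stopifnot(inherits(result, "field_result"), inherits(map, "region_map"))
  if (length(map$region) != length(result$min_principal_stress))
    stop("region map and field result refer to different meshes")
  metrics <- list(min_principal_stress = result$min_principal_stress,
                  von_mises_stress = result$von_mises_stress,
                  min_principal_strain = result$min_principal_strain * 1e6,
                  von_mises_strain = result$von_mises_strain * 1e6)
  keep <- map$region != "unassigned"
  reg <- droplevels(map$region[keep])
  w <- result$volumes[keep]
  rows <- list()
  for (mn in names(metrics)) {
    v <- metrics[[mn]][keep]
    wm <- vapply(levels(reg), function(r) {
      i <- reg == r
      sum(v[i] * w[i]) / sum(w[i])
    }, 0)
    rows[[mn]] <- data.frame(region = levels(reg), metric = mn, mean = wm,
                             n_elements = as.integer(table(reg)[levels(reg)]),
                             region_volume = vapply(levels(reg), function(r)
                               sum(w[reg == r]), 0),
                             row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Voxel-grid region map for the tibia
#'
#' Applies the same banding rules as [assign_regions()] directly to the
#' tibia voxels of the depth volume, giving a region assignment that is
#' independent of any particular FE mesh. Used as the fixed probe set for
#' mesh-independent regional reporting (and for the mesh-convergence
#' utility, where only the FE field may change between meshes).
#'
#' @param depth A [depth_volume()] for the tibia.
#' @param landmarks A [tibia_landmarks()] list.
#' @return List: `idx` (linear voxel indices of assigned tibia voxels),
#'   `region` (factor over the 17 regions for those voxels), `xyz`
#'   (world coordinates of the voxel centres).
#' @export
voxel_region_map <- function(depth, landmarks) {
  dm <- dim(depth$data)
  inside <- which(depth$data > 0)
  ijk <- arrayInd(inside, dm)
  xyz <- voxel_to_world(depth, ijk)
  d <- depth$data[inside]
  top_z <- landmarks$top_z[cbind(ijk[, 1], ijk[, 2])]
  top_z[is.na(top_z)] <- landmarks$z_plateau
  on_fp <- landmarks$footprint[cbind(ijk[, 1], ijk[, 2])]
  d_top <- pmax(0, top_z - xyz[, 3])
  axial <- landmarks$z_plateau - xyz[, 3]
  dx <- xyz[, 1] - landmarks$x0
  sector <- ifelse(abs(dx) <= landmarks$central_halfwidth, "central",
                   ifelse(dx > 0, "medial", "lateral"))
  lab <- rep("unassigned", length(inside))
  band <- function(x, lo, hi, closed = FALSE)
    x >= lo & (if (closed) x <= hi else x < hi)
  side_near <- d < 5 & d < d_top - 1
  pc <- on_fp & !side_near
  cen <- sector == "central"
  side <- sector
  sel <- pc & !cen & band(d_top, 0, 2.5)
  lab[sel] <- paste(side[sel], "subchondral cortical")
  sel <- pc & !cen & band(d_top, 2.5, 5)
  lab[sel] <- paste(side[sel], "subchondral trabecular")
  sel <- pc & !cen & band(d_top, 5, 15)
  lab[sel] <- paste(side[sel], "epiphyseal trabecular")
  sel <- pc & !cen & band(d_top, 15, 35, TRUE)
  lab[sel] <- paste(side[sel], "metaphyseal trabecular")
  lab[pc & cen & band(d_top, 0, 5)] <- "subchondral spine"
  lab[pc & cen & band(d_top, 5, 15)] <- "epiphyseal central"
  lab[pc & cen & band(d_top, 15, 35, TRUE)] <- "metaphyseal central"
  wall <- !pc & sector != "central"
  sel <- wall & d < 5 & band(axial, -2.5, 5)
  lab[sel] <- paste(side[sel], "peripheral cortical")
  sel <- wall & d < 2.5 & band(axial, 5, 15)
  lab[sel] <- paste(side[sel], "epiphyseal cortical")
  sel <- wall & d < 2.5 & band(axial, 15, 35, TRUE)
  lab[sel] <- paste(side[sel], "metaphyseal cortical")
  keep <- lab != "unassigned"
  list(idx = inside[keep],
       region = factor(lab[keep], levels = region_levels()),
       xyz = xyz[keep, , drop = FALSE])
}

# volume-weighted per-node average of per-element values (hex meshes),
# restricted to the elements in `sel`; returns a dense vector over nodes
nodal_average <- function(mesh, values, sel) {
  idx <- as.vector(mesh$conn[sel, , drop = FALSE])
  w <- rep(mesh$volumes[sel], times = ncol(mesh$conn))
  v <- rep(values[sel] * mesh$volumes[sel], times = ncol(mesh$conn))
  sw <- rowsum(w, idx)
  sv <- rowsum(v, idx)
  out <- rep(NA_real_, nrow(mesh$nodes))
  out[as.integer(rownames(sw))] <- sv / sw
  out
}

# element id containing each point, via the structured cell grid; points in
# unmeshed cells fall back to the nearest meshed neighbour cell (27-ring)
locate_cells <- function(mesh, pts, domain = NULL) {
  g <- mesh$grid
  h <- mesh$element_size
  keys_of <- function(ijk) {
    (ijk[, 3] - 1) * as.numeric(g$ncell[1]) * g$ncell[2] +
      (ijk[, 2] - 1) * g$ncell[1] + ijk[, 1]
  }
  ok_elems <- if (is.null(domain)) seq_len(nrow(mesh$conn)) else
    which(mesh$element_domain %in% domain)
  key_tab <- g$cell_key[ok_elems]
  ijk <- floor(sweep(pts, 2, g$lo, `-`) / h) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), g$ncell[a])
  eid <- ok_elems[match(keys_of(ijk), key_tab)]
  miss <- which(is.na(eid))
  if (length(miss)) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[order(rowSums(abs(offs))), , drop = FALSE][-1, , drop = FALSE]
    for (o in seq_len(nrow(offs))) {
      if (!length(miss)) break
      ij2 <- sweep(ijk[miss, , drop = FALSE], 2, offs[o, ], `+`)
      bad <- ij2[, 1] < 1 | ij2[, 2] < 1 | ij2[, 3] < 1 |
        ij2[, 1] > g$ncell[1] | ij2[, 2] > g$ncell[2] | ij2[, 3] > g$ncell[3]
      cand <- rep(NA_integer_, length(miss))
      cand[!bad] <- ok_elems[match(keys_of(ij2[!bad, , drop = FALSE]),
                                   key_tab)]
      found <- !is.na(cand)
      eid[miss[found]] <- cand[found]
      miss <- miss[!found]
    }
  }
  eid
}

#' Mesh-independent regional metrics from fixed voxel probes
#'
#' Projects the per-element fields to nodes (volume-weighted averaging over
#' tibia elements, the standard FE nodal recovery), interpolates the nodal
#' field trilinearly at the tibia voxel centres of a fixed
#' [voxel_region_map()], and averages per region. Because the probe set and
#' its region assignment live on the image grid, values from meshes of
#' different element size are directly comparable.
#'
#' @param mesh A hex `fe_mesh`.
#' @param result A `field_result` for `mesh`.
#' @param vox_map A [voxel_region_map()].
#' @return Data frame `region` x `metric` with `mean`, `n_probes`.
#'   Strains in microstrain.
#' @export
probe_regional_metrics <- function(mesh, result, vox_map) {
  stopifnot(mesh$type == "hex8")
  tib <- which(mesh$element_domain == "tibia")
  eid <- locate_cells(mesh, vox_map$xyz, domain = "tibia")
  ok <- !is.na(eid)
  metrics <- list(min_principal_stress = result$min_principal_stress,
                  von_mises_stress = result$von_mises_stress,
                  min_principal_strain = result$min_principal_strain * 1e6,
                  von_mises_strain = result$von_mises_strain * 1e6)
  # trilinear weights inside each containing cell
  h <- mesh$element_size
  ctr <- mesh$centroids[eid[ok], , drop = FALSE]
  xi <- 2 * (vox_map$xyz[ok, , drop = FALSE] - ctr) / h
  xi <- pmin(pmax(xi, -1), 1)
  conn_ok <- mesh$conn[eid[ok], , drop = FALSE]
  s <- hex_corner_signs
  W <- matrix(0, nrow(xi), 8)
  for (i in 1:8)
    W[, i] <- (1 + s[i, 1] * xi[, 1]) * (1 + s[i, 2] * xi[, 2]) *
      (1 + s[i, 3] * xi[, 3]) / 8
  reg <- droplevels(vox_map$region[ok])
  rows <- list()
  for (mn in names(metrics)) {
    nod <- nodal_average(mesh, metrics[[mn]], tib)
    vals <- nod[conn_ok]
    dim(vals) <- dim(conn_ok)
    # nodes not touched by tibia elements: fall back to the element value
    navals <- is.na(vals)
    if (any(navals)) {
      ev <- metrics[[mn]][eid[ok]]
      vals[navals] <- ev[row(vals)[navals]]
    }
    pv <- rowSums(W * vals)
    wm <- vapply(levels(reg), function(r) mean(pv[reg == r]), 0)
    rows[[mn]] <- data.frame(region = levels(reg), metric = mn, mean = wm,
                             n_probes = as.integer(table(reg)[levels(reg)]),
                             row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compartmental structural stiffness
#'
#' Stiffness of the medial or lateral proximal-tibial compartment from an
#' extra displacement-driven solve in which the opposite femoral compartment
#' is softened to E = 10 MPa so the load passes through the compartment of
#' interest: stiffness = vertical reaction force / mean vertical displacement
#' of that compartment's subchondral surface nodes. Stiffness is a
#' geometric/material property and is not body-weight scaled.
#'
#' @param mesh An `fe_mesh` with subchondral surface node sets.
#' @param materials A `material_field`.
#' @param load A [load_case()].
#' @param side `"medial"`, `"lateral"` or `"both"`.
#' @param E_soft_opposite Modulus assigned to the opposite femoral
#'   compartment, MPa (default 10).
#' @return Named numeric vector of stiffness in N/mm.
#' @export
compartment_stiffness <- function(mesh, materials, load = load_case(),
                                  side = c("both", "medial", "lateral"),
                                  E_soft_opposite = 10) {
  side <- match.arg(side)
  sides <- if (side == "both") c("medial", "lateral") else side
  fem <- which(mesh$element_domain == "femur")
  if (!length(fem)) stop("mesh has no femur elements")
  x0f <- stats::median(mesh$centroids[fem, 1])
  out <- c()
  for (s in sides) {
    mats <- materials
    opp <- if (s == "medial") mesh$centroids[fem, 1] < x0f
           else mesh$centroids[fem, 1] >= x0f
    mats$E[fem[opp]] <- E_soft_opposite
    res <- assemble_and_solve(mesh, mats, load)
    nset <- mesh$node_sets[[paste0("subchondral_surface_", s)]]
    if (!length(nset)) stop("empty subchondral node set for side ", s)
    uz <- res$u[3L * (nset - 1L) + 3L]
    mean_disp <- abs(mean(uz))
    if (mean_disp == 0) stop("zero subchondral displacement")
    out[s] <- res$reaction_force / mean_disp
  }
  out
}
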