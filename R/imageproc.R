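#' Calibrate a HU volume to equivalent volumetric BMD
#'
#' Fits the linear least-squares relation between the nominal densities of
#' the in-image calibration rods and their mean measured intensities, then
#' maps the whole volume to mg/cm^3 K2HPO4-equivalent density.
#'
#' @param volume A `density_volume` in HU.
#' @param rod_regions List of voxel index vectors (one per rod, non-empty,
#'   disjoint) sampling each rod's interior.
#' @param rod_densities Nominal rod densities, mg/cm^3 (same length).
#' @return List with `volume` (calibrated, units `"mg_cm3"`) and `model`
#'   (slope, intercept, r_squared, per-rod samples).
#' @export
calibrate <- function(volume, rod_regions, rod_densities) {
  stopifnot(is_density_volume(volume))
  if (volume$units != "HU")
    stop("volume is already calibrated (units mg_cm3)")
  if (length(rod_regions) < 2 || length(rod_regions) != length(rod_densities))
    stop("need >= 2 rod regions matching rod_densities")
  if (any(lengths(rod_regions) == 0)) stop("empty rod region")
  all_idx <- unlist(rod_regions)
  if (anyDuplicated(all_idx)) stop("rod regions must be disjoint")
  mean_hu <- vapply(rod_regions, function(i) mean(volume$data[i]), 0)
  if (diff(range(mean_hu)) < 1e-9)
    stop("rods have identical mean HU: singular calibration fit")
  fit <- stats::lm(rod_densities ~ mean_hu)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rod_densities - mean(rod_densities))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  out <- volume
  out$data <- slope * volume$data + intercept
  out$units <- "mg_cm3"
  model <- list(slope = slope, intercept = intercept,
                r_squared = max(0, min(1, r2)),
                rod_samples = data.frame(mean_hu = mean_hu,
                                         nominal_density = rod_densities))
  list(volume = out, model = model)
}

#' Invert a calibration
#'
#' @param volume Calibrated `density_volume`.
#' @param model Calibration model from [calibrate()].
#' @return The HU-valued `density_volume`.
#' @export
uncalibrate <- function(volume, model) {
  stopifnot(is_density_volume(volume), volume$units == "mg_cm3")
  out <- volume
  out$data <- (volume$data - model$intercept) / model$slope
  out$units <- "HU"
  out
}

#' Rod voxel regions from known rod geometry
#'
#' Maps rod axes (centre x/y, radius, z range) into voxel index sets, with a
#' radial safety margin so partial-volume voxels at the rod boundary are
#' excluded. An optional rigid transform (as recorded by
#' [generate_repeat_scans()]) repositions the rods first.
#'
#' @param volume Target `density_volume`.
#' @param rod_centres n x 2 matrix of rod centre (x, y), mm.
#' @param rod_radius Rod radius, mm.
#' @param rod_zrange Length-2 z extent, mm.
#' @param transform Optional list(rotation, translation, centre).
#' @param margin Fraction of the radius retained (default 0.6).
#' @return List of voxel index vectors, one per rod.
#' @export
rod_regions_from_geometry <- function(volume, rod_centres, rod_radius,
                                      rod_zrange, transform = NULL,
                                      margin = 0.6) {
  d <- dim(volume$data)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- voxel_to_world(volume, ijk)
  if (!is.null(transform)) {
    # pull each voxel back into the source frame where rod geometry is known
    xyz <- sweep(sweep(xyz, 2, transform$centre + transform$translation, `-`) %*%
                   transform$rotation, 2, transform$centre, `+`)
  }
  lapply(seq_len(nrow(rod_centres)), function(r) {
    which((xyz[, 1] - rod_centres[r, 1])^2 + (xyz[, 2] - rod_centres[r, 2])^2 <=
            (margin * rod_radius)^2 &
            xyz[, 3] >= rod_zrange[1] + 2 & xyz[, 3] <= rod_zrange[2] - 2)
  })
}

#' Half-maximum-height segmentation threshold
#'
#' The HMH rule places the bone threshold at the intensity of a voxel
#' containing 50% cortical bone and 50% background (joint space): the
#' midpoint between the cortical peak level and the adjacent background
#' level, both estimated as medians of the probe regions.
#'
#' @param volume A `density_volume`.
#' @param bone_peak_region Voxel indices probing dense cortical bone.
#' @param background_region Voxel indices probing the adjacent background.
#' @return Threshold in the volume's units.
#' @export
hmh_threshold <- function(volume, bone_peak_region, background_region) {
  stopifnot(is_density_volume(volume))
  if (length(bone_peak_region) == 0 || length(background_region) == 0)
    stop("probe regions must be non-empty")
  peak <- stats::median(volume$data[bone_peak_region])
  bg <- stats::median(volume$data[background_region])
  if (peak <= bg) stop("cortical peak level not above background level")
  bg + 0.5 * (peak - bg)
}

#' Automatic HMH probe placement
#'
#' Heuristic stand-in for the operator-driven probe placement: the cortical
#' probe is the top-0.2% intensity voxels (the dense shell); the background
#' probe is soft-tissue-range voxels (above air, below 30% of the cortical
#' level). Manual probes can always be passed to [hmh_threshold()] directly.
#'
#' @param volume A `density_volume`.
#' @return List with `bone_peak_region` and `background_region` index vectors.
#' @export
auto_probe_regions <- function(volume) {
  v <- volume$data
  cort_cut <- stats::quantile(v, 0.998, names = FALSE)
  air_cut <- if (volume$units == "HU") -300 else -200
  bone_peak <- which(v >= cort_cut)
  cort_level <- stats::median(v[bone_peak])
  background <- which(v > air_cut & v < 0.3 * cort_level)
  if (length(background) == 0) background <- which(v < 0.3 * cort_level)
  list(bone_peak_region = bone_peak, background_region = background)
}

#' Segment bones by threshold and seeded connected components
#'
#' Voxels at or above the threshold are split into 26-connected components;
#' components are assigned to tibia/femur/fibula by seed-point membership,
#' and interior cavities (trabecular voxels below threshold enclosed by the
#' cortical shell) are filled back into each bone.
#'
#' @param volume A `density_volume` (calibrated or HU; threshold in the same
#'   units).
#' @param threshold Segmentation threshold.
#' @param seeds Named list of world-coordinate seed points, e.g.
#'   `list(tibia = c(x,y,z), femur = ..., fibula = ...)`. Label codes follow
#'   the list order (tibia 1, femur 2, fibula 3 by convention).
#' @return A `segmentation_mask`: `labels` volume (integer codes, 0
#'   background), `threshold_used`, `provenance`.
#' @export
segment_bones <- function(volume, threshold,
                          seeds = list(tibia = NULL, femur = NULL,
                                       fibula = NULL)) {
  stopifnot(is_density_volume(volume))
  v <- volume$data
  if (threshold > max(v) || threshold < min(v))
    stop("threshold outside the volume intensity range")
  d <- dim(v)
  binary <- v >= threshold
  if (!any(binary)) stop("empty segmentation: no voxels above threshold")
  comp <- .cc_label3(binary, d, 26L)
  labels <- array(0L, dim = d)
  comp_of <- integer(length(seeds))
  for (b in seq_along(seeds)) {
    if (is.null(seeds[[b]])) next
    vox <- round(world_to_voxel(volume, matrix(seeds[[b]], ncol = 3)))
    vox <- pmin(pmax(vox, 1), matrix(d, ncol = 3))
    cid <- comp[vox[1], vox[2], vox[3]]
    if (cid == 0) {
      # the seed often sits in sub-threshold trabecular interior enclosed by
      # the cortical shell; expand the search box until a component is found
      for (rad_mm in c(3, 6, 12, 24)) {
        rad <- ceiling(rad_mm / min(volume$spacing))
        rng <- lapply(1:3, function(a)
          max(1, vox[a] - rad):min(d[a], vox[a] + rad))
        sub <- comp[rng[[1]], rng[[2]], rng[[3]]]
        if (any(sub > 0)) {
          tab <- table(sub[sub > 0])
          cid <- as.integer(names(tab)[which.max(tab)])
          break
        }
      }
    }
    if (cid == 0) stop("seed for '", names(seeds)[b], "' falls in background")
    if (cid %in% comp_of[seq_len(b - 1)])
      warning("components merged across the joint space: '", names(seeds)[b],
              "' shares a component with another bone")
    comp_of[b] <- cid
    bone_mask <- comp == cid
    # fill enclosed cavities: complement voxels not reachable from the border
    open <- !bone_mask
    reach <- .flood_border3(open, d)
    bone_mask <- bone_mask | (open & !reach & comp == 0)
    labels[bone_mask & labels == 0L] <- b
  }
  structure(list(labels = labels, threshold_used = threshold,
                 spacing = volume$spacing, origin = volume$origin,
                 orientation = volume$orientation,
                 bone_names = names(seeds),
                 provenance = "threshold + seeded 26-connected components"),
            class = "segmentation_mask")
}

mask_as_volume <- function(mask, which_label = NULL) {
  d <- if (is.null(which_label)) mask$labels else (mask$labels == which_label)
  density_volume(array(as.numeric(d), dim = dim(mask$labels)),
                 spacing = mask$spacing, origin = mask$origin,
                 orientation = mask$orientation, units = "HU")
}

# best-fit 3D line through points: centroid + first principal direction
fit_line_direction <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  dir <- sv$v[, 1]
  if (dir[3] < 0) dir <- -dir   # orient superiorly
  list(centre = ctr, direction = dir)
}

# centroid (world) of a bone label on one axial slice
slice_centroid <- function(mask, label, k) {
  sl <- mask$labels[, , k] == label
  if (!any(sl)) return(NULL)
  ij <- which(sl, arr.ind = TRUE)
  voxel_to_world(mask, cbind(colMeans(ij)[1], colMeans(ij)[2], k))
}

#' Best-fit longitudinal axes of tibia and femur
#'
#' The tibial axis is the best-fit line through cross-section centroids at
#' the distal end of the imaged tibia, 50%, 66% and the proximal end of its
#' extent; the femoral axis is the best-fit line through 32 cross-section
#' centroids spanning 20 mm starting just proximal to the condylar region.
#' Both unit vectors point superiorly.
#'
#' @param mask A `segmentation_mask` with tibia (label 1) and femur (label 2).
#' @return List with unit `axis_tibia` and `axis_femur`.
#' @export
fit_bone_axes <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  d <- dim(mask$labels)
  kz <- seq_len(d[3])
  has_t <- vapply(kz, function(k) any(mask$labels[, , k] == 1L), TRUE)
  has_f <- vapply(kz, function(k) any(mask$labels[, , k] == 2L), TRUE)
  if (sum(has_t) < 2 || sum(has_f) < 2)
    stop("fewer than 2 usable cross-sections for a bone")
  tz <- range(kz[has_t])
  # most distal imaged level, midshaft, 66%, and a proximal level. The very
  # ends are avoided: slices through the oblique distal cut face or through
  # the tilted plateau surface have laterally biased centroids.
  k_dist <- tz[1] + max(1L, as.integer(ceiling(4 / mask$spacing[3])))
  levels_rel <- c(0, 0.5, 0.66, 0.85)
  ks <- unique(pmax(tz[1], pmin(tz[2],
                                round(k_dist + levels_rel *
                                        (tz[2] - k_dist)))))
  tib_pts <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(ks, slice_centroid,
                                          mask = mask, label = 1L)))
  if (is.null(tib_pts) || nrow(tib_pts) < 2)
    stop("fewer than 2 usable tibial cross-sections")
  fz <- range(kz[has_f])
  # 32 shaft cross-sections starting just proximal to the condylar region
  # (65% up the imaged femoral extent clears the condylar lobes of a short
  # distal-femur segment) and ending below the oblique top cut
  k0 <- round(fz[1] + 0.65 * diff(fz))
  ktop <- fz[2] - max(1L, as.integer(ceiling(4 / mask$spacing[3])))
  span_vox <- max(2, round(20 / mask$spacing[3]))
  kf <- unique(round(seq(k0, min(ktop, k0 + span_vox), length.out = 32)))
  fem_pts <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(kf, slice_centroid,
                                          mask = mask, label = 2L)))
  if (is.null(fem_pts) || nrow(fem_pts) < 2)
    stop("fewer than 2 usable femoral cross-sections")
  list(axis_tibia = fit_line_direction(tib_pts)$direction,
       axis_femur = fit_line_direction(fem_pts)$direction)
}

#' Apply the averaged-axis re-alignment rule to axis vectors
#'
#' Rotates so that the normalised average of the femoral and tibial axis
#' vectors is vertical; both axes then make equal angles with the vertical,
#' each equal to half the supplement of the inter-axis angle (e.g. a 175
#' degree femorotibial angle leaves each axis 2.5 degrees from vertical). An
#' optional mediolateral direction fixes the in-plane twist by aligning its
#' rotated projection with +x.
#'
#' @param axis_femur,axis_tibia Unit axis vectors, superior-pointing.
#' @param ml_direction Mediolateral (toward-medial) direction used to fix the
#'   axial twist; default +x.
#' @return An `alignment_result`: `rotation` (3x3, proper), rotated unit
#'   axes, `angle_femur_vertical`, `angle_tibia_vertical`, and the
#'   `inter_axis_angle`/`varus_angle` in degrees.
#' @export
realign_axes <- function(axis_femur, axis_tibia, ml_direction = c(1, 0, 0)) {
  f <- axis_femur / sqrt(sum(axis_femur^2))
  t2 <- axis_tibia / sqrt(sum(axis_tibia^2))
  if (f[3] <= 0 || t2[3] <= 0) stop("axes must point superiorly")
  avg <- f + t2
  na <- sqrt(sum(avg^2))
  if (na < 1e-9) stop("antiparallel axes: average direction undefined")
  avg <- avg / na
  R1 <- rotation_between(avg, c(0, 0, 1))
  m <- R1 %*% ml_direction
  twist <- atan2(m[2], m[1])
  R <- rotation_about_axis(c(0, 0, 1), -twist) %*% R1
  fr <- as.numeric(R %*% f); tr <- as.numeric(R %*% t2)
  inter <- angle_between_deg(fr, tr)
  structure(list(rotation = R, axis_femur = fr, axis_tibia = tr,
                 angle_femur_vertical = angle_between_deg(fr, c(0, 0, 1)),
                 angle_tibia_vertical = angle_between_deg(tr, c(0, 0, 1)),
                 inter_axis_angle = inter, varus_angle = 180 - inter),
            class = "alignment_result")
}

#' Re-align a volume and mask to neutral standing orientation
#'
#' Rotates the image so the average of the femoral and tibial best-fit axes
#' is vertical (see [realign_axes()]), resampling the density volume linearly
#' and the label mask by nearest neighbour about the tibial plateau region's
#' centre.
#'
#' @param volume A `density_volume`.
#' @param mask A `segmentation_mask` on the same grid.
#' @param axes List with `axis_femur`, `axis_tibia` (e.g. [fit_bone_axes()]).
#' @param ml_direction Mediolateral direction for the twist fix.
#' @return List with `volume`, `mask`, and `alignment` (an
#'   `alignment_result`).
#' @export
realign <- function(volume, mask, axes, ml_direction = c(1, 0, 0)) {
  al <- realign_axes(axes$axis_femur, axes$axis_tibia, ml_direction)
  # resample_rigid rotates content by R about the grid centre
  vol2 <- resample_rigid(volume, al$rotation, c(0, 0, 0), method = "linear")
  lab <- mask_as_volume(mask)
  lab2 <- resample_rigid(lab, al$rotation, c(0, 0, 0), method = "nearest",
                         fill = 0)
  mask2 <- mask
  mask2$labels <- array(as.integer(lab2$data), dim = dim(lab2$data))
  mask2$provenance <- paste0(mask$provenance, " + realigned")
  list(volume = vol2, mask = mask2, alignment = al)
}
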