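#' Synthetic knee phantom specification
#'
#' Parameters of the parametric knee phantom: a proximal tibia, distal femur
#' and fibula built from stacked superellipse cross-sections with a dense
#' cortical shell and a smoothly varying trabecular interior, embedded in a
#' soft-tissue limb with a three-rod calibration insert below the limb. The
#' phantom emulates the acquisition conditions of an in-vivo knee QCT
#' precision study: 0.625 mm isotropic voxels, OA knees with higher body mass
#' (101 +/- 16 kg vs 72 +/- 13 kg), slight varus alignment and elevated
#' medial density.
#'
#' @param group `"OA"` or `"normal"`; sets defaults for mass, varus and
#'   medial density scaling.
#' @param body_mass Body mass in kg (> 0). Default: the group mean (101 kg OA,
#'   72 kg normal).
#' @param varus_angle Femorotibial inter-axis angle in degrees, 180 = neutral,
#'   < 180 = varus. Must lie in [150, 210]. Default 175 (OA) / 179 (normal).
#' @param density_scale Multiplier applied to medial-side bone density
#'   (default 1.15 for OA, 1 for normal).
#' @param voxel_size Isotropic voxel size, mm (default 0.625).
#' @param cortical_shell_mm Cortical shell thickness, mm (default 3). Must
#'   span at least 2 voxels.
#' @param side `"right"` or `"left"`; left knees are mirrored in x.
#' @param seed Integer seed; identical spec + seed is bit-reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(group = c("normal", "OA"), body_mass = NULL,
                         varus_angle = NULL, density_scale = NULL,
                         voxel_size = 0.625, cortical_shell_mm = 3,
                         side = c("right", "left"), seed = 1L) {
  group <- match.arg(group)
  side <- match.arg(side)
  if (is.null(body_mass)) body_mass <- if (group == "OA") 101 else 72
  if (is.null(varus_angle)) varus_angle <- if (group == "OA") 175 else 179
  if (is.null(density_scale)) density_scale <- if (group == "OA") 1.15 else 1
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  if (!is.finite(body_mass) || body_mass <= 0) stop("body_mass must be > 0")
  if (varus_angle < 150 || varus_angle > 210)
    stop("varus_angle must lie in [150, 210] degrees")
  if (cortical_shell_mm < 2 * voxel_size)
    stop("voxel_size too coarse to resolve the cortical shell ",
         "(< 2 voxels across)")
  structure(list(group = group, body_mass = body_mass,
                 varus_angle = varus_angle, density_scale = density_scale,
                 voxel_size = voxel_size, cortical_shell_mm = cortical_shell_mm,
                 side = side, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Repeat-scan noise specification
#'
#' Models scan-rescan variability as an independent 6-DOF rigid repositioning
#' (Gaussian translations and rotations) plus additive Gaussian voxel noise,
#' emulating a precision protocol where each knee is scanned three times.
#'
#' @param translation_sd SD of each translation component, mm (>= 0).
#' @param rotation_sd SD of each rotation component, degrees (>= 0).
#' @param intensity_sd SD of additive voxel noise, HU (>= 0).
#' @param n_repeats Number of repeat scans (>= 1). Default 3.
#' @param seed Integer master seed; per-repeat streams are derived by counter
#'   (`seed + repeat index`).
#' @return A `repeat_noise_spec` list.
#' @export
repeat_noise_spec <- function(translation_sd = 1, rotation_sd = 1,
                              intensity_sd = 5, n_repeats = 3, seed = 1L) {
  stopifnot(translation_sd >= 0, rotation_sd >= 0, intensity_sd >= 0,
            n_repeats >= 1)
  structure(list(translation_sd = translation_sd, rotation_sd = rotation_sd,
                 intensity_sd = intensity_sd, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "repeat_noise_spec")
}

# Generative HU <-> density line used by the phantom (density = a*HU + b).
phantom_calibration <- function() list(slope = 0.8, intercept = -4)

density_to_hu <- function(rho, cal = phantom_calibration()) {
  (rho - cal$intercept) / cal$slope
}

# Smooth random field on the voxel grid: white noise on a coarse lattice,
# trilinearly upsampled. Deterministic given the current RNG state.
smooth_noise_field <- function(dim, spacing, coarse_mm = 10, sd = 1) {
  cd <- pmax(2L, as.integer(ceiling(dim * spacing / coarse_mm)) + 1L)
  coarse <- array(stats::rnorm(prod(cd), sd = sd), dim = cd)
  # map fine voxel (0-based) to coarse 0-based coordinates
  sc <- (dim - 1) / (cd - 1)
  g <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1, j = seq_len(dim[2]) - 1,
                             k = seq_len(dim[3]) - 1))
  pts <- sweep(g, 2, sc, `/`)
  array(.trilinear3(as.numeric(coarse), cd, pts, 0), dim = dim)
}

# Superellipse membership |x/a|^e + |y/b|^e <= 1 (vectorised).
inside_superellipse <- function(x, y, a, b, e = 2.5) {
  (abs(x) / a)^e + (abs(y) / b)^e <= 1
}

# Smoothly tapering half-width between plateau and shaft values.
taper <- function(s, wide, narrow, mid = 22, scale = 7) {
  narrow + (wide - narrow) / (1 + exp((s - mid) / scale))
}

#' Generate a synthetic calibrated-knee CT volume
#'
#' Builds an uncalibrated (HU) knee volume containing distal femur, proximal
#' tibia and fibula (cortical shell + trabecular interior), a soft-tissue
#' limb, and three calibration rods of known density below the limb, together
#' with voxel-exact ground truth. Bone axes realise `spec$varus_angle`: with
#' both axis unit vectors pointing superiorly their mutual angle is
#' `180 - varus_angle` degrees, symmetric about the vertical.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a `density_volume`, HU) and `truth`
#'   (ground truth: `labels` volume coded 1 tibia / 2 femur / 3 fibula /
#'   11-13 rods, unit `axis_femur` and `axis_tibia`, rod geometry and nominal
#'   densities, the generative calibration line, plateau level and spine
#'   half-width).
#' @export
generate_knee_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$voxel_size
  half <- (180 - spec$varus_angle) / 2 * pi / 180
  sh <- sin(half); ch <- cos(half)

  xv <- seq(-58, 58, by = h)
  yv <- seq(-72, 42, by = h)
  zv <- seq(-74, 60, by = h)
  dm <- c(length(xv), length(yv), length(zv))
  X <- array(rep(xv, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(yv, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(zv, each = dm[1] * dm[2]), dim = dm)

  # --- tibia: local frame tilted by -half about y (axis (-sh, 0, ch)) ---
  qx <- ch * X + sh * Z; qz <- -sh * X + ch * Z
  s <- -qz                                   # depth below the plateau plane
  ridge <- 4 * exp(-(qx / 6)^2)              # intercondylar spine ridge
  a_t <- taper(pmax(s, 0), 34, 16)
  b_t <- taper(pmax(s, 0), 26, 14)
  tibia <- (qz <= ridge) & (s <= 70) &
    inside_superellipse(qx, Y, a_t, b_t)

  # --- femur: local frame tilted by +half about y (axis (sh, 0, ch)) ---
  qx <- ch * X - sh * Z; qz <- sh * X + ch * Z
  cond <- function(cx) {
    (abs(qx - cx) / 19)^2.2 + (abs(Y + 2) / 22)^2.2 +
      (abs(qz - 22) / 17)^2.2 <= 1
  }
  zc <- pmax(qz - 28, 0)
  shaft <- (qz >= 28) & (qz <= 58) &
    inside_superellipse(qx, Y + 2, 26 - 0.08 * zc, 21 - 0.08 * zc)
  femur <- (cond(17) | cond(-17) | shaft) & (qz <= 58) & (qz >= 3)

  # --- fibula: parallel to the tibial axis ---
  qx <- ch * X + sh * Z; qz <- -sh * X + ch * Z
  fibula <- ((qx + 42)^2 + (Y + 8)^2 <= 7^2) & (qz <= -12) & (qz >= -70)
  fibula <- fibula & !tibia
  femur <- femur & !tibia & !fibula

  # --- soft-tissue limb and calibration insert ---
  limb <- inside_superellipse(X, Y + 4, 52, 40, e = 2)
  slab <- (abs(X) <= 42) & (Y >= -70) & (Y <= -52) & (Z >= -66) & (Z <= 30)
  rod_densities <- c(0, 200, 400)
  rod_centres <- cbind(x = c(-25, 0, 25), y = c(-61, -61, -61))
  rod_radius <- 6
  rod_zrange <- c(-60, 24)
  rods <- vector("list", 3)
  for (r in 1:3) {
    rods[[r]] <- ((X - rod_centres[r, 1])^2 + (Y - rod_centres[r, 2])^2 <=
                    rod_radius^2) & (Z >= rod_zrange[1]) & (Z <= rod_zrange[2])
  }

  # --- densities (mg/cm^3), then HU ---
  labels <- array(0L, dim = dm)
  labels[tibia] <- 1L; labels[femur] <- 2L; labels[fibula] <- 3L
  bone <- labels > 0L
  depth <- sqrt(.edt3_sq(bone, dm, rep(h, 3)))   # depth into bone from surface
  trab <- bone & (depth > spec$cortical_shell_mm)

  rho <- array(NA_real_, dim = dm)
  noise_rel <- smooth_noise_field(dm, rep(h, 3), coarse_mm = 9, sd = 0.08)
  cortical_rho <- 950
  # trabecular density decays with depth below the joint surfaces
  sj <- pmax(0, -( -sh * X + ch * Z) )  # tibial depth-below-plateau proxy
  trab_rho <- 140 + 160 * exp(-sj / 15)
  trab_rho[Z > 0] <- 140 + 160 * exp(-pmax(0, (sh * X + ch * Z)[Z > 0] - 3) / 15)
  rho[bone] <- cortical_rho
  rho[trab] <- trab_rho[trab]
  rho[bone] <- rho[bone] * (1 + noise_rel[bone])
  medial <- X > 0
  rho[bone & medial] <- rho[bone & medial] * spec$density_scale

  hu <- array(-1000, dim = dm)
  hu[limb] <- 35
  hu[slab] <- 0
  for (r in 1:3) hu[rods[[r]]] <- density_to_hu(rod_densities[r])
  hu[bone] <- density_to_hu(rho[bone])

  hu <- array(.gauss_blur3(hu, dm, rep(0.7, 3)), dim = dm)
  hu <- hu + array(stats::rnorm(prod(dm), sd = 4), dim = dm)

  for (r in 1:3) labels[rods[[r]] & !bone] <- 10L + r

  axis_tibia <- c(-sh, 0, ch)
  axis_femur <- c(sh, 0, ch)

  if (spec$side == "left") {  # mirror so that +x is always medial at load time
    hu <- hu[rev(seq_len(dm[1])), , , drop = FALSE]
    labels <- labels[rev(seq_len(dm[1])), , , drop = FALSE]
    axis_tibia[1] <- -axis_tibia[1]
    axis_femur[1] <- -axis_femur[1]
    rod_centres[, 1] <- -rod_centres[, 1]
  }

  origin <- c(xv[1], yv[1], zv[1])
  vol <- density_volume(hu, spacing = rep(h, 3), origin = origin, units = "HU")
  lab_vol <- density_volume(array(as.numeric(labels), dim = dm),
                            spacing = rep(h, 3), origin = origin,
                            units = "HU")
  truth <- list(labels = lab_vol,
                axis_femur = axis_femur, axis_tibia = axis_tibia,
                varus_angle = spec$varus_angle,
                rod_densities = rod_densities, rod_centres = rod_centres,
                rod_radius = rod_radius, rod_zrange = rod_zrange,
                calibration = phantom_calibration(),
                plateau_z = 0, spine_halfwidth = 6,
                body_mass = spec$body_mass, group = spec$group,
                side = spec$side, seed = spec$seed)
  list(volume = vol, truth = truth)
}

#' Simulate repeat scans of a volume
#'
#' Applies an independent random rigid transform (6 DOF, Gaussian) and
#' additive Gaussian intensity noise to the source volume for each repeat,
#' recording the transform parameters. With all noise SDs zero the repeats
#' are bit-identical copies of the source.
#'
#' @param volume Source `density_volume`.
#' @param noise A [repeat_noise_spec()].
#' @return List of `density_volume`s; each carries an attribute `transform`
#'   with elements `rotation`, `translation`, `centre`.
#' @export
generate_repeat_scans <- function(volume, noise) {
  stopifnot(is_density_volume(volume), inherits(noise, "repeat_noise_spec"))
  out <- vector("list", noise$n_repeats)
  for (r in seq_len(noise$n_repeats)) {
    set.seed(noise$seed + r)            # per-repeat counter-derived stream
    tr <- stats::rnorm(3, sd = noise$translation_sd)
    ang <- stats::rnorm(3, sd = noise$rotation_sd) * pi / 180
    R <- rotation_about_axis(c(0, 0, 1), ang[3]) %*%
      rotation_about_axis(c(0, 1, 0), ang[2]) %*%
      rotation_about_axis(c(1, 0, 0), ang[1])
    d <- dim(volume$data)
    centre <- as.numeric(voxel_to_world(volume, matrix((d + 1) / 2, ncol = 3)))
    identity_tf <- noise$translation_sd == 0 && noise$rotation_sd == 0
    v <- if (identity_tf) volume else
      resample_rigid(volume, R, tr, centre = centre, method = "linear")
    if (noise$intensity_sd > 0)
      v$data <- v$data + array(stats::rnorm(prod(d), sd = noise$intensity_sd),
                               dim = d)
    if (identity_tf) { R <- diag(3); tr <- c(0, 0, 0) }
    attr(v, "transform") <- list(rotation = R, translation = tr,
                                 centre = centre)
    out[[r]] <- v
  }
  out
}

#' Draw a synthetic study cohort
#'
#' Draws per-subject phantom specifications with group-specific body-mass
#' distributions (OA 101 +/- 16 kg, normal 72 +/- 13 kg), alignment (OA mean
#' 175.5 deg varus, normal 179 deg) and medial density scaling.
#'
#' @param n_oa,n_normal Group sizes.
#' @param seed Master seed; subject seeds are derived by counter.
#' @param voxel_size,cortical_shell_mm Passed to [phantom_spec()].
#' @return List of `phantom_spec` (OA subjects first).
#' @export
draw_cohort <- function(n_oa = 7, n_normal = 7, seed = 1L,
                        voxel_size = 0.625, cortical_shell_mm = 3) {
  set.seed(seed)
  specs <- vector("list", n_oa + n_normal)
  for (i in seq_len(n_oa + n_normal)) {
    oa <- i <= n_oa
    mass <- stats::rnorm(1, if (oa) 101 else 72, if (oa) 16 else 13)
    mass <- max(mass, 40)
    varus <- stats::rnorm(1, if (oa) 175.5 else 179, if (oa) 1.5 else 1)
    varus <- min(max(varus, 172), 182)
    specs[[i]] <- phantom_spec(group = if (oa) "OA" else "normal",
                               body_mass = mass, varus_angle = varus,
                               density_scale = if (oa) 1.15 else 1,
                               voxel_size = voxel_size,
                               cortical_shell_mm = cortical_shell_mm,
                               seed = seed * 1000L + i)
  }
  specs
}
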