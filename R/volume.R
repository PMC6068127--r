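#' Create a density volume
#'
#' A `density_volume` is the package's container for a 3D scalar image: a
#' column-major array with voxel spacing (mm), world origin (mm), an
#' orthonormal direction matrix, and a units flag recording whether voxels are
#' raw Hounsfield units (`"HU"`) or calibrated equivalent volumetric bone
#' mineral density in mg/cm^3 K2HPO4 (`"mg_cm3"`). The units flag prevents
#' silent double calibration.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3 voxel spacing in mm (all > 0).
#' @param origin Numeric length-3 world coordinate of voxel (1,1,1), mm.
#' @param orientation 3x3 orthonormal direction matrix (voxel axes -> world).
#' @param units `"HU"` or `"mg_cm3"`.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(data, spacing, origin = c(0, 0, 0),
                           orientation = diag(3), units = c("HU", "mg_cm3")) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      abs(abs(det(orientation)) - 1) > 1e-6 ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be orthonormal (|det| = 1)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 orientation = orientation, units = units),
            class = "density_volume")
}

#' @exportS3Method base::print
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "), x$units))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_density_volume <- function(x) inherits(x, "density_volume")

#' World coordinates of voxel centres
#'
#' @param vol A `density_volume`.
#' @param ijk n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @keywords internal
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep((ijk - 1) %*% (t(vol$orientation) * vol$spacing), 2, vol$origin, `+`)
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @keywords internal
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  rel <- sweep(xyz, 2, vol$origin, `-`) %*% vol$orientation
  sweep(rel, 2, vol$spacing, `/`) + 1
}

#' Sample a volume at world coordinates
#'
#' Trilinear (for densities) or nearest-neighbour (for labels) interpolation.
#'
#' @param vol A `density_volume` or a plain 3D array sharing `ref`'s grid.
#' @param xyz n x 3 world coordinates, mm.
#' @param method `"linear"` or `"nearest"`.
#' @param fill Value returned outside the grid.
#' @return Numeric vector of sampled values.
#' @export
sample_volume <- function(vol, xyz, method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  pts <- world_to_voxel(vol, xyz) - 1 # 0-based for the C++ samplers
  if (method == "linear")
    .trilinear3(as.numeric(vol$data), dim(vol$data), pts, fill)
  else
    .nearest3(as.numeric(vol$data), dim(vol$data), pts, fill)
}

#' Resample a volume under a rigid transform
#'
#' The output grid equals the input grid; a point `p` of the input content
#' moves to `R (p - c) + c + t`, so each output voxel centre `x` is filled
#' from the input at `R^T (x - t - c) + c`.
#'
#' @param vol A `density_volume`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation, mm.
#' @param centre Centre of rotation (world mm); default grid centre.
#' @param method `"linear"` or `"nearest"`.
#' @param fill Background fill value.
#' @return A `density_volume` on the same grid.
#' @export
resample_rigid <- function(vol, rotation = diag(3), translation = c(0, 0, 0),
                           centre = NULL, method = c("linear", "nearest"),
                           fill = NULL) {
  method <- match.arg(method)
  d <- dim(vol$data)
  if (is.null(centre)) {
    centre <- as.numeric(voxel_to_world(vol, matrix((d + 1) / 2, ncol = 3)))
  }
  if (is.null(fill)) fill <- min(vol$data)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- voxel_to_world(vol, ijk)
  src <- sweep(sweep(xyz, 2, centre + as.numeric(translation), `-`) %*% rotation,
               2, centre, `+`)
  v <- sample_volume(vol, src, method = method, fill = fill)
  out <- vol
  out$data <- array(v, dim = d)
  out
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}. Units are carried in the NIfTI
#' description field so a written volume round-trips its calibration state.
#'
#' @param vol A `density_volume`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `density_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img$descrip <- vol$units
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  units <- tryCatch(RNifti::niftiHeader(img)$descrip, error = function(e) "")
  if (!identical(units, "mg_cm3")) units <- "HU"
  density_volume(array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img)[seq_len(3)],
                 units = units)
}

# Rotation by angle (rad) about a unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation taking unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t2 <- to / sqrt(sum(to^2))
  c_ <- sum(f * t2)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) stop("antiparallel vectors: rotation undefined")
  v <- c(f[2] * t2[3] - f[3] * t2[2],
         f[3] * t2[1] - f[1] * t2[3],
         f[1] * t2[2] - f[2] * t2[1])
  s <- sqrt(sum(v^2))
  rotation_about_axis(v / s, atan2(s, c_))
}

angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}
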