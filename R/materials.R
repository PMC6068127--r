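#' Default finite-element configuration
#'
#' Central place for the material-mapping and solver constants: power-law
#' density-modulus coefficient and exponent, modulus floor, soft-tissue and
#' rigid-femur constants, Poisson ratios, the prescribed displacement and the
#' gravitational constant used to convert body mass to body weight.
#'
#' The power-law coefficient `coeff_a` (MPa at 1 g/cm^3) multiplies
#' `(rho/1000)^exponent` with `rho` in mg/cm^3; its default keeps peak
#' cortical moduli in the tens-of-GPa range with a 2.1 exponent. It is a
#' required, documented configuration value: substitute the coefficient of
#' whichever published calibration applies to your density measure.
#'
#' @param ... Named overrides of any default.
#' @return A named list of configuration values.
#' @export
fe_config <- function(...) {
  cfg <- list(element_size_bone_mm = 2, element_size_soft_mm = 20,
              coeff_a = 12000, exponent = 2.1, E_floor = 1,
              E_soft = 10, nu_soft = 0.495, nu_bone = 0.3,
              E_rigid = 500000, displacement_mm = 1, g = 9.81,
              density_pretransform = c(slope = 1, intercept = 0))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Power-law density-to-modulus conversion
#'
#' `E = max(floor, coeff_a * (rho/1000)^exponent)` with `rho` in mg/cm^3 and
#' `E` in MPa; the 2.1 exponent follows the power-law relation between bone
#' density and elastic modulus commonly used for the proximal tibia. Negative
#' densities (air/fat partial volume) are clamped to zero before the power.
#'
#' @param rho Density vector, mg/cm^3.
#' @param coeff_a Coefficient, MPa at 1 g/cm^3 (> 0).
#' @param exponent Power-law exponent (default 2.1).
#' @param floor Minimum modulus, MPa (default 1).
#' @return Elastic moduli, MPa.
#' @export
goulet_modulus <- function(rho, coeff_a = fe_config()$coeff_a,
                           exponent = 2.1, floor = 1) {
  if (!all(is.finite(rho))) stop("rho must be finite")
  if (coeff_a <= 0) stop("coeff_a must be > 0")
  pmax(floor, coeff_a * (pmax(rho, 0) / 1000)^exponent)
}

#' Map calibrated densities to per-element materials
#'
#' Per-element density is the mean of the calibrated volume sampled at the
#' element's integration points; bone moduli follow [goulet_modulus()]; the
#' soft-tissue cylinder is overridden to an incompressible-like constant
#' (E = 10 MPa, nu = 0.495) and the distal femur to a rigid-surrogate
#' stiff elastic material (E = 500 GPa).
#'
#' @param mesh An `fe_mesh`.
#' @param volume Calibrated `density_volume` (mg/cm^3) covering the mesh.
#' @param config A [fe_config()] list.
#' @param rigid_femur Logical; apply the stiff-femur override (default TRUE).
#' @return A `material_field`: vectors `E` (MPa), `nu`, `rho` (mg/cm^3) and
#'   logical `rigid` per element.
#' @export
map_materials <- function(mesh, volume, config = fe_config(),
                          rigid_femur = TRUE) {
  stopifnot(inherits(mesh, "fe_mesh"), is_density_volume(volume))
  if (volume$units != "mg_cm3") stop("volume must be calibrated (mg_cm3)")
  ne <- nrow(mesh$conn)
  if (mesh$type == "hex8") {
    gp <- 0.5 / sqrt(3) * mesh$element_size
    offs <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  } else {
    # 4-point rule positions for tets, expressed via corner coordinates
    offs <- NULL
  }
  acc <- numeric(ne)
  nok <- numeric(ne)
  if (mesh$type == "hex8") {
    for (s in seq_len(nrow(offs))) {
      pts <- sweep(mesh$centroids, 2, offs[s, ], `+`)
      v <- sample_volume(volume, pts, method = "linear", fill = NA_real_)
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      nok <- nok + ok
    }
    rho <- ifelse(nok > 0, acc / nok, NA_real_)
  } else {
    aa <- 0.5854102; bb <- 0.1381966
    wpos <- rbind(c(aa, bb, bb, bb), c(bb, aa, bb, bb),
                  c(bb, bb, aa, bb), c(bb, bb, bb, aa))
    for (s in 1:4) {
      pts <- wpos[s, 1] * mesh$nodes[mesh$conn[, 1], , drop = FALSE] +
        wpos[s, 2] * mesh$nodes[mesh$conn[, 2], , drop = FALSE] +
        wpos[s, 3] * mesh$nodes[mesh$conn[, 3], , drop = FALSE] +
        wpos[s, 4] * mesh$nodes[mesh$conn[, 4], , drop = FALSE]
      v <- sample_volume(volume, pts, method = "linear", fill = NA_real_)
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      nok <- nok + ok
    }
    rho <- ifelse(nok > 0, acc / nok, NA_real_)
  }
  if (anyNA(rho)) stop("element(s) with no density sample inside the volume: ",
                       paste(utils::head(which(is.na(rho))), collapse = ", "))
  pt <- config$density_pretransform
  rho_law <- pt[["slope"]] * rho + pt[["intercept"]]
  E <- goulet_modulus(rho_law, config$coeff_a, config$exponent, config$E_floor)
  nu <- rep(config$nu_bone, ne)
  rigid <- rep(FALSE, ne)
  soft <- mesh$element_domain == "soft_tissue"
  E[soft] <- config$E_soft
  nu[soft] <- config$nu_soft
  if (rigid_femur) {
    fem <- mesh$element_domain == "femur"
    E[fem] <- config$E_rigid
    rigid[fem] <- TRUE
  }
  structure(list(E = E, nu = nu, rho = rho, rigid = rigid, config = config),
            class = "material_field")
}
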