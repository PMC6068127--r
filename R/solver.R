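# Linear elastostatic solver: isoparametric 8-node hexahedra (2x2x2 Gauss,
# mean-dilatation B-bar so the near-incompressible soft tissue does not
# volumetrically lock) and 10-node quadratic tetrahedra (4-point rule).
# Displacement-driven single-leg-stance boundary conditions with reaction
# recovery and body-weight scaling.

# isotropic elasticity matrix, engineering-shear Voigt convention
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# hex shape-function derivative matrix (6 x 24) at natural point xi for a
# cube of side h; VTK corner order
hex_corner_signs <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1),
                          c(-1, 1, -1), c(-1, -1, 1), c(1, -1, 1),
                          c(1, 1, 1), c(-1, 1, 1))

hex_B <- function(xi, h) {
  s <- hex_corner_signs
  dN <- matrix(0, 8, 3)
  for (i in 1:8) {
    dN[i, 1] <- s[i, 1] * (1 + s[i, 2] * xi[2]) * (1 + s[i, 3] * xi[3]) / 8
    dN[i, 2] <- s[i, 2] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 3] * xi[3]) / 8
    dN[i, 3] <- s[i, 3] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 2] * xi[2]) / 8
  }
  dN <- dN * (2 / h)                 # d/dx = d/dxi * 2/h on a cube
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[i, 1]
    B[2, c0 + 2] <- dN[i, 2]
    B[3, c0 + 3] <- dN[i, 3]
    B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
    B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
    B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
  }
  B
}

# volumetric part of B (rows 1-3 replaced by the mean normal row)
hex_B_vol <- function(B) {
  vol <- (B[1, ] + B[2, ] + B[3, ]) / 3
  Bv <- matrix(0, 6, 24)
  Bv[1, ] <- vol; Bv[2, ] <- vol; Bv[3, ] <- vol
  Bv
}

# unit (E = 1, h = 1) hexahedral stiffness for a given nu; Ke = E * h * Keu
hex_unit_stiffness <- function(nu, bbar = TRUE) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  D <- elastic_D(1, nu)
  Bc <- hex_B(c(0, 0, 0), 1)
  Bvc <- hex_B_vol(Bc)
  Ke <- matrix(0, 24, 24)
  detJ <- 1 / 8
  for (p in seq_len(nrow(pts))) {
    B <- hex_B(pts[p, ], 1)
    if (bbar) B <- B - hex_B_vol(B) + Bvc
    Ke <- Ke + detJ * t(B) %*% D %*% B
  }
  (Ke + t(Ke)) / 2
}

# 10-node tet B matrix (6 x 30) at barycentric point L, given corner coords
tet10_B <- function(corners, L) {
  M <- t(corners[2:4, ] - matrix(corners[1, ], 3, 3, byrow = TRUE))
  Minv <- solve(M)
  gL <- rbind(-colSums(Minv), Minv)   # rows: grad L1..L4 (1 x 3 each)
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  dN <- matrix(0, 10, 3)
  for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * gL[i, ]
  for (e in 1:6) {
    a <- edge_pairs[e, 1]; b <- edge_pairs[e, 2]
    dN[4 + e, ] <- 4 * (L[a] * gL[b, ] + L[b] * gL[a, ])
  }
  B <- matrix(0, 6, 30)
  for (i in 1:10) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[i, 1]
    B[2, c0 + 2] <- dN[i, 2]
    B[3, c0 + 3] <- dN[i, 3]
    B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
    B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
    B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
  }
  B
}

tet10_stiffness <- function(corners, E, nu) {
  aa <- 0.5854102; bb <- 0.1381966
  pts <- rbind(c(aa, bb, bb, bb), c(bb, aa, bb, bb),
               c(bb, bb, aa, bb), c(bb, bb, bb, aa))
  M <- t(corners[2:4, ] - matrix(corners[1, ], 3, 3, byrow = TRUE))
  V <- abs(det(M)) / 6
  D <- elastic_D(E, nu)
  Ke <- matrix(0, 30, 30)
  for (p in 1:4) {
    B <- tet10_B(corners, pts[p, ])
    Ke <- Ke + (V / 4) * t(B) %*% D %*% B
  }
  (Ke + t(Ke)) / 2
}

# element dof matrix: Ne x (3*nodes_per_element)
element_dofs <- function(conn) {
  npe <- ncol(conn)
  ed <- matrix(0L, nrow(conn), 3L * npe)
  for (i in seq_len(npe)) {
    ed[, 3 * i - 2] <- 3L * (conn[, i] - 1L) + 1L
    ed[, 3 * i - 1] <- 3L * (conn[, i] - 1L) + 2L
    ed[, 3 * i] <- 3L * (conn[, i] - 1L) + 3L
  }
  ed
}

#' Assemble the global stiffness matrix
#'
#' @param mesh An `fe_mesh`.
#' @param materials A `material_field` from [map_materials()] (or any list
#'   with per-element `E` and `nu`).
#' @return Sparse symmetric stiffness matrix (3 dof per node).
#' @export
assemble_stiffness <- function(mesh, materials) {
  nd <- 3L * nrow(mesh$nodes)
  if (mesh$type == "hex8") {
    ed <- element_dofs(mesh$conn)
    ii_t <- rep(1:24, times = 24); jj_t <- rep(1:24, each = 24)
    # assemble in chunks to bound the triplet-buffer memory
    chunk <- 8000L
    K <- NULL
    for (nu in unique(materials$nu)) {
      sel <- which(materials$nu == nu)
      Keu <- hex_unit_stiffness(nu)
      vKeu <- as.vector(Keu)
      for (s0 in seq(1, length(sel), by = chunk)) {
        sub <- sel[s0:min(s0 + chunk - 1L, length(sel))]
        scale <- materials$E[sub] * mesh$element_size
        Kc <- Matrix::sparseMatrix(
          i = as.integer(ed[sub, ii_t, drop = FALSE]),
          j = as.integer(ed[sub, jj_t, drop = FALSE]),
          x = as.numeric(outer(scale, vKeu)), dims = c(nd, nd))
        K <- if (is.null(K)) Kc else K + Kc
      }
    }
  } else {
    ne <- nrow(mesh$conn)
    ed <- element_dofs(mesh$conn)
    ii <- integer(ne * 900); jj <- integer(ne * 900); xx <- numeric(ne * 900)
    ii_t <- rep(1:30, times = 30); jj_t <- rep(1:30, each = 30)
    pos <- 0L
    for (e in seq_len(ne)) {
      corners <- mesh$nodes[mesh$conn[e, 1:4], , drop = FALSE]
      Ke <- tet10_stiffness(corners, materials$E[e], materials$nu[e])
      idx <- pos + seq_len(900)
      ii[idx] <- ed[e, ii_t]; jj[idx] <- ed[e, jj_t]; xx[idx] <- as.vector(Ke)
      pos <- pos + 900L
    }
    K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
  }
  K
}

#' Single-leg-stance load case
#'
#' A uniform axial displacement (default 1 mm, compressive) prescribed on the
#' femoral top surface whose transverse degrees of freedom are fixed; the
#' most distal tibia and fibula node sets are fully constrained. Results are
#' later scaled so the femoral reaction equals one body weight.
#'
#' @param displacement Prescribed axial displacement, mm (> 0, applied
#'   downward).
#' @param body_mass Body mass, kg (used with `g` if `body_weight` missing).
#' @param body_weight Body weight, N.
#' @param g Gravitational constant, m/s^2 (default 9.81).
#' @param constraints Optional custom constraint table
#'   (`data.frame(node, dof, value)`, dof in 1:3) replacing the standard sets.
#' @return A `load_case` list.
#' @export
load_case <- function(displacement = 1, body_mass = NULL, body_weight = NULL,
                      g = 9.81, constraints = NULL) {
  if (is.null(body_weight))
    body_weight <- if (is.null(body_mass)) NA_real_ else body_mass * g
  if (displacement <= 0) stop("displacement must be > 0")
  structure(list(displacement = displacement, body_weight = body_weight,
                 constraints = constraints),
            class = "load_case")
}

standard_constraints <- function(mesh, load) {
  if (!is.null(load$constraints)) return(load$constraints)
  cs <- list()
  for (s in c("tibia_distal", "fibula_distal")) {
    nds <- mesh$node_sets[[s]]
    if (length(nds))
      cs[[s]] <- data.frame(node = rep(nds, each = 3),
                            dof = rep(1:3, length(nds)), value = 0)
  }
  ft <- mesh$node_sets$femur_top
  if (!length(ft)) stop("mesh has no femur_top node set")
  cs$femur_top <- data.frame(node = rep(ft, each = 3),
                             dof = rep(1:3, length(ft)),
                             value = rep(c(0, 0, -load$displacement),
                                         length(ft)))
  do.call(rbind, cs)
}

#' Assemble and solve the elastostatic system
#'
#' Direct sparse Cholesky solution of the constrained linear system; element
#' stress/strain tensors are recovered at element centroids and reduced to
#' minimum principal and von Mises scalars. The reported `reaction_force` is
#' the vertical reaction summed over the femoral top surface.
#'
#' @param mesh An `fe_mesh`.
#' @param materials A `material_field`.
#' @param load A [load_case()].
#' @return A `field_result`: per-element Voigt `stress` (MPa) and `strain`,
#'   `min_principal_stress`, `von_mises_stress` (MPa),
#'   `min_principal_strain`, `von_mises_strain` (strain units),
#'   displacements `u` (3 x nodes vector), `reaction_force` (N, pre-scaling),
#'   `reaction_bottom` (N, tibia+fibula), `scale_factor`, `residual`,
#'   element `volumes` and `element_domain`.
#' @export
assemble_and_solve <- function(mesh, materials, load = load_case()) {
  K <- assemble_stiffness(mesh, materials)
  nd <- nrow(K)
  con <- standard_constraints(mesh, load)
  cdof <- 3L * (con$node - 1L) + con$dof
  if (anyDuplicated(cdof)) {
    keep <- !duplicated(cdof)
    con <- con[keep, , drop = FALSE]
    cdof <- cdof[keep]
  }
  if (length(cdof) < 6) stop("fewer than 6 constrained dofs: rigid-body modes")
  free <- setdiff(seq_len(nd), cdof)
  uc <- con$value
  Kff <- K[free, free, drop = FALSE]
  Kfc <- K[free, cdof, drop = FALSE]
  rhs <- -Kfc %*% uc
  Kff_sym <- Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2, "L")
  uf <- tryCatch({
    # supernodal Cholesky (BLAS-backed) is much faster than the simplicial
    # default on 3D elasticity sparsity patterns
    ch <- Matrix::Cholesky(Kff_sym, LDL = FALSE, super = TRUE, perm = TRUE)
    as.numeric(Matrix::solve(ch, rhs))
  }, error = function(e)
    stop("singular system (floating component?): ",
         conditionMessage(e)))
  u <- numeric(nd)
  u[free] <- uf
  u[cdof] <- uc
  rhs_norm <- sqrt(sum(as.numeric(rhs)^2))
  residual <- if (rhs_norm > 0)
    sqrt(sum(as.numeric(Kff %*% uf - rhs)^2)) / rhs_norm else 0

  r_full <- as.numeric(K %*% u)
  ft <- mesh$node_sets$femur_top
  rz_top <- sum(r_full[3L * (ft - 1L) + 3L])
  bot <- c(mesh$node_sets$tibia_distal, mesh$node_sets$fibula_distal)
  rz_bot <- if (length(bot)) sum(r_full[3L * (bot - 1L) + 3L]) else NA_real_

  ne <- nrow(mesh$conn)
  if (mesh$type == "hex8") {
    Bc <- hex_B(c(0, 0, 0), mesh$element_size)
    ed <- element_dofs(mesh$conn)
    Ue <- matrix(u[ed], ne, 24)
    strain <- Ue %*% t(Bc)
  } else {
    ed <- element_dofs(mesh$conn)
    strain <- matrix(0, ne, 6)
    Lc <- rep(0.25, 4)
    for (e in seq_len(ne)) {
      corners <- mesh$nodes[mesh$conn[e, 1:4], , drop = FALSE]
      strain[e, ] <- tet10_B(corners, Lc) %*% u[ed[e, ]]
    }
  }
  lam <- materials$E * materials$nu /
    ((1 + materials$nu) * (1 - 2 * materials$nu))
  mu <- materials$E / (2 * (1 + materials$nu))
  tr3 <- strain[, 1] + strain[, 2] + strain[, 3]
  stress <- cbind(2 * mu * strain[, 1] + lam * tr3,
                  2 * mu * strain[, 2] + lam * tr3,
                  2 * mu * strain[, 3] + lam * tr3,
                  mu * strain[, 4], mu * strain[, 5], mu * strain[, 6])
  ps <- principal_and_vm(stress, "stress")
  pe <- principal_and_vm(strain, "strain")
  structure(list(stress = stress, strain = strain,
                 min_principal_stress = ps$min_principal,
                 von_mises_stress = ps$von_mises,
                 min_principal_strain = pe$min_principal,
                 von_mises_strain = pe$von_mises,
                 u = u, reaction_force = abs(rz_top),
                 reaction_bottom = rz_bot,
                 scale_factor = 1, residual = residual,
                 volumes = mesh$volumes,
                 element_domain = mesh$element_domain,
                 centroids = mesh$centroids),
            class = "field_result")
}

#' Scale a solution to one body weight
#'
#' Linear elasticity permits post-hoc scaling: all stress, strain and
#' displacement fields are multiplied by `body_weight / reaction_force` so
#' the femoral reaction equals one body weight.
#'
#' @param result A `field_result`.
#' @param body_weight Target body weight, N (> 0).
#' @return The scaled `field_result` (`scale_factor` records the ratio;
#'   `reaction_force` keeps the pre-scaling value).
#' @export
scale_to_bodyweight <- function(result, body_weight) {
  stopifnot(inherits(result, "field_result"))
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a positive number")
  if (result$reaction_force <= 0) stop("zero reaction force: cannot scale")
  s <- body_weight / result$reaction_force
  for (f in c("stress", "strain", "min_principal_stress", "von_mises_stress",
              "min_principal_strain", "von_mises_strain", "u"))
    result[[f]] <- result[[f]] * s
  result$scale_factor <- result$scale_factor * s
  result
}
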