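# Closed-form eigenvalues of symmetric 3x3 tensors, vectorised over elements.
# Input: n x 6 Voigt matrix (xx, yy, zz, xy, yz, zx) of TENSOR components
# (shears already halved for strain). Returns n x 3, ascending.
symeig3 <- function(v) {
  v <- matrix(v, ncol = 6)
  a11 <- v[, 1]; a22 <- v[, 2]; a33 <- v[, 3]
  a12 <- v[, 4]; a23 <- v[, 5]; a13 <- v[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(0, nrow(v), 3)
  deg <- p < 1e-300 * pmax(1, abs(q))  # (near-)hydrostatic: all eigs = q
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p
  b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b23 <- a23 / safe_p; b13 <- a13 / safe_p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out[, 1] <- ifelse(deg, q, e3)
  out[, 2] <- ifelse(deg, q, e2)
  out[, 3] <- ifelse(deg, q, e1)
  out
}

#' Principal values and von Mises equivalents of symmetric tensors
#'
#' For stress, the equivalent is the usual von Mises stress
#' `sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))`; for strain the
#' (2/3)-normalised equivalent strain is used, which reduces to `(2/3)(1+nu)`
#' times the axial strain under uniaxial loading and to the axial strain for
#' an incompressible material. The minimum principal value is the smallest
#' (most compressive, most negative) eigenvalue.
#'
#' @param tensor A symmetric 3x3 matrix, or an n x 6 Voigt matrix
#'   `(xx, yy, zz, xy, yz, zx)`. For strain input in Voigt form the shear
#'   entries are engineering shears (2 * tensor shear).
#' @param type `"stress"` or `"strain"` (selects the equivalent-value
#'   normalisation and the Voigt shear convention).
#' @return List with numeric `min_principal` and `von_mises` (vectors for
#'   matrix input).
#' @export
principal_and_vm <- function(tensor, type = c("stress", "strain")) {
  type <- match.arg(type)
  if (is.matrix(tensor) && all(dim(tensor) == c(3, 3))) {
    if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
      stop("tensor must be symmetric")
    v <- cbind(tensor[1, 1], tensor[2, 2], tensor[3, 3],
               tensor[1, 2], tensor[2, 3], tensor[1, 3])
  } else {
    v <- matrix(tensor, ncol = 6)
    if (type == "strain") v[, 4:6] <- v[, 4:6] / 2  # engineering -> tensor
  }
  e <- symeig3(v)
  vm <- sqrt(0.5 * ((e[, 1] - e[, 2])^2 + (e[, 2] - e[, 3])^2 +
                      (e[, 3] - e[, 1])^2))
  if (type == "strain") vm <- (2 / 3) * vm
  list(min_principal = e[, 1], von_mises = vm)
}
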