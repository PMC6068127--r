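test_that("homogeneous prism reproduces the EA/L stiffness closed form", {
  # 10 x 10 mm cross-section (A = 100 mm^2), L = 50 mm, E = 100 MPa, nu = 0
  mesh <- prism_mesh(5, 5, 25, 2)
  mats <- uniform_materials(mesh, E = 100, nu = 0)
  res <- assemble_and_solve(mesh, mats, load_case(displacement = 1))
  expect_equal(res$reaction_force, 100 * 100 / 50, tolerance = 0.005)
  expect_lt(res$residual, 1e-8)
  # same prism as quadratic tets
  tet <- tibiamech:::hex_to_tet10(prism_mesh(3, 3, 15, 10 / 3))
  mats_t <- uniform_materials(tet, E = 100, nu = 0)
  res_t <- assemble_and_solve(tet, mats_t, load_case(displacement = 1))
  expect_equal(res_t$reaction_force, 100 * 100 / 50, tolerance = 0.005)
})

test_that("patch test: linear displacement fields are reproduced exactly", {
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 3e-4, 8e-4), 3, 3)  # symmetric strain field
  for (kind in c("hex8", "tet10")) {
    mesh <- prism_mesh(3, 3, 3, 1.7)
    if (kind == "tet10") mesh <- tibiamech:::hex_to_tet10(mesh)
    mats <- uniform_materials(mesh, E = 250, nu = 0.3)
    u_exact <- as.vector(t(mesh$nodes %*% A))
    boundary <- which(
      apply(mesh$nodes, 1, function(p)
        any(abs(p - 0) < 1e-9 | abs(p - 3 * 1.7) < 1e-9)))
    con <- data.frame(node = rep(boundary, each = 3),
                      dof = rep(1:3, length(boundary)),
                      value = u_exact[as.vector(t(outer(3 * (boundary - 1),
                                                        1:3, `+`)))])
    res <- assemble_and_solve(mesh, mats,
                              load_case(displacement = 1,
                                        constraints = con))
    expect_lt(max(abs(res$u - u_exact)) / max(abs(u_exact)), 1e-10)
    exx <- A[1, 1]
    expect_lt(max(abs(res$strain[, 1] - exx)) / abs(exx), 1e-9)
    expect_lt(max(abs(res$strain[, 4] - 2 * A[1, 2])) / abs(2 * A[1, 2]),
              1e-9)
  }
})

test_that("solution is linear in the prescribed displacement", {
  mesh <- prism_mesh(3, 3, 6, 2)
  mats <- uniform_materials(mesh, E = 500, nu = 0.3)
  r1 <- assemble_and_solve(mesh, mats, load_case(displacement = 1))
  r2 <- assemble_and_solve(mesh, mats, load_case(displacement = 2))
  expect_equal(r2$reaction_force, 2 * r1$reaction_force, tolerance = 1e-9)
  expect_equal(r2$stress, 2 * r1$stress, tolerance = 1e-9)
})

test_that("global stiffness is symmetric and annihilates rigid translations", {
  mesh <- prism_mesh(2, 3, 4, 1.3)
  mats <- uniform_materials(mesh, E = 123, nu = 0.28)
  K <- assemble_stiffness(mesh, mats)
  asym <- max(abs(K - Matrix::t(K)))
  expect_lt(asym, 1e-10 * max(abs(K)))
  for (dof in 1:3) {
    u <- rep(0, nrow(K)); u[seq(dof, nrow(K), by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
})

test_that("reactions at the femoral top balance the distal constraints", {
  res <- coarse_solution()$res
  expect_lt(abs(res$reaction_force - abs(res$reaction_bottom)) /
              res$reaction_force, 1e-6)
  expect_lt(res$residual, 1e-8)
})

test_that("uniaxial stress state gives the stated equivalent-strain form", {
  # free lateral surfaces; constrain rigid-body modes only at the base
  mesh <- prism_mesh(2, 2, 10, 2)
  nu <- 0.3
  mats <- uniform_materials(mesh, E = 200, nu = nu)
  bottom <- mesh$node_sets$tibia_distal
  top <- mesh$node_sets$femur_top
  con <- rbind(
    data.frame(node = bottom, dof = 3, value = 0),
    data.frame(node = bottom[1], dof = 1, value = 0),
    data.frame(node = bottom[1], dof = 2, value = 0),
    data.frame(node = bottom[2], dof = 2, value = 0),
    data.frame(node = top, dof = 3, value = -1))
  res <- assemble_and_solve(mesh, mats, load_case(constraints = con))
  ez <- -1 / 20  # uniform axial strain
  expect_equal(mean(res$strain[, 3]), ez, tolerance = 1e-6)
  expect_equal(mean(res$strain[, 1]), -nu * ez, tolerance = 1e-6)
  expect_equal(mean(res$von_mises_strain), (2 / 3) * (1 + nu) * abs(ez),
               tolerance = 1e-6)
  expect_equal(mean(res$min_principal_strain), ez, tolerance = 1e-6)
})

test_that("body-weight scaling is exact and linear in mass", {
  res <- coarse_solution()$res
  s1 <- scale_to_bodyweight(res, res$reaction_force)
  expect_equal(s1$scale_factor, 1)
  expect_equal(s1$stress, res$stress)
  half <- scale_to_bodyweight(res, res$reaction_force / 2)
  expect_equal(half$stress, res$stress / 2, tolerance = 1e-12)
  m72 <- scale_to_bodyweight(res, 72 * 9.81)
  m101 <- scale_to_bodyweight(res, 101 * 9.81)
  nz <- abs(res$min_principal_stress) > 1e-12
  expect_equal(m101$min_principal_stress[nz] / m72$min_principal_stress[nz],
               rep(101 / 72, sum(nz)), tolerance = 1e-9)
  expect_error(scale_to_bodyweight(res, -5), "positive")
})

test_that("under-constrained systems are rejected", {
  mesh <- prism_mesh(2, 2, 2, 1)
  mats <- uniform_materials(mesh, 100, 0.3)
  con <- data.frame(node = 1L, dof = 1:3, value = 0)
  expect_error(assemble_and_solve(mesh, mats,
                                  load_case(constraints = con)),
               "constrained dofs")
})
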