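cube_mask <- function(n, voxel = 1) {
  labels <- array(1L, dim = c(n, n, n))
  structure(list(labels = labels, spacing = rep(voxel, 3),
                 origin = c(0, 0, 0), orientation = diag(3),
                 threshold_used = 0, provenance = "synthetic"),
            class = "segmentation_mask")
}

test_that("hex meshing a solid cube gives the expected element count and volume", {
  n <- 12
  mask <- cube_mask(n)
  mesh <- build_mesh(mask, 2, soft_tissue = FALSE)
  expect_equal(nrow(mesh$conn), ceiling(n / 2)^3)
  expect_equal(sum(mesh$volumes), n^3, tolerance = 0.03)
  expect_true(all(mesh$element_domain == "tibia"))
  # no orphan nodes
  expect_setequal(seq_len(nrow(mesh$nodes)), sort(unique(as.vector(mesh$conn))))
})

test_that("element size below the voxel size is rejected", {
  expect_error(build_mesh(cube_mask(8, voxel = 2), 1), "voxel")
})

test_that("phantom mesh volume matches the mask volume per bone within 3%", {
  m <- coarse_model()
  sol <- coarse_solution()
  cropped <- crop_to_joint(m$re$mask, m$landmarks, 50, 28)
  vox_mm3 <- prod(cropped$spacing)
  for (b in c(tibia = 1L, femur = 2L)) {
    mask_vol <- sum(cropped$labels == b) * vox_mm3
    nm <- c("tibia", "femur")[b]
    mesh_vol <- sum(sol$mesh$volumes[sol$mesh$element_domain == nm])
    expect_lt(abs(mesh_vol - mask_vol) / mask_vol, 0.03)
  }
})

test_that("subchondral surface nodes lie on the plateau and sets are sane", {
  m <- coarse_model()
  mesh <- coarse_solution()$mesh
  for (s in c("subchondral_surface_medial", "subchondral_surface_lateral")) {
    nds <- mesh$node_sets[[s]]
    expect_gt(length(nds), 10)
    dz <- abs(mesh$nodes[nds, 3] - m$landmarks$z_plateau)
    # within one element of the (sloped) plateau surface
    expect_lt(stats::median(dz), 2 * mesh$element_size)
  }
  expect_true(all(mesh$nodes[mesh$node_sets$subchondral_surface_medial, 1] >=
                    m$landmarks$x0))
  expect_gt(length(mesh$node_sets$femur_top), 10)
})

test_that("touching bones are rejected as a closed joint gap", {
  labels <- array(0L, dim = c(12, 12, 12))
  labels[, , 1:6] <- 1L   # tibia directly below femur, no gap
  labels[, , 7:12] <- 2L
  mask <- structure(list(labels = labels, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), orientation = diag(3),
                         threshold_used = 0, provenance = "synthetic"),
                    class = "segmentation_mask")
  expect_error(build_mesh(mask, 2, soft_tissue = FALSE), "joint gap")
})

test_that("quadratic-tet conversion is conforming with positive volumes", {
  mesh <- prism_mesh(3, 3, 4, 2)
  tet <- tibiamech:::hex_to_tet10(mesh)
  expect_equal(tet$type, "tet10")
  expect_equal(nrow(tet$conn), 6 * nrow(mesh$conn))
  expect_true(all(tet$volumes > 0))
  expect_equal(sum(tet$volumes), sum(mesh$volumes), tolerance = 1e-9)
  # corner tets of adjacent hexes share midside nodes: every midside node
  # coordinate is unique (conforming, no duplicated midpoints)
  mids <- tet$nodes[(nrow(mesh$nodes) + 1):nrow(tet$nodes), ]
  expect_equal(nrow(unique(round(mids, 9))), nrow(mids))
  # 10-node connectivity references valid nodes
  expect_true(all(tet$conn >= 1 & tet$conn <= nrow(tet$nodes)))
})

test_that("analysis crop keeps the joint region and drops far shaft", {
  m <- coarse_model()
  cropped <- crop_to_joint(m$re$mask, m$landmarks, 40, 20)
  z <- m$re$mask$origin[3] +
    (seq_len(dim(cropped$labels)[3]) - 1) * m$re$mask$spacing[3]
  occupied <- apply(cropped$labels > 0, 3, any)
  expect_true(all(z[occupied] >= m$landmarks$z_plateau - 40 - 1e-9))
  expect_true(all(z[occupied] <= m$landmarks$z_plateau + 20 + 1e-9))
  expect_error(crop_to_joint(m$re$mask, m$landmarks, -100, -90), "crop")
})
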