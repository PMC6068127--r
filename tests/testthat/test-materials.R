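test_that("power-law modulus honours the floor, ratio and monotonicity", {
  expect_equal(goulet_modulus(0), 1)
  expect_equal(goulet_modulus(-50), 1)  # negative densities clamp to floor
  rho <- c(200, 400, 800, 1200)
  E <- goulet_modulus(rho)
  expect_equal(goulet_modulus(2 * rho) / E, rep(2^2.1, 4), tolerance = 1e-12)
  set.seed(1)
  r <- sort(stats::runif(50, 0, 1500))
  expect_true(all(diff(goulet_modulus(r)) >= 0))
  expect_error(goulet_modulus(NaN), "finite")
  expect_error(goulet_modulus(500, coeff_a = -1), "coeff_a")
})

test_that("material mapping: uniform volume gives uniform bone moduli and overrides hold", {
  mesh <- coarse_solution()$mesh
  m <- coarse_model()
  uni <- m$re$volume
  uni$data[] <- 500
  mats <- map_materials(mesh, uni)
  bone <- mesh$element_domain %in% c("tibia", "fibula")
  expect_equal(length(unique(mats$E[bone])), 1)
  expect_equal(unique(mats$nu[bone]), 0.3)
  soft <- mesh$element_domain == "soft_tissue"
  expect_true(all(mats$E[soft] == 10))
  expect_true(all(mats$nu[soft] == 0.495))
  fem <- mesh$element_domain == "femur"
  expect_true(all(mats$E[fem] == 500000))
  expect_true(all(mats$rigid[fem]))
})

test_that("two-phase volume yields bimodal moduli with intermediate boundary elements", {
  mask <- structure(list(labels = array(1L, dim = c(20, 20, 20)),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3), threshold_used = 0,
                         provenance = "synthetic"),
                    class = "segmentation_mask")
  vol <- density_volume(array(200, dim = c(20, 20, 20)), spacing = c(1, 1, 1),
                        units = "mg_cm3")
  vol$data[, , 11:20] <- 1000
  mesh <- build_mesh(mask, 2, soft_tissue = FALSE)
  mats <- map_materials(mesh, vol)
  E_lo <- goulet_modulus(200); E_hi <- goulet_modulus(1000)
  lo <- sum(abs(mats$E - E_lo) < 1)
  hi <- sum(abs(mats$E - E_hi) < 1)
  mid <- sum(mats$E > E_lo + 1 & mats$E < E_hi - 1)
  expect_gt(lo, 0.3 * length(mats$E))
  expect_gt(hi, 0.3 * length(mats$E))
  expect_gt(mid, 0)  # plane-straddling elements are intermediate
})

test_that("phantom moduli stay inside the physiological envelope", {
  sol <- coarse_solution()
  bone <- sol$mesh$element_domain %in% c("tibia", "fibula")
  expect_gte(min(sol$mats$E[bone]), 1)
  expect_lt(max(sol$mats$E[bone]), 30000)  # ~25 GPa envelope
  expect_gt(max(sol$mats$E[bone]), 2000)   # cortical shell is stiff
})

test_that("material mapping is permutation-invariant over element order", {
  mesh <- prism_mesh(3, 3, 3, 2)
  vol <- density_volume(array(stats::runif(8000, 100, 900),
                              dim = c(20, 20, 20)),
                        spacing = c(0.5, 0.5, 0.5), units = "mg_cm3")
  mats <- map_materials(mesh, vol)
  p <- sample(nrow(mesh$conn))
  mesh2 <- mesh
  mesh2$conn <- mesh$conn[p, , drop = FALSE]
  mesh2$centroids <- mesh$centroids[p, , drop = FALSE]
  mesh2$volumes <- mesh$volumes[p]
  mesh2$element_domain <- mesh$element_domain[p]
  mats2 <- map_materials(mesh2, vol)
  expect_equal(mats2$E, mats$E[p], tolerance = 1e-12)
})

test_that("elements outside the volume are rejected", {
  mesh <- prism_mesh(2, 2, 2, 10)  # 20 mm cube
  vol <- density_volume(array(300, dim = c(5, 5, 5)), spacing = c(1, 1, 1),
                        units = "mg_cm3")
  expect_error(map_materials(mesh, vol), "no density sample")
})
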