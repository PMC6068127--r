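test_that("slab band volumes are proportional to the band thicknesses", {
  s <- slab_fixture()
  reg <- s$map$region
  vol_of <- function(pattern) {
    sum(s$mesh$volumes[grepl(pattern, as.character(reg))])
  }
  v_sc <- vol_of("subchondral cortical|subchondral spine")
  v_st <- vol_of("subchondral trabecular")
  v_ep <- vol_of("epiphyseal trabecular|epiphyseal central")
  v_mt <- vol_of("metaphyseal trabecular|metaphyseal central")
  # spine band covers 0-5 mm, so compare the summed 0-2.5/2.5-5 bands of the
  # medial+lateral sectors only
  med_lat <- function(pattern) sum(s$mesh$volumes[grepl(pattern,
                                                        as.character(reg))])
  v1 <- med_lat("(medial|lateral) subchondral cortical")
  v2 <- med_lat("(medial|lateral) subchondral trabecular")
  v3 <- med_lat("(medial|lateral) epiphyseal trabecular")
  v4 <- med_lat("(medial|lateral) metaphyseal trabecular")
  # discrete slab oracle at h = 2: element-centroid depths fall at
  # 0.5, 2.5, 4.5, ... mm, so the 2.5/2.5/10/20 mm bands capture exactly
  # 1/2/5/10 element layers (continuum ratio 1/1/4/8 recovered as h -> 0)
  expect_equal(v2 / v1, 2, tolerance = 0.05)
  expect_equal(v3 / v1, 5, tolerance = 0.05)
  expect_equal(v4 / v1, 10, tolerance = 0.05)
})

test_that("band boundaries are half-open with depth 0 in the surface band", {
  s <- slab_fixture()
  # top element layer (vertical depth < 2.5) must be subchondral cortical
  tib <- which(s$mesh$element_domain == "tibia")
  top_layer <- tib[s$mesh$centroids[tib, 3] > 79 - 2]
  labs <- as.character(s$map$region[top_layer])
  expect_true(all(grepl("subchondral cortical|subchondral spine", labs)))
  # an element at vertical depth 3 mm in the medial sector is subchondral
  # trabecular
  x0 <- s$lm$x0; w <- s$lm$central_halfwidth
  pick <- tib[abs(s$mesh$centroids[tib, 3] - (80 - 3)) < 1 &
                s$mesh$centroids[tib, 1] > x0 + w + 5 &
                s$mesh$centroids[tib, 1] < 50]  # clear of the side wall
  expect_true(all(s$map$region[pick] == "medial subchondral trabecular"))
})

test_that("region volumes sum without double counting", {
  s <- slab_fixture()
  assigned <- s$map$region != "unassigned"
  per_region <- tapply(s$mesh$volumes[assigned],
                       droplevels(s$map$region[assigned]), sum)
  expect_equal(sum(per_region), sum(s$mesh$volumes[assigned]))
})

test_that("voxel-grid region map matches the element banding on the slab", {
  s <- slab_fixture()
  vm <- voxel_region_map(s$depth, s$lm)
  counts <- table(vm$region)
  v1 <- sum(counts[c("medial subchondral cortical",
                     "lateral subchondral cortical")])
  v2 <- sum(counts[c("medial subchondral trabecular",
                     "lateral subchondral trabecular")])
  v3 <- sum(counts[c("medial epiphyseal trabecular",
                     "lateral epiphyseal trabecular")])
  v4 <- sum(counts[c("medial metaphyseal trabecular",
                     "lateral metaphyseal trabecular")])
  # discrete oracle at 1 mm voxels: integer vertical depths 0..79 put
  # 3 / 2 / 10 / 21 voxel layers in the 0-2.5 / 2.5-5 / 5-15 / 15-35 bands
  # (the deepest band is closed at 35)
  expect_equal(v2 / v1, 2 / 3, tolerance = 0.03)
  expect_equal(v3 / v1, 10 / 3, tolerance = 0.03)
  expect_equal(v4 / v1, 21 / 3, tolerance = 0.03)
  expect_true(all(levels(vm$region) == region_levels()))
})

test_that("aggregation reproduces a constant field and a hand-computed mean", {
  s <- slab_fixture()
  ne <- nrow(s$mesh$conn)
  fake <- structure(list(
    min_principal_stress = rep(-2, ne), von_mises_stress = rep(3, ne),
    min_principal_strain = rep(-1e-3, ne), von_mises_strain = rep(2e-3, ne),
    volumes = s$mesh$volumes), class = "field_result")
  agg <- aggregate_regional_metrics(fake, s$map)
  expect_true(all(abs(agg$mean[agg$metric == "min_principal_stress"] + 2)
                  < 1e-12))
  expect_true(all(abs(agg$mean[agg$metric == "min_principal_strain"] + 1000)
                  < 1e-9))

  # 4-element hand oracle with unequal volumes
  map <- structure(list(region = factor(
    c("medial subchondral cortical", "medial subchondral cortical",
      "lateral subchondral cortical", "unassigned"),
    levels = c(region_levels(), "unassigned")),
    depth_mm = c(1, 1, 1, NA)), class = "region_map")
  fr <- structure(list(
    min_principal_stress = c(-1, -3, -5, -100),
    von_mises_stress = c(1, 3, 5, 100),
    min_principal_strain = c(-1e-6, -3e-6, -5e-6, 0),
    von_mises_strain = c(1e-6, 3e-6, 5e-6, 0),
    volumes = c(1, 3, 2, 10)), class = "field_result")
  agg2 <- aggregate_regional_metrics(fr, map)
  med <- agg2$mean[agg2$region == "medial subchondral cortical" &
                     agg2$metric == "min_principal_stress"]
  expect_equal(med, (-1 * 1 + -3 * 3) / 4)  # volume-weighted
  lat <- agg2$mean[agg2$region == "lateral subchondral cortical" &
                     agg2$metric == "von_mises_stress"]
  expect_equal(lat, 5)
})

test_that("aggregation is permutation-invariant", {
  s <- slab_fixture()
  ne <- nrow(s$mesh$conn)
  set.seed(3)
  vals <- stats::rnorm(ne)
  fr <- structure(list(min_principal_stress = vals, von_mises_stress = abs(vals),
                       min_principal_strain = vals * 1e-6,
                       von_mises_strain = abs(vals) * 1e-6,
                       volumes = s$mesh$volumes), class = "field_result")
  a1 <- aggregate_regional_metrics(fr, s$map)
  p <- sample(ne)
  fr2 <- fr
  for (f in c("min_principal_stress", "von_mises_stress",
              "min_principal_strain", "von_mises_strain", "volumes"))
    fr2[[f]] <- fr[[f]][p]
  map2 <- structure(list(region = s$map$region[p],
                         depth_mm = s$map$depth_mm[p]),
                    class = "region_map")
  a2 <- aggregate_regional_metrics(fr2, map2)
  expect_equal(a1$mean, a2$mean, tolerance = 1e-12)
})

test_that("compartment stiffness is symmetric for a neutral phantom and scales with modulus", {
  sol <- coarse_solution()
  st <- compartment_stiffness(sol$mesh, sol$mats, sol$load, "both")
  expect_true(all(st > 0))
  expect_lt(abs(st["medial"] - st["lateral"]) / st["lateral"], 0.05)
  mats2 <- sol$mats
  mats2$E <- 2 * mats2$E
  st2 <- compartment_stiffness(sol$mesh, mats2, sol$load, "medial",
                               E_soft_opposite = 20)
  expect_equal(unname(st2["medial"] / st["medial"]), 2, tolerance = 1e-6)
})
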