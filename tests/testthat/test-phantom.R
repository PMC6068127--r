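test_that("phantom generation is seed-deterministic and seed-sensitive", {
  s <- coarse_spec(group = "normal", seed = 42)
  a <- generate_knee_phantom(s)
  b <- generate_knee_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels$data, b$truth$labels$data)
  c <- generate_knee_phantom(coarse_spec(group = "normal", seed = 43))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("ground-truth axes realise the requested varus angle", {
  neutral <- generate_knee_phantom(coarse_spec(varus_angle = 180, seed = 1))
  ang <- tibiamech:::angle_between_deg(neutral$truth$axis_femur,
                                       neutral$truth$axis_tibia)
  expect_lt(ang, 0.5)  # parallel axes at neutral alignment
  varus <- generate_knee_phantom(coarse_spec(varus_angle = 175, seed = 1))
  inter <- 180 - tibiamech:::angle_between_deg(varus$truth$axis_femur,
                                               varus$truth$axis_tibia)
  expect_lt(abs(inter - 175), 0.5)
  expect_equal(sqrt(sum(varus$truth$axis_femur^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(varus$truth$axis_tibia^2)), 1, tolerance = 1e-9)
})

test_that("bone and rod masks are disjoint and rods ordered by density", {
  ph <- generate_knee_phantom(coarse_spec(seed = 5))
  lab <- ph$truth$labels$data
  expect_true(all(lab %in% c(0, 1, 2, 3, 11, 12, 13)))
  rods <- rod_regions_from_geometry(ph$volume, ph$truth$rod_centres,
                                    ph$truth$rod_radius, ph$truth$rod_zrange)
  means <- vapply(rods, function(i) mean(ph$volume$data[i]), 0)
  expect_identical(order(means), order(ph$truth$rod_densities))
  expect_true(all(diff(means[order(ph$truth$rod_densities)]) > 0))
})

test_that("cohort draws reproduce the group body-mass distributions", {
  specs <- draw_cohort(7, 7, seed = 123, voxel_size = 2,
                       cortical_shell_mm = 4)
  mass <- vapply(specs, `[[`, 0, "body_mass")
  grp <- vapply(specs, `[[`, "", "group")
  # sampling error of a 7-subject mean is sd/sqrt(7) ~ 6 (OA) / 5 (normal)
  expect_lt(abs(mean(mass[grp == "OA"]) - 101), 18)
  expect_lt(abs(mean(mass[grp == "normal"]) - 72), 15)
  expect_true(all(vapply(specs[grp == "OA"], `[[`, 0, "varus_angle") <= 180))
})

test_that("too-coarse voxels for the cortical shell are rejected", {
  expect_error(phantom_spec(voxel_size = 2, cortical_shell_mm = 3),
               "coarse")
})

test_that("zero-noise repeats are bit-identical and transforms recorded", {
  ph <- generate_knee_phantom(coarse_spec(seed = 9))
  reps <- generate_repeat_scans(ph$volume,
                                repeat_noise_spec(0, 0, 0, 2, seed = 1))
  expect_identical(reps[[1]]$data, ph$volume$data)
  expect_identical(reps[[2]]$data, ph$volume$data)
  noisy1 <- generate_repeat_scans(ph$volume,
                                  repeat_noise_spec(1, 1, 0, 3, seed = 4))
  noisy2 <- generate_repeat_scans(ph$volume,
                                  repeat_noise_spec(1, 1, 0, 3, seed = 4))
  for (r in 1:3) {
    t1 <- attr(noisy1[[r]], "transform")
    t2 <- attr(noisy2[[r]], "transform")
    expect_identical(t1$rotation, t2$rotation)
    expect_identical(t1$translation, t2$translation)
    expect_equal(det(t1$rotation), 1, tolerance = 1e-9)
  }
  expect_false(identical(attr(noisy1[[1]], "transform")$translation,
                         attr(noisy1[[2]], "transform")$translation))
})

test_that("repeat intensity noise monotonically inflates a regional CV", {
  ph <- generate_knee_phantom(coarse_spec(seed = 2))
  tib <- ph$truth$labels$data == 1
  cvs <- vapply(c(2, 10, 40), function(sdv) {
    reps <- generate_repeat_scans(ph$volume,
                                  repeat_noise_spec(0, 0, sdv, 3, seed = 31))
    vals <- vapply(reps, function(v) mean(v$data[tib]), 0)
    cv_rms(list(vals))
  }, 0)
  expect_true(all(diff(cvs) > 0))
})

test_that("left knees are mirrored copies of the right-side geometry", {
  r <- generate_knee_phantom(coarse_spec(seed = 4, side = "right"))
  l <- generate_knee_phantom(coarse_spec(seed = 4, side = "left"))
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  expect_identical(l$volume$data, flip(r$volume$data))
  expect_equal(l$truth$axis_tibia[1], -r$truth$axis_tibia[1])
  std <- tibiamech:::standardize_side(list(volume = l$volume, truth = l$truth))
  expect_identical(std$volume$data, r$volume$data)
  expect_identical(std$truth$side, "right")
})
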