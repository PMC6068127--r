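make_flat_volume <- function(value, dim = c(8, 8, 8)) {
  density_volume(array(value, dim = dim), spacing = c(1, 1, 1))
}

test_that("two-point rod calibration is an exact line", {
  vol <- make_flat_volume(500)
  vol$data[1, 1, 1] <- 0
  vol$data[1, 1, 2] <- 1000
  out <- calibrate(vol, list(1L, which(vol$data == 1000)[1]), c(0, 400))
  expect_equal(out$model$slope, 0.4, tolerance = 1e-12)
  expect_equal(out$model$intercept, 0, tolerance = 1e-9)
  expect_equal(out$volume$data[2, 1, 1], 200, tolerance = 1e-9)
  expect_identical(out$volume$units, "mg_cm3")
})

test_that("three noiseless collinear rods give r_squared 1 and noisy phantom rods recover the generative slope", {
  vol <- make_flat_volume(0)
  vol$data[1:3, 1, 1] <- c(0, 500, 1000)
  out <- calibrate(vol, list(1L, 2L, 3L), c(0, 200, 400))
  expect_equal(out$model$r_squared, 1, tolerance = 1e-12)

  m <- coarse_model()
  expect_lt(abs(m$cal$model$slope - 0.8) / 0.8, 0.05)
  expect_gt(m$cal$model$r_squared, 0.999)
})

test_that("degenerate or double calibration is rejected", {
  vol <- make_flat_volume(100)
  expect_error(calibrate(vol, list(1L, 2L), c(0, 400)), "identical mean HU")
  cal <- make_flat_volume(100)
  cal$units <- "mg_cm3"
  expect_error(calibrate(cal, list(1L, 2L), c(0, 400)), "already calibrated")
  expect_error(calibrate(vol, list(integer(0), 2L), c(0, 400)), "empty")
})

test_that("calibration followed by its inverse is the identity", {
  m <- coarse_model()
  back <- uncalibrate(m$cal$volume, m$cal$model)
  ph <- m$phantom$volume
  expect_lt(max(abs(back$data - ph$data)) / max(abs(ph$data)), 1e-9)
})

test_that("HMH threshold is the midpoint of the probe levels", {
  vol <- make_flat_volume(0)
  vol$data[, , 5:8] <- 1000
  thr <- hmh_threshold(vol, which(vol$data == 1000), which(vol$data == 0))
  expect_equal(thr, 500)
  vol$data[vol$data == 0] <- 20
  vol$data[vol$data == 1000] <- 820
  expect_equal(hmh_threshold(vol, which(vol$data == 820),
                             which(vol$data == 20)), 420)
  expect_error(hmh_threshold(vol, which(vol$data == 20),
                             which(vol$data == 820)), "not above")
})

test_that("HMH localises a linear edge ramp at its 50% crossing", {
  # 1D ramp along z between background 100 and cortical 900
  nz <- 40
  ramp <- pmin(pmax((seq_len(nz) - 15) / 10, 0), 1) * 800 + 100
  vol <- density_volume(array(rep(ramp, each = 16), dim = c(4, 4, nz)),
                        spacing = c(1, 1, 1))
  thr <- hmh_threshold(vol, which(vol$data == 900), which(vol$data == 100))
  crossing <- min(which(ramp >= thr))
  expect_equal(ramp[crossing - 1] < thr, TRUE)
  expect_equal(crossing, 21, tolerance = 1)  # midpoint of the 15..25 ramp
})

test_that("HMH threshold is affine-equivariant in intensity", {
  m <- coarse_model()
  pr <- auto_probe_regions(m$cal$volume)
  t1 <- hmh_threshold(m$cal$volume, pr$bone_peak_region,
                      pr$background_region)
  scaled <- m$cal$volume
  scaled$data <- 3 * scaled$data + 17
  t2 <- hmh_threshold(scaled, pr$bone_peak_region, pr$background_region)
  expect_equal(t2, 3 * t1 + 17, tolerance = 1e-9)
})

test_that("segmentation recovers the generative masks (Dice >= 0.95)", {
  m <- coarse_model()
  for (b in 1:3) {
    truth <- m$phantom$truth$labels$data == b
    seg <- m$mask$labels == b
    dice <- 2 * sum(truth & seg) / (sum(truth) + sum(seg))
    expect_gt(dice, 0.95)
  }
})

test_that("segmentation rejects bad thresholds and background seeds", {
  m <- coarse_model()
  vol <- m$cal$volume
  expect_error(segment_bones(vol, max(vol$data) + 1, coarse_seeds),
               "range")
  expect_error(segment_bones(vol, m$threshold,
                             list(tibia = c(55, 40, -70))),
               "background")
})

test_that("axes of synthetic cylinders are recovered exactly and under rotation", {
  dims <- c(30, 30, 60)
  mk_mask <- function(rot_deg = 0) {
    x <- (seq_len(dims[1]) - 15.5) * 2
    y <- (seq_len(dims[2]) - 15.5) * 2
    z <- (seq_len(dims[3]) - 30.5) * 2
    X <- array(rep(x, times = dims[2] * dims[3]), dim = dims)
    Y <- array(rep(rep(y, each = dims[1]), dims[3]), dim = dims)
    Z <- array(rep(z, each = dims[1] * dims[2]), dim = dims)
    th <- rot_deg * pi / 180
    qx <- cos(th) * X - sin(th) * Z
    labels <- array(0L, dim = dims)
    labels[qx^2 + Y^2 <= 12^2 & Z < 0] <- 1L      # tibia below
    labels[qx^2 + Y^2 <= 12^2 & Z > 10] <- 2L     # femur above
    structure(list(labels = labels, spacing = c(2, 2, 2),
                   origin = c(min(x), min(y), min(z)),
                   orientation = diag(3), threshold_used = 0,
                   provenance = "synthetic"),
              class = "segmentation_mask")
  }
  ax <- fit_bone_axes(mk_mask(0))
  expect_lt(tibiamech:::angle_between_deg(ax$axis_tibia, c(0, 0, 1)), 1e-6)
  ax10 <- fit_bone_axes(mk_mask(10))
  truth <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_lt(tibiamech:::angle_between_deg(ax10$axis_tibia, truth), 0.5)
})

test_that("phantom axes are recovered within 1 degree of ground truth", {
  m <- coarse_model()
  t_err <- tibiamech:::angle_between_deg(m$axes$axis_tibia,
                                         m$phantom$truth$axis_tibia)
  f_err <- tibiamech:::angle_between_deg(m$axes$axis_femur,
                                         m$phantom$truth$axis_femur)
  expect_lt(t_err, 1)
  expect_lt(f_err, 1)
})

test_that("averaged-axis rule puts each axis at half the supplement from vertical", {
  mk <- function(varus) {
    half <- (180 - varus) / 2 * pi / 180
    list(f = c(sin(half), 0, cos(half)), t = c(-sin(half), 0, cos(half)))
  }
  for (varus in c(175, 180, 170)) {
    ax <- mk(varus)
    al <- realign_axes(ax$f, ax$t)
    expect_equal(al$angle_femur_vertical, (180 - varus) / 2,
                 tolerance = 1e-9)
    expect_equal(al$angle_tibia_vertical, (180 - varus) / 2,
                 tolerance = 1e-9)
    expect_equal(al$varus_angle, varus, tolerance = 1e-9)
    expect_equal(det(al$rotation), 1, tolerance = 1e-12)
  }
  expect_error(realign_axes(c(0, 0, 1), c(0, 0, -1)), "superior")
})

test_that("volume realignment preserves label counts and the inter-axis angle", {
  spec <- coarse_spec(group = "OA", varus_angle = 175, seed = 21)
  ph <- generate_knee_phantom(spec)
  rods <- rod_regions_from_geometry(ph$volume, ph$truth$rod_centres,
                                    ph$truth$rod_radius, ph$truth$rod_zrange)
  cal <- calibrate(ph$volume, rods, ph$truth$rod_densities)
  pr <- auto_probe_regions(cal$volume)
  thr <- hmh_threshold(cal$volume, pr$bone_peak_region, pr$background_region)
  mask <- segment_bones(cal$volume, thr, coarse_seeds)
  axes <- fit_bone_axes(mask)
  re <- realign(cal$volume, mask, axes)
  for (b in 1:3) {
    n0 <- sum(mask$labels == b)
    n1 <- sum(re$mask$labels == b)
    expect_lt(abs(n1 - n0) / n0, 0.02)
  }
  ax2 <- fit_bone_axes(re$mask)
  inter0 <- tibiamech:::angle_between_deg(axes$axis_femur, axes$axis_tibia)
  inter1 <- tibiamech:::angle_between_deg(ax2$axis_femur, ax2$axis_tibia)
  expect_lt(abs(inter0 - inter1), 0.5)
  # after re-alignment both axes make equal angles with vertical
  expect_equal(re$alignment$angle_femur_vertical,
               re$alignment$angle_tibia_vertical, tolerance = 1e-6)
})
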