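# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

# coarse analysis settings used throughout the tests: 2 mm voxels with a
# 4 mm cortical shell and 3 mm elements keep a full pipeline run ~5 s
coarse_config <- function(...) {
  args <- list(voxel_size = 2, cortical_shell_mm = 4, element_size = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(study_config, args)
}

coarse_spec <- function(...) {
  phantom_spec(voxel_size = 2, cortical_shell_mm = 4, ...)
}

coarse_seeds <- list(tibia = c(0, 0, -30), femur = c(0, -2, 35),
                     fibula = c(-42, -8, -40))

# neutral symmetric phantom, segmented and re-aligned
coarse_model <- function() fixture("coarse_model", function() {
  spec <- coarse_spec(group = "normal", varus_angle = 180, seed = 7)
  ph <- generate_knee_phantom(spec)
  rods <- rod_regions_from_geometry(ph$volume, ph$truth$rod_centres,
                                    ph$truth$rod_radius, ph$truth$rod_zrange)
  cal <- calibrate(ph$volume, rods, ph$truth$rod_densities)
  pr <- auto_probe_regions(cal$volume)
  thr <- hmh_threshold(cal$volume, pr$bone_peak_region, pr$background_region)
  mask <- segment_bones(cal$volume, thr, coarse_seeds)
  axes <- fit_bone_axes(mask)
  re <- realign(cal$volume, mask, axes)
  lm <- tibia_landmarks(re$mask)
  list(spec = spec, phantom = ph, cal = cal, threshold = thr, mask = mask,
       axes = axes, re = re, landmarks = lm)
})

# meshed + solved version of the coarse model
coarse_solution <- function() fixture("coarse_solution", function() {
  m <- coarse_model()
  cropped <- crop_to_joint(m$re$mask, m$landmarks, 50, 28)
  mesh <- build_mesh(cropped, 3, landmarks = m$landmarks)
  mats <- map_materials(mesh, m$re$volume)
  load <- load_case(body_mass = 72)
  res <- assemble_and_solve(mesh, mats, load)
  list(mesh = mesh, mats = mats, load = load, res = res,
       scaled = scale_to_bodyweight(res, load$body_weight))
})

# rectangular prism mesh (structured hex block), nx x ny x nz elements of
# size h, with `femur_top` (z max) and `tibia_distal` (z min) node sets
prism_mesh <- function(nx, ny, nz, h) {
  nn <- c(nx, ny, nz) + 1L
  nodes <- as.matrix(expand.grid(x = (0:nx) * h, y = (0:ny) * h,
                                 z = (0:nz) * h))
  gid <- function(i, j, k) (k - 1) * nn[1] * nn[2] + (j - 1) * nn[1] + i
  cells <- as.matrix(expand.grid(i = 1:nx, j = 1:ny, k = 1:nz))
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  conn <- sapply(1:8, function(c8)
    gid(cells[, 1] + off[c8, 1], cells[, 2] + off[c8, 2],
        cells[, 3] + off[c8, 3]))
  conn <- matrix(as.integer(conn), ncol = 8)
  ne <- nrow(conn)
  centroids <- cbind((cells[, 1] - 0.5) * h, (cells[, 2] - 0.5) * h,
                     (cells[, 3] - 0.5) * h)
  structure(list(
    nodes = nodes, conn = conn, type = "hex8",
    element_domain = factor(rep("tibia", ne),
                            levels = c("tibia", "femur", "fibula",
                                       "soft_tissue")),
    element_size = h, volumes = rep(h^3, ne), centroids = centroids,
    node_sets = list(
      femur_top = which(nodes[, 3] > nz * h - 1e-9),
      tibia_distal = which(nodes[, 3] < 1e-9)),
    grid = list(lo = c(0, 0, 0), ncell = c(nx, ny, nz),
                cell_key = (cells[, 3] - 1) * nx * ny +
                  (cells[, 2] - 1) * nx + cells[, 1])),
    class = "fe_mesh")
}

uniform_materials <- function(mesh, E, nu) {
  ne <- nrow(mesh$conn)
  structure(list(E = rep(E, ne), nu = rep(nu, ne), rho = rep(NA_real_, ne),
                 rigid = rep(FALSE, ne)), class = "material_field")
}

# brute-force two-sided Mann-Whitney p-value by permutation enumeration
brute_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  U_of <- function(ix) {
    xx <- all[ix]; yy <- all[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- U_of(seq_len(nx))
  mu <- nx * ny / 2
  combs <- utils::combn(nx + ny, nx)
  stat <- apply(combs, 2, U_of)
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-12)
}

slab_fixture <- function() fixture("slab", function() {
  # half-space with a flat top surface: 60 x 60 x 80 mm of "tibia",
  # 1 mm voxels; the bottom is > 35 mm from every band of interest
  dims <- c(60, 60, 80)
  labels <- array(1L, dim = dims)
  mask <- structure(list(labels = labels, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), orientation = diag(3),
                         threshold_used = 0, provenance = "synthetic"),
                    class = "segmentation_mask")
  lm <- tibia_landmarks(mask)
  mesh <- build_mesh(mask, 2, landmarks = lm, soft_tissue = FALSE)
  depth <- depth_volume(mask, 1L)
  list(mask = mask, lm = lm, mesh = mesh, depth = depth,
       map = assign_regions(mesh, depth, lm))
})

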