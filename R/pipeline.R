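#' Study configuration
#'
#' Serializable configuration for an end-to-end synthetic study: cohort
#' sizes, repeat-scan noise, phantom resolution, mesh/material/solver
#' settings and the master seed. A run is reproducible from the
#' configuration alone.
#'
#' @param n_oa,n_normal Group sizes (default 7 + 7).
#' @param n_repeats Repeat scans per subject (default 3).
#' @param translation_sd,rotation_sd,intensity_sd Repeat-scan noise
#'   (mm / degrees / HU).
#' @param voxel_size Phantom voxel size, mm.
#' @param cortical_shell_mm Phantom cortical shell thickness, mm.
#' @param element_size Bone element size for meshing, mm.
#' @param model_distal_mm,model_proximal_mm Analysis crop below/above the
#'   tibial plateau, mm (see [crop_to_joint()]).
#' @param do_stiffness Logical: run the two extra compartmental-stiffness
#'   solves per scan (default TRUE).
#' @param fe Material/solver configuration from [fe_config()].
#' @param seed Master seed (all randomness derives from it).
#' @param out_dir Optional output directory for CSV reports.
#' @return A `study_config` list.
#' @export
study_config <- function(n_oa = 7, n_normal = 7, n_repeats = 3,
                         translation_sd = 1, rotation_sd = 1,
                         intensity_sd = 5, voxel_size = 0.625,
                         cortical_shell_mm = 3, element_size = 2,
                         model_distal_mm = 50, model_proximal_mm = 28,
                         do_stiffness = TRUE,
                         fe = fe_config(), seed = 1L, out_dir = NULL) {
  structure(list(n_oa = n_oa, n_normal = n_normal, n_repeats = n_repeats,
                 translation_sd = translation_sd, rotation_sd = rotation_sd,
                 intensity_sd = intensity_sd, voxel_size = voxel_size,
                 cortical_shell_mm = cortical_shell_mm,
                 element_size = element_size,
                 model_distal_mm = model_distal_mm,
                 model_proximal_mm = model_proximal_mm,
                 do_stiffness = do_stiffness, fe = fe,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

with_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s | %s] %s", stage, id, conditionMessage(e)),
         call. = FALSE))
}

# mirror a left-knee phantom into the side-agnostic (+x medial) frame
standardize_side <- function(ph) {
  if (ph$truth$side != "left") return(ph)
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  ph$volume$data <- flip(ph$volume$data)
  ph$truth$labels$data <- flip(ph$truth$labels$data)
  ph$truth$axis_femur[1] <- -ph$truth$axis_femur[1]
  ph$truth$axis_tibia[1] <- -ph$truth$axis_tibia[1]
  ph$truth$rod_centres[, 1] <- -ph$truth$rod_centres[, 1]
  ph$truth$side <- "right"
  ph
}

#' Process one scan through the full FE pipeline
#'
#' calibrate -> HMH threshold -> segment -> fit axes -> re-align -> mesh ->
#' map materials -> solve -> scale to body weight -> regional metrics, plus
#' the two compartmental stiffness solves.
#'
#' @param scan A `density_volume` (HU), optionally carrying a `transform`
#'   attribute from [generate_repeat_scans()].
#' @param truth Phantom ground truth (rod geometry, used to place rod
#'   sampling regions and bone seed points).
#' @param body_mass Subject body mass, kg.
#' @param config A [study_config()].
#' @param id Label used in error messages.
#' @return List: `metrics` (regional data frame), `stiffness` (medial /
#'   lateral N/mm), `alignment`, `calibration`, `threshold`, `mesh_size`.
#' @export
process_scan <- function(scan, truth, body_mass, config = study_config(),
                         id = "scan") {
  tf <- attr(scan, "transform")
  rods <- with_stage("calibrate", id,
    rod_regions_from_geometry(scan, truth$rod_centres, truth$rod_radius,
                              truth$rod_zrange, transform = tf))
  cal <- with_stage("calibrate", id,
    calibrate(scan, rods, truth$rod_densities))
  thr <- with_stage("hmh_threshold", id, {
    pr <- auto_probe_regions(cal$volume)
    hmh_threshold(cal$volume, pr$bone_peak_region, pr$background_region)
  })
  seeds <- with_stage("segment", id, {
    lab <- truth$labels
    sds <- lapply(1:3, function(b) {
      ijk <- which(lab$data == b, arr.ind = TRUE)
      ctr <- voxel_to_world(lab, matrix(colMeans(ijk), ncol = 3))
      if (!is.null(tf))
        ctr <- sweep((ctr - matrix(tf$centre, 1, 3)) %*% t(tf$rotation), 2,
                     tf$centre + tf$translation, `+`)
      as.numeric(ctr)
    })
    names(sds) <- c("tibia", "femur", "fibula")
    sds
  })
  mask <- with_stage("segment", id, segment_bones(cal$volume, thr, seeds))
  axes <- with_stage("fit_axes", id, fit_bone_axes(mask))
  re <- with_stage("realign", id, realign(cal$volume, mask, axes))
  lm <- with_stage("landmarks", id, tibia_landmarks(re$mask))
  cropped <- with_stage("mesh", id,
    crop_to_joint(re$mask, lm, config$model_distal_mm,
                  config$model_proximal_mm))
  mesh <- with_stage("mesh", id,
    build_mesh(cropped, config$element_size, mode = "hex_voxel",
               landmarks = lm))
  mats <- with_stage("materials", id, map_materials(mesh, re$volume,
                                                    config$fe))
  load <- load_case(displacement = config$fe$displacement_mm,
                    body_mass = body_mass, g = config$fe$g)
  res <- with_stage("solve", id, assemble_and_solve(mesh, mats, load))
  scaled <- with_stage("scale", id,
                       scale_to_bodyweight(res, load$body_weight))
  depth <- with_stage("regions", id, depth_volume(re$mask, 1L))
  vox_map <- with_stage("regions", id, voxel_region_map(depth, lm))
  metrics <- with_stage("regions", id,
                        probe_regional_metrics(mesh, scaled, vox_map))
  stiff <- if (isTRUE(config$do_stiffness))
    with_stage("stiffness", id,
               compartment_stiffness(mesh, mats, load, "both"))
  else c(medial = NA_real_, lateral = NA_real_)
  list(metrics = metrics, stiffness = stiff, alignment = re$alignment,
       calibration = cal$model, threshold = thr,
       mesh_size = nrow(mesh$conn))
}

#' Run one subject (phantom + repeat scans) through the pipeline
#'
#' @param spec A [phantom_spec()].
#' @param noise A [repeat_noise_spec()].
#' @param config A [study_config()].
#' @param id Subject label for error messages.
#' @return List with per-repeat `metrics` (list of data frames), `stiffness`
#'   (n_repeats x 2 matrix), the phantom `truth` summary and the spec.
#' @export
run_subject <- function(spec, noise, config = study_config(), id = "subject") {
  ph <- with_stage("phantom", id, generate_knee_phantom(spec))
  ph <- standardize_side(ph)
  scans <- with_stage("repeats", id, generate_repeat_scans(ph$volume, noise))
  reps <- vector("list", length(scans))
  for (r in seq_along(scans)) {
    reps[[r]] <- process_scan(scans[[r]], ph$truth, spec$body_mass, config,
                              id = paste0(id, "/repeat", r))
  }
  stiff <- do.call(rbind, lapply(reps, `[[`, "stiffness"))
  list(metrics = lapply(reps, `[[`, "metrics"), stiffness = stiff,
       spec = spec, group = spec$group, body_mass = spec$body_mass)
}

metric_names <- function() c("min_principal_stress", "von_mises_stress",
                             "min_principal_strain", "von_mises_strain")

# per-subject repeat values for one region x metric as a list of vectors
# (NA where a repeat's mesh produced no elements in the region)
extract_repeats <- function(subjects, region, metric) {
  lapply(subjects, function(s)
    vapply(s$metrics, function(m) {
      v <- m$mean[m$region == region & m$metric == metric]
      if (length(v)) v else NA_real_
    }, 0))
}

#' Run a full synthetic precision + group-comparison study
#'
#' Generates the cohort, runs every subject and repeat through the FE
#' pipeline, and assembles the study tables: per-region CV%RMS precision for
#' each metric, OA-vs-normal comparison tables for minimum principal stress
#' and strain, and the compartmental stiffness comparison. Subjects whose
#' pipeline fails are flagged and excluded rather than aborting the study.
#'
#' @param config A [study_config()].
#' @return A `study_tables` list: `precision`, `stress_comparison`,
#'   `strain_comparison`, `stiffness_comparison`, `summary`, `excluded`.
#'   If `config$out_dir` is set the tables are also written as CSV.
#' @export
run_study <- function(config = study_config()) {
  specs <- draw_cohort(config$n_oa, config$n_normal, seed = config$seed,
                       voxel_size = config$voxel_size,
                       cortical_shell_mm = config$cortical_shell_mm)
  subjects <- list(); excluded <- character()
  for (i in seq_along(specs)) {
    id <- sprintf("s%02d_%s", i, specs[[i]]$group)
    noise <- repeat_noise_spec(config$translation_sd, config$rotation_sd,
                               config$intensity_sd, config$n_repeats,
                               seed = specs[[i]]$seed + 500L)
    subjects[[id]] <- tryCatch(
      run_subject(specs[[i]], noise, config, id = id),
      error = function(e) {
        warning("subject ", id, " excluded: ", conditionMessage(e))
        NULL
      })
    if (is.null(subjects[[id]])) excluded <- c(excluded, id)
  }
  subjects <- Filter(Negate(is.null), subjects)
  if (length(subjects) < 2) stop("too few subjects completed the pipeline")
  groups <- vapply(subjects, `[[`, "", "group")

  regions <- region_levels()
  precision <- list()
  for (mn in metric_names()) {
    cvs <- vapply(regions, function(rg) {
      vals <- extract_repeats(subjects, rg, mn)
      vals <- vals[lengths(vals) >= 2 & !vapply(vals, anyNA, TRUE)]
      if (!length(vals)) return(NA_real_)
      cv_rms(vals)
    }, 0)
    precision[[mn]] <- data.frame(region = regions, metric = mn,
                                  cv_rms = cvs, row.names = NULL)
  }
  stiff_cv <- vapply(1:2, function(cc) {
    vals <- lapply(subjects, function(s) s$stiffness[, cc])
    vals <- vals[lengths(vals) >= 2 & !vapply(vals, anyNA, TRUE)]
    if (!length(vals)) return(NA_real_)
    cv_rms(vals)
  }, 0)
  precision$stiffness <- data.frame(
    region = c("medial compartment", "lateral compartment"),
    metric = "stiffness", cv_rms = stiff_cv, row.names = NULL)
  precision <- do.call(rbind, precision)
  rownames(precision) <- NULL

  comparison_table <- function(metric) {
    rows <- lapply(regions, function(rg) {
      per_rep <- extract_repeats(subjects, rg, metric)
      submeans <- vapply(per_rep, mean, 0)
      ok <- !is.na(submeans)
      all_scans <- unlist(per_rep)[!is.na(unlist(per_rep))]
      cmp <- compare_groups(submeans[ok & groups == "OA"],
                            submeans[ok & groups == "normal"],
                            sd_for_d = stats::sd(all_scans))
      cbind(data.frame(region = rg, metric = metric,
                       all_mean = mean(all_scans), all_sd = stats::sd(all_scans),
                       cv_rms = precision$cv_rms[precision$region == rg &
                                                   precision$metric == metric]),
            cmp)
    })
    do.call(rbind, rows)
  }
  stress_cmp <- comparison_table("min_principal_stress")
  strain_cmp <- comparison_table("min_principal_strain")

  stiff_rows <- lapply(1:2, function(cc) {
    per_rep <- lapply(subjects, function(s) s$stiffness[, cc])
    submeans <- vapply(per_rep, mean, 0)
    ok <- !is.na(submeans)
    if (sum(ok & groups == "OA") < 2 || sum(ok & groups == "normal") < 2)
      return(NULL)
    all_scans <- unlist(per_rep)[!is.na(unlist(per_rep))]
    cmp <- compare_groups(submeans[ok & groups == "OA"],
                          submeans[ok & groups == "normal"],
                          sd_for_d = stats::sd(all_scans))
    cbind(data.frame(region = c("medial compartment",
                                "lateral compartment")[cc],
                     metric = "stiffness",
                     all_mean = mean(all_scans), all_sd = stats::sd(all_scans),
                     cv_rms = stiff_cv[cc]),
          cmp)
  })
  stiffness_cmp <- do.call(rbind, Filter(Negate(is.null), stiff_rows))

  summary <- lapply(split(precision, precision$metric), summarize_precision)
  out <- structure(list(precision = precision,
                        stress_comparison = stress_cmp,
                        strain_comparison = strain_cmp,
                        stiffness_comparison = stiffness_cmp,
                        summary = summary, excluded = excluded,
                        config = config),
                   class = "study_tables")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(precision, file.path(config$out_dir, "precision.csv"),
                     row.names = FALSE)
    write_comparison_csv(stress_cmp,
                         file.path(config$out_dir, "stress_comparison.csv"))
    write_comparison_csv(strain_cmp,
                         file.path(config$out_dir, "strain_comparison.csv"))
    write_comparison_csv(stiffness_cmp,
                         file.path(config$out_dir, "stiffness_comparison.csv"))
  }
  out
}

#' Mesh-refinement (convergence) study on one model
#'
#' Builds and solves the same re-aligned model at a sequence of bone element
#' sizes and reports regional metric means per size plus the maximum
#' absolute relative change between successive sizes.
#'
#' @param re Re-aligned scan: list with `volume` (calibrated) and `mask`
#'   as returned by [realign()].
#' @param sizes Decreasing element sizes, mm (e.g. `c(2, 1.8)`).
#' @param body_mass Body mass, kg.
#' @param config A [study_config()].
#' @return List: `metrics` (list per size), `max_rel_change_pct` (vector,
#'   one per refinement step, over all regions and metrics).
#' @export
mesh_refinement_study <- function(re, sizes, body_mass,
                                  config = study_config()) {
  lm <- tibia_landmarks(re$mask)
  depth <- depth_volume(re$mask, 1L)
  vox_map <- voxel_region_map(depth, lm)
  cropped <- crop_to_joint(re$mask, lm, config$model_distal_mm,
                           config$model_proximal_mm)
  runs <- lapply(sizes, function(h) {
    mesh <- build_mesh(cropped, h, mode = "hex_voxel", landmarks = lm)
    mats <- map_materials(mesh, re$volume, config$fe)
    load <- load_case(displacement = config$fe$displacement_mm,
                      body_mass = body_mass, g = config$fe$g)
    res <- scale_to_bodyweight(assemble_and_solve(mesh, mats, load),
                               load$body_weight)
    list(metrics = probe_regional_metrics(mesh, res, vox_map),
         n_elements = nrow(mesh$conn))
  })
  deltas <- vapply(seq_len(length(sizes) - 1), function(s) {
    a <- runs[[s]]$metrics; b <- runs[[s + 1]]$metrics
    m <- merge(a, b, by = c("region", "metric"))
    max(abs((m$mean.y - m$mean.x) / m$mean.x)) * 100
  }, 0)
  list(metrics = runs, max_rel_change_pct = deltas, sizes = sizes)
}
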