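# End-to-end orchestration: validated YAML configuration, the segmentation
# pipeline (threshold -> fill -> crown removal -> frame -> planes ->
# partition -> volumes) and the desk-scale study run (cohort simulation +
# statistical report). Every run writes its resolved configuration, package
# version and seeds beside the outputs so reports are regenerable.

pipeline_config_defaults <- function() {
  list(
    image = NULL, mask = NULL,
    landmarks = NULL, landmarks_format = "json", ras = FALSE,
    threshold_lower = 500, threshold_upper = Inf,
    closing_radius_mm = 1.0,
    crown_clip = NULL,           # list(normal =, point =) or NULL to skip
    bisector_parents = "ramus_base",
    tilt_deg = 6,
    alpha = 0.05, posthoc = "bonferroni",
    cohort_sizes = "table", rho = 0.8,
    seed = 1,
    out_dir = NULL
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration from defaults, an optional YAML file and
#' direct overrides (highest precedence). Unknown keys are rejected.
#'
#' @param path optional YAML file.
#' @param ... direct overrides of config fields.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- pipeline_config_defaults()
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s) in ", src, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "call")
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$closing_radius_mm >= 0,
            cfg$threshold_lower <= cfg$threshold_upper,
            cfg$posthoc %in% c("bonferroni", "tukey"),
            cfg$bisector_parents %in% c("ramus_base", "ramus_cpoint"))
  class(cfg) <- "pipeline_config"
  cfg
}

write_resolved_config <- function(cfg, out_dir, extra = list()) {
  resolved <- unclass(cfg)
  resolved$package_version <- as.character(utils::packageVersion("mandivol"))
  resolved <- c(resolved, extra)
  resolved <- lapply(resolved, function(x) if (is.null(x)) NA else x)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
}

stage_log <- function(log, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  c(log, line)
}

#' Run the segmentation pipeline
#'
#' Reads an image (or binary mask) and a landmark file, then applies the
#' stages in order: threshold (grayscale input only), internal-cavity fill,
#' crown removal (if a clip plane is configured), reference-frame and
#' cutting-plane construction, voxel partition, volume computation. Writes
#' `labels.nii.gz` (+ JSON sidecar), `volumes.csv`, `volumes.json`, a stage
#' log and the resolved config into `out_dir`.
#'
#' @param config a [pipeline_config()]; needs `image` or `mask`,
#'   `landmarks`, and `out_dir`.
#' @param landmarks optional in-memory [landmark_set()] overriding the file.
#' @param volume optional in-memory [vol3d()] overriding the file.
#' @param crown_clip optional in-memory [plane3()] (or per-side list)
#'   overriding the config.
#' @return Invisibly, a list with `volumes` (a `segment_volumes`), `labels`
#'   (a [label_map()]) and `log`.
#' @export
cmd_segment <- function(config, landmarks = NULL, volume = NULL,
                        crown_clip = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()

  if (is.null(landmarks)) {
    if (is.null(config$landmarks)) stop("no landmarks given", call. = FALSE)
    if (!file.exists(config$landmarks)) {
      stop("landmark file not found: ", config$landmarks, call. = FALSE)
    }
    landmarks <- switch(config$landmarks_format,
      json = read_landmarks_json(config$landmarks, ras = isTRUE(config$ras)),
      fcsv = read_landmarks_fcsv(config$landmarks),
      stop("unknown landmarks_format: ", config$landmarks_format,
           call. = FALSE))
  }
  log <- stage_log(log, "landmarks", "12 landmarks loaded")

  if (is.null(volume)) {
    src <- if (!is.null(config$mask)) config$mask else config$image
    if (is.null(src)) stop("no image or mask given", call. = FALSE)
    if (!file.exists(src)) stop("volume file not found: ", src, call. = FALSE)
    volume <- read_volume(src, binary = !is.null(config$mask))
  }
  if (is.logical(volume$values)) {
    mask <- volume
    log <- stage_log(log, "input", "binary mask: %d foreground voxels",
                     sum(mask$values))
  } else {
    mask <- threshold_mask(volume, config$threshold_lower,
                           config$threshold_upper)
    log <- stage_log(log, "threshold", "[%g, %g] -> %d foreground voxels",
                     config$threshold_lower, config$threshold_upper,
                     sum(mask$values))
  }

  filled <- fill_internal_cavities(mask, config$closing_radius_mm)
  log <- stage_log(log, "fill", "closing %g mm; %d -> %d foreground voxels",
                   config$closing_radius_mm, sum(mask$values),
                   sum(filled$values))

  frame <- build_reference_frame(landmarks, tilt_deg = config$tilt_deg)
  planes_L <- build_mandibular_planes(landmarks, frame, "L",
                                      config$bisector_parents)
  planes_R <- build_mandibular_planes(landmarks, frame, "R",
                                      config$bisector_parents)
  log <- stage_log(log, "planes", "reference frame and cutting planes built")

  if (is.null(crown_clip) && !is.null(config$crown_clip)) {
    cc <- config$crown_clip
    crown_clip <- plane3(unlist(cc$normal), unlist(cc$point),
                         label = "crown_clip")
  }
  if (!is.null(crown_clip)) {
    before <- sum(filled$values)
    filled <- remove_crowns(filled, crown_clip, median = planes_L$median)
    log <- stage_log(log, "crowns", "removed %d crown voxels",
                     before - sum(filled$values))
  } else {
    log <- stage_log(log, "crowns", "no clip plane configured; skipped")
  }

  labels <- partition_mandible(filled, planes_L, planes_R, landmarks)
  nlab <- sum(labels$values > 0L)
  log <- stage_log(log, "partition", "%d voxels labelled (input %d)",
                   nlab, sum(filled$values))
  vols <- compute_volumes(labels)

  write_label_map(labels, file.path(config$out_dir, "labels.nii.gz"))
  write_segment_volumes(vols,
                        csv = file.path(config$out_dir, "volumes.csv"),
                        json = file.path(config$out_dir, "volumes.json"))
  writeLines(log, file.path(config$out_dir, "segment.log"))
  write_resolved_config(config, config$out_dir)
  invisible(list(volumes = vols, labels = labels, log = log))
}

#' Run the desk-scale study
#'
#' Simulates the three arms from [default_calibration()] at the configured
#' sizes and seed, computes the [full_study_report()], and writes
#' `report.json`, `group_means.csv`, `cohort_*.csv` and the resolved config
#' to `out_dir`. Deterministic given the seed.
#'
#' @param config a [pipeline_config()]; uses `alpha`, `posthoc`,
#'   `cohort_sizes`, `rho`, `seed`, `out_dir`.
#' @return Invisibly, a list with `report`, `cohorts` and `group_means`.
#' @export
cmd_run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- default_calibration(sizes = config$cohort_sizes, rho = config$rho)
  seeds <- config$seed + c(uni_jia = 11L, bil_jia = 22L, control = 33L)
  cohorts <- lapply(names(cal), function(g) {
    simulate_cohort(cal[[g]], seed = seeds[[g]])
  })
  names(cohorts) <- names(cal)
  report <- suppressWarnings(
    full_study_report(cohorts, alpha = config$alpha,
                      posthoc_method = config$posthoc))
  gm <- do.call(rbind, lapply(names(cohorts), function(g) {
    d <- cohort_group_means(cohorts[[g]])
    d$group <- g
    d
  }))
  for (g in names(cohorts)) {
    utils::write.csv(cohorts[[g]],
                     file.path(config$out_dir, paste0("cohort_", g, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(gm, file.path(config$out_dir, "group_means.csv"),
                   row.names = FALSE)
  report_to_json(report, file.path(config$out_dir, "report.json"))
  write_resolved_config(config, config$out_dir,
                        extra = list(cohort_seeds = as.list(seeds)))
  invisible(list(report = report, cohorts = cohorts, group_means = gm))
}

#' End-to-end phantom segmentation
#'
#' Convenience wrapper used by tests and examples: generates (or accepts) a
#' phantom, runs the full segmentation pipeline on its mask with its exact
#' landmarks and clip plane, and returns measured and ground-truth volumes.
#'
#' @param phantom a [generate_phantom()] result (or a [phantom_spec()]).
#' @param closing_radius_mm closing radius for the cavity fill. The
#'   phantom's canal is fully internal, so `0` (plain hole fill) reproduces
#'   the reference solid exactly.
#' @param bisector_parents passed to [build_mandibular_planes()].
#' @return List with `measured` and `truth` (`segment_volumes`), `labels`
#'   and the `phantom`.
#' @export
segment_phantom <- function(phantom, closing_radius_mm = 0,
                            bisector_parents = "ramus_base") {
  if (inherits(phantom, "phantom_spec")) {
    phantom <- generate_phantom(phantom, image = FALSE)
  }
  stopifnot(inherits(phantom, "mandible_phantom"))
  filled <- fill_internal_cavities(phantom$mask, closing_radius_mm)
  frame <- build_reference_frame(phantom$landmarks)
  pl <- build_mandibular_planes(phantom$landmarks, frame, "L",
                                bisector_parents)
  pr <- build_mandibular_planes(phantom$landmarks, frame, "R",
                                bisector_parents)
  clipped <- remove_crowns(filled, phantom$crown_clip, median = pl$median)
  labels <- partition_mandible(clipped, pl, pr, phantom$landmarks)
  list(measured = compute_volumes(labels), truth = phantom$truth,
       labels = labels, phantom = phantom)
}
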