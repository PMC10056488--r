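#' Default run configuration
#'
#' Every tunable of the analysis modules, with its default. Configurations
#' are validated strictly: unknown keys are rejected, and the configuration
#' used for a run is serialized alongside its outputs for provenance.
#'
#' @return named list of parameters.
#' @export
run_config <- function() {
  list(
    seed = 1L,
    # OCT border segmentation
    bilateral_sigma_spatial = 5, bilateral_sigma_range = 0.1,
    lumen_speed_eps = 0.01, lumen_closure_tol = 3L, lumen_overlap_rows = 8L,
    adventitia_thickness_px = 31, adventitia_threshold = 0.05,
    adventitia_sd_window = 11L,
    guidewire_shadow_frac = 0.4, guidewire_corner_quantile = 0.9,
    # strut detection
    strut_percentile = 99.5, strut_min_shadow_len = 60, strut_max_slope = 0.08,
    strut_shadow_frac = 0.2, strut_peak_gap = 10,
    dbscan_eps = 0.15, dbscan_min_pts = 1L,
    bvs_threshold = 0.15, bvs_area_min = 10, bvs_area_max = 40,
    bvs_max_aspect = 5, bvs_band_width = 10,
    # CTCA
    vesselness_scales = c(1, 1.5, 2), centerline_eps = 0.05,
    levelset_kappa = 0.2, levelset_dt = 0.4, levelset_max_iter = 500L,
    levelset_tol = 1e-3, levelset_roi_radius = 5,
    stent_station_mm = 0.5, stent_run_threshold = 0.1,
    # fusion
    frame_step_mm = 0.5, ring_size = 72L, strut_link_dist = 0.3,
    mesh_smooth = FALSE, mesh_smooth_lambda = 0.1, mesh_smooth_iters = 5L,
    # metrics
    strut_thickness = 0.1, malappose_threshold = 0.1, fracture_gap_frames = 3L,
    # patches
    patch_px = 25L, patches_per_frame = 1000L, train_fraction = 0.7
  )
}

#' Load a YAML run configuration
#'
#' Values override the defaults of [run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file (optional; NULL gives the defaults).
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(user)] <- user
  cfg
}

#' Save the configuration used by a run next to its outputs
#' @param cfg configuration list.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
save_config <- function(cfg, dir) {
  path <- file.path(dir, "run_config.yaml")
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(cfg, tmp)
  file.rename(tmp, path)
  invisible(path)
}
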