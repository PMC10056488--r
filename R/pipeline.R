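# High-level pipeline drivers tying the modules together; these back the
# command-line interface and keep scripts short.

#' Segment lumen and adventitia borders across a pullback
#'
#' Per frame: guidewire removal, bilateral denoising, fast-marching lumen
#' segmentation, adventitia segmentation. Deterministic: repeated runs on
#' the same frames are bit-identical.
#'
#' @param frames list of [polar_frame()].
#' @param cfg configuration from [run_config()] / [load_config()].
#' @param adventitia also segment the outer border.
#' @return list per frame: `lumen`, `adventitia` (or NULL), `mask`.
#' @export
segment_pullback <- function(frames, cfg = run_config(), adventitia = TRUE) {
  lapply(frames, function(fr) {
    gw <- remove_guidewire(fr, cfg$guidewire_shadow_frac,
                           cfg$guidewire_corner_quantile)
    den <- bilateral_denoise(fr, cfg$bilateral_sigma_spatial,
                             cfg$bilateral_sigma_range)
    lum <- segment_lumen(den, gw$mask, eps = cfg$lumen_speed_eps,
                         closure_tol = cfg$lumen_closure_tol,
                         overlap_rows = cfg$lumen_overlap_rows)
    adv <- if (adventitia)
      segment_adventitia(fr, lum, thickness_px = cfg$adventitia_thickness_px,
                         threshold = cfg$adventitia_threshold,
                         sd_window = cfg$adventitia_sd_window,
                         sigma_spatial = cfg$bilateral_sigma_spatial,
                         sigma_range = cfg$bilateral_sigma_range)
    else NULL
    list(lumen = lum, adventitia = adv, mask = gw$mask)
  })
}

#' Detect and cluster metallic struts across a pullback
#'
#' @param frames list of [polar_frame()].
#' @param segs output of [segment_pullback()] (provides lumen contours and
#'   guidewire sectors).
#' @param cfg configuration list.
#' @return strut cloud data frame (one row per clustered strut).
#' @export
detect_struts_pullback <- function(frames, segs, cfg = run_config()) {
  params <- strut_params(percentile = cfg$strut_percentile,
                         min_shadow_len = cfg$strut_min_shadow_len,
                         max_slope = cfg$strut_max_slope,
                         shadow_frac = cfg$strut_shadow_frac,
                         peak_gap = cfg$strut_peak_gap,
                         dbscan_eps = cfg$dbscan_eps,
                         dbscan_min_pts = cfg$dbscan_min_pts,
                         bvs_threshold = cfg$bvs_threshold,
                         bvs_area_range = c(cfg$bvs_area_min, cfg$bvs_area_max),
                         bvs_max_aspect = cfg$bvs_max_aspect,
                         bvs_band_width = cfg$bvs_band_width)
  out <- NULL
  for (i in seq_along(frames)) {
    cand <- detect_metal_candidates(frames[[i]], segs[[i]]$lumen, params)
    out <- rbind(out, cluster_struts(cand, frames[[i]], params))
  }
  if (is.null(out))
    out <- data.frame(frame = integer(0), aline = numeric(0),
                      depth_px = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), cluster = integer(0),
                      type = character(0))
  out
}

#' Per-frame vessel metrics across a pullback
#'
#' @param segs output of [segment_pullback()].
#' @param radial_spacing mm/px.
#' @return data frame, one row per frame: lumen/wall areas (mm^2) and
#'   perimeters (mm), plaque burden (%).
#' @export
vessel_metrics_pullback <- function(segs, radial_spacing) {
  out <- NULL
  for (i in seq_along(segs)) {
    lp <- contour_to_polygon(segs[[i]]$lumen, radial_spacing)
    lm <- contour_metrics(lp)
    row <- data.frame(frame = i, lumen_area_mm2 = lm$area,
                      lumen_perimeter_mm = lm$perimeter,
                      wall_area_mm2 = NA_real_, wall_perimeter_mm = NA_real_,
                      plaque_burden_pct = NA_real_)
    if (!is.null(segs[[i]]$adventitia)) {
      wp <- contour_to_polygon(segs[[i]]$adventitia, radial_spacing)
      wm <- contour_metrics(wp)
      row$wall_area_mm2 <- wm$area
      row$wall_perimeter_mm <- wm$perimeter
      row$plaque_burden_pct <- plaque_burden(lp, wp)
    }
    out <- rbind(out, row)
  }
  out
}

#' Fuse a segmented pullback onto a centerline and compare model vs frames
#'
#' Places the per-frame lumen contours along the (framed) centerline,
#' lofts the surface mesh, slices it every `station_mm`, registers stations
#' to frames through the landmarks, and reports correlation/RSS/Bland-Altman
#' agreement between model cross-sections and the 2D analysis.
#'
#' @param segs output of [segment_pullback()].
#' @param cl centerline ([centerline3d()] or n x 3 matrix).
#' @param radial_spacing mm/px.
#' @param frame_spacing mm between frames.
#' @param landmarks data frame with `arclength`, `frame` (>= 2 rows);
#'   defaults to the identity registration at both pullback ends.
#' @param cfg configuration list.
#' @return list: `mesh`, `centerline`, `comparison` (series + report).
#' @export
fuse_and_compare <- function(segs, cl, radial_spacing, frame_spacing,
                             landmarks = NULL, cfg = run_config()) {
  clf <- build_frames(cl, step = cfg$frame_step_mm)
  contours <- lapply(segs, function(s) contour_to_polygon(s$lumen, radial_spacing))
  placed <- place_contours(contours, clf, frame_spacing, 0, cfg$ring_size)
  mesh <- loft_mesh(placed$rings, smooth = cfg$mesh_smooth,
                    lambda = cfg$mesh_smooth_lambda,
                    smooth_iters = cfg$mesh_smooth_iters)
  areas <- vapply(contours, function(p) contour_metrics(p)$area, numeric(1))
  frame_series <- data.frame(frame = seq_along(contours), area_mm2 = areas)
  if (is.null(landmarks)) {
    n <- length(contours)
    landmarks <- data.frame(arclength = c(0, (n - 1) * frame_spacing),
                            frame = c(1, n))
  }
  comparison <- compare_model_to_frames(mesh, clf, frame_series, landmarks,
                                        station_mm = 0.5)
  list(mesh = mesh, centerline = clf, comparison = comparison)
}

#' Segment a CTCA volume end to end
#'
#' Vesselness preprocessing, minimum-cost-path centerline between the seeds,
#' weight calibration from the annotations, level-set segmentation, and
#' stent detection.
#'
#' @param vol a [volume3d()].
#' @param seeds list of voxel-index matrices per class (lumen, wall, cp; see
#'   [calibrate_weights()]).
#' @param start,end centerline seed voxels (1-based c(x, y, z)).
#' @param cfg configuration list.
#' @return list: `vesselness`, `centerline`, `weights`, `segmentation`,
#'   `stent`.
#' @export
segment_ctca <- function(vol, seeds, start, end, cfg = run_config()) {
  ves <- vesselness_preprocess(vol, cfg$vesselness_scales)
  cl <- extract_centerline(ves, start, end, eps = cfg$centerline_eps)
  w <- calibrate_weights(vol, seeds)
  seg <- levelset_segment(vol, w, cl, kappa = cfg$levelset_kappa,
                          dt = cfg$levelset_dt,
                          max_iter = cfg$levelset_max_iter,
                          tol = cfg$levelset_tol,
                          roi_radius = cfg$levelset_roi_radius)
  stent <- detect_stent_ctca(vol, seg$lumen_mask, cl,
                             station_mm = cfg$stent_station_mm,
                             run_threshold = cfg$stent_run_threshold)
  lab <- seg$labels
  lab$labels[stent$stent_voxels] <- LABELS["stent"]
  list(vesselness = ves, centerline = cl, weights = w,
       segmentation = seg, stent = stent, labels = lab)
}

#' Dice overlap of two equal-center radial contours
#'
#' For star-shaped regions sharing the catheter center, per-A-line wedge
#' areas are proportional to the squared radii, so
#' `Dice = 2 sum min(r1, r2)^2 / (sum r1^2 + sum r2^2)`.
#'
#' @param r1,r2 per-A-line radius vectors (same length, any common unit).
#' @return Dice similarity in [0, 1].
#' @export
radial_dice <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  2 * sum(pmin(r1, r2)^2) / (sum(r1^2) + sum(r2^2))
}

#' Dice overlap of two logical masks
#' @param a,b logical arrays of equal dimension.
#' @return Dice similarity in [0, 1].
#' @export
mask_dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Symmetric Hausdorff distance between two radial contours (mm)
#'
#' Computed between the polygonal cartesian traces of the two contours.
#'
#' @param r1,r2 per-A-line radius vectors in px.
#' @param radial_spacing mm/px.
#' @return Hausdorff distance in mm.
#' @export
radial_hausdorff <- function(r1, r2, radial_spacing) {
  n <- length(r1)
  th <- 2 * pi * (seq_len(n) - 1) / n
  p1 <- cbind(r1 * cos(th), r1 * sin(th)) * radial_spacing
  p2 <- cbind(r2 * cos(th), r2 * sin(th)) * radial_spacing
  d <- as.matrix(dist(rbind(p1, p2)))[seq_len(n), n + seq_len(n)]
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}
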