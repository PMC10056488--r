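#' Specification of a synthetic OCT pullback phantom
#'
#' The phantom emulates the imaging features the OCT pipeline keys on: a dark
#' lumen interior, a bright intima ridge at the true lumen radius, a speckled
#' tissue band, a dark media ring ending at the true adventitia radius, a
#' guidewire reflection with a full-depth shadow, metallic struts as bright
#' blooms with full-depth shadows, and BVS struts as bright-rimmed dark boxes
#' at the lumen border. It makes no attempt at physically realistic light
#' transport.
#'
#' @param n_frames number of frames in the pullback.
#' @param n_alines A-lines per frame (rows).
#' @param n_depth depth samples per A-line (columns).
#' @param radial_spacing radial pixel size, mm/px.
#' @param lumen_radius_profile function of the frame index returning the lumen
#'   radius in mm: either one scalar (circular lumen) or a vector of length
#'   `n_alines` (per-A-line radii, e.g. an ellipse).
#' @param wall_thickness distance from lumen border to adventitia border, mm.
#' @param media_thickness thickness of the dark media ring (the outermost part
#'   of the wall), mm.
#' @param guidewire_angle center angle of the guidewire sector in degrees, or
#'   `NA` for no guidewire.
#' @param guidewire_width angular width of the wire shadow sector, degrees.
#' @param strut_layout data frame with columns `frame`, `angle` (degrees),
#'   `depth` (mm from catheter center), `type` ("metal" or "BVS"); or NULL.
#' @param malapposed_offsets per-strut radial offset in mm; positive moves the
#'   strut toward the catheter (away from the wall, i.e. malapposed).
#' @param speckle_grain correlation length of the multiplicative speckle, px.
#' @param noise_seed mandatory integer seed for the speckle field.
#' @return An object of class `oct_phantom_spec`.
#' @export
oct_phantom_spec <- function(n_frames = 1L, n_alines = 360L, n_depth = 500L,
                             radial_spacing = 0.01,
                             lumen_radius_profile = function(frame) 1.5,
                             wall_thickness = 0.7, media_thickness = 0.31,
                             guidewire_angle = NA, guidewire_width = 12,
                             strut_layout = NULL, malapposed_offsets = NULL,
                             speckle_grain = 1.5, noise_seed) {
  if (missing(noise_seed) || is.null(noise_seed))
    stop("noise_seed is mandatory")
  stopifnot(n_frames >= 1, n_alines >= 8, n_depth >= 32, radial_spacing > 0,
            wall_thickness > 0, media_thickness > 0,
            media_thickness < wall_thickness)
  max_r <- vapply(seq_len(n_frames),
                  function(f) max(lumen_radius_profile(f)), numeric(1))
  if (any(max_r + wall_thickness >= n_depth * radial_spacing))
    stop("lumen radius + wall thickness must fit inside the imaged depth")
  if (!is.na(guidewire_angle) &&
      (guidewire_angle < 0 || guidewire_angle >= 360))
    stop("angles must lie in [0, 360)")
  if (!is.null(strut_layout)) {
    stopifnot(all(c("frame", "angle", "depth", "type") %in% names(strut_layout)))
    if (any(strut_layout$angle < 0 | strut_layout$angle >= 360))
      stop("angles must lie in [0, 360)")
    if (!all(strut_layout$type %in% c("metal", "BVS")))
      stop("strut type must be 'metal' or 'BVS'")
    off <- if (is.null(malapposed_offsets)) rep(0, nrow(strut_layout)) else malapposed_offsets
    stopifnot(length(off) == nrow(strut_layout))
    d_px <- (strut_layout$depth - off) / radial_spacing
    if (any(d_px < 5 | d_px > n_depth - 5))
      stop("strut placed outside imaged depth")
    malapposed_offsets <- off
  }
  structure(list(n_frames = as.integer(n_frames), n_alines = as.integer(n_alines),
                 n_depth = as.integer(n_depth), radial_spacing = radial_spacing,
                 lumen_radius_profile = lumen_radius_profile,
                 wall_thickness = wall_thickness, media_thickness = media_thickness,
                 guidewire_angle = guidewire_angle, guidewire_width = guidewire_width,
                 strut_layout = strut_layout, malapposed_offsets = malapposed_offsets,
                 speckle_grain = speckle_grain, noise_seed = as.integer(noise_seed)),
            class = "oct_phantom_spec")
}

# angle (deg) -> nearest 1-based A-line row
angle_to_aline <- function(angle, n_alines) {
  (round(angle / 360 * n_alines) %% n_alines) + 1L
}

#' Generate a synthetic OCT pullback with exact ground truth
#'
#' Deterministic given `spec$noise_seed`: the same spec yields bit-identical
#' stacks. Speckle is multiplicative exponential noise with a finite grain
#' size applied to a piecewise-constant radial template.
#'
#' @param spec an [oct_phantom_spec()].
#' @return A list with `frames` (list of [polar_frame()]) and `truth`, a list
#'   holding per-frame `lumen_radii_px` and `adventitia_radii_px` matrices
#'   (frames x A-lines), the `struts` table (with per-strut A-line/depth pixel
#'   positions and malapposition offsets in mm), and the `guidewire` sector
#'   (1-based A-line indices) or NULL.
#' @export
synth_oct_pullback <- function(spec) {
  stopifnot(inherits(spec, "oct_phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$noise_seed)

  na <- spec$n_alines; nd <- spec$n_depth; sp <- spec$radial_spacing
  wall_px <- spec$wall_thickness / sp
  media_px <- spec$media_thickness / sp
  depth_idx <- matrix(seq_len(nd), nrow = na, ncol = nd, byrow = TRUE)

  gw_alines <- NULL
  if (!is.na(spec$guidewire_angle)) {
    half <- spec$guidewire_width / 2
    ang <- (seq_len(na) - 1) / na * 360
    d <- pmin(abs(ang - spec$guidewire_angle),
              360 - abs(ang - spec$guidewire_angle))
    gw_alines <- which(d <= half)
  }

  lum_mat <- matrix(0, spec$n_frames, na)
  adv_mat <- matrix(0, spec$n_frames, na)
  struts_out <- NULL
  frames <- vector("list", spec$n_frames)

  for (f in seq_len(spec$n_frames)) {
    r_mm <- spec$lumen_radius_profile(f)
    r_l <- rep(r_mm / sp, length.out = na)
    r_a <- r_l + wall_px
    lum_mat[f, ] <- r_l
    adv_mat[f, ] <- r_a

    rl <- matrix(r_l, na, nd)
    ra <- matrix(r_a, na, nd)
    tmpl <- matrix(0.04, na, nd)
    tissue <- depth_idx >= rl & depth_idx < ra - media_px
    tmpl[tissue] <- 0.55 + 0.45 * exp(-(depth_idx[tissue] - rl[tissue]) / 6)
    media <- depth_idx >= ra - media_px & depth_idx < ra
    tmpl[media] <- 0.06
    bg <- depth_idx >= ra
    tmpl[bg] <- 0.02 + 0.20 * exp(-(depth_idx[bg] - ra[bg]) / 60)
    tmpl[, seq_len(12)] <- 0.03  # catheter near field

    # guidewire: bright rectangular reflection + full-depth shadow
    if (length(gw_alines)) {
      tmpl[gw_alines, 40:nd] <- tmpl[gw_alines, 40:nd] * 0.02
      core <- gw_alines[gw_alines != gw_alines[1] & gw_alines != gw_alines[length(gw_alines)]]
      tmpl[core, 22:34] <- 0.95
    }

    # struts for this frame
    if (!is.null(spec$strut_layout)) {
      rows <- which(spec$strut_layout$frame == f)
      for (k in rows) {
        st <- spec$strut_layout[k, ]
        off <- spec$malapposed_offsets[k]
        a0 <- angle_to_aline(st$angle, na)
        d0 <- round((st$depth - off) / sp)
        aw <- ((a0 - 3):(a0 + 3) - 1) %% na + 1
        if (st$type == "metal") {
          # full-depth shadow behind the strut, then bright bloom
          ash <- ((a0 - 1):(a0 + 1) - 1) %% na + 1
          sh_cols <- (d0 + 3):nd
          tmpl[ash, sh_cols] <- tmpl[ash, sh_cols] * 0.05
          for (ai in seq_along(aw)) {
            da <- ai - 4
            cols <- max(1, d0 - 4):min(nd, d0 + 4)
            bloom <- 1.2 * exp(-((da)^2 + (cols - d0)^2) / (2 * 2^2))
            tmpl[aw[ai], cols] <- pmax(tmpl[aw[ai], cols], bloom)
          }
        } else {
          # bright-rimmed dark box: rim then dark core
          arim <- ((a0 - 2):(a0 + 2) - 1) %% na + 1
          rim_cols <- max(1, d0 - 3):min(nd, d0 + 3)
          tmpl[arim, rim_cols] <- 0.95
          acore <- ((a0 - 1):(a0 + 1) - 1) %% na + 1
          core_cols <- max(1, d0 - 1):min(nd, d0 + 1)
          tmpl[acore, core_cols] <- 0.02
        }
        rec <- data.frame(frame = f, aline = a0, depth_px = d0,
                          angle = st$angle, depth_mm = d0 * sp,
                          type = st$type, malapposed_mm = off)
        struts_out <- rbind(struts_out, rec)
      }
    }

    # multiplicative speckle with finite grain, mean 1
    e <- matrix(rexp(na * nd), na, nd)
    if (spec$speckle_grain > 0) {
      e <- .cpp_gauss2d(e, spec$speckle_grain)
      e <- e / mean(e)
    }
    img <- pmin(pmax(tmpl * e, 0), 1)
    frames[[f]] <- polar_frame(img, sp, frame_index = f)
  }

  truth <- list(lumen_radii_px = lum_mat, adventitia_radii_px = adv_mat,
                struts = struts_out, guidewire_alines = gw_alines,
                radial_spacing = sp)
  list(frames = frames, truth = truth)
}

#' Specification of a synthetic CT-like coronary volume
#'
#' A tubular vessel (straight line or helix centerline) rasterized into a
#' Hounsfield-unit volume with the tissue classes the CTCA pipeline segments:
#' lumen, wall, calcified plaque (CP), non-calcified plaque (NCP), stent, and
#' background. Class intensities must be ordered
#' background < NCP < wall < lumen < CP <= stent.
#'
#' @param grid_dim voxel counts per axis (x, y, z).
#' @param spacing voxel size per axis, mm.
#' @param centerline list: `type` "line" or "helix"; for "line", `xy` (mm) and
#'   `z_range` (mm); for "helix", `center`, `radius`, `pitch`, `z_range`.
#' @param lumen_radius lumen radius, mm.
#' @param wall_thickness wall thickness, mm.
#' @param intensities named HU values: background, ncp, wall, lumen, cp, stent.
#' @param cp_inclusions data frame with `arclength` (mm), `angle` (deg),
#'   `radius` (mm) describing spherical calcified inclusions in the wall.
#' @param ncp_inclusions same format, non-calcified inclusions.
#' @param stent_extent arclength interval c(s0, s1) in mm, or NULL.
#' @param stent_half_thickness half thickness of the stent shell, mm.
#' @param blur_sigma Gaussian blur of the emitted intensities, mm.
#' @param noise_sd additive Gaussian noise, HU.
#' @param seed mandatory integer seed.
#' @return An object of class `ct_phantom_spec`.
#' @export
ct_phantom_spec <- function(grid_dim = c(64, 64, 110), spacing = c(0.4, 0.4, 0.4),
                            centerline = list(type = "line", xy = c(12.8, 12.8),
                                              z_range = c(2, 42)),
                            lumen_radius = 1.5, wall_thickness = 1.0,
                            intensities = c(background = -100, ncp = 20, wall = 50,
                                            lumen = 350, cp = 800, stent = 1100),
                            cp_inclusions = NULL, ncp_inclusions = NULL,
                            stent_extent = NULL, stent_half_thickness = 0.4,
                            blur_sigma = 0, noise_sd = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  need <- c("background", "ncp", "wall", "lumen", "cp", "stent")
  stopifnot(all(need %in% names(intensities)))
  iv <- intensities[need]
  if (!(iv["background"] < iv["ncp"] && iv["ncp"] < iv["wall"] &&
        iv["wall"] < iv["lumen"] && iv["lumen"] < iv["cp"] &&
        iv["cp"] <= iv["stent"]))
    stop("class intensities must be ordered background < NCP < wall < lumen < CP <= stent")
  structure(list(grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
                 centerline = centerline, lumen_radius = lumen_radius,
                 wall_thickness = wall_thickness, intensities = iv,
                 cp_inclusions = cp_inclusions, ncp_inclusions = ncp_inclusions,
                 stent_extent = stent_extent,
                 stent_half_thickness = stent_half_thickness,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ct_phantom_spec")
}

# sample the parametric centerline at ~0.25 mm steps; returns n x 3 mm matrix
ct_centerline_points <- function(cl) {
  if (cl$type == "line") {
    z <- seq(cl$z_range[1], cl$z_range[2], by = 0.25)
    if (length(z) < 2) stop("degenerate centerline: zero length")
    cbind(cl$xy[1], cl$xy[2], z)
  } else if (cl$type == "helix") {
    z <- seq(cl$z_range[1], cl$z_range[2], by = 0.1)
    if (length(z) < 2) stop("degenerate centerline: zero length")
    th <- 2 * pi * (z - cl$z_range[1]) / cl$pitch
    cbind(cl$center[1] + cl$radius * cos(th),
          cl$center[2] + cl$radius * sin(th), z)
  } else stop("unknown centerline type")
}

#' Generate a synthetic CT-like coronary volume with exact ground truth
#'
#' Labels are rasterized from the parametric tube; intensities are then
#' emitted per class, optionally blurred and noised. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [ct_phantom_spec()].
#' @return A list with `volume` ([volume3d()]) and `truth`: the
#'   [label_volume()], the true [centerline3d()], and the spec echo.
#' @export
synth_ct_volume <- function(spec) {
  stopifnot(inherits(spec, "ct_phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  dims <- spec$grid_dim
  sp <- spec$spacing
  pts <- ct_centerline_points(spec$centerline)
  extent <- (dims - 1) * sp
  margin <- spec$lumen_radius + spec$wall_thickness
  if (any(pts[, 1] < margin | pts[, 1] > extent[1] - margin |
          pts[, 2] < margin | pts[, 2] > extent[2] - margin))
    stop("centerline too close to the grid boundary for the vessel radius")

  td <- .cpp_tube_distance(dims, sp, c(0, 0, 0), pts)
  dist <- td$dist
  s <- td$arclength
  interior <- !td$clamped  # flat tube ends, no spherical caps

  lab <- array(LABELS["background"], dims)
  lab[interior & dist < spec$lumen_radius + spec$wall_thickness] <- LABELS["wall"]
  lab[interior & dist < spec$lumen_radius] <- LABELS["lumen"]

  # spherical plaque inclusions centered mid-wall
  cl3 <- centerline3d(pts)
  cl3 <- build_frames(cl3, step = 0.25)
  place_inclusions <- function(tab, code) {
    if (is.null(tab)) return(invisible())
    xs <- (seq_len(dims[1]) - 1) * sp[1]
    ys <- (seq_len(dims[2]) - 1) * sp[2]
    zs <- (seq_len(dims[3]) - 1) * sp[3]
    for (k in seq_len(nrow(tab))) {
      i <- which.min(abs(cl3$arclength - tab$arclength[k]))
      th <- tab$angle[k] * pi / 180
      ctr <- cl3$points[i, ] +
        (spec$lumen_radius + spec$wall_thickness / 2) *
        (cos(th) * cl3$normal[i, ] + sin(th) * cl3$binormal[i, ])
      dx2 <- (xs - ctr[1])^2
      dy2 <- (ys - ctr[2])^2
      dz2 <- (zs - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sel <- d2 <= tab$radius[k]^2 & lab == LABELS["wall"]
      lab[sel] <<- code
    }
  }
  place_inclusions(spec$cp_inclusions, LABELS["cp"])
  place_inclusions(spec$ncp_inclusions, LABELS["ncp"])

  if (!is.null(spec$stent_extent)) {
    sel <- interior & abs(dist - spec$lumen_radius) <= spec$stent_half_thickness &
      s >= spec$stent_extent[1] & s <= spec$stent_extent[2]
    lab[sel] <- LABELS["stent"]
  }

  code2hu <- numeric(6)
  code2hu[LABELS + 1] <- spec$intensities[c("background", "lumen", "wall", "cp",
                                            "ncp", "stent")]
  vol <- array(code2hu[lab + 1], dims)
  if (spec$blur_sigma > 0)
    vol <- .cpp_gauss3d(vol, dims, spec$blur_sigma / sp)
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(prod(dims), sd = spec$noise_sd), dims)

  list(volume = volume3d(vol, sp),
       truth = list(labels = label_volume(lab, sp), centerline = cl3,
                    spec = spec))
}
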