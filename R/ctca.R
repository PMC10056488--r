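#' Multiscale 3D Frangi vesselness preprocessing
#'
#' Hessian-eigenvalue tube enhancement with bright-tube polarity, maximum
#' over scales, rescaled to [0, 1]. Being derivative-based, the response is
#' invariant under volume-wide intensity offsets.
#'
#' @param vol a [volume3d()].
#' @param scales Gaussian scales in mm; scales below the voxel spacing are
#'   skipped with a warning.
#' @param alpha,beta plate/blob sensitivity parameters.
#' @param c_frac structureness scale as a fraction of the maximum Frobenius
#'   Hessian norm per scale.
#' @return A [volume3d()] of vesselness responses in [0, 1].
#' @export
vesselness_preprocess <- function(vol, scales = c(1, 1.5, 2), alpha = 0.5,
                                  beta = 0.5, c_frac = 0.5) {
  stopifnot(inherits(vol, "volume3d"), length(scales) >= 1)
  dims <- dim(vol$intensities)
  usable <- scales[scales >= min(vol$spacing)]
  if (length(usable) < length(scales))
    warning("skipping vesselness scales below the voxel spacing")
  if (length(usable) == 0) stop("no usable vesselness scale")
  best <- array(0, dims)
  for (s in usable) {
    eg <- .cpp_hessian_eig3d(vol$intensities, dims, vol$spacing, s)
    l1 <- eg$l1; l2 <- eg$l2; l3 <- eg$l3
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- c_frac * max(S)
    if (cc <= 0) next
    Ra <- abs(l2) / pmax(abs(l3), 1e-12)
    Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-12)
    v <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 > 0 | l3 > 0] <- 0  # bright tubes only
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  volume3d(best, vol$spacing, vol$origin)
}

#' Extract a centerline as a minimum-cost path through a vesselness volume
#'
#' Cost is `1 / (eps + vesselness)`; the path runs over the 26-neighborhood
#' with metric edge lengths, is smoothed by a moving average, and is
#' returned in mm.
#'
#' @param vesselness a [volume3d()] of responses in [0, 1].
#' @param start,end 1-based voxel indices c(x, y, z).
#' @param eps cost floor.
#' @param smooth_window moving-average window (points).
#' @return A [centerline3d()].
#' @export
extract_centerline <- function(vesselness, start, end, eps = 0.05,
                               smooth_window = 5L) {
  stopifnot(inherits(vesselness, "volume3d"))
  dims <- dim(vesselness$intensities)
  chk <- function(p) all(p >= 1 & p <= dims)
  if (!chk(start) || !chk(end)) stop("seed outside the grid")
  if (vesselness$intensities[start[1], start[2], start[3]] <= 0 ||
      vesselness$intensities[end[1], end[2], end[3]] <= 0)
    stop("seed has zero vesselness response")
  if (all(start == end)) {
    p <- vesselness$origin + (start - 1) * vesselness$spacing
    return(centerline3d(matrix(p, 1, 3), arclength = 0))
  }
  cost <- 1 / (eps + vesselness$intensities)
  path <- .cpp_dijkstra26(cost, dims, vesselness$spacing,
                          as.integer(start - 1L), as.integer(end - 1L))
  pts <- sweep(path, 2, vesselness$spacing, "*")
  pts <- sweep(pts, 2, vesselness$origin, "+")
  if (nrow(pts) > smooth_window) {
    k <- smooth_window
    sm <- apply(pts, 2, function(v) as.numeric(stats::filter(v, rep(1 / k, k),
                                                             sides = 2)))
    keep <- !is.na(sm[, 1])
    sm[!keep, ] <- pts[!keep, ]
    pts <- sm
  }
  # drop duplicate consecutive points the smoothing may create
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  pts <- pts[c(TRUE, seg > 1e-9), , drop = FALSE]
  centerline3d(pts)
}

#' Sigmoidal class membership weight
#'
#' Rising form `1 / (1 + exp(-slope (x - mid)))`, falling form its
#' complement, band form the product of a rising and a falling sigmoid
#' (requires `mid_low < mid_high`). Output is in [0, 1] and equals 0.5
#' exactly at a single midpoint.
#'
#' @param class one of "lumen", "wall", "cp", "stent".
#' @param form "rising", "falling" or "band".
#' @param midpoints one midpoint (rising/falling) or two (band), HU.
#' @param slopes one or two slopes, 1/HU.
#' @return An object of class `sigmoid_weight`.
#' @export
sigmoid_weight <- function(class, form = c("rising", "falling", "band"),
                           midpoints, slopes) {
  form <- match.arg(form)
  if (form == "band") {
    stopifnot(length(midpoints) == 2, midpoints[1] < midpoints[2])
    if (length(slopes) == 1) slopes <- rep(slopes, 2)
  } else {
    stopifnot(length(midpoints) == 1)
  }
  stopifnot(all(slopes > 0))
  structure(list(class = class, form = form, midpoints = midpoints,
                 slopes = slopes), class = "sigmoid_weight")
}

#' Evaluate a sigmoidal weight at intensities
#'
#' @param w a [sigmoid_weight()].
#' @param x numeric HU values.
#' @return values in [0, 1].
#' @export
eval_weight <- function(w, x) {
  rising <- function(x, m, s) 1 / (1 + exp(-s * (x - m)))
  switch(w$form,
         rising = rising(x, w$midpoints[1], w$slopes[1]),
         falling = 1 - rising(x, w$midpoints[1], w$slopes[1]),
         band = rising(x, w$midpoints[1], w$slopes[1]) *
           (1 - rising(x, w$midpoints[2], w$slopes[2])))
}

#' Calibrate class weight functions from user seed annotations
#'
#' Lumen: band form with midpoints at the 5th/95th percentiles of the
#' lumen-seed HU values (widened to a 10 HU band when degenerate) and slope
#' `4 / max(IQR, 5)`. Wall: product of a falling sigmoid at the midpoint
#' between the wall-seed mean and the lumen-seed 5th percentile and a rising
#' sigmoid `max(4 IQR_wall, 20)` HU below the wall mean (bounding the wall
#' class against low-HU background and non-calcified plaque). CP: rising
#' sigmoid at the midpoint between the lumen-seed 95th percentile and the
#' CP-seed mean.
#'
#' @param vol a [volume3d()].
#' @param seeds list of 1-based voxel-index matrices (n x 3), one per class:
#'   `lumen`, `wall`, `cp` required, `ncp` optional; at least 5 voxels each,
#'   classes disjoint.
#' @return named list of [sigmoid_weight()] objects (`lumen`, `wall`, `cp`).
#' @export
calibrate_weights <- function(vol, seeds) {
  stopifnot(inherits(vol, "volume3d"),
            all(c("lumen", "wall", "cp") %in% names(seeds)))
  hu <- lapply(seeds[c("lumen", "wall", "cp")], function(ix) {
    ix <- as.matrix(ix)
    stopifnot(ncol(ix) == 3, nrow(ix) >= 5)
    vol$intensities[ix]
  })
  if (!(mean(hu$wall) < mean(hu$lumen) && mean(hu$lumen) < mean(hu$cp)))
    stop("calibration inconsistent: seed means must be ordered wall < lumen < CP")

  p5 <- quantile(hu$lumen, 0.05, names = FALSE)
  p95 <- quantile(hu$lumen, 0.95, names = FALSE)
  iqr_l <- stats::IQR(hu$lumen)
  if (p95 - p5 < 10) {
    mid <- (p5 + p95) / 2
    p5 <- mid - 5; p95 <- mid + 5
  }
  slope_l <- 4 / max(iqr_l, 5)
  w_lumen <- sigmoid_weight("lumen", "band", c(p5, p95), slope_l)

  wall_mean <- mean(hu$wall)
  iqr_w <- stats::IQR(hu$wall)
  mid_hi <- (wall_mean + p5) / 2
  mid_lo <- wall_mean - max(4 * iqr_w, 20)
  slope_w <- 4 / max(iqr_w, 5)
  w_wall <- sigmoid_weight("wall", "band", c(mid_lo, mid_hi), slope_w)

  cp_mean <- mean(hu$cp)
  mid_cp <- (p95 + cp_mean) / 2
  slope_cp <- 4 / max(stats::IQR(hu$cp), 5)
  w_cp <- sigmoid_weight("cp", "rising", mid_cp, slope_cp)

  weights <- list(lumen = w_lumen, wall = w_wall, cp = w_cp)
  for (cls in names(weights)) {
    frac <- mean(eval_weight(weights[[cls]], hu[[cls]]) >= 0.5)
    if (frac < 0.9)
      warning(sprintf("%s weight covers only %.0f%% of its own seeds",
                      cls, 100 * frac))
  }
  weights
}

#' 3D level-set segmentation of lumen, outer wall, CP and NCP
#'
#' The lumen level set starts as a 1-voxel tube around the centerline and
#' evolves with speed `(2 w_lumen(I) - 1) - kappa * curvature` (narrow-band,
#' first-order upwind). The outer wall runs the same scheme seeded from the
#' lumen result with the wall weight, restricted to `roi_radius` mm around
#' the centerline. CP voxels are the connected components of
#' `w_cp(I) > 0.5` inside the wall; NCP voxels lie between lumen and outer
#' wall, are not CP, and are not wall-typical (`w_wall(I) <= 0.5`). Labels
#' compose with precedence stent > CP > lumen > NCP > wall.
#'
#' @param vol a [volume3d()].
#' @param weights output of [calibrate_weights()].
#' @param centerline a [centerline3d()] inside the vessel.
#' @param kappa curvature weight.
#' @param dt time step.
#' @param max_iter iteration cap (a warning flag is set on non-convergence).
#' @param tol relative labeled-volume change defining convergence, checked
#'   every `every` iterations.
#' @param every convergence check interval.
#' @param roi_radius radius of the region of interest around the
#'   centerline, mm.
#' @return list: `labels` (a [label_volume()]), `lumen_mask`, `wall_mask`
#'   (logical arrays), `converged` (per stage), `iterations`.
#' @export
levelset_segment <- function(vol, weights, centerline, kappa = 0.2, dt = 0.4,
                             max_iter = 500L, tol = 1e-3, every = 10L,
                             roi_radius = 5) {
  stopifnot(inherits(vol, "volume3d"), inherits(centerline, "centerline3d"))
  dims <- dim(vol$intensities)
  td <- .cpp_tube_distance(dims, vol$spacing, vol$origin, centerline$points)
  allowed <- td$dist <= roi_radius

  run_stage <- function(phi0, w) {
    D <- 2 * eval_weight(w, vol$intensities) - 1
    .cpp_levelset(phi0, D, dims, allowed, kappa, dt, as.integer(max_iter),
                  tol, as.integer(every), band = 3)
  }

  vox <- min(vol$spacing)
  phi_l <- (td$dist - vox) / vox  # signed distance in voxel units, tube r = 1 voxel
  res_l <- run_stage(array(phi_l, dims), weights$lumen)
  lumen <- res_l$phi < 0

  # wall stage: initialize just outside the lumen result
  init_w <- .cpp_gauss3d(array(ifelse(lumen, -1, 1), dims), dims, c(1, 1, 1))
  res_w <- run_stage(init_w * 3, weights$wall)
  wall_region <- (res_w$phi < 0) | lumen

  # CP voxels repel the wall level set (their weight is near zero there), so
  # candidate components count as "within the wall" when they touch the wall
  # region; the vessel interior is the wall region plus accepted CP.
  wcp <- eval_weight(weights$cp, vol$intensities)
  cp_cand <- wcp > 0.5 & !lumen & allowed
  cp_mask <- array(FALSE, dims)
  if (any(cp_cand)) {
    comp <- .cpp_components26(cp_cand, dims)
    touch <- .cpp_morph3d(wall_region, dims, TRUE)
    for (k in seq_len(max(comp))) {
      sel <- comp == k
      if (any(sel & touch)) cp_mask[sel] <- TRUE
    }
  }
  wall_region <- wall_region | cp_mask
  wwall <- eval_weight(weights$wall, vol$intensities)
  ncp_mask <- wall_region & !lumen & !cp_mask & wwall <= 0.5

  lab <- array(LABELS["background"], dims)
  lab[wall_region] <- LABELS["wall"]
  lab[ncp_mask] <- LABELS["ncp"]
  lab[lumen] <- LABELS["lumen"]
  lab[cp_mask] <- LABELS["cp"]

  conv <- c(lumen = res_l$converged, wall = res_w$converged)
  if (!all(conv)) warning("level set did not converge; returning best labels")
  list(labels = label_volume(lab, vol$spacing, vol$origin),
       lumen_mask = lumen, wall_mask = wall_region,
       converged = conv,
       iterations = c(lumen = res_l$iterations, wall = res_w$iterations))
}

#' Count and extract calcified-plaque components
#'
#' @param labels a [label_volume()].
#' @return list: `n`, component label array (`components`), per-component
#'   voxel counts.
#' @export
cp_components <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  dims <- dim(labels$labels)
  comp <- .cpp_components26(labels$labels == LABELS["cp"], dims)
  n <- max(comp)
  list(n = n, components = comp,
       sizes = if (n > 0) tabulate(comp[comp > 0], nbins = n) else integer(0))
}

#' Detect the stent extent along the centerline in a CTCA volume
#'
#' A rising sigmoid with midpoint `mean + 3 sd` of the luminal HU scores
#' perilumenal shell voxels (morphological gradient of the lumen mask,
#' dilated by one voxel). Per 0.5 mm centerline station, the stent score is
#' the fraction of shell voxels with weight above 0.5; the stent extent is
#' the longest contiguous run of stations with score above `run_threshold`.
#'
#' @param vol a [volume3d()].
#' @param lumen_mask logical array of lumen voxels.
#' @param centerline a [centerline3d()].
#' @param station_mm station spacing along the centerline, mm.
#' @param run_threshold minimum per-station score.
#' @return list: `extent_mm` (c(s0, s1) arclength interval, or NULL),
#'   `stations` (data frame of arclength/score), `stent_voxels` (logical
#'   array), `weight` (the fitted [sigmoid_weight()]).
#' @export
detect_stent_ctca <- function(vol, lumen_mask, centerline, station_mm = 0.5,
                              run_threshold = 0.1) {
  stopifnot(inherits(vol, "volume3d"), inherits(centerline, "centerline3d"))
  dims <- dim(vol$intensities)
  hu <- vol$intensities[lumen_mask]
  mu <- mean(hu); sg <- sd(hu)
  w <- sigmoid_weight("stent", "rising", mu + 3 * max(sg, 1e-6),
                      4 / max(sg, 5))
  grad <- .cpp_morph3d(lumen_mask, dims, TRUE) &
    !(.cpp_morph3d(lumen_mask, dims, FALSE))
  shell <- .cpp_morph3d(grad, dims, TRUE)
  td <- .cpp_tube_distance(dims, vol$spacing, vol$origin, centerline$points)
  smax <- max(centerline$arclength)
  edges <- seq(0, smax + station_mm, by = station_mm)
  sidx <- findInterval(td$arclength[shell], edges, rightmost.closed = TRUE)
  wval <- eval_weight(w, vol$intensities[shell]) > 0.5
  nst <- length(edges) - 1
  tot <- tabulate(sidx, nbins = nst)
  hit <- tabulate(sidx[wval], nbins = nst)
  score <- ifelse(tot > 0, hit / pmax(tot, 1), 0)
  stations <- data.frame(arclength = edges[-length(edges)] + station_mm / 2,
                         score = score, n_shell = tot)
  above <- score > run_threshold
  r <- rle(above)
  if (!any(r$values)) {
    return(list(extent_mm = NULL, stations = stations,
                stent_voxels = array(FALSE, dims), weight = w))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  extent <- c(edges[i0], edges[i1 + 1])
  sv <- array(FALSE, dims)
  inshell <- which(shell)
  selrun <- td$arclength[inshell] >= extent[1] &
    td$arclength[inshell] <= extent[2] & wval
  sv[inshell[selrun]] <- TRUE
  list(extent_mm = extent, stations = stations, stent_voxels = sv, weight = w)
}
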