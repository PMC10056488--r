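#' Default parameters for stent strut detection
#'
#' Percentile, shadow and slope thresholds are tunable (the scan-line
#' criteria are brightness-percentile retention, a steep drop behind the
#' peak, and a long dark shadow to the image edge); BVS rule-chain constants
#' default to the standard values (binarization threshold 0.15, area within
#' [10, 40] px, aspect ratio < 5, 10-px band around the lumen border).
#'
#' @param percentile intensity percentile retained per frame (percent).
#' @param min_shadow_len minimum shadow run behind the peak, px.
#' @param max_slope minimum drop slope magnitude behind the peak,
#'   intensity/px (the name follows the scan-line criterion: profiles whose
#'   slope magnitude reaches this value qualify).
#' @param shadow_frac shadow level as a fraction of the beyond-lumen frame
#'   median.
#' @param peak_gap pixels skipped behind the peak before the shadow test.
#' @param dbscan_eps DBSCAN radius, mm.
#' @param dbscan_min_pts DBSCAN minimum cluster size.
#' @param bvs_threshold binarization threshold on [0, 1] intensities.
#' @param bvs_area_range connected-component area filter, px.
#' @param bvs_max_aspect maximum major/minor axis ratio.
#' @param bvs_band_width width of the acceptance band around the lumen
#'   border, px.
#' @return list of parameters.
#' @export
strut_params <- function(percentile = 99.5, min_shadow_len = 60,
                         max_slope = 0.08, shadow_frac = 0.2, peak_gap = 10,
                         dbscan_eps = 0.15, dbscan_min_pts = 1,
                         bvs_threshold = 0.15, bvs_area_range = c(10, 40),
                         bvs_max_aspect = 5, bvs_band_width = 10) {
  stopifnot(percentile > 50, percentile < 100)
  list(percentile = percentile, min_shadow_len = min_shadow_len,
       max_slope = max_slope, shadow_frac = shadow_frac, peak_gap = peak_gap,
       dbscan_eps = dbscan_eps, dbscan_min_pts = dbscan_min_pts,
       bvs_threshold = bvs_threshold, bvs_area_range = bvs_area_range,
       bvs_max_aspect = bvs_max_aspect, bvs_band_width = bvs_band_width)
}

#' Detect metallic strut candidates on a polar frame
#'
#' Per A-line scan-line analysis: pixels above the stated intensity
#' percentile are retained; an A-line is a candidate iff the brightness
#' profile drops steeply behind its peak and a long dark shadow follows
#' through to the image edge. The candidate position is the brightest
#' retained pixel of the A-line. A-lines excluded by the lumen contour
#' (guidewire sector) are skipped.
#'
#' @param frame a [polar_frame()] (preprocessed).
#' @param lumen lumen [radial_contour()] (provides the beyond-lumen shadow
#'   reference and the excluded sector).
#' @param params see [strut_params()].
#' @return data frame with `aline`, `depth_px`, `intensity` (possibly empty).
#' @export
detect_metal_candidates <- function(frame, lumen, params = strut_params()) {
  stopifnot(inherits(frame, "polar_frame"))
  img <- frame$intensities
  na <- nrow(img); nd <- ncol(img)
  # shadow reference: median intensity of the near-wall band beyond the
  # lumen border (the tissue an unshadowed beam would illuminate)
  sel <- matrix(FALSE, na, nd)
  for (i in seq_len(na)) {
    from <- min(nd, ceiling(lumen$radii[i]) + 1L)
    to <- min(nd, from + 50L)
    sel[i, from:to] <- TRUE
  }
  shadow_level <- params$shadow_frac * median(img[sel])

  skip <- rep(FALSE, na)
  skip[lumen$excluded_alines] <- TRUE

  out <- NULL
  for (i in seq_len(na)) {
    if (skip[i]) next
    p <- img[i, ]
    # percentile thresholding per scan line: keep the line's brightest pixels
    retained <- which(p >= quantile(p, params$percentile / 100))
    if (length(retained) == 0) next
    pk <- retained[which.max(p[retained])]
    # slope criterion: steep drop within 5 px behind the peak
    behind <- pk + seq_len(min(5L, nd - pk))
    if (length(behind) == 0) next
    slopes <- (p[pk] - p[behind]) / (behind - pk)
    if (max(slopes) < params$max_slope) next
    # shadow criterion: the mean intensity behind the peak must stay below
    # the shadow level over at least min_shadow_len px
    from <- pk + params$peak_gap
    to <- from + params$min_shadow_len - 1L
    if (to > nd) next
    if (mean(p[from:to]) >= shadow_level) next
    out <- rbind(out, data.frame(aline = i, depth_px = pk, intensity = p[pk]))
  }
  if (is.null(out)) out <- data.frame(aline = integer(0), depth_px = integer(0),
                                      intensity = numeric(0))
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on 2D points: core points have at least `min_pts`
#' neighbors within `eps`; clusters are the connected components of the
#' core-point neighborhood graph plus their border points. Returns -1 for
#' noise. Labels are stable under input permutation up to relabeling.
#'
#' @param xy n x 2 matrix.
#' @param eps neighborhood radius (same units as `xy`).
#' @param min_pts minimum neighborhood size (including the point itself).
#' @return integer vector of cluster ids (1..k, or -1 for noise).
#' @export
dbscan_points <- function(xy, eps, min_pts = 1L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L || labels[k] == -1L) {
          grow <- labels[k] == 0L && core[k]
          labels[k] <- cl
          if (grow) queue <- c(queue, k)
        }
      }
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Cluster strut candidates into one strut point per physical strut
#'
#' DBSCAN over the candidates' cartesian positions; each cluster is reduced
#' to its intensity-weighted centroid. Noise points are dropped.
#'
#' @param candidates data frame from [detect_metal_candidates()].
#' @param frame the source [polar_frame()] (for the polar-to-mm mapping).
#' @param params see [strut_params()].
#' @return data frame of strut points: `frame`, `aline`, `depth_px`, `x_mm`,
#'   `y_mm`, `cluster`, `type`.
#' @export
cluster_struts <- function(candidates, frame, params = strut_params()) {
  na <- nrow(frame$intensities)
  sp <- frame$radial_spacing
  if (nrow(candidates) == 0)
    return(data.frame(frame = integer(0), aline = numeric(0),
                      depth_px = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), cluster = integer(0),
                      type = character(0)))
  th <- 2 * pi * (candidates$aline - 1) / na
  r <- candidates$depth_px * sp
  xy <- cbind(r * cos(th), r * sin(th))
  labels <- dbscan_points(xy, params$dbscan_eps, params$dbscan_min_pts)
  keep <- labels > 0
  if (!any(keep))
    return(data.frame(frame = integer(0), aline = numeric(0),
                      depth_px = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), cluster = integer(0),
                      type = character(0)))
  xy <- xy[keep, , drop = FALSE]
  cand <- candidates[keep, , drop = FALSE]
  labels <- labels[keep]
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    s <- labels == cl
    w <- cand$intensity[s]
    cx <- sum(xy[s, 1] * w) / sum(w)
    cy <- sum(xy[s, 2] * w) / sum(w)
    rr <- sqrt(cx^2 + cy^2)
    aa <- (atan2(cy, cx) %% (2 * pi)) / (2 * pi) * na + 1
    data.frame(frame = frame$frame_index, aline = aa, depth_px = rr / sp,
               x_mm = cx, y_mm = cy, cluster = cl, type = "metal")
  }))
  rownames(out) <- NULL
  out
}

#' Detect bioresorbable (BVS) struts on a scan-converted frame
#'
#' Exact morphological rule chain: binarize at `bvs_threshold`, close with a
#' one-pixel-radius disk, fill holes, subtract the binarized image; the
#' 8-connected components of the subtraction image are filtered by area
#' within `bvs_area_range`, best-fit-ellipse aspect ratio below
#' `bvs_max_aspect`, and centroid within the `bvs_band_width`-px band around
#' the lumen border. Survivors become BVS strut points.
#'
#' @param img cartesian grayscale matrix in [0, 1] (min-max normalized per
#'   frame before the threshold is applied).
#' @param lumen_poly_px lumen polygon in the same pixel coordinates, n x 2,
#'   relative to `center`.
#' @param center c(x, y) pixel coordinates of the catheter center.
#' @param spacing mm/px.
#' @param frame_index frame id attached to the output.
#' @param params see [strut_params()].
#' @return data frame of strut points (`type = "BVS"`), columns as in
#'   [cluster_struts()].
#' @export
detect_bvs_struts <- function(img, lumen_poly_px, center, spacing,
                              frame_index = 1L, params = strut_params()) {
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  bin <- img > params$bvs_threshold
  closed <- EBImage::closing(EBImage::Image(bin * 1),
                             EBImage::makeBrush(3, shape = "disc"))
  filled <- EBImage::fillHull(closed)
  diffimg <- (as.array(filled) > 0.5) & !bin
  lab <- EBImage::bwlabel(EBImage::Image(diffimg * 1))
  nlab <- max(lab)
  empty <- data.frame(frame = integer(0), aline = numeric(0),
                      depth_px = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), cluster = integer(0),
                      type = character(0), area_px = numeric(0))
  if (nlab == 0) return(empty)
  mom <- EBImage::computeFeatures.moment(lab)
  mom <- matrix(mom, ncol = ncol(mom),
                dimnames = list(NULL, colnames(mom)))
  areas <- tabulate(as.integer(as.array(lab)), nbins = nlab)
  keep <- which(areas >= params$bvs_area_range[1] &
                  areas <= params$bvs_area_range[2])
  if (length(keep) == 0) return(empty)
  out <- NULL
  cl <- 0L
  for (k in keep) {
    maj <- mom[k, "m.majoraxis"]
    ecc <- mom[k, "m.eccentricity"]
    minr <- maj * sqrt(1 - min(ecc, 0.999999)^2)
    aspect <- maj / max(minr, 1e-9)
    if (aspect >= params$bvs_max_aspect) next
    cx <- mom[k, "m.cx"] - center[1]
    cy <- mom[k, "m.cy"] - center[2]
    dband <- point_polyline_distance(c(cx, cy), lumen_poly_px)
    if (dband > params$bvs_band_width / 2) next
    cl <- cl + 1L
    n_alines_guess <- nrow(lumen_poly_px)
    aa <- (atan2(cy, cx) %% (2 * pi)) / (2 * pi) * n_alines_guess + 1
    out <- rbind(out, data.frame(frame = frame_index, aline = aa,
                                 depth_px = sqrt(cx^2 + cy^2),
                                 x_mm = cx * spacing, y_mm = cy * spacing,
                                 cluster = cl, type = "BVS",
                                 area_px = areas[k]))
  }
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# minimum distance from a point to a closed polyline
point_polyline_distance <- function(p, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  L2 <- rowSums(ab^2)
  t <- pmin(pmax(rowSums(ap * ab) / pmax(L2, 1e-12), 0), 1)
  qx <- a[, 1] + t * ab[, 1] - p[1]
  qy <- a[, 2] + t * ab[, 2] - p[2]
  sqrt(min(qx^2 + qy^2))
}
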