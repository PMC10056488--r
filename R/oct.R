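#' Detect and mask the guidewire artifact on a polar OCT frame
#'
#' The guidewire blocks the beam over a small angular sector: it leaves a
#' bright reflection near the catheter and a shadow that extends to the full
#' imaging depth. Corner candidates are located with the Harris--Stephens
#' response; among contiguous runs of A-lines whose far field is nearly dark,
#' the run with the strongest total corner response is flagged as the wire
#' sector. Flagged A-lines are masked and later interpolated, never fed to
#' border detection as data.
#'
#' @param frame a [polar_frame()].
#' @param shadow_frac an A-line counts as shadowed when its far-field mean
#'   intensity is below this fraction of the across-A-line median far-field
#'   mean.
#' @param corner_quantile corner strength required inside the run, as a
#'   quantile of the per-A-line maximum Harris response.
#' @return list with `frame` (unchanged input) and `mask`, a
#'   [guidewire_mask()] (empty when no candidate sector is found).
#' @export
remove_guidewire <- function(frame, shadow_frac = 0.4, corner_quantile = 0.9) {
  stopifnot(inherits(frame, "polar_frame"))
  img <- frame$intensities
  na <- nrow(img); nd <- ncol(img)
  far <- img[, max(1, floor(0.7 * nd)):nd, drop = FALSE]
  tailmean <- rowMeans(far)
  shadowed <- tailmean < shadow_frac * median(tailmean)
  if (!any(shadowed))
    return(list(frame = frame, mask = guidewire_mask(rep(FALSE, na))))

  h <- harris_response(img)
  hmax <- apply(h, 1, max)
  strong <- quantile(hmax, corner_quantile)

  # contiguous periodic runs of shadowed A-lines
  runs <- periodic_runs(shadowed)
  score <- vapply(runs, function(r) sum(pmax(hmax[r], 0)), numeric(1))
  has_corner <- vapply(runs, function(r) any(hmax[r] >= strong), logical(1))
  if (!any(has_corner))
    return(list(frame = frame, mask = guidewire_mask(rep(FALSE, na))))
  best <- runs[[which.max(ifelse(has_corner, score, -Inf))]]
  # widen by 2 A-lines on both sides (penumbra)
  ext <- unique(((c(outer(best, -2:2, "+")) - 1) %% na) + 1)
  occl <- rep(FALSE, na)
  occl[ext] <- TRUE
  tip_aline <- best[which.max(hmax[best])]
  tip_depth <- which.max(h[tip_aline, ])
  list(frame = frame,
       mask = guidewire_mask(occl, tip = c(tip_aline, tip_depth)))
}

# split TRUE positions of a logical vector into periodically contiguous runs
periodic_runs <- function(flag) {
  n <- length(flag)
  idx <- which(flag)
  if (length(idx) == 0) return(list())
  if (length(idx) == n) return(list(idx))
  gap <- which(!flag)[1]
  ord <- ((idx - gap) %% n)
  o <- order(ord)
  idx <- idx[o]
  ord <- ord[o]
  grp <- cumsum(c(1, diff(ord) > 1))
  unname(split(idx, grp))
}

#' Edge-preserving bilateral denoising of a polar frame
#'
#' @param frame a [polar_frame()].
#' @param sigma_spatial spatial Gaussian scale, px.
#' @param sigma_range intensity Gaussian scale (same units as the
#'   normalized intensities).
#' @return A denoised [polar_frame()].
#' @export
bilateral_denoise <- function(frame, sigma_spatial = 5, sigma_range = 0.1) {
  stopifnot(inherits(frame, "polar_frame"), sigma_spatial > 0, sigma_range > 0)
  out <- .cpp_bilateral(frame$intensities, sigma_spatial, sigma_range)
  out <- pmin(pmax(out, 0), 1)
  polar_frame(out, frame$radial_spacing, frame$frame_index,
              frame$catheter_offset)
}

# ridge response for the lumen border: smoothed intensity times its positive
# radial gradient, rescaled to [0, 1]; the smoothing localizes the dark-to-
# bright intima transition against residual speckle
lumen_ridge <- function(img, min_depth = 14L, sigma = 2) {
  nd <- ncol(img)
  s <- .cpp_gauss2d(img, sigma)
  grad <- cbind(0, (s[, 3:nd] - s[, 1:(nd - 2)]) / 2, 0)
  r <- s * pmax(grad, 0)
  r[, seq_len(min_depth)] <- 0
  mx <- max(r)
  if (mx > 0) r <- r / mx
  r
}

#' Segment the lumen border by a fast-marching minimal path
#'
#' A minimal path is traced across the polar image from the first A-line row
#' to the last using the fast-marching eikonal solver on a speed function
#' `F = eps + (1 - eps) * R`, where `R` is the ridge response (intensity
#' times positive radial gradient, rescaled to [0, 1]): the path hugs the
#' bright intima transition and `eps` guarantees finite arrival times.
#' Periodic closure is enforced by duplicating the first A-line rows below
#' the image and accepting the traversal whose start/end radii agree within
#' `closure_tol` px. Masked (guidewire) A-lines are filled by periodic linear
#' interpolation, and the extracted radii get a light circular median smoothing.
#'
#' @param frame a denoised [polar_frame()].
#' @param mask a [guidewire_mask()] or NULL.
#' @param eps floor of the speed function.
#' @param closure_tol allowed start/end radius difference, px.
#' @param overlap_rows number of duplicated closure rows.
#' @return A [radial_contour()] of kind `"lumen"`.
#' @export
segment_lumen <- function(frame, mask = NULL, eps = 0.01, closure_tol = 3L,
                          overlap_rows = 8L) {
  stopifnot(inherits(frame, "polar_frame"))
  img <- frame$intensities
  na <- nrow(img); nd <- ncol(img)
  R <- lumen_ridge(img)
  if (max(R) < 1e-6) stop("no lumen detected")

  excl <- integer(0)
  if (!is.null(mask) && any(mask$occluded)) {
    excl <- which(mask$occluded)
    keep <- setdiff(seq_len(na), excl)
    # replace masked rows column-wise by periodic interpolation so the
    # minimal path can cross the sector smoothly
    for (j in seq_len(nd)) R[excl, j] <- interp_periodic(R[, j], excl)[excl]
  }

  Rext <- rbind(R, R[seq_len(overlap_rows), , drop = FALSE])
  speed <- eps + (1 - eps) * Rext
  W <- 1 / speed

  seed_row <- 1L
  # seed column: ridge argmax on the first A-line after smoothing across
  # neighboring A-lines (robust to residual speckle, tracks eccentric lumens)
  Rs <- .cpp_gauss2d(Rext, 3)
  c0 <- which.max(Rs[1, ])
  Tm <- .cpp_fmm2d(W, seed_row - 1L, c0 - 1L)
  endrow <- na + overlap_rows
  lo <- max(1, c0 - closure_tol); hi <- min(nd, c0 + closure_tol)
  endcol <- (lo:hi)[which.min(Tm[endrow, lo:hi])]
  path <- .cpp_descend(Tm, endrow - 1L, endcol - 1L)
  pr <- path[, 1] + 1L
  pc <- path[, 2] + 1L
  # fold duplicated closure rows back onto the first rows
  pr[pr > na] <- pr[pr > na] - na

  radii <- rep(NA_real_, na)
  agg <- tapply(pc, pr, mean)
  radii[as.integer(names(agg))] <- as.numeric(agg)
  missing_rows <- which(is.na(radii))
  if (length(missing_rows) == na) stop("no lumen detected")
  if (length(missing_rows))
    radii <- interp_periodic(ifelse(is.na(radii), 0, radii), missing_rows)
  if (length(excl)) radii <- interp_periodic(radii, excl)
  radii <- circular_median(radii, 5L)
  radii <- pmin(pmax(radii, 1), nd - 1)
  radial_contour(radii, "lumen", excluded_alines = excl, n_depth = nd)
}

#' Segment the adventitia (outer wall) border
#'
#' Pipeline: bilateral filter, 11 x 11 neighborhood standard-deviation image,
#' then a Frangi vesselness filter tuned to the dark media ring (a tubular,
#' continuous structure of about `thickness_px` px). The per-A-line maximum
#' vesselness beyond the lumen locates the ring center; the adventitia radius
#' is the ring center plus half the tuned thickness. A-lines with response
#' below `threshold` are interpolated; if more than half fail, the ring is
#' deemed not recoverable.
#'
#' @param frame a [polar_frame()] (raw; the pipeline filters internally).
#' @param lumen the lumen [radial_contour()] restricting the search depth.
#' @param thickness_px tuned ring thickness parameter, px.
#' @param threshold minimum acceptable vesselness response.
#' @param sd_window window size of the standard-deviation filter, px.
#' @param sigma_spatial,sigma_range bilateral parameters.
#' @return A [radial_contour()] of kind `"adventitia"`.
#' @export
segment_adventitia <- function(frame, lumen, thickness_px = 31,
                               threshold = 0.05, sd_window = 11L,
                               sigma_spatial = 5, sigma_range = 0.1) {
  stopifnot(inherits(frame, "polar_frame"), inherits(lumen, "radial_contour"))
  den <- bilateral_denoise(frame, sigma_spatial, sigma_range)
  sdimg <- .cpp_sdfilter(den$intensities, (sd_window - 1L) %/% 2L)
  sigma <- thickness_px / (2 * sqrt(3))
  v <- frangi2d(sdimg, sigma, polarity = "dark")
  na <- nrow(v); nd <- ncol(v)

  margin <- 8L
  radii <- rep(NA_real_, na)
  for (i in seq_len(na)) {
    from <- min(nd - 2L, ceiling(lumen$radii[i]) + margin)
    prof <- v[i, from:nd]
    idx <- which(prof >= threshold)
    if (length(idx) == 0) next
    # the media is the outermost qualifying dark-ring response (inner
    # low-variance bands inside the tissue can also respond)
    grp <- cumsum(c(1, diff(idx) > 1))
    run <- idx[grp == max(grp)]
    j <- run[which.max(prof[run])]
    radii[i] <- from + j - 1 + thickness_px / 2
  }
  bad <- which(is.na(radii))
  if (length(bad) > na / 2) stop("adventitia not recoverable")
  if (length(bad))
    radii <- interp_periodic(ifelse(is.na(radii), 0, radii), bad)
  radii <- circular_median(radii, 5L)
  radii <- pmax(radii, lumen$radii + 1)
  radii <- pmin(radii, nd - 1)
  excl <- sort(unique(c(bad, lumen$excluded_alines)))
  radial_contour(radii, "adventitia", excluded_alines = excl, n_depth = nd)
}

#' Polar to cartesian scan conversion of a frame
#'
#' Maps the A-line-by-depth grid to a square cartesian image centered on the
#' catheter by bilinear interpolation (periodic in angle). Pixel size equals
#' the radial spacing.
#'
#' @param frame a [polar_frame()].
#' @param out_px side length of the output image (default `2 * n_depth + 1`).
#' @return list: `image` (out_px x out_px matrix), `center` (px coordinates of
#'   the catheter), `spacing` (mm/px).
#' @export
scan_convert_frame <- function(frame, out_px = NULL) {
  stopifnot(inherits(frame, "polar_frame"))
  img <- frame$intensities
  na <- nrow(img); nd <- ncol(img)
  if (is.null(out_px)) out_px <- 2L * nd + 1L
  ctr <- (out_px + 1) / 2
  xs <- matrix(seq_len(out_px) - ctr, out_px, out_px)
  ys <- t(xs)
  r <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs) %% (2 * pi)
  a <- th / (2 * pi) * na  # 0-based fractional A-line
  a0 <- floor(a); fa <- a - a0
  r0 <- floor(r); fr <- r - r0
  inside <- r0 >= 1 & r0 <= nd - 1
  out <- matrix(0, out_px, out_px)
  i1 <- (a0 %% na) + 1L
  i2 <- ((a0 + 1) %% na) + 1L
  j1 <- pmin(pmax(r0, 1L), nd)
  j2 <- pmin(j1 + 1L, nd)
  idx <- function(i, j) (j - 1L) * na + i
  vals <- (1 - fa) * (1 - fr) * img[idx(i1, j1)] +
    fa * (1 - fr) * img[idx(i2, j1)] +
    (1 - fa) * fr * img[idx(i1, j2)] +
    fa * fr * img[idx(i2, j2)]
  out[inside] <- vals[inside]
  list(image = out, center = c(ctr, ctr), spacing = frame$radial_spacing)
}

#' Convert a radial contour to a closed cartesian polygon
#'
#' Vertices are ordered counter-clockwise, first point not repeated.
#'
#' @param contour a [radial_contour()].
#' @param radial_spacing mm/px; when given, output is in mm, otherwise px.
#' @return n x 2 matrix of (x, y) vertices.
#' @export
contour_to_polygon <- function(contour, radial_spacing = NULL) {
  stopifnot(inherits(contour, "radial_contour"))
  n <- length(contour$radii)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- contour$radii
  if (!is.null(radial_spacing)) r <- r * radial_spacing
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Convert cartesian points back to polar (A-line, radius) coordinates
#'
#' Inverse of [contour_to_polygon()] on its vertex grid; round-trip error is
#' sub-pixel.
#'
#' @param xy n x 2 matrix of cartesian coordinates (px units unless
#'   `radial_spacing` is supplied).
#' @param n_alines number of A-lines of the target polar grid.
#' @param radial_spacing mm/px of the input coordinates, if in mm.
#' @return data frame with fractional `aline` (1-based) and `radius_px`.
#' @export
cartesian_to_polar <- function(xy, n_alines, radial_spacing = NULL) {
  xy <- as.matrix(xy)
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  if (!is.null(radial_spacing)) r <- r / radial_spacing
  th <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  data.frame(aline = th / (2 * pi) * n_alines + 1, radius_px = r)
}
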