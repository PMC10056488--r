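#' Construct a polar OCT frame
#'
#' A polar frame stores one OCT cross-section as an A-line-by-depth intensity
#' grid. Row `i` is the A-line at angle `theta = 2*pi*(i-1)/n_alines`
#' (theta = 0 at the image top, counter-clockwise in the cartesian view);
#' column `j` is depth `j` pixels from the catheter center.
#'
#' @param intensities numeric matrix (n_alines x n_depth), values in [0, 1].
#' @param radial_spacing radial pixel size in mm/px.
#' @param frame_index 1-based index of the frame within its pullback.
#' @param catheter_offset first valid depth sample in px (near-field
#'   catheter artifacts are ignored up to this column).
#' @return An object of class `polar_frame`.
#' @export
polar_frame <- function(intensities, radial_spacing, frame_index = 1L,
                        catheter_offset = 0L) {
  stopifnot(is.matrix(intensities), nrow(intensities) >= 8)
  if (!all(is.finite(intensities)))
    stop("polar frame intensities must be finite")
  if (min(intensities) < 0 || max(intensities) > 1)
    stop("polar frame intensities must lie in [0, 1]")
  stopifnot(radial_spacing > 0)
  structure(
    list(intensities = intensities,
         radial_spacing = as.numeric(radial_spacing),
         frame_index = as.integer(frame_index),
         catheter_offset = as.integer(catheter_offset)),
    class = "polar_frame")
}

#' @export
print.polar_frame <- function(x, ...) {
  cat(sprintf("<polar_frame #%d: %d A-lines x %d depth px, %.4f mm/px>\n",
              x$frame_index, nrow(x$intensities), ncol(x$intensities),
              x$radial_spacing))
  invisible(x)
}

#' Construct a radial contour
#'
#' A closed vessel border sampled as one radius per A-line on the same
#' angular grid as its frame.
#'
#' @param radii numeric vector of per-A-line radii in px.
#' @param kind `"lumen"` or `"adventitia"`.
#' @param excluded_alines integer vector of 1-based A-line indices whose radii
#'   were interpolated (guidewire / shadow sectors), not measured.
#' @param n_depth frame depth in px, used for range validation (optional).
#' @return An object of class `radial_contour`.
#' @export
radial_contour <- function(radii, kind = c("lumen", "adventitia"),
                           excluded_alines = integer(0), n_depth = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(radii), length(radii) >= 8, all(is.finite(radii)),
            all(radii > 0))
  if (!is.null(n_depth) && any(radii >= n_depth))
    stop("contour radius exceeds frame depth")
  structure(list(radii = as.numeric(radii), kind = kind,
                 excluded_alines = as.integer(excluded_alines)),
            class = "radial_contour")
}

#' @export
print.radial_contour <- function(x, ...) {
  cat(sprintf("<radial_contour (%s): %d A-lines, radius %.1f-%.1f px, %d interpolated>\n",
              x$kind, length(x$radii), min(x$radii), max(x$radii),
              length(x$excluded_alines)))
  invisible(x)
}

#' Guidewire occlusion mask
#'
#' @param occluded logical vector, one entry per A-line; `TRUE` where the
#'   guidewire shadow occludes the tissue. Must be a single contiguous
#'   angular run (periodic) or all-FALSE.
#' @param tip c(aline, depth) position of the wire reflection, or NULL.
#' @return An object of class `guidewire_mask`.
#' @export
guidewire_mask <- function(occluded, tip = NULL) {
  stopifnot(is.logical(occluded))
  if (any(occluded)) {
    # periodic contiguity: rotating so the run does not wrap must leave
    # exactly one block of TRUE
    idx <- which(occluded)
    n <- length(occluded)
    if (length(idx) < n) {
      gap <- which(!occluded)[1]
      rot <- c(occluded[gap:n], occluded[seq_len(gap - 1)])
      r <- rle(rot)
      if (sum(r$values) > 1)
        stop("guidewire mask must be one contiguous angular run")
    }
  }
  structure(list(occluded = occluded, tip = tip), class = "guidewire_mask")
}

#' Ordered 3D centerline with per-point orthonormal frames
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param arclength cumulative arclength (mm), strictly increasing.
#' @param tangent,normal,binormal n x 3 orthonormal frame vectors (optional
#'   until [build_frames()] is applied).
#' @return An object of class `centerline3d`.
#' @export
centerline3d <- function(points, arclength = NULL, tangent = NULL,
                         normal = NULL, binormal = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (is.null(arclength)) {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    arclength <- c(0, cumsum(seg))
  }
  if (nrow(points) > 1 && any(diff(arclength) <= 0))
    stop("centerline arclength must be strictly increasing")
  structure(list(points = points, arclength = arclength, tangent = tangent,
                 normal = normal, binormal = binormal),
            class = "centerline3d")
}

#' @export
print.centerline3d <- function(x, ...) {
  cat(sprintf("<centerline3d: %d points, length %.2f mm%s>\n",
              nrow(x$points), max(x$arclength),
              if (is.null(x$normal)) "" else ", framed"))
  invisible(x)
}

#' 3D scalar volume with physical spacing
#'
#' @param intensities 3D numeric array (HU for CTCA-like volumes).
#' @param spacing voxel size per axis, mm (length 3).
#' @param origin physical position of voxel (1,1,1) center, mm.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(intensities)) == 3, all(spacing > 0),
            all(is.finite(intensities)))
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d: %dx%dx%d voxels @ %.2fx%.2fx%.2f mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# label codes shared by the CTCA pipeline
LABELS <- c(background = 0L, lumen = 1L, wall = 2L, cp = 3L, ncp = 4L, stent = 5L)

#' Multi-class label volume companion to [volume3d()]
#'
#' Labels: 0 background, 1 lumen, 2 wall, 3 calcified plaque (CP),
#' 4 non-calcified plaque (NCP), 5 stent.
#'
#' @param labels 3D integer array of class codes.
#' @param spacing,origin grid geometry as in [volume3d()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, all(labels %in% LABELS))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

# periodic linear interpolation of values at `fill` indices from the
# remaining indices (1-based, circular in index)
interp_periodic <- function(values, fill) {
  n <- length(values)
  if (length(fill) == 0) return(values)
  keep <- setdiff(seq_len(n), fill)
  if (length(keep) < 2) stop("too few valid A-lines to interpolate")
  # triplicate for wraparound
  x <- c(keep - n, keep, keep + n)
  y <- rep(values[keep], 3)
  values[fill] <- approx(x, y, xout = fill)$y
  values
}

# circular running median, odd window
circular_median <- function(v, window = 5L) {
  n <- length(v)
  h <- window %/% 2
  ext <- c(tail(v, h), v, head(v, h))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- median(ext[i:(i + 2 * h)])
  out
}
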