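#' Area, perimeter and diameters of a simple closed polygon
#'
#' Shoelace area, polyline perimeter, maximum diameter as the largest
#' pairwise vertex distance, and minimum diameter as the smallest width over
#' rotating-calipers directions (hull-edge supported widths). All metrics are
#' invariant under rigid motions.
#'
#' @param poly n x 2 matrix of vertices (closed, first point not repeated).
#' @return list: `area`, `perimeter`, `min_diameter`, `max_diameter`.
#' @export
contour_metrics <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  stopifnot(n >= 3)
  if (polygon_self_intersects(poly)) stop("polygon is self-intersecting")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  h <- grDevices::chull(poly)
  hp <- poly[h, , drop = FALSE]
  dmat <- as.matrix(dist(hp))
  max_d <- max(dmat)
  k <- nrow(hp)
  widths <- vapply(seq_len(k), function(i) {
    j <- i %% k + 1
    e <- hp[j, ] - hp[i, ]
    le <- sqrt(sum(e^2))
    if (le < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / le
    proj <- as.numeric(hp %*% nrm)
    diff(range(proj))
  }, numeric(1))
  list(area = area, perimeter = perimeter, min_diameter = min(widths),
       max_diameter = max_d)
}

# O(n^2) segment intersection test, skipping shared endpoints
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - bx) - (bx - ax) * (cy - by)
  for (i in seq_len(n - 2)) {
    rng <- (i + 2):n
    rng <- rng[!(i == 1 & rng == n)]
    for (j in rng) {
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c2 <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- ccw(a[1], a[2], b[1], b[2], c2[1], c2[2])
      d2 <- ccw(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- ccw(c2[1], c2[2], d[1], d[2], a[1], a[2])
      d4 <- ccw(c2[1], c2[2], d[1], d[2], b[1], b[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Plaque burden from lumen and outer-wall polygons
#'
#' The standard external-elastic-membrane-based definition:
#' `100 * (A_wall - A_lumen) / A_wall` percent.
#'
#' @param lumen,wall n x 2 polygons (mm); the lumen must lie inside the wall.
#' @return percent in [0, 100).
#' @export
plaque_burden <- function(lumen, wall) {
  al <- contour_metrics(lumen)$area
  aw <- contour_metrics(wall)$area
  if (al > aw + 1e-9) stop("lumen not inside wall (lumen area exceeds wall area)")
  ctr <- colMeans(as.matrix(lumen))
  if (!point_in_polygon(ctr, wall)) stop("lumen not inside wall")
  100 * (aw - al) / aw
}

point_in_polygon <- function(p, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2]) &&
        p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
    j <- i
  }
  inside
}

#' Per-class plaque area and arc angle from a label mask
#'
#' Area is the pixel count times the pixel area; the arc angle is the angular
#' measure (degrees) of the union of angular sectors containing the class,
#' measured about the lumen center with `n_bins` sector bins.
#'
#' @param mask integer matrix of class labels on a cartesian grid (0 =
#'   background).
#' @param center c(x, y) pixel coordinates of the lumen center.
#' @param spacing mm/px.
#' @param n_bins angular bins used to measure arcs.
#' @return data frame: `class`, `area_mm2`, `angle_deg`.
#' @export
plaque_class_metrics <- function(mask, center, spacing, n_bins = 360L) {
  classes <- sort(setdiff(unique(as.integer(mask)), 0L))
  px_area <- spacing^2
  if (length(classes) == 0)
    return(data.frame(class = integer(0), area_mm2 = numeric(0),
                      angle_deg = numeric(0)))
  idx <- which(mask != 0, arr.ind = TRUE)
  th <- atan2(idx[, 2] - center[2], idx[, 1] - center[1]) %% (2 * pi)
  bin <- floor(th / (2 * pi) * n_bins)
  vals <- mask[idx]
  out <- do.call(rbind, lapply(classes, function(cl) {
    s <- vals == cl
    data.frame(class = cl, area_mm2 = sum(s) * px_area,
               angle_deg = length(unique(bin[s])) * 360 / n_bins)
  }))
  rownames(out) <- NULL
  out
}

#' Per-frame and pullback-level stent metrics from strut points
#'
#' Per frame, the stent polygon orders the struts by azimuth about the lumen
#' centroid; its area is the stent cross-sectional area (CSA). The
#' malapposition distance of a strut is the radial distance from its
#' abluminal edge (strut center plus `strut_thickness`) to the lumen
#' contour, positive when the strut sits inside the lumen cavity away from
#' the wall; a strut is unapposed when the distance exceeds
#' `malappose_threshold`. Restenosis burden is
#' `100 * (CSA - lumen area) / CSA`, clipped at zero. A fracture is flagged
#' for any run of at least `gap_frames` consecutive frames without struts
#' strictly inside the stented extent.
#'
#' @param struts data frame of strut points (`frame`, `aline`, `depth_px`).
#' @param lumen_contours list of lumen [radial_contour()] per frame.
#' @param radial_spacing mm/px.
#' @param strut_thickness physical strut thickness, mm.
#' @param malappose_threshold malapposition threshold, mm.
#' @param gap_frames minimum strut-free run flagged as fracture.
#' @param frames frame indices covered by the pullback (default: range of
#'   contour list).
#' @return list: `per_frame` data frame (frame, n_struts, stent_csa_mm2,
#'   min_diameter_mm, max_diameter_mm, lumen_area_mm2, restenosis_burden_pct,
#'   pct_unapposed), `per_strut` (with `malapposition_mm`, `unapposed`),
#'   `fractures` (data frame of frame gaps), `pct_unapposed` overall.
#' @export
stent_metrics <- function(struts, lumen_contours, radial_spacing,
                          strut_thickness = 0.1, malappose_threshold = 0.1,
                          gap_frames = 3L, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(lumen_contours)
  empty_pf <- data.frame(frame = integer(0), n_struts = integer(0),
                         stent_csa_mm2 = numeric(0), min_diameter_mm = numeric(0),
                         max_diameter_mm = numeric(0), lumen_area_mm2 = numeric(0),
                         restenosis_burden_pct = numeric(0),
                         pct_unapposed = numeric(0))
  if (is.null(struts) || nrow(struts) == 0)
    return(list(per_frame = empty_pf, per_strut = NULL,
                fractures = data.frame(from = integer(0), to = integer(0)),
                pct_unapposed = NA_real_))

  per_strut <- NULL
  per_frame <- NULL
  for (f in sort(unique(struts$frame))) {
    st <- struts[struts$frame == f, , drop = FALSE]
    lc <- lumen_contours[[f]]
    na <- length(lc$radii)
    # lumen radius at each strut azimuth (periodic interpolation)
    al <- ((st$aline - 1) %% na) + 1
    r_lum <- approx(c(seq_len(na), na + 1), c(lc$radii, lc$radii[1]),
                    xout = al)$y
    mal <- (r_lum - (st$depth_px + strut_thickness / radial_spacing)) *
      radial_spacing
    unap <- mal > malappose_threshold
    st$malapposition_mm <- mal
    st$unapposed <- unap
    per_strut <- rbind(per_strut, st)

    lumen_poly <- contour_to_polygon(lc, radial_spacing)
    lum_area <- contour_metrics(lumen_poly)$area
    if (nrow(st) >= 3) {
      th <- 2 * pi * (st$aline - 1) / na
      r <- st$depth_px * radial_spacing
      o <- order(th)
      poly <- cbind(r[o] * cos(th[o]), r[o] * sin(th[o]))
      cm <- contour_metrics(poly)
      csa <- cm$area
      mind <- cm$min_diameter; maxd <- cm$max_diameter
    } else {
      csa <- NA_real_; mind <- NA_real_; maxd <- NA_real_
    }
    resten <- if (is.na(csa)) NA_real_ else max(0, 100 * (csa - lum_area) / csa)
    per_frame <- rbind(per_frame, data.frame(
      frame = f, n_struts = nrow(st), stent_csa_mm2 = csa,
      min_diameter_mm = mind, max_diameter_mm = maxd,
      lumen_area_mm2 = lum_area, restenosis_burden_pct = resten,
      pct_unapposed = 100 * mean(unap)))
  }

  # fracture: strut-free runs strictly inside the stented extent
  sf <- sort(unique(struts$frame))
  extent <- range(sf)
  inner <- setdiff(seq(extent[1], extent[2]), sf)
  fractures <- data.frame(from = integer(0), to = integer(0))
  if (length(inner)) {
    grp <- cumsum(c(1, diff(inner) > 1))
    for (g in unique(grp)) {
      run <- inner[grp == g]
      if (length(run) >= gap_frames)
        fractures <- rbind(fractures, data.frame(from = min(run), to = max(run)))
    }
  }
  list(per_frame = per_frame, per_strut = per_strut, fractures = fractures,
       pct_unapposed = 100 * mean(per_strut$unapposed))
}
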