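#' Resample a 3D path and attach rotation-minimizing frames
#'
#' The path is resampled at a uniform arclength step; tangents come from
#' central differences; normals are propagated by parallel transport
#' (each normal is the previous one projected orthogonal to the new tangent),
#' which is defined on straight segments and free of the flips Frenet frames
#' exhibit at inflections. Duplicate consecutive points are removed with a
#' warning.
#'
#' @param cl a [centerline3d()] or an n x 3 matrix of mm points.
#' @param step resampling step, mm.
#' @return A framed [centerline3d()].
#' @export
build_frames <- function(cl, step = 0.5) {
  pts <- if (inherits(cl, "centerline3d")) cl$points else as.matrix(cl)
  stopifnot(ncol(pts) == 3)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg <= 1e-12)) {
    warning("duplicate consecutive centerline points removed")
    pts <- pts[c(TRUE, seg > 1e-12), , drop = FALSE]
    seg <- seg[seg > 1e-12]
  }
  if (nrow(pts) < 2) stop("need at least 2 distinct points")
  s <- c(0, cumsum(seg))
  stot <- s[length(s)]
  sout <- seq(0, stot, by = step)
  if (sout[length(sout)] < stot - 1e-9) sout <- c(sout, stot)
  res <- sapply(1:3, function(k) approx(s, pts[, k], xout = sout)$y)
  res <- matrix(res, ncol = 3)

  n <- nrow(res)
  tang <- matrix(0, n, 3)
  tang[1, ] <- res[2, ] - res[1, ]
  tang[n, ] <- res[n, ] - res[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- res[3:n, ] - res[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))

  normal <- matrix(0, n, 3)
  binormal <- matrix(0, n, 3)
  # initial normal: any unit vector orthogonal to the first tangent
  t0 <- tang[1, ]
  ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n0 <- ref - sum(ref * t0) * t0
  normal[1, ] <- n0 / sqrt(sum(n0^2))
  binormal[1, ] <- cross3(t0, normal[1, ])
  for (i in 2:n) {
    v <- normal[i - 1, ] - sum(normal[i - 1, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- binormal[i - 1, ] - sum(binormal[i - 1, ] * tang[i, ]) * tang[i, ]
    normal[i, ] <- v / sqrt(sum(v^2))
    binormal[i, ] <- cross3(tang[i, ], normal[i, ])
  }
  centerline3d(res, arclength = sout, tangent = tang, normal = normal,
               binormal = binormal)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# interpolated position and frame at arclength s (frame taken from the
# nearest station, re-orthogonalized against the interpolated tangent)
frame_at <- function(cl, s) {
  sa <- cl$arclength
  if (s < sa[1] - 1e-9 || s > sa[length(sa)] + 1e-9) return(NULL)
  p <- vapply(1:3, function(k) approx(sa, cl$points[, k], xout = s)$y, numeric(1))
  i <- which.min(abs(sa - s))
  tg <- vapply(1:3, function(k) approx(sa, cl$tangent[, k], xout = s)$y, numeric(1))
  tg <- tg / sqrt(sum(tg^2))
  nv <- cl$normal[i, ] - sum(cl$normal[i, ] * tg) * tg
  nv <- nv / sqrt(sum(nv^2))
  bv <- cross3(tg, nv)
  list(point = p, tangent = tg, normal = nv, binormal = bv)
}

# resample a closed polygon to k vertices uniformly by perimeter arclength
resample_polygon <- function(poly, k) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  tot <- s[n + 1]
  sq <- seq(0, tot, length.out = k + 1)[seq_len(k)]
  cbind(approx(s, closed[, 1], xout = sq)$y,
        approx(s, closed[, 2], xout = sq)$y)
}

#' Place per-frame 2D contours into 3D along a centerline
#'
#' Frame `i` maps to arclength `s_i = offset + (i - 1) * frame_spacing`; each
#' 2D contour point (x, y) maps rigidly to
#' `C(s_i) + x * normal(s_i) + y * binormal(s_i)`. The placement is an
#' isometry: in-frame distances and areas are preserved exactly. Frames whose
#' arclength falls outside the centerline are dropped with a warning.
#'
#' @param contours list of n x 2 polygons (mm, frame coordinates).
#' @param cl a framed [centerline3d()] (see [build_frames()]).
#' @param frame_spacing pullback frame spacing, mm.
#' @param registration_offset arclength of the first frame, mm.
#' @param ring_size number of points per output ring.
#' @return list with `rings` (list of ring_size x 3 matrices), `arclengths`,
#'   and `frames_used` (indices of placed frames).
#' @export
place_contours <- function(contours, cl, frame_spacing, registration_offset = 0,
                           ring_size = 72L) {
  stopifnot(!is.null(cl$normal))
  rings <- list(); arcl <- numeric(0); used <- integer(0)
  for (i in seq_along(contours)) {
    s <- registration_offset + (i - 1) * frame_spacing
    fr <- frame_at(cl, s)
    if (is.null(fr)) next
    poly <- resample_polygon(contours[[i]], ring_size)
    ring <- t(apply(poly, 1, function(p)
      fr$point + p[1] * fr$normal + p[2] * fr$binormal))
    rings[[length(rings) + 1]] <- ring
    arcl <- c(arcl, s)
    used <- c(used, i)
  }
  if (length(used) < length(contours))
    warning(sprintf("%d frame(s) fell outside the centerline and were dropped",
                    length(contours) - length(used)))
  list(rings = rings, arclengths = arcl, frames_used = used)
}

#' Transform a 2D strut cloud into 3D along the centerline
#'
#' Applies the same rigid per-frame mapping as [place_contours()], preserving
#' cluster ids, then links struts across adjacent frames into stent-wire
#' sample sets: struts in neighboring frames closer than `link_dist` mm share
#' a `wire_id`.
#'
#' @param cloud data frame of strut points (columns `frame`, `x_mm`, `y_mm`,
#'   `cluster`, `type`).
#' @param cl a framed [centerline3d()].
#' @param frame_spacing,registration_offset as in [place_contours()].
#' @param link_dist cross-frame linking distance, mm.
#' @return the cloud with added `x3d`, `y3d`, `z3d`, `arclength`, `wire_id`.
#' @export
transform_struts <- function(cloud, cl, frame_spacing, registration_offset = 0,
                             link_dist = 0.3) {
  if (nrow(cloud) == 0) return(cbind(cloud, x3d = numeric(0), y3d = numeric(0),
                                     z3d = numeric(0), arclength = numeric(0),
                                     wire_id = integer(0)))
  out <- NULL
  for (i in seq_len(nrow(cloud))) {
    s <- registration_offset + (cloud$frame[i] - 1) * frame_spacing
    fr <- frame_at(cl, s)
    if (is.null(fr)) next
    p <- fr$point + cloud$x_mm[i] * fr$normal + cloud$y_mm[i] * fr$binormal
    out <- rbind(out, cbind(cloud[i, , drop = FALSE],
                            data.frame(x3d = p[1], y3d = p[2], z3d = p[3],
                                       arclength = s)))
  }
  if (is.null(out)) stop("all strut frames fell outside the centerline")
  rownames(out) <- NULL
  # union-find linking across adjacent frames
  n <- nrow(out)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  frames <- sort(unique(out$frame))
  for (fi in seq_along(frames)[-1]) {
    a <- which(out$frame == frames[fi - 1])
    b <- which(out$frame == frames[fi])
    if (frames[fi] - frames[fi - 1] > 1) next
    for (i in a) for (j in b) {
      d <- sqrt((out$x3d[i] - out$x3d[j])^2 + (out$y3d[i] - out$y3d[j])^2 +
                  (out$z3d[i] - out$z3d[j])^2)
      if (d <= link_dist + frame_spacing) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out$wire_id <- as.integer(factor(roots))
  out
}

#' Back-project 3D points to their frame coordinates
#'
#' Inverse of the rigid per-frame mapping: given the frame arclength, returns
#' the in-frame (x, y) of each 3D point.
#'
#' @param pts3 n x 3 matrix of mm points.
#' @param arclengths frame arclength per point, mm.
#' @param cl a framed [centerline3d()].
#' @return n x 2 matrix of frame coordinates.
#' @export
back_project <- function(pts3, arclengths, cl) {
  pts3 <- as.matrix(pts3)
  out <- matrix(0, nrow(pts3), 2)
  for (i in seq_len(nrow(pts3))) {
    fr <- frame_at(cl, arclengths[i])
    d <- pts3[i, ] - fr$point
    out[i, ] <- c(sum(d * fr$normal), sum(d * fr$binormal))
  }
  out
}

#' Loft a ring stack into a triangulated tubular surface
#'
#' Adjacent rings are joined by quads split into two triangles, with the seam
#' aligned by minimal twist (the cyclic shift minimizing total vertex
#' distance); ends are clipped flat with centroid-fan caps. Optional
#' Laplacian smoothing (lambda = 0.1, 5 iterations) is off by default.
#'
#' @param rings list of k x 3 matrices with equal k and consistent winding.
#' @param smooth logical; apply Laplacian smoothing.
#' @param lambda,smooth_iters smoothing parameters.
#' @return An object of class `vessel_mesh`: `vertices` (V x 3), `triangles`
#'   (F x 3, 1-based), `n_rings`, `ring_size`.
#' @export
loft_mesh <- function(rings, smooth = FALSE, lambda = 0.1, smooth_iters = 5L) {
  stopifnot(length(rings) >= 2)
  k <- nrow(rings[[1]])
  stopifnot(all(vapply(rings, nrow, integer(1)) == k))
  nr <- length(rings)
  # seam alignment by minimal twist
  aligned <- rings
  for (i in 2:nr) {
    a <- aligned[[i - 1]]; b <- aligned[[i]]
    costs <- vapply(0:(k - 1), function(sh) {
      idx <- ((seq_len(k) - 1 + sh) %% k) + 1
      sum((a - b[idx, , drop = FALSE])^2)
    }, numeric(1))
    sh <- which.min(costs) - 1
    idx <- ((seq_len(k) - 1 + sh) %% k) + 1
    aligned[[i]] <- b[idx, , drop = FALSE]
  }
  verts <- do.call(rbind, aligned)
  tris <- NULL
  for (i in seq_len(nr - 1)) {
    base <- (i - 1) * k
    for (j in seq_len(k)) {
      jn <- j %% k + 1
      a <- base + j; b <- base + jn; c2 <- base + k + j; d <- base + k + jn
      # fold-over guard: adjacent rings must not interpenetrate
      tris <- rbind(tris, c(a, b, d), c(a, d, c2))
    }
  }
  # flat end caps
  c1 <- colMeans(aligned[[1]]); c2v <- colMeans(aligned[[nr]])
  verts <- rbind(verts, c1, c2v)
  i1 <- nrow(verts) - 1; i2 <- nrow(verts)
  for (j in seq_len(k)) {
    jn <- j %% k + 1
    tris <- rbind(tris, c(i1, jn, j))
    base <- (nr - 1) * k
    tris <- rbind(tris, c(i2, base + j, base + jn))
  }
  mesh <- structure(list(vertices = verts, triangles = tris, n_rings = nr,
                         ring_size = k), class = "vessel_mesh")
  if (mesh_volume(mesh) < 0) {  # enforce outward orientation
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  }
  if (fold_over(aligned)) stop("fold-over; reduce step or smooth centerline")
  if (smooth) mesh <- laplacian_smooth(mesh, lambda, smooth_iters)
  mesh
}

# detect interpenetrating adjacent rings: matched ring vertices must advance
# monotonically along the local axis, and the axis itself must not reverse
fold_over <- function(rings) {
  prev_axis <- NULL
  for (i in seq_along(rings)[-1]) {
    axis <- colMeans(rings[[i]]) - colMeans(rings[[i - 1]])
    la <- sqrt(sum(axis^2))
    if (la < 1e-12) return(TRUE)
    axis <- axis / la
    if (!is.null(prev_axis) && sum(axis * prev_axis) <= 0) return(TRUE)
    adv <- as.matrix(rings[[i]] - rings[[i - 1]]) %*% axis
    if (any(adv <= 0)) return(TRUE)
    prev_axis <- axis
  }
  FALSE
}

laplacian_smooth <- function(mesh, lambda, iters) {
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- nrow(v)
  nb <- vector("list", n)
  for (r in seq_len(nrow(tr))) {
    t3 <- tr[r, ]
    nb[[t3[1]]] <- c(nb[[t3[1]]], t3[2], t3[3])
    nb[[t3[2]]] <- c(nb[[t3[2]]], t3[1], t3[3])
    nb[[t3[3]]] <- c(nb[[t3[3]]], t3[1], t3[2])
  }
  nb <- lapply(nb, unique)
  for (it in seq_len(iters)) {
    vn <- v
    for (i in seq_len(n)) {
      m <- colMeans(v[nb[[i]], , drop = FALSE])
      vn[i, ] <- v[i, ] + lambda * (m - v[i, ])
    }
    v <- vn
  }
  mesh$vertices <- v
  mesh
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh: %d vertices, %d triangles (%d rings x %d)>\n",
              nrow(x$vertices), nrow(x$triangles), x$n_rings, x$ring_size))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `vessel_mesh`.
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]
  b <- v[tr[, 3], ] - v[tr[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# signed volume via divergence theorem (positive = outward orientation)
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
        p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
        p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Euler characteristic check for watertightness
#' @param mesh a `vessel_mesh`.
#' @return list with `V`, `E`, `F` and `euler` (V - E + F; 2 for a closed
#'   genus-0 surface).
#' @export
mesh_euler <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  E <- nrow(unique(e))
  V <- nrow(mesh$vertices)
  F <- nrow(tr)
  list(V = V, E = E, F = F, euler = V - E + F)
}

#' Slice a lofted mesh with planes orthogonal to the centerline
#'
#' At each station the mesh is cut by the plane through `C(s)` with normal
#' `tangent(s)`; the intersection polygon's area and area-equivalent
#' diameter `2 sqrt(A / pi)` are reported.
#'
#' @param mesh a `vessel_mesh`.
#' @param cl a framed [centerline3d()].
#' @param station_mm station spacing, mm.
#' @return data frame: `arclength`, `area_mm2`, `diameter_mm`.
#' @export
mesh_cross_sections <- function(mesh, cl, station_mm = 0.5) {
  smax <- max(cl$arclength)
  stations <- seq(0, smax, by = station_mm)
  v <- mesh$vertices; tr <- mesh$triangles
  out <- NULL
  for (s in stations) {
    fr <- frame_at(cl, s)
    if (is.null(fr)) next
    d <- as.numeric((v - matrix(fr$point, nrow(v), 3, byrow = TRUE)) %*% fr$tangent)
    pts <- NULL
    for (r in seq_len(nrow(tr))) {
      ids <- tr[r, ]
      dv <- d[ids]
      for (q in 1:3) {
        i <- ids[q]; j <- ids[q %% 3 + 1]
        if ((d[i] < 0) != (d[j] < 0)) {
          t0 <- d[i] / (d[i] - d[j])
          pts <- rbind(pts, v[i, ] + t0 * (v[j, ] - v[i, ]))
        }
      }
    }
    if (is.null(pts) || nrow(pts) < 3) next
    # project to in-plane coordinates, order by angle (star-shaped sections)
    rel <- pts - matrix(fr$point, nrow(pts), 3, byrow = TRUE)
    u <- as.numeric(rel %*% fr$normal)
    w <- as.numeric(rel %*% fr$binormal)
    ctr <- c(mean(u), mean(w))
    ang <- atan2(w - ctr[2], u - ctr[1])
    o <- order(ang)
    u <- u[o]; w <- w[o]
    area <- abs(sum(u * c(w[-1], w[1]) - c(u[-1], u[1]) * w)) / 2
    out <- rbind(out, data.frame(arclength = s, area_mm2 = area,
                                 diameter_mm = 2 * sqrt(area / pi)))
  }
  out
}

#' Compare a reconstructed 3D model against per-frame 2D measurements
#'
#' The mesh is sliced every `station_mm` along the centerline; a linear
#' arclength-to-frame mapping is fitted through at least two landmarks
#' (arclength in the model, frame index in the series); paired series yield
#' the correlation, residual sum of squares, and Bland-Altman statistics.
#'
#' @param mesh a `vessel_mesh`.
#' @param cl a framed [centerline3d()].
#' @param frame_series data frame with `frame`, `area_mm2` (and optionally
#'   `diameter_mm`) from the 2D analysis.
#' @param landmarks data frame with `arclength` and `frame` (>= 2 rows).
#' @param station_mm station spacing, mm.
#' @return list: `series` (paired station table) and `report` (r_squared,
#'   rss, bland_altman bias and limits of agreement, per quantity).
#' @export
compare_model_to_frames <- function(mesh, cl, frame_series, landmarks,
                                    station_mm = 0.5) {
  if (is.null(landmarks) || nrow(landmarks) < 2)
    stop("at least 2 landmarks are required for registration")
  fit <- lm(frame ~ arclength, data = landmarks)
  xs <- mesh_cross_sections(mesh, cl, station_mm)
  frame_at_s <- predict_frame(fit, xs$arclength)
  ok <- frame_at_s >= min(frame_series$frame) & frame_at_s <= max(frame_series$frame)
  xs <- xs[ok, , drop = FALSE]
  frame_at_s <- frame_at_s[ok]
  a2 <- approx(frame_series$frame, frame_series$area_mm2, xout = frame_at_s)$y
  series <- data.frame(station_mm = xs$arclength, frame = frame_at_s,
                       area_model = xs$area_mm2, area_frames = a2,
                       diam_model = xs$diameter_mm,
                       diam_frames = 2 * sqrt(a2 / pi))
  if ("diameter_mm" %in% names(frame_series))
    series$diam_frames <- approx(frame_series$frame, frame_series$diameter_mm,
                                 xout = frame_at_s)$y
  stats_for <- function(m, f) {
    d <- m - f
    list(r_squared = cor(m, f)^2, rss = sum(d^2),
         bland_altman = c(bias = mean(d),
                          lower = mean(d) - 1.96 * sd(d),
                          upper = mean(d) + 1.96 * sd(d)))
  }
  report <- list(area = stats_for(series$area_model, series$area_frames),
                 diameter = stats_for(series$diam_model, series$diam_frames))
  list(series = series, report = report)
}

predict_frame <- function(fit, s) {
  as.numeric(stats::predict(fit, newdata = data.frame(arclength = s)))
}
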