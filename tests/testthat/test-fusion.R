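test_that("frames on a straight line share one normal; spacing is uniform", {
  cl <- build_frames(cbind(0, 0, seq(0, 10, by = 1)), step = 0.5)
  expect_lt(max(abs(sweep(cl$normal, 2, cl$normal[1, ]))), 1e-12)
  steps <- diff(cl$arclength)
  expect_lt(max(abs(head(steps, -1) - 0.5)), 1e-6)
  # orthonormality
  dots <- rowSums(cl$tangent * cl$normal)
  expect_lt(max(abs(dots)), 1e-9)
  expect_lt(max(abs(rowSums(cl$normal^2) - 1)), 1e-9)
})

test_that("frames on a planar circle transport without flips", {
  th <- seq(0, 2 * pi, length.out = 200)
  pts <- cbind(10 * cos(th), 10 * sin(th), 0)
  cl <- build_frames(pts, step = 0.3)
  rot <- acos(pmin(1, rowSums(cl$normal[-1, ] * cl$normal[-nrow(cl$normal), ])))
  expect_lt(max(rot) * 180 / pi, 30)
})

test_that("duplicate consecutive points are removed with a warning", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 5))
  expect_warning(cl <- build_frames(pts, 0.5), "duplicate")
  expect_equal(nrow(cl$points), 11)
})

test_that("contour placement is a rigid isometry", {
  th <- seq(0, 2 * pi, length.out = 201)[1:200]
  helix <- cbind(8 * cos(th), 8 * sin(th), 3 * th)
  cl <- build_frames(helix, step = 0.4)
  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  placed <- place_contours(list(sq, sq, sq), cl, frame_spacing = 2,
                           registration_offset = 1, ring_size = 4L)
  for (r in placed$rings) {
    d3 <- as.matrix(dist(r))
    d2 <- as.matrix(dist(sq))
    expect_lt(max(abs(d3 - d2)), 1e-9)
  }
  # centered contours have centroids on the centerline
  circ <- cbind(cos(th[1:72] * 5), sin(th[1:72] * 5))
  circ <- cbind(1.5 * cos(2 * pi * (0:71) / 72), 1.5 * sin(2 * pi * (0:71) / 72))
  pc <- place_contours(rep(list(circ), 5), cl, frame_spacing = 2,
                       registration_offset = 0.8)
  for (i in seq_along(pc$rings)) {
    ctr <- colMeans(pc$rings[[i]])
    fr_pt <- vessel3d:::frame_at(cl, pc$arclengths[i])$point
    expect_lt(sqrt(sum((ctr - fr_pt)^2)), 1e-6)
  }
})

test_that("frames beyond the centerline are dropped with a warning", {
  cl <- build_frames(cbind(0, 0, 0:5), step = 0.5)
  circ <- cbind(cos(2 * pi * (0:35) / 36), sin(2 * pi * (0:35) / 36))
  expect_warning(pl <- place_contours(rep(list(circ), 30), cl, 1), "dropped")
  expect_lt(length(pl$rings), 30)
})

test_that("strut transform preserves distances and inverts exactly", {
  th <- seq(0, 4 * pi, length.out = 120)
  helix <- cbind(6 * cos(th), 6 * sin(th), 2 * th)
  cl <- build_frames(helix, step = 0.4)
  ang <- 2 * pi * (0:7) / 8
  cloud <- do.call(rbind, lapply(1:4, function(f)
    data.frame(frame = f, x_mm = 1.6 * cos(ang), y_mm = 1.6 * sin(ang),
               cluster = 1:8, type = "metal")))
  tc <- transform_struts(cloud, cl, frame_spacing = 1, registration_offset = 2)
  for (f in 1:4) {
    s <- tc[tc$frame == f, ]
    d3 <- as.matrix(dist(s[, c("x3d", "y3d", "z3d")]))
    d2 <- as.matrix(dist(cbind(s$x_mm, s$y_mm)))
    expect_lt(max(abs(d3 - d2)), 1e-9)
  }
  back <- back_project(as.matrix(tc[, c("x3d", "y3d", "z3d")]),
                       tc$arclength, cl)
  expect_lt(max(abs(back - cbind(tc$x_mm, tc$y_mm))), 1e-9)
  expect_identical(tc$cluster, cloud$cluster[seq_len(nrow(tc))])
})

test_that("struts on a straight centerline land on the expected cylinder", {
  cl <- build_frames(cbind(0, 0, seq(0, 8, by = 0.5)), step = 0.5)
  ang <- 2 * pi * (0:7) / 8
  cloud <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, x_mm = 1.6 * cos(ang), y_mm = 1.6 * sin(ang),
               cluster = 1:8, type = "metal")))
  tc <- transform_struts(cloud, cl, frame_spacing = 1)
  rad <- sqrt(tc$x3d^2 + tc$y3d^2)
  expect_lt(max(abs(rad - 1.6)), 1e-9)
})

test_that("lofted cylinder has the analytic lateral area and is watertight", {
  th <- 2 * pi * (0:359) / 360
  circ <- cbind(2 * cos(th), 2 * sin(th))
  cl <- build_frames(cbind(0, 0, c(0, 0.5, 1)), step = 0.5)
  pl <- place_contours(list(circ, circ, circ), cl, frame_spacing = 0.5,
                       ring_size = 360L)
  mesh <- loft_mesh(pl$rings)
  lateral <- mesh_area(mesh) - 2 * contour_metrics(circ)$area
  expect_lt(abs(lateral / (2 * pi * 2 * 1) - 1), 0.005)
  eu <- mesh_euler(mesh)
  expect_equal(eu$euler, 2)
})

test_that("Laplacian smoothing shrinks cross-sections by less than 1%", {
  th <- 2 * pi * (0:71) / 72
  circ <- cbind(2 * cos(th), 2 * sin(th))
  cl <- build_frames(cbind(0, 0, seq(0, 10, by = 0.5)), step = 0.5)
  pl <- place_contours(rep(list(circ), 21), cl, frame_spacing = 0.5)
  plain <- loft_mesh(pl$rings)
  smoothed <- loft_mesh(pl$rings, smooth = TRUE)
  a0 <- mesh_cross_sections(plain, cl, 1)
  a1 <- mesh_cross_sections(smoothed, cl, 1)
  mid <- 3:(nrow(a0) - 3)
  shrink <- 1 - a1$area_mm2[mid] / a0$area_mm2[mid]
  expect_true(all(shrink < 0.01))
})

test_that("interpenetrating rings raise a fold-over error", {
  th <- 2 * pi * (0:35) / 36
  r1 <- cbind(2 * cos(th), 2 * sin(th), 0)
  r2 <- cbind(2 * cos(th), 2 * sin(th), -1)  # behind the first ring
  r3 <- cbind(2 * cos(th), 2 * sin(th), 1)
  expect_error(loft_mesh(list(r1, r3, r2)), "fold-over")
})

test_that("cylinder cross-sections match the ring area within 2%", {
  th <- 2 * pi * (0:71) / 72
  circ <- cbind(2 * cos(th), 2 * sin(th))
  cl <- build_frames(cbind(0, 0, seq(0, 6, by = 0.5)), step = 0.5)
  pl <- place_contours(rep(list(circ), 13), cl, frame_spacing = 0.5)
  mesh <- loft_mesh(pl$rings)
  xs <- mesh_cross_sections(mesh, cl, 0.5)
  ring_area <- contour_metrics(circ)$area
  expect_true(all(abs(xs$area_mm2 / ring_area - 1) < 0.02))
  expect_true(all(abs(xs$area_mm2 / (4 * pi) - 1) < 0.005))
})

test_that("self-comparison through identity registration is near perfect", {
  th <- 2 * pi * (0:71) / 72
  radii <- 1.5 + 0.3 * sin(2 * pi * (1:15) / 15)
  contours <- lapply(radii, function(r) cbind(r * cos(th), r * sin(th)))
  cl <- build_frames(cbind(0, 0, seq(0, 14 * 0.5 + 1, by = 0.5)), step = 0.5)
  pl <- place_contours(contours, cl, frame_spacing = 0.5)
  mesh <- loft_mesh(pl$rings)
  areas <- vapply(contours, function(p) contour_metrics(p)$area, numeric(1))
  fs <- data.frame(frame = 1:15, area_mm2 = areas)
  lmk <- data.frame(arclength = c(0, 7), frame = c(1, 15))
  cmp <- compare_model_to_frames(mesh, cl, fs, lmk)
  expect_gte(cmp$report$area$r_squared, 0.99)
  expect_lt(abs(cmp$report$area$bland_altman["bias"]), 0.05)
  expect_error(compare_model_to_frames(mesh, cl, fs, lmk[1, , drop = FALSE]),
               "landmarks")
})
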