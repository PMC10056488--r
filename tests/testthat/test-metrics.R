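test_that("closed-form polygon metrics: regular 360-gon and unit square", {
  th <- 2 * pi * (0:359) / 360
  gon <- cbind(2 * cos(th), 2 * sin(th))
  m <- contour_metrics(gon)
  expect_lt(abs(m$area / (pi * 4) - 1), 0.001)
  expect_lt(abs(m$perimeter / (2 * pi * 2) - 1), 0.001)

  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ms <- contour_metrics(sq)
  expect_equal(ms$area, 1)
  expect_equal(ms$perimeter, 4)
  expect_equal(ms$min_diameter, 1)
  expect_equal(ms$max_diameter, sqrt(2))
})

test_that("polygon metrics are invariant under rigid motions", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(n, 1, 3)
    poly <- cbind(r * cos(th), r * sin(th))  # star-shaped, simple
    m0 <- contour_metrics(poly)
    a <- runif(1, 0, 2 * pi); t <- runif(2, -5, 5)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    m1 <- contour_metrics(sweep(poly %*% R, 2, t, "+"))
    expect_equal(m1$area, m0$area, tolerance = 1e-9)
    expect_equal(m1$perimeter, m0$perimeter, tolerance = 1e-9)
    expect_equal(m1$min_diameter, m0$min_diameter, tolerance = 1e-9)
    expect_equal(m1$max_diameter, m0$max_diameter, tolerance = 1e-9)
  }
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(contour_metrics(bowtie), "self-intersecting")
})

test_that("plaque burden follows the EEM definition and is monotone", {
  sq <- function(s) cbind(c(-s, s, s, -s), c(-s, -s, s, s))
  expect_equal(plaque_burden(sq(sqrt(5) / 2), sq(sqrt(10) / 2)), 50)
  expect_equal(plaque_burden(sq(1), sq(1)), 0)
  expect_error(plaque_burden(sq(2), sq(1)), "lumen not inside wall")
  b1 <- plaque_burden(sq(0.8), sq(2))
  b2 <- plaque_burden(sq(0.5), sq(2))
  expect_gt(b2, b1)

  ph <- oct_small()
  lp <- contour_to_polygon(ph$segs[[1]]$lumen, 0.01)
  wp <- contour_to_polygon(ph$segs[[1]]$adventitia, 0.01)
  truth <- 100 * (1 - 1.5^2 / 2.2^2)  # analytic: r_lumen 1.5, r_adv 2.2 mm
  expect_lt(abs(plaque_burden(lp, wp) - truth), 1)
})

test_that("plaque class metrics recover a quarter-annulus arc and area", {
  n <- 401
  ctr <- c(201, 201)
  mask <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) {
    r <- sqrt((i - ctr[1])^2 + (j - ctr[2])^2)
    th <- atan2(j - ctr[2], i - ctr[1])
    if (r >= 100 && r <= 150 && th >= 0 && th <= pi / 2) mask[i, j] <- 1L
  }
  m <- plaque_class_metrics(mask, ctr, spacing = 0.01)
  expect_lt(abs(m$angle_deg - 90), 2)
  analytic <- pi / 4 * (1.5^2 - 1.0^2)
  expect_lt(abs(m$area_mm2 / analytic - 1), 0.02)

  expect_equal(nrow(plaque_class_metrics(matrix(0L, 10, 10), c(5, 5), 0.01)), 0)
  ring <- matrix(0L, 81, 81)
  for (i in 1:81) for (j in 1:81) {
    r <- sqrt((i - 41)^2 + (j - 41)^2)
    if (r >= 20 && r <= 30) ring[i, j] <- 2L
  }
  # bin width must respect the pixel sampling of the ring circumference
  expect_equal(plaque_class_metrics(ring, c(41, 41), 0.01,
                                    n_bins = 90L)$angle_deg, 360)
})

test_that("embedded octagonal stent: CSA closed form, no unapposed struts", {
  sp <- 0.01
  n_al <- 360
  lum <- radial_contour(rep(1.6 / sp, n_al), "lumen")
  ang <- (0:7) * 45
  struts <- data.frame(frame = 1, aline = ang / 360 * n_al + 1,
                       depth_px = 1.6 / sp)
  sm <- stent_metrics(struts, list(lum), sp, strut_thickness = 0.1,
                      malappose_threshold = 0.1)
  expect_equal(sm$per_frame$stent_csa_mm2, 2 * sqrt(2) * 1.6^2,
               tolerance = 1e-9)
  expect_equal(sm$per_strut$malapposition_mm, rep(-0.1, 8), tolerance = 1e-9)
  expect_equal(sm$pct_unapposed, 0)
  expect_equal(sm$per_frame$restenosis_burden_pct, 0)
})

test_that("struts floating 0.3 mm from the wall are 100% unapposed", {
  sp <- 0.01
  lum <- radial_contour(rep(2.0 / sp, 360), "lumen")
  ang <- (0:7) * 45
  struts <- data.frame(frame = 1, aline = ang / 360 * 360 + 1,
                       depth_px = 1.6 / sp)
  sm <- stent_metrics(struts, list(lum), sp, strut_thickness = 0.1,
                      malappose_threshold = 0.1)
  expect_equal(sm$per_strut$malapposition_mm, rep(0.3, 8), tolerance = 1e-9)
  expect_equal(sm$pct_unapposed, 100)
})

test_that("a 5-frame strut-free run inside the stented extent flags one fracture", {
  sp <- 0.01
  lum <- radial_contour(rep(170, 360), "lumen")
  frames_with <- setdiff(10:29, 18:22)
  struts <- do.call(rbind, lapply(frames_with, function(f)
    data.frame(frame = f, aline = c(1, 121, 241), depth_px = 160)))
  contours <- rep(list(lum), 30)
  sm <- stent_metrics(struts, contours, sp, gap_frames = 3)
  expect_equal(nrow(sm$fractures), 1)
  expect_equal(sm$fractures$from, 18)
  expect_equal(sm$fractures$to, 22)

  empty <- stent_metrics(NULL, contours, sp)
  expect_equal(nrow(empty$per_frame), 0)
})
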