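test_that("metal strut candidates appear on strut A-lines and nowhere else", {
  ph <- oct_struts()
  fr <- ph$frames[[1]]
  den <- bilateral_denoise(fr)
  cand <- detect_metal_candidates(den, ph$segs[[1]]$lumen)
  truth_alines <- ph$truth$struts$aline[ph$truth$struts$frame == 1]
  circ_dist <- function(a, t) min(pmin(abs(a - t), 360 - abs(a - t)))
  near_truth <- vapply(cand$aline, function(a) circ_dist(a, truth_alines) <= 3,
                       logical(1))
  expect_true(all(near_truth))  # no false alarms away from struts
  hit <- vapply(truth_alines, function(a) any(abs(cand$aline - a) <= 3),
                logical(1))
  expect_gte(sum(hit), 7)  # at least 7 of 8 strut groups found
})

test_that("uniform frames yield no candidates; bright spots without shadows are rejected", {
  lum <- radial_contour(rep(100, 90), "lumen")
  uni <- polar_frame(matrix(0.3, 90, 300), 0.01)
  expect_equal(nrow(detect_metal_candidates(uni, lum)), 0)

  # calcium-like bright spot with bright tissue behind it: no shadow
  img <- matrix(0.3, 90, 300)
  img[44:46, 118:122] <- 1
  fr <- polar_frame(img, 0.01)
  expect_equal(nrow(detect_metal_candidates(fr, lum)), 0)
})

test_that("DBSCAN matches the brute-force eps-graph oracle and is permutation invariant", {
  set.seed(17)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    xy <- matrix(runif(2 * n, 0, 3), ncol = 2)
    eps <- runif(1, 0.1, 0.8)
    got <- dbscan_points(xy, eps, min_pts = 1)
    want <- dbscan_oracle_minpts1(xy, eps)
    expect_true(same_partition(got, want))
    perm <- sample(n)
    got_p <- dbscan_points(xy[perm, ], eps, min_pts = 1)
    expect_true(same_partition(got_p, want[perm]))
  }
})

test_that("DBSCAN separates groups farther apart than eps and keeps singletons with min_pts 1", {
  g1 <- cbind(rnorm(5, 0, 0.02), rnorm(5, 0, 0.02))
  g2 <- cbind(rnorm(5, 1, 0.02), rnorm(5, 1, 0.02))
  lab <- dbscan_points(rbind(g1, g2), eps = 0.2, min_pts = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(dbscan_points(matrix(c(0.5, 0.5), 1), 0.2, 1), 1L)
  # min_pts above the group size turns isolated points into noise
  lab2 <- dbscan_points(rbind(c(0, 0), c(5, 5), c(5.01, 5), c(5, 5.01)),
                        eps = 0.1, min_pts = 3)
  expect_equal(lab2[1], -1L)
  expect_true(all(lab2[2:4] == lab2[2]))
})

test_that("cluster centroids are stable under candidate permutation", {
  ph <- oct_struts()
  den <- bilateral_denoise(ph$frames[[1]])
  cand <- detect_metal_candidates(den, ph$segs[[1]]$lumen)
  a <- cluster_struts(cand, den)
  b <- cluster_struts(cand[sample(nrow(cand)), ], den)
  expect_equal(sort(a$x_mm), sort(b$x_mm), tolerance = 1e-12)
  expect_equal(sort(a$y_mm), sort(b$y_mm), tolerance = 1e-12)
  expect_lte(nrow(a), nrow(cand))
})

test_that("strut recall and precision reach 0.9 with one cluster per true strut", {
  ph <- oct_struts()
  cloud <- detect_struts_pullback(ph$frames, ph$segs)
  rates <- strut_match_rates(cloud, ph$truth, 1:5)
  expect_gte(rates$recall, 0.9)
  expect_gte(rates$precision, 0.9)
})

test_that("BVS toy-mask rule chain keeps exactly the in-band, mid-size, low-aspect boxes", {
  img <- matrix(0.5, 200, 200)
  # lumen border: circle of radius 60 px around (100, 100)
  th <- 2 * pi * (0:119) / 120
  poly <- cbind(60 * cos(th), 60 * sin(th))
  boxes <- list(
    list(rows = 100 + 40:41, cols = 100 + 43:46),       # area 8: too small
    list(rows = 100 + (-2:2), cols = 100 + (-62:-59)),  # area 20 near border
    list(rows = 100 + (-63:-58), cols = 100 + (-3:2)),  # area 36 near border
    list(rows = 100 + 56:60, cols = 100 + (-5:4)),      # area 50: too big
    list(rows = 10:13, cols = 10:14)                    # area 20 far away
  )
  for (b in boxes) img[b$rows, b$cols] <- 0.02
  st <- detect_bvs_struts(img, poly, center = c(100, 100), spacing = 0.01)
  expect_equal(sort(st$area_px), c(20, 36))
})

test_that("boxes with aspect ratio above 5 are rejected", {
  img <- matrix(0.5, 200, 200)
  th <- 2 * pi * (0:119) / 120
  poly <- cbind(60 * cos(th), 60 * sin(th))
  img[100 + 58:59, 100 + (-6:5)] <- 0.02  # 2 x 12, area 24, aspect ~6
  st <- detect_bvs_struts(img, poly, center = c(100, 100), spacing = 0.01)
  expect_equal(nrow(st), 0)
})

test_that("phantom BVS struts on the lumen are recalled", {
  ang <- c(20, 80, 140, 200, 260, 320)
  layout <- data.frame(frame = 1, angle = ang, depth = 1.48, type = "BVS")
  spec <- oct_phantom_spec(n_frames = 1, strut_layout = layout, noise_seed = 5)
  ph <- synth_oct_pullback(spec)
  den <- bilateral_denoise(ph$frames[[1]])
  lum <- segment_lumen(den, NULL)
  sc <- scan_convert_frame(den)
  st <- detect_bvs_struts(sc$image, contour_to_polygon(lum), sc$center,
                          sc$spacing)
  truth_al <- ph$truth$struts$aline
  hits <- vapply(truth_al, function(a) any(abs(st$aline - a) <= 3), logical(1))
  expect_gte(sum(hits), 5)
})
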