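test_that("vesselness is strong on the tube axis, zero on constants, offset invariant", {
  ph <- ct_tube()
  v <- ph$vesselness$intensities
  on_axis <- v[33, 33, 20:90]
  off_axis <- v[33 + round(3 / 0.4), 33, 20:90]  # 2r = 3 mm from the axis
  expect_gt(mean(on_axis), 5 * mean(off_axis))

  const <- volume3d(array(100, c(16, 16, 16)), c(1, 1, 1))
  expect_equal(max(vesselness_preprocess(const, 1.5)$intensities), 0)

  shifted <- volume3d(ph$volume$intensities + 100, ph$volume$spacing)
  v2 <- vesselness_preprocess(shifted)$intensities
  expect_lt(max(abs(v2 - v)), 0.01)
})

test_that("scales below the voxel spacing are skipped with a warning", {
  ph <- ct_tube()
  expect_warning(vesselness_preprocess(ph$volume, scales = c(0.1, 1.5)),
                 "skipping")
})

test_that("centerline on a straight tube stays within 1 voxel of the true axis", {
  ph <- ct_tube()
  dev <- sqrt((ph$cl$points[, 1] - 12.8)^2 + (ph$cl$points[, 2] - 12.8)^2)
  expect_lt(max(dev), 0.4)
})

test_that("start == end yields a single-point path; helix arclength matches the analytic value", {
  ph <- ct_tube()
  cl <- extract_centerline(ph$vesselness, c(33, 33, 20), c(33, 33, 20))
  expect_equal(nrow(cl$points), 1)

  spec <- ct_phantom_spec(grid_dim = c(80, 80, 75), spacing = c(0.4, 0.4, 0.4),
                          centerline = list(type = "helix", center = c(16, 16),
                                            radius = 10, pitch = 20,
                                            z_range = c(4, 24)),
                          seed = 4)
  hx <- synth_ct_volume(spec)
  ves <- vesselness_preprocess(hx$volume)
  pts <- hx$truth$centerline$points
  st <- round(pts[1, ] / 0.4) + 1L
  en <- round(pts[nrow(pts), ] / 0.4) + 1L
  cl2 <- extract_centerline(ves, st, en)
  analytic <- 20 * sqrt((2 * pi * 10 / 20)^2 + 1)
  expect_lt(abs(max(cl2$arclength) / analytic - 1), 0.03)
})

test_that("sigmoid weights are 0.5 at their midpoints and in [0, 1]", {
  w <- sigmoid_weight("cp", "rising", 500, 0.05)
  expect_equal(eval_weight(w, 500), 0.5)
  wb <- sigmoid_weight("lumen", "band", c(200, 400), 0.05)
  x <- seq(-500, 1500, by = 10)
  expect_true(all(eval_weight(wb, x) >= 0 & eval_weight(wb, x) <= 1))
  expect_error(sigmoid_weight("lumen", "band", c(400, 200), 0.05))
})

test_that("calibrated weights separate the phantom classes", {
  ph <- ct_tube()
  w <- calibrate_weights(ph$volume, ph$seeds)
  expect_gte(eval_weight(w$lumen, 350), 0.9)
  expect_lte(eval_weight(w$lumen, 50), 0.1)
  expect_lte(eval_weight(w$lumen, 800), 0.1)
  # each weight covers its own seeds
  for (cls in c("lumen", "wall", "cp")) {
    hu <- ph$volume$intensities[ph$seeds[[cls]]]
    expect_gte(mean(eval_weight(w[[cls]], hu) >= 0.5), 0.9)
  }
})

test_that("seed permutation does not change the calibration", {
  ph <- ct_tube()
  a <- calibrate_weights(ph$volume, ph$seeds)
  seeds2 <- lapply(ph$seeds, function(m) m[rev(seq_len(nrow(m))), ])
  b <- calibrate_weights(ph$volume, seeds2)
  expect_equal(a, b)
})

test_that("unordered seed means raise a calibration error", {
  ph <- ct_tube()
  bad <- ph$seeds
  bad$wall <- ph$seeds$cp
  bad$cp <- ph$seeds$wall
  expect_error(calibrate_weights(ph$volume, bad), "calibration inconsistent")
})

test_that("level set recovers the noiseless lumen and both CP inclusions", {
  ph <- ct_tube()
  w <- calibrate_weights(ph$volume, ph$seeds)
  seg <- levelset_segment(ph$volume, w, ph$cl)
  lab <- ph$truth$labels$labels
  expect_gte(mask_dice(seg$lumen_mask, lab == 1), 0.95)
  cpc <- cp_components(seg$labels)
  expect_equal(cpc$n, 2)
  tc <- vessel3d:::.cpp_components26(lab == 3, dim(lab))
  for (k in 1:2) {
    best <- max(vapply(seq_len(cpc$n), function(j)
      mask_dice(tc == k, cpc$components == j), numeric(1)))
    expect_gte(best, 0.8)
  }
  # label composition invariants
  expect_equal(sum(seg$labels$labels == 3 & seg$labels$labels == 1), 0)
  expect_true(all(seg$lumen_mask[seg$labels$labels == 1]))
})

test_that("level-set evolution is deterministic across reruns", {
  ph <- ct_tube()
  w <- calibrate_weights(ph$volume, ph$seeds)
  a <- levelset_segment(ph$volume, w, ph$cl)
  b <- levelset_segment(ph$volume, w, ph$cl)
  expect_gte(mask_dice(a$lumen_mask, b$lumen_mask), 0.99)
})

test_that("near-zero force keeps the front from inflating past its initialization", {
  ph <- ct_tube()
  flat <- sigmoid_weight("lumen", "rising", 0, 1e-12)  # ~0.5 everywhere
  w <- list(lumen = flat, wall = flat,
            cp = sigmoid_weight("cp", "rising", 1e6, 0.05))
  seg <- levelset_segment(ph$volume, w, ph$cl, max_iter = 100L)
  td <- vessel3d:::.cpp_tube_distance(dim(ph$volume$intensities),
                                      ph$volume$spacing, ph$volume$origin,
                                      ph$cl$points)
  expect_true(all(td$dist[seg$lumen_mask] <= 2 * 0.4 + 1e-9))
})

test_that("segmentation quality does not improve with added noise", {
  dice <- numeric(0)
  for (nsd in c(0, 10, 20, 40)) {
    spec <- ct_phantom_spec(grid_dim = c(40, 40, 50), spacing = c(0.4, 0.4, 0.4),
                            centerline = list(type = "line", xy = c(8, 8),
                                              z_range = c(2, 17)),
                            noise_sd = nsd, seed = 21)
    ph <- synth_ct_volume(spec)
    lab <- ph$truth$labels$labels
    pick <- function(code, n = 30) {
      idx <- which(lab == code, arr.ind = TRUE)
      idx[round(seq(1, nrow(idx), length.out = n)), ]
    }
    # CP seeds from a fixed bright reference patch (no CP in this phantom):
    # synthesize by adding a constant to wall seeds is not meaningful, so
    # calibrate on lumen/wall plus a nominal CP stat via direct construction
    hu_l <- ph$volume$intensities[pick(1)]
    w <- list(
      lumen = sigmoid_weight("lumen", "band",
                             c(quantile(hu_l, 0.05) - 5, quantile(hu_l, 0.95) + 5),
                             4 / max(stats::IQR(hu_l), 5)),
      wall = sigmoid_weight("wall", "band", c(-20, 200), 0.1),
      cp = sigmoid_weight("cp", "rising", 600, 0.1))
    ves <- vesselness_preprocess(ph$volume)
    cl <- extract_centerline(ves, c(21, 21, 8), c(21, 21, 42))
    seg <- levelset_segment(ph$volume, w, cl)
    dice <- c(dice, mask_dice(seg$lumen_mask, lab == 1))
  }
  expect_true(all(diff(dice) <= 0.01))  # non-increasing up to voxel jitter
  expect_gte(dice[1], 0.95)
})

test_that("stent extent is localized within 2 stations and adapts to contrast", {
  spec <- ct_phantom_spec(stent_extent = c(10, 25), seed = 3)
  ph <- synth_ct_volume(spec)
  lab <- ph$truth$labels$labels
  st <- detect_stent_ctca(ph$volume, lab == 1, ph$truth$centerline)
  expect_lte(abs(st$extent_mm[1] - 10), 1)
  expect_lte(abs(st$extent_mm[2] - 25), 1)

  # doubling the stent HU contrast must not move the extent
  spec2 <- ct_phantom_spec(stent_extent = c(10, 25),
                           intensities = c(background = -100, ncp = 20,
                                           wall = 50, lumen = 350, cp = 800,
                                           stent = 2200), seed = 3)
  ph2 <- synth_ct_volume(spec2)
  st2 <- detect_stent_ctca(ph2$volume, ph2$truth$labels$labels == 1,
                           ph2$truth$centerline)
  expect_equal(st2$extent_mm, st$extent_mm)

  # no stent -> empty extent
  spec3 <- ct_phantom_spec(seed = 3)
  ph3 <- synth_ct_volume(spec3)
  st3 <- detect_stent_ctca(ph3$volume, ph3$truth$labels$labels == 1,
                           ph3$truth$centerline)
  expect_null(st3$extent_mm)
})
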