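test_that("OCT phantom is deterministic given the seed, with seed-independent truth", {
  spec <- oct_phantom_spec(n_frames = 2, noise_seed = 7)
  a <- synth_oct_pullback(spec)
  b <- synth_oct_pullback(spec)
  expect_identical(a$frames[[1]]$intensities, b$frames[[1]]$intensities)
  expect_identical(a$frames[[2]]$intensities, b$frames[[2]]$intensities)
  spec2 <- oct_phantom_spec(n_frames = 2, noise_seed = 8)
  c <- synth_oct_pullback(spec2)
  expect_false(identical(a$frames[[1]]$intensities, c$frames[[1]]$intensities))
  expect_identical(a$truth$lumen_radii_px, c$truth$lumen_radii_px)
})

test_that("OCT phantom truth geometry is consistent", {
  ph <- oct_small()
  # lumen strictly inside adventitia at every A-line
  expect_true(all(ph$truth$lumen_radii_px < ph$truth$adventitia_radii_px))
  # no struts requested -> empty truth strut list
  expect_null(ph$truth$struts)
})

test_that("metal strut blooms are brighter than the frame median", {
  ph <- oct_struts()
  img <- ph$frames[[1]]$intensities
  tr <- ph$truth$struts[ph$truth$struts$frame == 1, ]
  med <- median(img)
  for (k in seq_len(nrow(tr))) {
    a0 <- tr$aline[k]; d0 <- tr$depth_px[k]
    rows <- ((a0 - 2):(a0 + 2) - 1) %% nrow(img) + 1
    disc <- img[rows, (d0 - 2):(d0 + 2)]
    expect_gt(mean(disc), med)
  }
})

test_that("strut placed outside the imaged depth rejects the spec", {
  layout <- data.frame(frame = 1, angle = 10, depth = 5.2, type = "metal")
  expect_error(oct_phantom_spec(n_frames = 1, strut_layout = layout,
                                noise_seed = 1),
               "outside imaged depth")
})

test_that("seed is mandatory and geometric invariants are validated", {
  expect_error(oct_phantom_spec(n_frames = 1), "noise_seed")
  expect_error(oct_phantom_spec(n_frames = 1, noise_seed = 1,
                                lumen_radius_profile = function(f) 6),
               "imaged depth")
  expect_error(ct_phantom_spec(), "seed")
  expect_error(ct_phantom_spec(seed = 1,
                               intensities = c(background = 500, ncp = 20,
                                               wall = 50, lumen = 350,
                                               cp = 800, stent = 1100)),
               "ordered")
})

test_that("noiseless CT phantom intensities equal class HU values exactly", {
  spec <- ct_phantom_spec(grid_dim = c(32, 32, 40), spacing = c(0.4, 0.4, 0.4),
                          centerline = list(type = "line", xy = c(6.4, 6.4),
                                            z_range = c(2, 13)),
                          blur_sigma = 0, noise_sd = 0, seed = 5)
  ph <- synth_ct_volume(spec)
  lab <- ph$truth$labels$labels
  v <- ph$volume$intensities
  expect_true(all(v[lab == 1] == 350))
  expect_true(all(v[lab == 2] == 50))
  expect_true(all(v[lab == 0] == -100))
})

test_that("straight-line CT centerline truth has constant x, y", {
  ph <- ct_tube()
  expect_lt(max(abs(ph$truth$centerline$points[, 1] - 12.8)), 1e-9)
  expect_lt(max(abs(ph$truth$centerline$points[, 2] - 12.8)), 1e-9)
})

test_that("rasterized lumen volume matches the analytic cylinder within 3%", {
  spec <- ct_phantom_spec(seed = 2)  # r = 1.5 mm, L = 40 mm, 0.4 mm spacing
  ph <- synth_ct_volume(spec)
  vox <- sum(ph$truth$labels$labels == 1) * prod(spec$spacing)
  expect_lt(abs(vox / (pi * 1.5^2 * 40) - 1), 0.03)
})

test_that("CT phantom is deterministic given the seed", {
  spec <- ct_phantom_spec(grid_dim = c(24, 24, 30),
                          centerline = list(type = "line", xy = c(4.8, 4.8),
                                            z_range = c(1, 10)),
                          lumen_radius = 1, wall_thickness = 0.8,
                          noise_sd = 15, seed = 9)
  a <- synth_ct_volume(spec)
  b <- synth_ct_volume(spec)
  expect_identical(a$volume$intensities, b$volume$intensities)
})

test_that("degenerate (zero-length) centerline is rejected", {
  expect_error(synth_ct_volume(ct_phantom_spec(
    centerline = list(type = "line", xy = c(12.8, 12.8), z_range = c(5, 5)),
    seed = 1)), "degenerate")
})
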