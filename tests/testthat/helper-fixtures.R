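# Shared fixtures, built once per test run and cached. Phantom settings here
# are the study conditions of the validation suite, not tuning knobs.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# 3-frame circular-lumen pullback with guidewire, r = 1.5 mm
oct_small <- function() fixture("oct_small", function() {
  spec <- oct_phantom_spec(n_frames = 3, guidewire_angle = 200, noise_seed = 7)
  ph <- synth_oct_pullback(spec)
  ph$segs <- segment_pullback(ph$frames)
  ph
})

# strut phantom: 5 frames x 8 metal struts at the lumen border + guidewire
strut_angles <- c(10, 55, 100, 145, 235, 280, 325, 350)

oct_struts <- function() fixture("oct_struts", function() {
  layout <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, angle = strut_angles, depth = 1.5, type = "metal")))
  spec <- oct_phantom_spec(n_frames = 5, guidewire_angle = 200,
                           strut_layout = layout, noise_seed = 11)
  ph <- synth_oct_pullback(spec)
  ph$segs <- segment_pullback(ph$frames, adventitia = FALSE)
  ph
})

# straight-tube CT phantom with two calcified inclusions
ct_tube <- function() fixture("ct_tube", function() {
  cp <- data.frame(arclength = c(12, 28), angle = c(45, 200),
                   radius = c(1.2, 1.2))
  spec <- ct_phantom_spec(cp_inclusions = cp, seed = 2)
  ph <- synth_ct_volume(spec)
  lab <- ph$truth$labels$labels
  pick <- function(code, n = 30) {
    idx <- which(lab == code, arr.ind = TRUE)
    idx[round(seq(1, nrow(idx), length.out = n)), ]
  }
  ph$seeds <- list(lumen = pick(1), wall = pick(2), cp = pick(3))
  ph$vesselness <- vesselness_preprocess(ph$volume)
  ph$cl <- extract_centerline(ph$vesselness, c(33, 33, 6), c(33, 33, 106))
  ph
})

# truth strut positions of a pullback in cartesian mm
truth_strut_xy <- function(truth, frame, n_alines = 360) {
  tr <- truth$struts[truth$struts$frame == frame, , drop = FALSE]
  th <- 2 * pi * (tr$aline - 1) / n_alines
  cbind(tr$depth_px * truth$radial_spacing * cos(th),
        tr$depth_px * truth$radial_spacing * sin(th))
}

# strut-level recall/precision of detections vs truth, matched within tol mm
strut_match_rates <- function(detected, truth, frames, tol = 0.15) {
  hit_t <- 0; n_t <- 0; hit_d <- 0; n_d <- 0
  for (f in frames) {
    txy <- truth_strut_xy(truth, f)
    st <- detected[detected$frame == f, , drop = FALSE]
    n_t <- n_t + nrow(txy); n_d <- n_d + nrow(st)
    if (nrow(st) == 0 || nrow(txy) == 0) next
    d <- sqrt(outer(txy[, 1], st$x_mm, "-")^2 + outer(txy[, 2], st$y_mm, "-")^2)
    hit_t <- hit_t + sum(apply(d, 1, min) <= tol)
    hit_d <- hit_d + sum(apply(d, 2, min) <= tol)
  }
  list(recall = hit_t / n_t, precision = hit_d / n_d)
}

# brute-force DBSCAN oracle: with min_pts = 1 every point is core, so the
# clustering is exactly the connected components of the eps-distance graph
dbscan_oracle_minpts1 <- function(xy, eps) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  adj <- d <= eps
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[j, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# compare two clusterings up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
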