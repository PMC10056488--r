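#' Sample patch centers in the lumen-adventitia region of interest
#'
#' Draws `n_per_frame` patch centers uniformly (seeded) from the polar-frame
#' pixels between the lumen and adventitia contours, clipping centers so the
#' patch never crosses the frame bounds. Only bookkeeping is stored (frame
#' id, center, size): pixel data are never materialized.
#'
#' @param frame_index frame id recorded with each patch.
#' @param frame_dim c(n_alines, n_depth) of the source frame.
#' @param lumen,adventitia [radial_contour()] pair bounding the ROI.
#' @param n_per_frame number of patch centers.
#' @param patch_px square patch side, px.
#' @param seed integer seed.
#' @return An object of class `patch_set`: `patches` data frame (frame,
#'   aline, depth, size, rotation, label) and `counts`.
#' @export
extract_patches <- function(frame_index, frame_dim, lumen, adventitia,
                            n_per_frame = 1000L, patch_px = 25L, seed = 1L) {
  na <- frame_dim[1]; nd <- frame_dim[2]
  stopifnot(patch_px < nd)
  half <- patch_px %/% 2
  lo <- pmax(ceiling(lumen$radii), half + 1L)
  hi <- pmin(floor(adventitia$radii), nd - half)
  counts <- pmax(hi - lo + 1L, 0L)
  total <- sum(counts)
  if (total == 0) stop("empty ROI between contours")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  replace <- total < n_per_frame
  if (replace) warning("ROI smaller than n_per_frame; sampling with replacement")
  pick <- sample.int(total, n_per_frame, replace = replace)
  cum <- cumsum(counts)
  aline <- findInterval(pick - 1L, c(0L, cum), rightmost.closed = FALSE)
  depth <- lo[aline] + (pick - c(0L, cum)[aline] - 1L)
  patches <- data.frame(frame = frame_index, aline = aline, depth = depth,
                        size = patch_px, rotation = 0L, label = NA_integer_)
  structure(list(patches = patches,
                 counts = list(originals = nrow(patches), augmented = nrow(patches),
                               train = NA_integer_, validation = NA_integer_)),
            class = "patch_set")
}

#' Merge patch sets from several frames
#' @param ... `patch_set` objects (or a single list of them).
#' @return A combined `patch_set`.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  patches <- do.call(rbind, lapply(sets, function(s) s$patches))
  structure(list(patches = patches,
                 counts = list(originals = sum(patches$rotation == 0),
                               augmented = nrow(patches),
                               train = NA_integer_, validation = NA_integer_)),
            class = "patch_set")
}

#' Augment patches by rotation
#'
#' Each original patch yields one copy per requested rotation; rotations of
#' rotations are never applied, so the augmented count is
#' `originals * (1 + length(rotations))`.
#'
#' @param ps a `patch_set`.
#' @param rotations rotation angles in degrees (subset of c(90, 180)).
#' @return The augmented `patch_set`.
#' @export
augment_patches <- function(ps, rotations = c(90, 180)) {
  stopifnot(inherits(ps, "patch_set"), all(rotations %in% c(90, 180, 270)))
  orig <- ps$patches[ps$patches$rotation == 0L, , drop = FALSE]
  aug <- list(orig)
  for (r in rotations) {
    cp <- orig
    cp$rotation <- as.integer(r)
    aug[[length(aug) + 1]] <- cp
  }
  patches <- do.call(rbind, aug)
  structure(list(patches = patches,
                 counts = list(originals = nrow(orig), augmented = nrow(patches),
                               train = NA_integer_, validation = NA_integer_)),
            class = "patch_set")
}

#' Split a patch set into training and validation sets
#'
#' With `group_by_frame = TRUE` (the default), frames - not patches - are
#' partitioned, so no frame contributes patches to both sets (avoiding
#' frame-level leakage between training and validation).
#'
#' @param ps a `patch_set`.
#' @param train_fraction fraction of frames (or patches) assigned to
#'   training.
#' @param seed integer seed for the partition.
#' @param group_by_frame partition frames rather than patches.
#' @return list: `train` and `validation` `patch_set`s, plus `counts`.
#' @export
split_patches <- function(ps, train_fraction = 0.7, seed = 1L,
                          group_by_frame = TRUE) {
  stopifnot(inherits(ps, "patch_set"), train_fraction > 0, train_fraction < 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  p <- ps$patches
  if (group_by_frame) {
    fr <- unique(p$frame)
    ntrain <- round(train_fraction * length(fr))
    ntrain <- min(max(ntrain, 1L), length(fr))
    train_frames <- sample(fr, ntrain)
    tr <- p[p$frame %in% train_frames, , drop = FALSE]
    va <- p[!(p$frame %in% train_frames), , drop = FALSE]
  } else {
    n <- nrow(p)
    idx <- sample.int(n, round(train_fraction * n))
    tr <- p[idx, , drop = FALSE]
    va <- p[-idx, , drop = FALSE]
  }
  mk <- function(d) structure(list(patches = d,
                                   counts = list(originals = sum(d$rotation == 0),
                                                 augmented = nrow(d),
                                                 train = NA_integer_,
                                                 validation = NA_integer_)),
                              class = "patch_set")
  list(train = mk(tr), validation = mk(va),
       counts = list(train = nrow(tr), validation = nrow(va),
                     total = nrow(p)))
}

#' Build a CNN architecture specification for plaque classification
#'
#' Nine convolutional blocks (3 x 3 convolution, batch normalization, ReLU)
#' with a per-modality filter plan (OCT: 32, 32, 32, 64, 64, 64, 128, 128,
#' 128; IVUS: 16, 16, 16, 32, 32, 32, 128, 128, 128), 2 x 2 max pooling
#' after blocks 3 and 6, global average pooling after block 9, a
#' 512-neuron fully connected layer, dropout 0.5, a final fully connected
#' layer sized to `n_classes`, and softmax. Output shapes and trainable
#' parameter counts are chained through the stack.
#'
#' @param modality "OCT" or "IVUS".
#' @param patch_px square input patch side, px (>= 13 so the pooled feature
#'   map stays at least 1 x 1).
#' @param n_classes number of output classes (four plaque types plus
#'   background).
#' @return An object of class `architecture_spec`: `layers` data frame and
#'   `total_params`.
#' @export
build_architecture_spec <- function(modality = c("OCT", "IVUS"), patch_px = 25L,
                                    n_classes = 5L) {
  modality <- match.arg(modality)
  if (patch_px < 13)
    stop("patch too small: need at least 13 px so pooling keeps a 1x1 map")
  filters <- if (modality == "OCT") c(32, 32, 32, 64, 64, 64, 128, 128, 128)
  else c(16, 16, 16, 32, 32, 32, 128, 128, 128)
  layers <- NULL
  sz <- patch_px
  chan <- 1L
  add <- function(kind, detail, out_shape, params) {
    layers <<- rbind(layers, data.frame(kind = kind, detail = detail,
                                        out_shape = out_shape, params = params))
  }
  for (b in seq_len(9)) {
    f <- filters[b]
    conv_p <- (3 * 3 * chan + 1) * f
    add("conv", sprintf("block %d: 3x3, %d filters", b, f),
        sprintf("%dx%dx%d", sz, sz, f), conv_p)
    add("batchnorm", sprintf("block %d", b), sprintf("%dx%dx%d", sz, sz, f), 2 * f)
    add("relu", sprintf("block %d", b), sprintf("%dx%dx%d", sz, sz, f), 0)
    chan <- f
    if (b %in% c(3, 6)) {
      sz <- sz %/% 2L
      add("maxpool", "2x2 stride 2", sprintf("%dx%dx%d", sz, sz, chan), 0)
    }
  }
  add("avgpool", "global", sprintf("1x1x%d", chan), 0)
  add("fc", "512 neurons", "512", (chan + 1) * 512)
  add("dropout", "rate 0.5", "512", 0)
  add("fc", sprintf("%d neurons", n_classes), as.character(n_classes),
      (512 + 1) * n_classes)
  add("softmax", "", as.character(n_classes), 0)
  structure(list(modality = modality, patch_px = patch_px,
                 n_classes = n_classes, layers = layers,
                 total_params = sum(layers$params)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec (%s): %d conv blocks, %d classes, %s params>\n",
              x$modality, sum(x$layers$kind == "conv"), x$n_classes,
              format(x$total_params, big.mark = ",")))
  invisible(x)
}
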