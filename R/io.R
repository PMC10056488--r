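# Interchange formats. Conventions: all file coordinates are 0-based, all
# intervals half-open, all physical quantities in mm; polygons are CCW with
# the first point not repeated.

#' Write an OCT pullback as a 16-bit TIFF series with a sidecar JSON
#'
#' The sidecar (`pullback.json`) carries the acquisition metadata the frames
#' themselves cannot: radial spacing (mm/px), frame spacing (mm) and the
#' catheter offset (px).
#'
#' @param frames list of [polar_frame()].
#' @param dir output directory (created if needed).
#' @param frame_spacing pullback frame spacing, mm.
#' @return `dir`, invisibly.
#' @export
write_pullback <- function(frames, dir, frame_spacing = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    f <- file.path(dir, sprintf("frame_%04d.tif", i - 1))
    tiff::writeTIFF(frames[[i]]$intensities, f, bits.per.sample = 16L)
  }
  meta <- list(n_frames = length(frames),
               radial_spacing_mm = frames[[1]]$radial_spacing,
               frame_spacing_mm = frame_spacing,
               catheter_offset_px = frames[[1]]$catheter_offset)
  write_json_atomic(meta, file.path(dir, "pullback.json"))
  invisible(dir)
}

#' Read an OCT pullback from a TIFF/PNG series plus sidecar JSON
#'
#' Spacing metadata must be present in the sidecar; a missing field raises
#' an explicit error naming it. A truncated or unreadable frame aborts the
#' read with no partial stack returned.
#'
#' @param dir directory containing `frame_*.tif` (or `.png`) and
#'   `pullback.json`.
#' @return list: `frames` (list of [polar_frame()]), `frame_spacing`.
#' @export
read_pullback <- function(dir) {
  sidecar <- file.path(dir, "pullback.json")
  if (!file.exists(sidecar)) stop("missing sidecar pullback.json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("radial_spacing_mm", "frame_spacing_mm"))
    if (is.null(meta[[key]]))
      stop(sprintf("missing spacing metadata: field '%s' in pullback.json", key))
  files <- sort(c(list.files(dir, pattern = "^frame_\\d+\\.tif$", full.names = TRUE),
                  list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE)))
  if (length(files) == 0) stop("no frames found")
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch({
      if (grepl("\\.png$", files[i])) png::readPNG(files[i])
      else tiff::readTIFF(files[i])
    }, error = function(e)
      stop(sprintf("unreadable frame %s: %s", basename(files[i]),
                   conditionMessage(e))))
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[[i]] <- polar_frame(img, meta$radial_spacing_mm, i,
                               catheter_offset = meta$catheter_offset_px %||% 0L)
  }
  list(frames = frames, frame_spacing = meta$frame_spacing_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-frame radial contours as JSON
#'
#' Radius arrays are per-A-line in px with 0-based A-line index order;
#' excluded (interpolated) A-lines are listed 0-based.
#'
#' @param contours list (per frame) of lists with `lumen` and optionally
#'   `adventitia` [radial_contour()]s.
#' @param path output file.
#' @param radial_spacing mm/px recorded in the header.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path, radial_spacing) {
  enc <- lapply(contours, function(fr) {
    lapply(Filter(Negate(is.null), fr), function(ct)
      list(kind = ct$kind, radii_px = ct$radii,
           excluded_alines = ct$excluded_alines - 1L))
  })
  write_json_atomic(list(radial_spacing_mm = radial_spacing, frames = enc), path)
  invisible(path)
}

#' Read contours written by [write_contours()]
#' @param path JSON file.
#' @return list with `radial_spacing` and per-frame contour lists.
#' @export
read_contours <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  frames <- lapply(x$frames, function(fr)
    lapply(fr, function(ct)
      radial_contour(unlist(ct$radii_px), ct$kind,
                     excluded_alines = unlist(ct$excluded_alines) + 1L)))
  list(radial_spacing = x$radial_spacing_mm, frames = frames)
}

#' Write a cartesian contour polygon as CSV (x_mm, y_mm, CCW)
#' @param poly n x 2 matrix in mm.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygon_csv <- function(poly, path) {
  df <- data.frame(x_mm = poly[, 1], y_mm = poly[, 2])
  write_csv_atomic(df, path)
  invisible(path)
}

#' Write a strut cloud as CSV
#' @param struts strut data frame (frame, aline, depth_px, x_mm, y_mm,
#'   cluster, type).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_struts_csv <- function(struts, path) {
  cols <- c("frame", "aline", "depth_px", "x_mm", "y_mm", "cluster", "type")
  write_csv_atomic(struts[, intersect(cols, names(struts)), drop = FALSE], path)
  invisible(path)
}

#' Write a 3D volume or label volume as NIfTI
#' @param vol a [volume3d()] or [label_volume()].
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  arr <- if (inherits(vol, "label_volume")) vol$labels else vol$intensities
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a [volume3d()]
#' @param path `.nii` / `.nii.gz` file.
#' @return A [volume3d()] (spacing from the NIfTI pixdim).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' Write a centerline as CSV (x_mm, y_mm, z_mm, arclength_mm)
#' @param cl a [centerline3d()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x_mm = cl$points[, 1], y_mm = cl$points[, 2],
                   z_mm = cl$points[, 3], arclength_mm = cl$arclength)
  write_csv_atomic(df, path)
  invisible(path)
}

#' Read a centerline CSV written by [write_centerline_csv()]
#' @param path CSV file.
#' @return A [centerline3d()].
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path)
  centerline3d(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' Write a mesh as ASCII PLY
#' @param mesh a `vessel_mesh`.
#' @param path output `.ply` file.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' Write a mesh as ASCII STL
#' @param mesh a `vessel_mesh`.
#' @param path output `.stl` file.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel", con)
  for (r in seq_len(nrow(tr))) {
    p1 <- v[tr[r, 1], ]; p2 <- v[tr[r, 2], ]; p3 <- v[tr[r, 3], ]
    n <- cross3(p2 - p1, p3 - p1)
    ln <- sqrt(sum(n^2))
    if (ln > 0) n <- n / ln
    writeLines(c(sprintf("facet normal %.6e %.6e %.6e", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.6e %.6e %.6e", p1[1], p1[2], p1[3]),
                 sprintf("    vertex %.6e %.6e %.6e", p2[1], p2[2], p2[3]),
                 sprintf("    vertex %.6e %.6e %.6e", p3[1], p3[2], p3[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid vessel", con)
  invisible(path)
}

#' Read seed annotations from JSON
#'
#' Voxel indices are stored 0-based in (x, y, z) order and returned 1-based.
#'
#' @param path JSON file with per-class lists of [x, y, z] triples.
#' @return named list of n x 3 integer matrices.
#' @export
read_seeds_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(m) {
    m <- matrix(as.integer(unlist(m)), ncol = 3, byrow = !is.matrix(m))
    m + 1L
  })
}

# atomic writers: write to a temp file in the same directory, then rename
write_json_atomic <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, ...)
  file.rename(tmp, path)
}

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}
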