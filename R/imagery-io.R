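#' Labeled frames
#'
#' A labeled frame couples an RGB raster with its ground-truth boxes and
#' capture metadata. The raster is an `H x W x 3` numeric array with values
#' in `[0, 1]` (the representation `png::readPNG()` produces). Frames may be
#' label-only (`image = NULL` with explicit `width`/`height`): manifest
#' statistics, splitting, tiling geometry and the noisy-oracle detector all
#' operate on labels alone, which keeps survey-scale simulations cheap.
#'
#' A frame with zero boxes is a *background* frame.
#'
#' @param image `H x W x 3` array in `[0, 1]`, or `NULL` for a label-only
#'   frame.
#' @param frame_id Unique frame identifier.
#' @param source_id Identifier of the originating video/flight; frames of
#'   one video share it (this is the unit of the train/validation split).
#' @param boxes Normalized boxes tibble (see [yolo_boxes()]).
#' @param width,height Image dimensions; required when `image` is `NULL`.
#' @param meta Optional named list (timestamp, altitude AGL in m, GPS fix).
#' @return An object of class `labeled_frame`.
#' @export
labeled_frame <- function(image = NULL, frame_id, source_id = frame_id,
                          boxes = yolo_boxes(), width = NULL, height = NULL,
                          meta = list()) {
  if (!is.null(image)) {
    d <- dim(image)
    if (length(d) != 3 || d[3] != 3) abort("image must be an H x W x 3 array")
    height <- d[1]; width <- d[2]
  }
  if (is.null(width) || is.null(height) || width < 1 || height < 1) {
    abort("labeled_frame: width and height must be >= 1")
  }
  boxes <- validate_yolo_boxes(boxes, context = frame_id)
  structure(
    list(image = image, frame_id = as.character(frame_id),
         source_id = as.character(source_id), boxes = boxes,
         width = as.integer(width), height = as.integer(height), meta = meta),
    class = "labeled_frame"
  )
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf("<labeled_frame %s> %dx%d px, %d box(es), source %s%s\n",
              x$frame_id, x$width, x$height, nrow(x$boxes), x$source_id,
              if (is.null(x$image)) " [label-only]" else ""))
  invisible(x)
}

#' @rdname labeled_frame
#' @param x Object to test.
#' @export
is_background <- function(x) {
  stopifnot(inherits(x, "labeled_frame"))
  nrow(x$boxes) == 0
}

#' Read and write YOLO-format label files
#'
#' One whitespace-separated record per line: `class cx cy w h`, all but the
#' class normalized to the image. Boxes are validated on read (class in
#' range, box inside the image); malformed input errors name the offending
#' line. An empty (or absent, if `missing_ok`) file is a background frame.
#' Files are written with 6-decimal fixed formatting so diffs are
#' reproducible; the write/read round trip is identity to within 1e-6 per
#' field.
#'
#' @param path Label file path.
#' @param n_classes Size of the configured class list.
#' @param clamp Clamp out-of-range boxes instead of rejecting (see
#'   [validate_yolo_boxes()]).
#' @param missing_ok If `TRUE`, a missing file reads as zero boxes.
#' @return `read_yolo_labels()`: a normalized-box tibble.
#' @export
read_yolo_labels <- function(path, n_classes = length(wildedge_classes()),
                             clamp = FALSE, missing_ok = FALSE) {
  if (!file.exists(path)) {
    if (missing_ok) return(yolo_boxes())
    abort(sprintf("label file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) return(yolo_boxes())
  parts <- strsplit(trimws(lines[lines_keep]), "\\s+")
  bad <- which(lengths(parts) != 5)
  if (length(bad)) {
    abort(sprintf("%s: malformed record at line %s (need 5 fields)",
                  path, paste(lines_keep[bad], collapse = ", ")))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE))
  bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric field at line %s",
                  path, paste(lines_keep[bad], collapse = ", ")))
  }
  boxes <- yolo_boxes(class_id = m[, 1], cx = m[, 2], cy = m[, 3],
                      w = m[, 4], h = m[, 5])
  if (any(m[, 1] != boxes$class_id)) abort(sprintf("%s: non-integer class id", path))
  validate_yolo_boxes(boxes, n_classes = n_classes, clamp = clamp, context = path)
}

#' @rdname read_yolo_labels
#' @param boxes Normalized boxes to write.
#' @return `write_yolo_labels()`: `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path) {
  boxes <- validate_yolo_boxes(boxes, n_classes = Inf, context = path)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   boxes$class_id, boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write an RGB image
#'
#' Thin wrappers over the PNG codec returning/accepting the package's
#' `H x W x 3` array convention (grayscale and alpha inputs are expanded /
#' dropped to plain RGB).
#'
#' @param path PNG file path.
#' @return `read_image()`: an `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, target = path)
  invisible(path)
}

#' Extract frames from a video container
#'
#' Splits a video into individual frames in temporal order, keeping every
#' `every_nth` frame. Supported containers are multi-frame TIFF files and
#' directories of alphabetically ordered PNG frames (the formats the
#' synthetic flight writer emits). Returned frames have empty box lists;
#' `frame_id` encodes the source and frame index and `source_id` is shared
#' by all frames of one video.
#'
#' @param video_path Path to a `.tif`/`.tiff` file or a frame directory.
#' @param every_nth Keep frames `0, every_nth, 2*every_nth, ...` (>= 1).
#' @param source_id Source identifier; defaults to the file/directory name.
#' @return List of [labeled_frame()] objects.
#' @export
extract_frames <- function(video_path, every_nth = 1L, source_id = NULL) {
  if (every_nth < 1) abort("every_nth must be >= 1")
  source_id <- source_id %||% sub("\\.tiff?$", "", basename(video_path))
  if (dir.exists(video_path)) {
    files <- sort(list.files(video_path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) abort(sprintf("no PNG frames in %s", video_path))
    rasters <- lapply(files, read_image)
  } else if (grepl("\\.tiff?$", video_path) && file.exists(video_path)) {
    rasters <- tiff::readTIFF(video_path, all = TRUE)
    rasters <- lapply(rasters, function(img) {
      if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
      if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
      img
    })
  } else {
    abort(sprintf("unreadable video: %s (expect multi-frame TIFF or PNG directory)",
                  video_path))
  }
  idx <- seq(1L, length(rasters), by = as.integer(every_nth))
  lapply(idx, function(i) {
    labeled_frame(image = rasters[[i]],
                  frame_id = sprintf("%s_f%05d", source_id, i - 1L),
                  source_id = source_id)
  })
}

#' Write frames as a multi-frame TIFF "video"
#'
#' Companion writer to [extract_frames()], used to materialise synthetic
#' flights as a single video container.
#'
#' @param frames List of [labeled_frame()] objects with rasters.
#' @param path Output `.tiff` path.
#' @export
write_video <- function(frames, path) {
  rasters <- lapply(frames, function(f) {
    if (is.null(f$image)) abort("write_video: frame has no raster")
    f$image
  })
  tiff::writeTIFF(rasters, path)
  invisible(path)
}

#' Render a QC overlay image
#'
#' Draws each box outline (and nothing else) onto a copy of the frame so
#' label alignment can be inspected by eye; the manual-relabeling QC loop
#' works from these images. Pixels outside the drawn rectangles are
#' untouched, so a background frame renders pixel-identical to its input.
#'
#' @param frame A [labeled_frame()] with a raster.
#' @param boxes Pixel boxes to draw; defaults to the frame's own labels.
#' @param colors Per-class RGB rows (values in `[0, 1]`); recycled by
#'   `class_id`.
#' @param thickness Outline thickness in pixels.
#' @return The annotated `H x W x 3` array.
#' @export
render_qc_overlay <- function(frame, boxes = NULL, colors = qc_palette(),
                              thickness = 2L) {
  stopifnot(inherits(frame, "labeled_frame"))
  if (is.null(frame$image)) abort("render_qc_overlay: frame has no raster")
  img <- frame$image
  if (is.null(boxes)) {
    if (nrow(frame$boxes) == 0) return(img)
    boxes <- to_pixel(frame$boxes, frame$width, frame$height)
  }
  if (nrow(boxes) == 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in seq_len(nrow(boxes))) {
    col <- colors[(boxes$class_id[i] %% nrow(colors)) + 1L, ]
    x0 <- max(0L, floor(boxes$x0[i])); x1 <- min(W, ceiling(boxes$x1[i]))
    y0 <- max(0L, floor(boxes$y0[i])); y1 <- min(H, ceiling(boxes$y1[i]))
    t <- thickness
    rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
    top <- (y0 + 1):min(y0 + t, y1); bot <- max(y1 - t + 1, y0 + 1):y1
    lef <- (x0 + 1):min(x0 + t, x1); rig <- max(x1 - t + 1, x0 + 1):x1
    for (ch in 1:3) {
      img[top, cols, ch] <- col[ch]
      img[bot, cols, ch] <- col[ch]
      img[rows, lef, ch] <- col[ch]
      img[rows, rig, ch] <- col[ch]
    }
  }
  img
}

#' @rdname render_qc_overlay
#' @export
qc_palette <- function() {
  rbind(
    c(1, 0, 0),       # rhino
    c(1, 0.65, 0),    # giraffe
    c(1, 1, 0),       # ostrich
    c(0, 1, 1),       # springbok
    c(1, 0, 1)        # human
  )
}
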