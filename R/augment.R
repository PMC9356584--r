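#' Label-aware data augmentations
#'
#' The three augmentations that transform labels as well as pixels:
#'
#' * `mosaic()` arranges four frames in a 2x2 grid, resizing each to one
#'   quadrant and remapping its boxes by the corresponding scale and
#'   offset;
#' * `mixup()` alpha-blends two frames (`alpha * a + (1 - alpha) * b`) and
#'   takes the union of the two hard label sets (YOLO-format files carry no
#'   label weights);
#' * `flip_frame()` mirrors the raster and reflects box centers
#'   (`cx -> 1 - cx` horizontally, `cy -> 1 - cy` vertically).
#'
#' All three conserve total box count and keep every transformed box valid.
#' Pixel-only augmentations (blur, HSV shifts, noise) carry no label
#' contract and are left to the training backend's configuration.
#'
#' @param frames List of exactly four [labeled_frame()] objects.
#' @param out_size `c(width, height)` of the mosaic output.
#' @param frame_id Identifier for the synthesized frame.
#' @return A [labeled_frame()].
#' @name augmentations
NULL

resize_image <- function(image, width, height) {
  d <- dim(image)
  rows <- pmin(d[1], floor(seq(0, d[1] - 1e-9, length.out = height)) + 1L)
  cols <- pmin(d[2], floor(seq(0, d[2] - 1e-9, length.out = width)) + 1L)
  image[rows, cols, , drop = FALSE]
}

#' @rdname augmentations
#' @export
mosaic <- function(frames, out_size = c(1280L, 1280L),
                   frame_id = "mosaic") {
  if (length(frames) != 4) abort("mosaic: exactly 4 frames required")
  W <- out_size[1]; H <- out_size[2]
  qw <- W %/% 2L; qh <- H %/% 2L
  offsets <- list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  has_img <- !any(vapply(frames, function(f) is.null(f$image), logical(1)))
  out_img <- if (has_img) array(0, dim = c(H, W, 3))
  boxes <- purrr::map_dfr(1:4, function(q) {
    f <- frames[[q]]
    if (has_img) {
      qimg <- resize_image(f$image, qw, qh)
      r0 <- offsets[[q]][2] * H; c0 <- offsets[[q]][1] * W
      out_img[(r0 + 1):(r0 + qh), (c0 + 1):(c0 + qw), ] <<- qimg
    }
    b <- f$boxes
    if (nrow(b) == 0) return(yolo_boxes())
    yolo_boxes(b$class_id,
               cx = offsets[[q]][1] + b$cx / 2,
               cy = offsets[[q]][2] + b$cy / 2,
               w = b$w / 2, h = b$h / 2)
  })
  labeled_frame(image = out_img, frame_id = frame_id,
                source_id = frames[[1]]$source_id, boxes = boxes,
                width = W, height = H)
}

#' @rdname augmentations
#' @param a,b Frames to blend; `b` is resized to `a`'s dimensions if they
#'   differ.
#' @param alpha Blend weight for `a`, in `[0, 1]`.
#' @export
mixup <- function(a, b, alpha = 0.5, frame_id = "mixup") {
  if (alpha < 0 || alpha > 1) abort("mixup: alpha must be in [0, 1]")
  if (is.null(a$image) || is.null(b$image)) abort("mixup: frames need rasters")
  bimg <- b$image
  if (!identical(dim(bimg)[1:2], dim(a$image)[1:2])) {
    bimg <- resize_image(bimg, a$width, a$height)
  }
  labeled_frame(image = alpha * a$image + (1 - alpha) * bimg,
                frame_id = frame_id, source_id = a$source_id,
                boxes = dplyr::bind_rows(a$boxes, b$boxes))
}

#' @rdname augmentations
#' @param frame Frame to mirror.
#' @param axis `"horizontal"` (left-right mirror) or `"vertical"`.
#' @export
flip_frame <- function(frame, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  img <- frame$image
  boxes <- frame$boxes
  if (axis == "horizontal") {
    if (!is.null(img)) img <- img[, dim(img)[2]:1, , drop = FALSE]
    if (nrow(boxes)) boxes$cx <- 1 - boxes$cx
  } else {
    if (!is.null(img)) img <- img[dim(img)[1]:1, , , drop = FALSE]
    if (nrow(boxes)) boxes$cy <- 1 - boxes$cy
  }
  labeled_frame(image = img, frame_id = frame$frame_id,
                source_id = frame$source_id, boxes = boxes,
                width = frame$width, height = frame$height,
                meta = frame$meta)
}
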