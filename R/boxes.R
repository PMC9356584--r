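#' Bounding-box tibbles
#'
#' Two tabular box representations flow through the package:
#'
#' * **normalized (YOLO) boxes** — columns `class_id` (integer, 0-based),
#'   `cx`, `cy` (box center as a fraction of image width/height) and
#'   `w`, `h` (box width/height as fractions). This is the on-disk label
#'   format.
#' * **pixel boxes** — columns `class_id`, `x0`, `y0` (top-left, 0-based)
#'   and `x1`, `y1` (exclusive bottom-right). Pixel boxes are half-open
#'   `[x0, x1) x [y0, y1)` so tiling and intersection arithmetic are exact:
#'   the box covers pixel columns `x0 .. x1 - 1`.
#'
#' `yolo_boxes()` and `pixel_boxes()` build validated empty or filled
#' tibbles; `validate_yolo_boxes()` checks the invariants and is applied by
#' every reader.
#'
#' @param class_id Integer class indices (0-based).
#' @param cx,cy,w,h Normalized center coordinates and box dimensions.
#' @param x0,y0,x1,y1 Pixel corner coordinates (half-open).
#' @return A tibble of boxes.
#' @export
#' @examples
#' yolo_boxes(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.2)
yolo_boxes <- function(class_id = integer(), cx = double(), cy = double(),
                       w = double(), h = double()) {
  tibble(
    class_id = as.integer(class_id),
    cx = as.double(cx), cy = as.double(cy),
    w = as.double(w), h = as.double(h)
  )
}

#' @rdname yolo_boxes
#' @export
pixel_boxes <- function(class_id = integer(), x0 = double(), y0 = double(),
                        x1 = double(), y1 = double()) {
  tibble(
    class_id = as.integer(class_id),
    x0 = as.double(x0), y0 = as.double(y0),
    x1 = as.double(x1), y1 = as.double(y1)
  )
}

#' @rdname yolo_boxes
#' @param boxes A tibble of normalized boxes.
#' @param n_classes Number of classes in the configured class list.
#' @param clamp If `TRUE`, boxes extending outside `[0, 1]` are clamped to
#'   the image instead of rejected (surfacing labeling errors is the
#'   default, mirroring manual QC).
#' @param context Character scalar used in error messages (e.g. a file
#'   path).
#' @export
validate_yolo_boxes <- function(boxes, n_classes = length(wildedge_classes()),
                                clamp = FALSE, context = "boxes") {
  boxes <- as_tibble(boxes)
  needed <- c("class_id", "cx", "cy", "w", "h")
  if (!all(needed %in% names(boxes))) {
    abort(sprintf("%s: missing columns %s", context,
                  paste(setdiff(needed, names(boxes)), collapse = ", ")))
  }
  if (nrow(boxes) == 0) return(yolo_boxes())
  bad_class <- which(boxes$class_id < 0L | boxes$class_id >= n_classes |
                       is.na(boxes$class_id))
  if (length(bad_class)) {
    abort(sprintf("%s: class_id outside 0..%d at line %s", context,
                  n_classes - 1L, paste(bad_class, collapse = ", ")))
  }
  if (any(!is.finite(boxes$w)) || any(!is.finite(boxes$h)) ||
      any(boxes$w <= 0) || any(boxes$h <= 0)) {
    abort(sprintf("%s: non-positive box width/height at line %s", context,
                  paste(which(boxes$w <= 0 | boxes$h <= 0), collapse = ", ")))
  }
  eps <- 1e-9
  lo_x <- boxes$cx - boxes$w / 2
  hi_x <- boxes$cx + boxes$w / 2
  lo_y <- boxes$cy - boxes$h / 2
  hi_y <- boxes$cy + boxes$h / 2
  out <- which(lo_x < -eps | hi_x > 1 + eps | lo_y < -eps | hi_y > 1 + eps)
  if (length(out)) {
    if (!clamp) {
      abort(sprintf("%s: box outside [0,1] at line %s (use clamp = TRUE to clip)",
                    context, paste(out, collapse = ", ")))
    }
    lo_x <- pmax(lo_x, 0); hi_x <- pmin(hi_x, 1)
    lo_y <- pmax(lo_y, 0); hi_y <- pmin(hi_y, 1)
    if (any(hi_x - lo_x <= 0) || any(hi_y - lo_y <= 0)) {
      abort(sprintf("%s: box entirely outside image after clamping", context))
    }
    boxes$cx <- (lo_x + hi_x) / 2; boxes$w <- hi_x - lo_x
    boxes$cy <- (lo_y + hi_y) / 2; boxes$h <- hi_y - lo_y
  }
  boxes
}

#' Convert between normalized and pixel boxes
#'
#' Normalized-to-pixel uses symmetric rounding of the real-valued corners:
#' `x0 = round(W * (cx - w/2))`, `x1 = round(W * (cx + w/2))` (and likewise
#' for y), so the two directions are mutually inverse on boxes whose pixel
#' corners are integers. Conversions producing a zero-area pixel box are
#' rejected.
#'
#' @param boxes Normalized boxes (`to_pixel()`) or pixel boxes
#'   (`from_pixel()`).
#' @param width,height Image dimensions in pixels.
#' @return A tibble of pixel boxes / normalized boxes.
#' @export
#' @examples
#' to_pixel(yolo_boxes(0L, 0.5, 0.5, 1, 1), width = 100, height = 100)
to_pixel <- function(boxes, width, height) {
  boxes <- as_tibble(boxes)
  if (nrow(boxes) == 0) return(pixel_boxes())
  px <- pixel_boxes(
    class_id = boxes$class_id,
    x0 = round(width * (boxes$cx - boxes$w / 2)),
    y0 = round(height * (boxes$cy - boxes$h / 2)),
    x1 = round(width * (boxes$cx + boxes$w / 2)),
    y1 = round(height * (boxes$cy + boxes$h / 2))
  )
  if (any(px$x1 <= px$x0) || any(px$y1 <= px$y0)) {
    abort("to_pixel: degenerate (zero-area) pixel box after rounding")
  }
  px
}

#' @rdname to_pixel
#' @export
from_pixel <- function(boxes, width, height) {
  boxes <- as_tibble(boxes)
  if (nrow(boxes) == 0) return(yolo_boxes())
  if (any(boxes$x1 <= boxes$x0) || any(boxes$y1 <= boxes$y0)) {
    abort("from_pixel: zero-area pixel box")
  }
  if (any(boxes$x0 < 0) || any(boxes$y0 < 0) ||
      any(boxes$x1 > width) || any(boxes$y1 > height)) {
    abort("from_pixel: pixel box outside image bounds")
  }
  yolo_boxes(
    class_id = boxes$class_id,
    cx = (boxes$x0 + boxes$x1) / (2 * width),
    cy = (boxes$y0 + boxes$y1) / (2 * height),
    w = (boxes$x1 - boxes$x0) / width,
    h = (boxes$y1 - boxes$y0) / height
  )
}
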