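#' Tiling parameters
#'
#' High-resolution survey frames are broken into fixed-size overlapping
#' tiles so small animals keep full pixel fidelity when fed to a
#' fixed-input detector. Defaults follow the deployed configuration:
#' 1,280 px square tiles with a 320 px (one-quarter tile) overlap between
#' adjacent tiles, applied to any image with a dimension strictly greater
#' than 1,280 px. A ground-truth box is retained on a tile only when
#' *strictly more* than `min_retention` (default 0.5) of its area lies on
#' that tile; retained boxes are clipped to the tile window and rescaled to
#' tile coordinates.
#'
#' @param tile_size Tile side length in pixels.
#' @param overlap Pixels shared by adjacent interior tiles; `0 < overlap <
#'   tile_size`.
#' @param min_retention Area fraction a box must exceed (strict) to be kept
#'   on a tile, in `[0, 1)`.
#' @param tiling_threshold Images with both dimensions `<= tiling_threshold`
#'   pass through untiled.
#' @return A `tile_spec` list.
#' @export
#' @examples
#' tile_spec()
tile_spec <- function(tile_size = 1280L, overlap = 320L,
                      min_retention = 0.5, tiling_threshold = 1280L) {
  if (overlap <= 0 || overlap >= tile_size) {
    abort("tile_spec: need 0 < overlap < tile_size")
  }
  if (min_retention < 0 || min_retention >= 1) {
    abort("tile_spec: need 0 <= min_retention < 1")
  }
  structure(
    list(tile_size = as.integer(tile_size), overlap = as.integer(overlap),
         min_retention = min_retention,
         tiling_threshold = as.integer(tiling_threshold),
         stride = as.integer(tile_size - overlap)),
    class = "tile_spec"
  )
}

#' @export
print.tile_spec <- function(x, ...) {
  cat(sprintf("<tile_spec> %d px tiles, %d px overlap (stride %d), retention > %.2f, threshold %d px\n",
              x$tile_size, x$overlap, x$stride, x$min_retention,
              x$tiling_threshold))
  invisible(x)
}

axis_origins <- function(extent, spec) {
  if (extent <= spec$tile_size) return(0L)
  o <- 0L
  origins <- integer()
  while (o + spec$tile_size < extent) {
    origins <- c(origins, o)
    o <- o + spec$stride
  }
  c(origins, extent - spec$tile_size)
}

#' Compute the tile grid for an image
#'
#' Origins along each axis are `0, s, 2s, ...` (stride `s = tile_size -
#' overlap`) while a further full tile fits strictly inside the extent,
#' plus a final origin at `extent - tile_size` so the far edge is covered
#' (the last pair of tiles may overlap by more than `overlap`). A dimension
#' not exceeding `tile_size` gets the single origin 0 with the tile
#' spanning the full extent — no padding is ever added. Images with both
#' dimensions at or below `tiling_threshold` yield a single full-frame
#' window.
#'
#' @param width,height Parent image dimensions in pixels.
#' @param spec A [tile_spec()].
#' @return Tibble with one row per tile in row-major order: `ox`, `oy`
#'   (origin of the tile's top-left corner in the parent) and `tw`, `th`
#'   (tile size; equal to `tile_size` unless the dimension is smaller).
#' @export
#' @examples
#' compute_tile_grid(3840, 2160, tile_spec()) # 8 tiles
compute_tile_grid <- function(width, height, spec = tile_spec()) {
  stopifnot(width >= 1, height >= 1)
  if (width <= spec$tiling_threshold && height <= spec$tiling_threshold) {
    return(tibble(ox = 0L, oy = 0L,
                  tw = as.integer(width), th = as.integer(height)))
  }
  oxs <- axis_origins(width, spec)
  oys <- axis_origins(height, spec)
  grid <- tidyr::expand_grid(oy = oys, ox = oxs)
  tibble(
    ox = as.integer(grid$ox), oy = as.integer(grid$oy),
    tw = as.integer(pmin(spec$tile_size, width)),
    th = as.integer(pmin(spec$tile_size, height))
  )
}

#' Assign ground-truth boxes to tiles by the area-retention rule
#'
#' For each (tile, box) pair, the fraction of the box's area lying on the
#' tile window is computed from the axis-aligned intersection of the
#' half-open pixel rectangles; the box is kept on that tile iff the
#' fraction strictly exceeds `spec$min_retention`. Kept boxes are clipped
#' to the tile window and reported in tile-local pixel coordinates.
#'
#' This is the label-only core of [tile_image()], usable without rasters.
#'
#' @param pboxes Pixel boxes in parent coordinates.
#' @param grid A tile grid from [compute_tile_grid()].
#' @param spec A [tile_spec()].
#' @return Tibble with columns `tile` (row index into `grid`), `box`
#'   (row index into `pboxes`), `class_id`, clipped tile-local `x0, y0,
#'   x1, y1`, and `retention`.
#' @export
tile_boxes <- function(pboxes, grid, spec = tile_spec()) {
  if (nrow(pboxes) == 0 || nrow(grid) == 0) {
    return(tibble(tile = integer(), box = integer(), class_id = integer(),
                  x0 = double(), y0 = double(), x1 = double(), y1 = double(),
                  retention = double()))
  }
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(ti) {
    ox <- grid$ox[ti]; oy <- grid$oy[ti]
    tx1 <- ox + grid$tw[ti]; ty1 <- oy + grid$th[ti]
    ix0 <- pmax(pboxes$x0, ox); iy0 <- pmax(pboxes$y0, oy)
    ix1 <- pmin(pboxes$x1, tx1); iy1 <- pmin(pboxes$y1, ty1)
    iw <- pmax(0, ix1 - ix0); ih <- pmax(0, iy1 - iy0)
    area <- (pboxes$x1 - pboxes$x0) * (pboxes$y1 - pboxes$y0)
    ratio <- (iw * ih) / area
    keep <- which(ratio > spec$min_retention)
    if (!length(keep)) return(NULL)
    tibble(tile = ti, box = keep, class_id = pboxes$class_id[keep],
           x0 = ix0[keep] - ox, y0 = iy0[keep] - oy,
           x1 = ix1[keep] - ox, y1 = iy1[keep] - oy,
           retention = ratio[keep])
  })
  res
}

#' Tile a labeled frame
#'
#' Produces one tile per grid window. Each tile carries the clipped,
#' re-normalized labels that pass the retention rule, the per-box retention
#' ratios, and a `background` flag when no box survives. Label-only frames
#' (no raster) produce label-only tiles.
#'
#' @param frame A [labeled_frame()].
#' @param spec A [tile_spec()].
#' @return List of `wild_tile` objects: `parent_id`, `origin` `(ox, oy)`,
#'   `size` `(tw, th)`, `image` (or `NULL`), normalized `boxes`,
#'   `retention`, `background`.
#' @export
tile_image <- function(frame, spec = tile_spec()) {
  stopifnot(inherits(frame, "labeled_frame"))
  grid <- compute_tile_grid(frame$width, frame$height, spec)
  pb <- if (nrow(frame$boxes)) to_pixel(frame$boxes, frame$width, frame$height)
        else pixel_boxes()
  placed <- tile_boxes(pb, grid, spec)
  lapply(seq_len(nrow(grid)), function(ti) {
    ox <- grid$ox[ti]; oy <- grid$oy[ti]
    tw <- grid$tw[ti]; th <- grid$th[ti]
    on_tile <- placed[placed$tile == ti, , drop = FALSE]
    boxes <- if (nrow(on_tile)) {
      from_pixel(pixel_boxes(on_tile$class_id, on_tile$x0, on_tile$y0,
                             on_tile$x1, on_tile$y1), tw, th)
    } else yolo_boxes()
    img <- if (!is.null(frame$image)) {
      frame$image[(oy + 1):(oy + th), (ox + 1):(ox + tw), , drop = FALSE]
    }
    structure(
      list(parent_id = frame$frame_id, origin = c(ox = ox, oy = oy),
           size = c(tw = tw, th = th), image = img, boxes = boxes,
           retention = on_tile$retention, source_id = frame$source_id,
           background = nrow(on_tile) == 0),
      class = "wild_tile"
    )
  })
}

#' @export
print.wild_tile <- function(x, ...) {
  cat(sprintf("<wild_tile of %s> origin (%d,%d) %dx%d, %d box(es)%s\n",
              x$parent_id, x$origin[["ox"]], x$origin[["oy"]],
              x$size[["tw"]], x$size[["th"]], nrow(x$boxes),
              if (x$background) " [background]" else ""))
  invisible(x)
}

#' Map a tile-local box back to parent coordinates
#'
#' Inverse transform for running a detector on tiles: converts a
#' normalized box on the tile to a pixel box and translates it by the
#' tile's origin. A clipped box maps to the intersection of the original
#' box with the tile window.
#'
#' @param tile A `wild_tile` from [tile_image()].
#' @param boxes Normalized boxes in tile coordinates (defaults to the
#'   tile's own labels).
#' @return Pixel boxes in parent-frame coordinates.
#' @export
map_to_parent <- function(tile, boxes = tile$boxes) {
  stopifnot(inherits(tile, "wild_tile"))
  if (nrow(boxes) == 0) return(pixel_boxes())
  px <- to_pixel(boxes, tile$size[["tw"]], tile$size[["th"]])
  if (any(px$x1 > tile$size[["tw"]]) || any(px$y1 > tile$size[["th"]]) ||
      any(px$x0 < 0) || any(px$y0 < 0)) {
    abort("map_to_parent: box outside tile")
  }
  px$x0 <- px$x0 + tile$origin[["ox"]]; px$x1 <- px$x1 + tile$origin[["ox"]]
  px$y0 <- px$y0 + tile$origin[["oy"]]; px$y1 <- px$y1 + tile$origin[["oy"]]
  px
}
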