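#' Scene generator configuration
#'
#' The generator emulates the statistical structure of a drone survey
#' dataset rather than its photorealism: frame formats drawn from the
#' mixture of camera formats observed in the field (24 MP stills, 4k and
#' 720p video), object boxes log-normally sized so that ~99% fall under
#' 200 px regardless of frame size, a configurable share of background
#' (object-free) frames, and one distinct flat color signature per class
#' so rendered objects admit a pixel-level oracle for box tightness.
#'
#' @param image_sizes List of `c(width, height)` choices.
#' @param size_weights Sampling weights over `image_sizes`.
#' @param class_names Ordered class names.
#' @param objects_lambda Poisson mean for extra objects on a non-background
#'   frame (frames get `1 + rpois(objects_lambda)` objects).
#' @param background_fraction Target share of background frames (>= 0.10
#'   by the training guideline).
#' @param box_meanlog,box_sdlog Log-normal parameters of box side length
#'   in px; the defaults put the 99th percentile at 200 px.
#' @param min_box_px Minimum rendered box side.
#' @param noise_sd Background texture noise standard deviation.
#' @return A `scene_config`.
#' @export
scene_config <- function(image_sizes = list(c(4000, 3000), c(6000, 4000),
                                            c(3840, 2160), c(1280, 720),
                                            c(1920, 1080)),
                         size_weights = c(0.30, 0.15, 0.25, 0.20, 0.10),
                         class_names = wildedge_classes(),
                         objects_lambda = 2,
                         background_fraction = 0.10,
                         box_meanlog = log(60),
                         box_sdlog = log(200 / 60) / stats::qnorm(0.99),
                         min_box_px = 8L,
                         noise_sd = 0.04) {
  if (background_fraction < 0 || background_fraction > 1) {
    abort("background_fraction must be in [0, 1]")
  }
  if (length(size_weights) != length(image_sizes)) {
    abort("size_weights must match image_sizes")
  }
  structure(list(image_sizes = image_sizes,
                 size_weights = size_weights / sum(size_weights),
                 class_names = class_names,
                 objects_lambda = objects_lambda,
                 background_fraction = background_fraction,
                 box_meanlog = box_meanlog, box_sdlog = box_sdlog,
                 min_box_px = as.integer(min_box_px), noise_sd = noise_sd),
            class = "scene_config")
}

#' Class color signatures used by the renderer
#'
#' @return Matrix of per-class RGB rows in `[0, 1]`.
#' @export
scene_palette <- function() {
  rbind(
    c(0.25, 0.22, 0.20),  # rhino: dark grey-brown
    c(0.85, 0.55, 0.15),  # giraffe: orange-tan
    c(0.05, 0.05, 0.08),  # ostrich: near-black
    c(0.95, 0.95, 0.92),  # springbok: pale, near-white flanks
    c(0.10, 0.30, 0.80)   # human: blue (clothing)
  )
}

sample_boxes_px <- function(cfg, n, W, H) {
  draw_side <- function(n, cap) {
    s <- stats::rlnorm(n, cfg$box_meanlog, cfg$box_sdlog)
    pmax(cfg$min_box_px, pmin(cap, round(s)))
  }
  w <- draw_side(n, max(cfg$min_box_px, floor(W / 2)))
  h <- draw_side(n, max(cfg$min_box_px, floor(H / 2)))
  x0 <- floor(runif(n, 0, W - w + 1))
  y0 <- floor(runif(n, 0, H - h + 1))
  pixel_boxes(class_id = sample(0:(length(cfg$class_names) - 1L), n,
                                replace = TRUE),
              x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
}

render_scene <- function(W, H, pboxes, cfg) {
  base <- c(0.76, 0.69, 0.50)   # dry savanna substrate
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(1, pmax(0, base[ch] + rnorm(H * W, 0, cfg$noise_sd)))
  }
  pal <- scene_palette()
  for (i in seq_len(nrow(pboxes))) {
    # ellipse inscribed in the box: every painted pixel lies inside the box
    x0 <- pboxes$x0[i]; x1 <- pboxes$x1[i]
    y0 <- pboxes$y0[i]; y1 <- pboxes$y1[i]
    cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
    rx <- (x1 - x0) / 2; ry <- (y1 - y0) / 2
    cols <- (x0 + 1):x1; rows <- (y0 + 1):y1
    px <- outer(rows - 0.5 - cy, rep(1, length(cols)))
    py <- outer(rep(1, length(rows)), cols - 0.5 - cx)
    inside <- (py / rx)^2 + (px / ry)^2 <= 1
    col <- pal[(pboxes$class_id[i] %% nrow(pal)) + 1L, ]
    for (ch in 1:3) {
      patch <- img[rows, cols, ch]
      patch[inside] <- col[ch]
      img[rows, cols, ch] <- patch
    }
  }
  img
}

#' Generate one synthetic labeled scene
#'
#' Renders class-colored elliptical "animals" on a textured substrate,
#' each exactly enclosed by its ground-truth box. Fully deterministic
#' under `seed`. With `render = FALSE` only the labels are produced
#' (frame geometry and boxes are identical either way), which keeps
#' survey-scale simulations cheap.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed.
#' @param frame_id,source_id Identifiers for the frame.
#' @param background Force a background (`TRUE`) or object-bearing
#'   (`FALSE`) frame; `NA` draws from `cfg$background_fraction`.
#' @param image_size Optional `c(width, height)` override.
#' @param render Render the raster (`TRUE`) or produce a label-only frame.
#' @return A [labeled_frame()].
#' @export
generate_scene <- function(cfg = scene_config(), seed = 1L,
                           frame_id = "scene", source_id = frame_id,
                           background = NA, image_size = NULL,
                           render = TRUE) {
  withr::with_seed(as.integer(seed), {
    sz <- image_size %||%
      cfg$image_sizes[[sample.int(length(cfg$image_sizes), 1,
                                  prob = cfg$size_weights)]]
    W <- as.integer(sz[1]); H <- as.integer(sz[2])
    if (W < cfg$min_box_px * 2 || H < cfg$min_box_px * 2) {
      abort("generate_scene: image too small for configured objects")
    }
    is_bg <- if (is.na(background)) runif(1) < cfg$background_fraction
             else isTRUE(background)
    pboxes <- if (is_bg) pixel_boxes()
              else sample_boxes_px(cfg, 1L + rpois(1, cfg$objects_lambda), W, H)
    img <- if (render) render_scene(W, H, pboxes, cfg)
    labeled_frame(image = img,
                  frame_id = frame_id, source_id = source_id,
                  boxes = if (nrow(pboxes)) from_pixel(pboxes, W, H)
                          else yolo_boxes(),
                  width = W, height = H)
  })
}

#' Simulate a survey flight
#'
#' A video-like sequence: objects persist across frames with a small
#' random walk (so consecutive frames are nearly identical — the leakage
#' hazard the split guard exists for), each frame independently swapped
#' for a background frame with probability `cfg$background_fraction`
#' (empty ground passing under the camera), and a lawnmower GPS track at
#' constant altitude flown at `speed_mps` with legs of `leg_frames`
#' frames.
#'
#' @param cfg A [scene_config()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param source_id Flight identifier shared by all frames.
#' @param image_size `c(width, height)` of every frame (video frames share
#'   a format).
#' @param frame_rate Frames per second.
#' @param origin `c(lat, lon)` of the first fix, decimal degrees.
#' @param altitude_m Altitude AGL in meters.
#' @param speed_mps Ground speed in m/s.
#' @param leg_frames Frames per lawnmower leg before turning.
#' @param render Render rasters or produce label-only frames.
#' @return List: `frames` (list of [labeled_frame()]), `track` tibble
#'   (`frame_id`, `timestamp`, `lat`, `lon`, `alt`).
#' @export
generate_flight <- function(cfg = scene_config(), n_frames = 100L, seed = 1L,
                            source_id = "flight01",
                            image_size = c(1280L, 720L), frame_rate = 2,
                            origin = c(-23.20, 18.40), altitude_m = 40,
                            speed_mps = 8, leg_frames = 25L,
                            render = FALSE) {
  withr::with_seed(as.integer(seed), {
    W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
    n_obj <- 1L + rpois(1, cfg$objects_lambda)
    base <- sample_boxes_px(cfg, n_obj, W, H)
    deg_per_m <- 1 / 111320
    lat <- origin[1]; lon <- origin[2]
    heading <- 1   # +1 east, -1 west along lawnmower legs
    frames <- vector("list", n_frames)
    track <- tibble(frame_id = character(n_frames), timestamp = double(n_frames),
                    lat = double(n_frames), lon = double(n_frames),
                    alt = altitude_m)
    boxes_now <- base
    for (i in seq_len(n_frames)) {
      fid <- sprintf("%s_f%05d", source_id, i - 1L)
      # object random walk, kept inside the frame
      if (nrow(boxes_now)) {
        dx <- round(rnorm(nrow(boxes_now), 0, 2))
        dy <- round(rnorm(nrow(boxes_now), 0, 2))
        w <- boxes_now$x1 - boxes_now$x0; h <- boxes_now$y1 - boxes_now$y0
        boxes_now$x0 <- pmin(pmax(boxes_now$x0 + dx, 0), W - w)
        boxes_now$y0 <- pmin(pmax(boxes_now$y0 + dy, 0), H - h)
        boxes_now$x1 <- boxes_now$x0 + w; boxes_now$y1 <- boxes_now$y0 + h
      }
      is_bg <- runif(1) < cfg$background_fraction
      pb <- if (is_bg) pixel_boxes() else boxes_now
      img <- if (render) render_scene(W, H, pb, cfg)
      frames[[i]] <- labeled_frame(
        image = img, frame_id = fid, source_id = source_id,
        boxes = if (nrow(pb)) from_pixel(pb, W, H) else yolo_boxes(),
        width = W, height = H,
        meta = list(lat = lat, lon = lon, alt = altitude_m,
                    timestamp = (i - 1) / frame_rate)
      )
      track$frame_id[i] <- fid
      track$timestamp[i] <- (i - 1) / frame_rate
      track$lat[i] <- lat; track$lon[i] <- lon
      step <- speed_mps / frame_rate * deg_per_m
      if (i %% leg_frames == 0) {
        lat <- lat + step        # step to the next leg
        heading <- -heading
      } else {
        lon <- lon + heading * step
      }
    }
    list(frames = frames, track = track)
  })
}

#' Generate a multi-video synthetic dataset
#'
#' `n_videos` simulated flights of `frames_per_video` frames each, with
#' per-video seeds derived from `seed`, plus the assembled manifest and
#' GPS tracks. Background share and box-size quantiles follow the
#' configuration across the dataset.
#'
#' @param cfg A [scene_config()].
#' @param n_videos Number of source videos (>= 1).
#' @param frames_per_video Frames per video.
#' @param seed Integer master seed.
#' @param image_size Frame format for all videos.
#' @param render Render rasters (memory-heavy at survey formats) or keep
#'   frames label-only.
#' @return List: `frames`, `manifest` (see [build_manifest()]), `tracks`.
#' @export
generate_dataset <- function(cfg = scene_config(), n_videos = 10L,
                             frames_per_video = 20L, seed = 1L,
                             image_size = c(1280L, 720L), render = FALSE) {
  if (n_videos < 1) abort("n_videos must be >= 1")
  if (cfg$background_fraction >= 1 && frames_per_video * n_videos > 0) {
    # all-background datasets are representable; objects just never appear
  }
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(2^31 - 2, n_videos))
  flights <- lapply(seq_len(n_videos), function(v) {
    generate_flight(cfg, n_frames = frames_per_video, seed = seeds[v],
                    source_id = sprintf("video%04d", v),
                    image_size = image_size, render = render)
  })
  frames <- purrr::flatten(lapply(flights, `[[`, "frames"))
  tracks <- dplyr::bind_rows(lapply(flights, `[[`, "track"))
  list(frames = frames, manifest = build_manifest(frames, cfg$class_names),
       tracks = tracks)
}
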