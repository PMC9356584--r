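#' Detection tibbles
#'
#' A detection is a predicted class, a pixel box in frame coordinates and
#' a confidence in `[0, 1]`. Detections are plain tibbles so detector
#' output pipes straight into filtering and evaluation.
#'
#' @param class_id Integer class indices.
#' @param x0,y0,x1,y1 Pixel box corners (half-open).
#' @param confidence Scores in `[0, 1]`.
#' @return A detections tibble.
#' @export
detections <- function(class_id = integer(), x0 = double(), y0 = double(),
                       x1 = double(), y1 = double(), confidence = double()) {
  if (length(confidence) && (any(confidence < 0) || any(confidence > 1))) {
    abort("detections: confidence must lie in [0, 1]")
  }
  tibble(class_id = as.integer(class_id),
         x0 = as.double(x0), y0 = as.double(y0),
         x1 = as.double(x1), y1 = as.double(y1),
         confidence = as.double(confidence))
}

#' Noisy-oracle detector configuration
#'
#' The noisy oracle emulates a trained detector with controllable error
#' rates, reading ground truth and corrupting it: each true object is
#' missed independently with probability `miss_rate`; surviving boxes get
#' Gaussian corner jitter (`jitter_sd` px, clamped to the frame, redrawn
#' if a box collapses) and a confidence drawn uniformly from `tp_conf`;
#' spurious detections arrive Poisson(`fp_rate`) per frame with random
#' boxes, random classes and `fp_conf` confidences. Output is a
#' deterministic function of (frame, config, seed).
#'
#' @param miss_rate Per-object probability of non-detection, in `[0, 1]`.
#' @param fp_rate Expected false positives per frame (Poisson mean).
#' @param jitter_sd Pixel standard deviation of corner perturbation.
#' @param tp_conf,fp_conf Length-2 uniform bounds for true/false-positive
#'   confidences, within `[0, 1]`.
#' @param seed Integer seed.
#' @return A `noisy_oracle_config` list.
#' @export
noisy_oracle_config <- function(miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                                tp_conf = c(0.6, 1), fp_conf = c(0.1, 0.6),
                                seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1) abort("miss_rate must be in [0, 1]")
  if (fp_rate < 0 || jitter_sd < 0) abort("rates must be >= 0")
  chk <- function(b) length(b) == 2 && all(b >= 0) && all(b <= 1) && b[1] <= b[2]
  if (!chk(tp_conf) || !chk(fp_conf)) {
    abort("confidence bounds must be increasing pairs within [0, 1]")
  }
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, tp_conf = tp_conf, fp_conf = fp_conf,
                 seed = as.integer(seed)),
            class = "noisy_oracle_config")
}

# stable 31-bit hash of a string, for per-frame seed derivation
string_seed <- function(s, seed = 0L) {
  h <- as.double(seed %% 2147483647)
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Run the noisy-oracle detector on a labeled frame
#'
#' See [noisy_oracle_config()] for the corruption model. With zero noise
#' (`miss_rate = 0`, `jitter_sd = 0`, `fp_rate = 0`, `tp_conf = c(1, 1)`)
#' the output equals the ground truth with confidence 1. Works on
#' label-only frames: only box geometry is consulted, never pixels.
#'
#' @param frame A [labeled_frame()].
#' @param cfg A [noisy_oracle_config()].
#' @return A [detections()] tibble.
#' @export
oracle_detect <- function(frame, cfg = noisy_oracle_config()) {
  stopifnot(inherits(frame, "labeled_frame"),
            inherits(cfg, "noisy_oracle_config"))
  W <- frame$width; H <- frame$height
  withr::with_seed(string_seed(frame$frame_id, cfg$seed), {
    out <- list()
    if (nrow(frame$boxes)) {
      gt <- to_pixel(frame$boxes, W, H)
      kept <- runif(nrow(gt)) >= cfg$miss_rate
      gt <- gt[kept, , drop = FALSE]
      if (nrow(gt)) {
        jit <- function(b) {
          for (tries in 1:100) {
            x0 <- max(0, min(W - 1, b$x0 + rnorm(1, 0, cfg$jitter_sd)))
            x1 <- max(x0 + 1e-9, min(W, b$x1 + rnorm(1, 0, cfg$jitter_sd)))
            y0 <- max(0, min(H - 1, b$y0 + rnorm(1, 0, cfg$jitter_sd)))
            y1 <- max(y0 + 1e-9, min(H, b$y1 + rnorm(1, 0, cfg$jitter_sd)))
            if (x1 > x0 && y1 > y0) return(c(x0, y0, x1, y1))
          }
          c(b$x0, b$y0, b$x1, b$y1)
        }
        coords <- if (cfg$jitter_sd > 0) {
          t(vapply(seq_len(nrow(gt)), function(i) jit(gt[i, ]), double(4)))
        } else {
          cbind(gt$x0, gt$y0, gt$x1, gt$y1)
        }
        out$tp <- detections(gt$class_id, coords[, 1], coords[, 2],
                             coords[, 3], coords[, 4],
                             runif(nrow(gt), cfg$tp_conf[1], cfg$tp_conf[2]))
      }
    }
    n_fp <- if (cfg$fp_rate > 0) rpois(1, cfg$fp_rate) else 0L
    if (n_fp > 0) {
      bw <- runif(n_fp, 4, pmax(5, pmin(200, W / 2)))
      bh <- runif(n_fp, 4, pmax(5, pmin(200, H / 2)))
      x0 <- runif(n_fp, 0, W - bw); y0 <- runif(n_fp, 0, H - bh)
      out$fp <- detections(sample(0:(length(wildedge_classes()) - 1L),
                                  n_fp, replace = TRUE),
                           x0, y0, x0 + bw, y0 + bh,
                           runif(n_fp, cfg$fp_conf[1], cfg$fp_conf[2]))
    }
    if (length(out)) dplyr::bind_rows(out) else detections()
  })
}

#' Color-matching detector for synthetic scenes
#'
#' An independent, pixel-driven detector implementation: scans the raster
#' for pixels near each class's palette color (the synthetic scene
#' generator paints each class a distinct color) and reports the bounding
#' box of each class's matched pixel mass. Deliberately naive — one box per
#' class per frame — but entirely independent of ground-truth labels,
#' which makes it a useful second implementation of the detector contract
#' in end-to-end checks.
#'
#' @param frame A [labeled_frame()] with a raster.
#' @param palette Per-class RGB rows, matching the scene generator's.
#' @param tol Per-channel color tolerance.
#' @param confidence Confidence assigned to every reported box.
#' @return A [detections()] tibble.
#' @export
color_match_detect <- function(frame, palette = scene_palette(), tol = 0.12,
                               confidence = 0.9) {
  if (is.null(frame$image)) abort("color_match_detect: frame has no raster")
  img <- frame$image
  purrr::map_dfr(seq_len(nrow(palette)), function(k) {
    col <- palette[k, ]
    hit <- abs(img[, , 1] - col[1]) < tol &
           abs(img[, , 2] - col[2]) < tol &
           abs(img[, , 3] - col[3]) < tol
    if (!any(hit)) return(detections())
    idx <- which(hit, arr.ind = TRUE)
    detections(class_id = k - 1L,
               x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
               x1 = max(idx[, 2]), y1 = max(idx[, 1]),
               confidence = confidence)
  })
}

#' Read/write a predictions interchange file
#'
#' One JSON-lines record per frame: `{"frame_id": ..., "detections":
#' [{"class", "x0", "y0", "x1", "y1", "conf"}, ...]}` — the offline input
#' format for evaluation.
#'
#' @param preds Tibble with `frame_id` plus [detections()] columns.
#' @param path JSON-lines file path.
#' @return `read_predictions()`: a tibble of per-frame detections.
#' @export
write_predictions <- function(preds, path) {
  ids <- unique(preds$frame_id)
  lines <- vapply(ids, function(id) {
    d <- preds[preds$frame_id == id, , drop = FALSE]
    jsonlite::toJSON(list(
      frame_id = id,
      detections = data.frame(class = d$class_id, x0 = d$x0, y0 = d$y0,
                              x1 = d$x1, y1 = d$y1, conf = d$confidence)
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  purrr::map_dfr(lines[nzchar(lines)], function(l) {
    rec <- jsonlite::fromJSON(l)
    if (length(rec$detections) == 0 || nrow(rec$detections) == 0) {
      return(tibble(frame_id = character(), class_id = integer(),
                    x0 = double(), y0 = double(), x1 = double(),
                    y1 = double(), confidence = double()))
    }
    d <- rec$detections
    tibble(frame_id = rec$frame_id, class_id = as.integer(d$class),
           x0 = d$x0, y0 = d$y0, x1 = d$x1, y1 = d$y1, confidence = d$conf)
  })
}
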