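#' Prepare a training dataset: tile, manifest, split, check
#'
#' Runs the preparation flow end to end: every frame above the tiling
#' threshold is broken into overlapping tiles with the retention rule
#' (small frames pass through as single windows), a manifest is built over
#' the resulting tiles, the manifest is split by source video without
#' leakage, and the background-image guideline is checked. The returned
#' summary counts are exactly what recomputation by calling each stage
#' directly yields — the pipeline keeps no hidden state.
#'
#' @param frames List of [labeled_frame()] objects.
#' @param spec A [tile_spec()].
#' @param train_fraction,seed Passed to [split_by_source()].
#' @param min_background Passed to [background_check()].
#' @param class_names Ordered class names.
#' @return List: `tiles` (flat list of tiles), `manifest` (with split),
#'   `summary` (one-row tibble: `frames_in`, `tiles_out`, `n_train`,
#'   `n_val`, `background_fraction`, `background_pass`).
#' @export
run_prepare <- function(frames, spec = tile_spec(), train_fraction = 0.8,
                        seed = 1L, min_background = 0.10,
                        class_names = wildedge_classes()) {
  tiles <- purrr::flatten(lapply(frames, function(f) {
    tryCatch(tile_image(f, spec),
             error = function(e) abort(sprintf("tiling stage (%s): %s",
                                               f$frame_id, e$message)))
  }))
  manifest <- tryCatch(build_manifest(tiles, class_names),
                       error = function(e) abort(paste("manifest stage:",
                                                       e$message)))
  manifest <- tryCatch(split_by_source(manifest, train_fraction, seed),
                       error = function(e) abort(paste("split stage:",
                                                       e$message)))
  bg <- background_check(manifest, min_background)
  list(
    tiles = tiles, manifest = manifest,
    summary = tibble(
      frames_in = length(frames), tiles_out = length(tiles),
      n_train = sum(manifest$split == "train"),
      n_val = sum(manifest$split == "val"),
      background_fraction = bg$fraction, background_pass = bg$pass
    )
  )
}

#' Run a simulated flight through the edge pipeline
#'
#' For each frame in order: run the detector on the whole frame (no
#' inference-time tiling), drop detections at or below the send threshold,
#' apply the throttle policy over the resulting positive-frame stream,
#' and publish one bundle per notifying frame with the GPS fix of that
#' frame; finally emit the GeoJSON sink from the subscriber's store.
#'
#' @param flight A flight from [generate_flight()] (`frames` + `track`).
#' @param detector Function `frame -> detections tibble`; defaults to the
#'   noisy oracle under `detector_cfg`.
#' @param detector_cfg A [noisy_oracle_config()].
#' @param min_confidence Send threshold (default 0.5, strict).
#' @param policy A [throttle_policy()].
#' @param channel A [sim_channel()].
#' @return List: `events` (per-frame tibble with `positive`, `notify`,
#'   `n_surviving`), `published`, `stored` (bundle
#'   list), `geojson` (FeatureCollection), `channel`.
#' @export
run_flight <- function(flight, detector = NULL,
                       detector_cfg = noisy_oracle_config(),
                       min_confidence = 0.5, policy = throttle_policy(),
                       channel = sim_channel()) {
  frames <- flight$frames; track <- flight$track
  detect_fn <- detector %||% function(f) oracle_detect(f, detector_cfg)
  per_frame <- lapply(frames, function(f) filter_detections(detect_fn(f),
                                                            min_confidence))
  events <- tibble(
    frame_id = vapply(frames, `[[`, character(1), "frame_id"),
    timestamp = track$timestamp,
    positive = vapply(per_frame, nrow, integer(1)) > 0,
    classes = lapply(per_frame, function(d) unique(d$class_id))
  )
  events <- throttle_frames(events, policy)
  published <- 0L
  for (i in seq_along(frames)) {
    if (!events$notify[i]) next
    bundle <- build_bundle(frames[[i]], per_frame[[i]],
                           lat = track$lat[i], lon = track$lon[i],
                           timestamp = track$timestamp[i])
    publish_bundle(channel, bundle)
    published <- published + 1L
  }
  store <- channel_store(channel)
  events$n_surviving <- vapply(per_frame, nrow, integer(1))
  list(events = events, published = published, stored = store,
       geojson = to_geojson(store), channel = channel)
}

#' Manual-review burden arithmetic
#'
#' How many minutes of drone flight one hour of manual image review keeps
#' up with: a reviewer processing `images_per_session` images in
#' `session_minutes` covers `images_per_session / session_minutes * 60`
#' images per hour; at a capture rate of `capture_fps` frames per second
#' that is `images / capture_fps` seconds, i.e.
#' `images_per_session / (session_minutes * capture_fps)` minutes of
#' flight per review hour. At the published reference rates (500 images
#' per 45-minute session, 2 fps capture) this is ~5.6 min — the
#' scalability wall that motivates on-board detection.
#'
#' @param images_per_session Images a reviewer processes per session.
#' @param session_minutes Session length in minutes.
#' @param capture_fps Capture rate in frames per second.
#' @return Minutes of flight reviewable per hour of review.
#' @export
#' @examples
#' review_burden(500, 45, 2)
review_burden <- function(images_per_session, session_minutes, capture_fps) {
  if (images_per_session <= 0 || session_minutes <= 0 || capture_fps <= 0) {
    abort("review_burden: all inputs must be positive")
  }
  images_per_session / (session_minutes * capture_fps)
}
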