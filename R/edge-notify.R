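#' Filter detections by the send threshold
#'
#' Only detections with confidence *strictly over* the threshold (default
#' 50%) are eligible for notification; a frame is forwarded iff at least
#' one detection survives. A detection at exactly the threshold is never
#' transmitted.
#'
#' @param dets A [detections()] tibble.
#' @param min_confidence Send threshold (default 0.5).
#' @return The surviving detections.
#' @export
filter_detections <- function(dets, min_confidence = 0.5) {
  dets[dets$confidence > min_confidence, , drop = FALSE]
}

#' Build a detection bundle
#'
#' Bundles everything a ground operator needs into one message so class,
#' frame and location can never be mismatched in transit: the frame id,
#' capture timestamp, the aircraft's GPS fix (WGS84 decimal degrees, the
#' drone's position — no ground projection of the animal is attempted),
#' every surviving detection of the frame, and one annotated image
#' payload. `message_id` is a deterministic function of
#' `(frame_id, timestamp)` so retransmissions are recognizable.
#'
#' @param frame A [labeled_frame()].
#' @param dets Surviving detections (>= 1 row).
#' @param lat,lon Aircraft latitude/longitude in decimal degrees.
#' @param timestamp Capture time (numeric seconds or POSIXct).
#' @return A `detection_bundle`.
#' @export
build_bundle <- function(frame, dets, lat, lon, timestamp = 0) {
  if (nrow(dets) == 0) abort("build_bundle: need >= 1 detection")
  if (!is.finite(lat) || lat < -90 || lat > 90) abort("invalid latitude")
  if (!is.finite(lon) || lon < -180 || lon > 180) abort("invalid longitude")
  ts <- as.double(timestamp)
  payload <- NULL
  if (!is.null(frame$image)) {
    annotated <- render_qc_overlay(frame, boxes = dets)
    payload <- png::writePNG(annotated)
  }
  structure(
    list(message_id = sprintf("%s-%010d", frame$frame_id,
                              string_seed(sprintf("%s@%.3f", frame$frame_id, ts))),
         frame_id = frame$frame_id, utc_timestamp = ts,
         lat = as.double(lat), lon = as.double(lon),
         detections = dets, image_payload = payload),
    class = "detection_bundle"
  )
}

#' @export
print.detection_bundle <- function(x, ...) {
  cat(sprintf("<detection_bundle %s> frame %s @ (%.5f, %.5f), %d detection(s)%s\n",
              x$message_id, x$frame_id, x$lat, x$lon, nrow(x$detections),
              if (is.null(x$image_payload)) "" else
                sprintf(", %d payload bytes", length(x$image_payload))))
  invisible(x)
}

#' Wire encoding of detection bundles
#'
#' JSON envelope (versioned `schema` field) with the annotated frame as a
#' base64 PNG payload — lightweight and human-debuggable. Decoding a
#' round trip reproduces every non-image field exactly; the image payload
#' decodes to a raster of identical dimensions. Malformed or truncated
#' bytes raise a decode error rather than yielding a partial bundle.
#'
#' @param bundle A `detection_bundle`.
#' @return `encode_bundle()`: a UTF-8 JSON string (the MQTT payload).
#' @export
encode_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "detection_bundle"))
  jsonlite::toJSON(list(
    schema = "wildedge/1",
    message_id = bundle$message_id,
    frame_id = bundle$frame_id,
    utc_timestamp = bundle$utc_timestamp,
    lat = bundle$lat, lon = bundle$lon,
    detections = as.data.frame(bundle$detections),
    image_png_b64 = if (is.null(bundle$image_payload)) NULL else
      jsonlite::base64_enc(bundle$image_payload)
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname encode_bundle
#' @param bytes Encoded payload.
#' @export
decode_bundle <- function(bytes) {
  rec <- tryCatch(jsonlite::fromJSON(bytes),
                  error = function(e) abort(paste("decode error:", e$message)))
  needed <- c("schema", "message_id", "frame_id", "utc_timestamp", "lat", "lon",
              "detections")
  if (!is.list(rec) || !all(needed %in% names(rec)) ||
      !identical(rec$schema, "wildedge/1")) {
    abort("decode error: missing fields or unknown schema")
  }
  payload <- NULL
  if (!is.null(rec$image_png_b64)) {
    payload <- jsonlite::base64_dec(rec$image_png_b64)
    tryCatch(png::readPNG(payload),
             error = function(e) abort("decode error: corrupt image payload"))
  }
  d <- rec$detections
  structure(
    list(message_id = rec$message_id, frame_id = rec$frame_id,
         utc_timestamp = as.double(rec$utc_timestamp),
         lat = as.double(rec$lat), lon = as.double(rec$lon),
         detections = detections(d$class_id, d$x0, d$y0, d$x1, d$y1,
                                 d$confidence),
         image_payload = payload),
    class = "detection_bundle"
  )
}

#' In-process publish/subscribe channel with QoS-1 semantics
#'
#' A broker simulator for the notification link: the publisher retries
#' until the broker acknowledges (at-least-once), so messages may arrive
#' more than once; the subscriber deduplicates by `message_id`, so every
#' published bundle is stored exactly once under any loss pattern with
#' eventual success. Loss and duplication are scriptable for tests:
#' `drop(message_id, attempt)` returns `TRUE` to swallow that delivery
#' attempt, `duplicate(message_id)` to deliver a second copy. Messages
#' still undelivered after `max_attempts` go to a bounded retry backlog;
#' when the backlog overflows, the oldest entry is dropped and counted.
#'
#' @param drop,duplicate Scripting functions (see above).
#' @param max_attempts Send attempts per publish call.
#' @param backlog_limit Maximum queued undelivered messages.
#' @return A `sim_channel` environment.
#' @export
sim_channel <- function(drop = function(message_id, attempt) FALSE,
                        duplicate = function(message_id) FALSE,
                        max_attempts = 8L, backlog_limit = 100L) {
  ch <- new.env(parent = emptyenv())
  ch$drop <- drop; ch$duplicate <- duplicate
  ch$max_attempts <- max_attempts; ch$backlog_limit <- backlog_limit
  ch$store <- list()        # message_id -> decoded bundle, insertion order
  ch$deliveries <- 0L       # raw deliveries incl. duplicates
  ch$backlog <- list()
  ch$backlog_dropped <- 0L
  class(ch) <- c("sim_channel", class(ch))
  ch
}

deliver <- function(channel, bytes) {
  channel$deliveries <- channel$deliveries + 1L
  b <- decode_bundle(bytes)
  if (is.null(channel$store[[b$message_id]])) {
    channel$store[[b$message_id]] <- b   # idempotent handler
  }
  invisible(TRUE)
}

#' @rdname sim_channel
#' @param channel A `sim_channel`.
#' @param bundle A `detection_bundle`.
#' @return `publish_bundle()`: `TRUE` if acknowledged, `FALSE` if queued to
#'   the backlog.
#' @export
publish_bundle <- function(channel, bundle) {
  stopifnot(inherits(channel, "sim_channel"))
  bytes <- encode_bundle(bundle)
  for (attempt in seq_len(channel$max_attempts)) {
    if (!isTRUE(channel$drop(bundle$message_id, attempt))) {
      deliver(channel, bytes)
      if (isTRUE(channel$duplicate(bundle$message_id))) deliver(channel, bytes)
      return(invisible(TRUE))
    }
  }
  if (length(channel$backlog) >= channel$backlog_limit) {
    channel$backlog <- channel$backlog[-1]
    channel$backlog_dropped <- channel$backlog_dropped + 1L
  }
  channel$backlog <- c(channel$backlog, list(bytes))
  invisible(FALSE)
}

#' @rdname sim_channel
#' @export
retry_backlog <- function(channel) {
  pending <- channel$backlog
  channel$backlog <- list()
  for (bytes in pending) deliver(channel, bytes)
  invisible(length(pending))
}

#' @rdname sim_channel
#' @export
channel_store <- function(channel) channel$store

#' Throttle a stream of detection-positive frames
#'
#' At survey frame rates each square meter of ground appears in many
#' consecutive frames, so notifying on every positive frame overwhelms
#' both the link and the operator. The policy emits at most one
#' notification per `frame_stride` consecutive positive frames (the
#' first of each run of `frame_stride` positives notifies), optionally
#' enforcing a per-class cooldown in seconds.
#'
#' @param frame_stride Emit at most one bundle per this many consecutive
#'   positive frames (>= 1).
#' @param per_class_cooldown Minimum seconds between notifications
#'   involving the same class (0 disables).
#' @return A `throttle_policy`.
#' @export
throttle_policy <- function(frame_stride = 10L, per_class_cooldown = 0) {
  if (frame_stride < 1) abort("frame_stride must be >= 1")
  if (per_class_cooldown < 0) abort("per_class_cooldown must be >= 0")
  structure(list(frame_stride = as.integer(frame_stride),
                 per_class_cooldown = per_class_cooldown),
            class = "throttle_policy")
}

#' @rdname throttle_policy
#' @param events Tibble in frame order with columns `positive` (logical),
#'   and optionally `timestamp` (numeric seconds) and `classes`
#'   (list-column of class ids per frame) for the cooldown.
#' @param policy A `throttle_policy`.
#' @return `throttle_frames()`: `events` with a logical `notify` column.
#' @export
throttle_frames <- function(events, policy = throttle_policy()) {
  n <- nrow(events)
  notify <- logical(n)
  pos_count <- 0L
  last_sent <- list()
  for (i in seq_len(n)) {
    if (!events$positive[i]) next
    pos_count <- pos_count + 1L
    if ((pos_count - 1L) %% policy$frame_stride != 0L) next
    if (policy$per_class_cooldown > 0 && !is.null(events$classes)) {
      ts <- events$timestamp[i]
      cls <- as.character(events$classes[[i]])
      blocked <- vapply(cls, function(cl) {
        !is.null(last_sent[[cl]]) &&
          (ts - last_sent[[cl]]) < policy$per_class_cooldown
      }, logical(1))
      if (all(blocked) && length(cls)) next
      for (cl in cls) last_sent[[cl]] <- ts
    }
    notify[i] <- TRUE
  }
  events$notify <- notify
  events
}

#' Convert stored bundles to GeoJSON
#'
#' One Point feature per bundle at `(lon, lat)` — GeoJSON coordinate
#' order — with the detected classes, the maximum confidence, the frame id
#' and an image reference as properties. This is the map-display sink:
#' any GeoJSON viewer can render the detection icons at the broadcast
#' locations.
#'
#' @param store A bundle list from [channel_store()] (or any list of
#'   `detection_bundle`s).
#' @param class_names Ordered class names.
#' @return A `list` FeatureCollection; serialize with [write_geojson()].
#' @export
to_geojson <- function(store, class_names = wildedge_classes()) {
  features <- lapply(store, function(b) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(b$lon, b$lat)),
      properties = list(
        frame_id = b$frame_id,
        message_id = b$message_id,
        utc_timestamp = b$utc_timestamp,
        classes = unique(class_names[b$detections$class_id + 1L]),
        max_confidence = max(b$detections$confidence),
        image = if (is.null(b$image_payload)) NA_character_ else
          sprintf("%s.png", b$message_id)
      )
    )
  })
  names(features) <- NULL
  list(type = "FeatureCollection", features = features)
}

#' @rdname to_geojson
#' @param x A FeatureCollection list from `to_geojson()`.
#' @param path Output file.
#' @export
write_geojson <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
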