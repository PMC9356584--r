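# Independent brute-force oracles used across the suite. These enumerate
# pixels or thresholds directly and never call the code paths they check.

# pixel set of a half-open integer box, as "x,y" keys
pixel_set <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) return(character())
  g <- expand.grid(x = x0:(x1 - 1), y = y0:(y1 - 1))
  paste(g$x, g$y)
}

# IoU by counting pixels of integer boxes
iou_pixel_oracle <- function(a, b) {
  pa <- pixel_set(a[1], a[2], a[3], a[4])
  pb <- pixel_set(b[1], b[2], b[3], b[4])
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# fraction of a box's pixels lying on a tile window, plus the clipped box
retention_pixel_oracle <- function(box, ox, oy, tw, th) {
  px <- pixel_set(box[1], box[2], box[3], box[4])
  xy <- do.call(rbind, strsplit(px, " "))
  x <- as.integer(xy[, 1]); y <- as.integer(xy[, 2])
  on <- x >= ox & x < ox + tw & y >= oy & y < oy + th
  if (!any(on)) return(list(ratio = 0, clip = NULL))
  list(ratio = mean(on),
       clip = c(min(x[on]), min(y[on]), max(x[on]) + 1, max(y[on]) + 1))
}

# AP by sweeping every confidence threshold and integrating the maximum
# precision attainable at or beyond each recall step
ap_sweep_oracle <- function(conf, tp, n_gt) {
  thr <- sort(unique(conf))
  pts <- t(vapply(thr, function(t) {
    keep <- conf >= t
    ntp <- sum(tp[keep]); nd <- sum(keep)
    c(recall = ntp / n_gt, precision = if (nd) ntp / nd else 1)
  }, c(recall = 0, precision = 0)))
  recs <- sort(unique(pts[, "recall"]))
  recs <- recs[recs > 0]
  ap <- 0; prev <- 0
  for (r in recs) {
    p_max <- max(pts[pts[, "recall"] >= r, "precision"])
    ap <- ap + (r - prev) * p_max
    prev <- r
  }
  ap
}

# random integer pixel box inside a W x H image
random_pixel_box <- function(W, H, max_side = 200, class_id = 0L) {
  w <- sample.int(min(max_side, W), 1)
  h <- sample.int(min(max_side, H), 1)
  x0 <- sample.int(W - w + 1, 1) - 1L
  y0 <- sample.int(H - h + 1, 1) - 1L
  pixel_boxes(class_id, x0, y0, x0 + w, y0 + h)
}

random_yolo_boxes <- function(n) {
  w <- runif(n, 0.01, 0.4); h <- runif(n, 0.01, 0.4)
  yolo_boxes(class_id = sample(0:4, n, replace = TRUE),
             cx = runif(n, w / 2, 1 - w / 2),
             cy = runif(n, h / 2, 1 - h / 2), w = w, h = h)
}

# tiny raster frame with given normalized boxes
tiny_frame <- function(id = "f1", src = "v1", W = 64, H = 48,
                       boxes = yolo_boxes(), value = 0.5) {
  labeled_frame(image = array(value, dim = c(H, W, 3)), frame_id = id,
                source_id = src, boxes = boxes)
}

# step-through replay of the edge pipeline: filter then stride throttle.
# Independent of throttle_frames()/run_flight().
replay_notifications <- function(det_list, min_conf, stride) {
  pos_seen <- 0L
  notified <- logical(length(det_list))
  for (i in seq_along(det_list)) {
    d <- det_list[[i]]
    if (nrow(d) == 0 || !any(d$confidence > min_conf)) next
    pos_seen <- pos_seen + 1L
    if ((pos_seen - 1L) %% stride == 0L) notified[i] <- TRUE
  }
  notified
}
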