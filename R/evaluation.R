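#' Intersection over union of pixel boxes
#'
#' Area of the axis-aligned intersection divided by the area of the union,
#' on half-open rectangles. Vectorized over rows; `a` and `b` must have
#' equal row counts (or one of them a single row).
#'
#' @param a,b Pixel-box tibbles (class columns ignored).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
#' @examples
#' box_iou(pixel_boxes(0L, 0, 0, 10, 10), pixel_boxes(0L, 5, 0, 15, 10))
box_iou <- function(a, b) {
  if (any(a$x1 <= a$x0) || any(a$y1 <= a$y0) ||
      any(b$x1 <= b$x0) || any(b$y1 <= b$y0)) {
    abort("box_iou: zero-area box")
  }
  iw <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  ih <- pmax(0, pmin(a$y1, b$y1) - pmax(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) +
           (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

#' Match detections to ground truth within one frame
#'
#' Greedy confidence-descending protocol: each detection is matched to the
#' unmatched ground-truth box of the same class (or any class when
#' `class_agnostic`) with the highest IoU at or above `iou_threshold`;
#' detections that find no partner are false positives and leftover ground
#' truth are false negatives. Ties are broken by higher IoU, then lower
#' ground-truth index, so matching is deterministic.
#'
#' @param dets A [detections()] tibble (one frame).
#' @param gts Pixel boxes of the frame's ground truth.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @param class_agnostic Ignore class when pairing (used by the confusion
#'   matrix so cross-class confusions are countable).
#' @return List: `det` tibble (`class_id`, `confidence`, `tp`, `iou`,
#'   `gt_index`, `gt_class`) in confidence-descending order, and
#'   `fn_gt` — indices of unmatched ground-truth boxes.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5,
                             class_agnostic = FALSE) {
  nd <- nrow(dets); ng <- nrow(gts)
  ord <- if (nd) order(-dets$confidence) else integer()
  matched_gt <- rep(FALSE, ng)
  det_rows <- vector("list", nd)
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0L; best_iou <- -1
    if (ng) {
      cand <- which(!matched_gt &
                      (class_agnostic | gts$class_id == dets$class_id[i]))
      if (length(cand)) {
        ious <- box_iou(dets[rep(i, length(cand)), ], gts[cand, ])
        ok <- ious >= iou_threshold
        if (any(ok)) {
          cand <- cand[ok]; ious <- ious[ok]
          pick <- which(ious == max(ious))[1]  # then lowest gt index
          best <- cand[pick]; best_iou <- ious[pick]
        }
      }
    }
    if (best > 0L) matched_gt[best] <- TRUE
    det_rows[[k]] <- tibble(
      class_id = dets$class_id[i], confidence = dets$confidence[i],
      tp = best > 0L, iou = if (best > 0L) best_iou else NA_real_,
      gt_index = if (best > 0L) best else NA_integer_,
      gt_class = if (best > 0L) gts$class_id[best] else NA_integer_
    )
  }
  det <- if (nd) dplyr::bind_rows(det_rows) else
    tibble(class_id = integer(), confidence = double(), tp = logical(),
           iou = double(), gt_index = integer(), gt_class = integer())
  list(det = det, fn_gt = which(!matched_gt))
}

ap_from_pr <- function(recall, precision) {
  # all-point interpolation: integrate the precision envelope over recall
  if (!length(recall)) return(0)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Evaluate detections against ground truth
#'
#' Pools per-frame greedy matches (class-exact, confidence-descending, at
#' `iou_threshold`), builds one precision–recall curve per class and
#' computes the all-point-interpolated average precision (area under the
#' precision envelope); `map` is the unweighted mean of the APs of classes
#' with at least one ground-truth box. A `(K+1) x (K+1)` confusion matrix
#' with a background row/column is built from a separate class-*agnostic*
#' pairing over detections at or above `conf_floor`, so cross-class
#' confusions land in off-diagonal cells, missed objects in the background
#' column and spurious detections in the background row.
#'
#' @param preds Tibble of detections across frames: `frame_id` +
#'   [detections()] columns.
#' @param gt Tibble of ground truth across frames: `frame_id` +
#'   pixel-box columns.
#' @param iou_threshold IoU threshold for true positives (default 0.5).
#' @param conf_floor Confidence floor for the confusion matrix (default
#'   0.25).
#' @param class_names Ordered class names.
#' @return An `eval_report`: `ap` tibble (`class`, `class_id`, `n_gt`,
#'   `n_det`, `tp`, `fp`, `fn`, `ap`), `map`, `pr` (per-class PR points),
#'   `confusion` matrix, and the thresholds used. Classes with zero ground
#'   truth have `ap = NA` and are excluded from `map`.
#' @export
evaluate_detections <- function(preds, gt, iou_threshold = 0.5,
                                conf_floor = 0.25,
                                class_names = wildedge_classes()) {
  K <- length(class_names)
  frame_ids <- union(unique(preds$frame_id), unique(gt$frame_id))
  pooled <- vector("list", length(frame_ids))
  confusion <- matrix(0L, nrow = K + 1, ncol = K + 1,
                      dimnames = list(true = c(class_names, "background"),
                                      predicted = c(class_names, "background")))
  for (fi in seq_along(frame_ids)) {
    id <- frame_ids[fi]
    d <- preds[preds$frame_id == id, , drop = FALSE]
    g <- gt[gt$frame_id == id, , drop = FALSE]
    m <- match_detections(d, g, iou_threshold)
    pooled[[fi]] <- m$det
    # class-agnostic pairing for the confusion matrix
    dc <- d[d$confidence >= conf_floor, , drop = FALSE]
    mc <- match_detections(dc, g, iou_threshold, class_agnostic = TRUE)
    if (nrow(mc$det)) {
      for (r in seq_len(nrow(mc$det))) {
        pred_j <- mc$det$class_id[r] + 1L
        true_i <- if (mc$det$tp[r]) mc$det$gt_class[r] + 1L else K + 1L
        confusion[true_i, pred_j] <- confusion[true_i, pred_j] + 1L
      }
    }
    for (gi in mc$fn_gt) {
      confusion[g$class_id[gi] + 1L, K + 1L] <-
        confusion[g$class_id[gi] + 1L, K + 1L] + 1L
    }
  }
  pooled <- dplyr::bind_rows(pooled)
  pr <- list()
  ap_rows <- purrr::map_dfr(0:(K - 1), function(cl) {
    n_gt <- sum(gt$class_id == cl)
    dc <- pooled[pooled$class_id == cl, , drop = FALSE]
    dc <- dc[order(-dc$confidence), , drop = FALSE]
    if (n_gt == 0) {
      pr[[class_names[cl + 1]]] <<- tibble(confidence = double(),
                                           recall = double(),
                                           precision = double())
      return(tibble(class = class_names[cl + 1], class_id = cl, n_gt = 0L,
                    n_det = nrow(dc), tp = sum(dc$tp), fp = sum(!dc$tp),
                    fn = 0L, ap = NA_real_))
    }
    cum_tp <- cumsum(dc$tp); cum_fp <- cumsum(!dc$tp)
    recall <- cum_tp / n_gt
    precision <- if (nrow(dc)) cum_tp / (cum_tp + cum_fp) else double()
    pr[[class_names[cl + 1]]] <<- tibble(confidence = dc$confidence,
                                         recall = recall,
                                         precision = precision)
    tibble(class = class_names[cl + 1], class_id = cl, n_gt = n_gt,
           n_det = nrow(dc), tp = sum(dc$tp), fp = sum(!dc$tp),
           fn = n_gt - sum(dc$tp), ap = ap_from_pr(recall, precision))
  })
  defined <- !is.na(ap_rows$ap)
  structure(
    list(ap = ap_rows,
         map = if (any(defined)) mean(ap_rows$ap[defined]) else NA_real_,
         pr = pr, confusion = confusion, iou_threshold = iou_threshold,
         conf_floor = conf_floor, class_names = class_names),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> IoU threshold %.2f, mAP %.4f\n",
              x$iou_threshold, x$map))
  print(x$ap)
  invisible(x)
}

#' Per-class AP over ground-truth-bearing classes
#'
#' @param report An `eval_report`.
#' @return The unweighted mean AP.
#' @export
mean_ap <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  report$map
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$ap

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(map = x$map, iou_threshold = x$iou_threshold,
         n_classes = sum(!is.na(x$ap$ap)),
         n_gt = sum(x$ap$n_gt), n_det = sum(x$ap$n_det),
         tp = sum(x$ap$tp), fp = sum(x$ap$fp), fn = sum(x$ap$fn))
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, type = c("pr", "confusion"),
                                 normalize = c("none", "row", "column"), ...) {
  type <- match.arg(type)
  if (type == "pr") {
    d <- dplyr::bind_rows(object$pr, .id = "class")
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$recall, y = .data$precision,
                                      color = .data$class)) +
        ggplot2::geom_step(direction = "vh") +
        ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
        ggplot2::labs(x = "recall", y = "precision",
                      title = sprintf("Precision-recall at IoU %.2f",
                                      object$iou_threshold)) +
        ggplot2::theme_minimal()
    )
  }
  normalize <- match.arg(normalize)
  m <- object$confusion
  m <- switch(normalize,
              none = m,
              row = sweep(m, 1, pmax(1, rowSums(m)), "/"),
              column = sweep(m, 2, pmax(1, colSums(m)), "/"))
  d <- as.data.frame(as.table(m))
  names(d) <- c("true", "predicted", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$count, 3)),
                       color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix (with background class)") +
    ggplot2::theme_minimal()
}
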