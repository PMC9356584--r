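test_that("IoU matches the pixel-counting oracle and basic identities", {
  expect_equal(box_iou(pixel_boxes(0L, 0, 0, 10, 10),
                       pixel_boxes(0L, 0, 0, 10, 10)), 1)
  expect_equal(box_iou(pixel_boxes(0L, 0, 0, 10, 10),
                       pixel_boxes(0L, 20, 20, 30, 30)), 0)
  expect_equal(box_iou(pixel_boxes(0L, 0, 0, 10, 10),
                       pixel_boxes(0L, 5, 0, 15, 10)), 50 / 150)
  expect_error(box_iou(pixel_boxes(0L, 0, 0, 0, 10),
                       pixel_boxes(0L, 0, 0, 10, 10)), "zero-area")
  withr::with_seed(31, {
    for (rep in 1:200) {
      a <- random_pixel_box(80, 80, max_side = 40)
      b <- random_pixel_box(80, 80, max_side = 40)
      expected <- iou_pixel_oracle(c(a$x0, a$y0, a$x1, a$y1),
                                   c(b$x0, b$y0, b$x1, b$y1))
      expect_equal(box_iou(a, b), expected)
      expect_equal(box_iou(b, a), box_iou(a, b))   # symmetry
    }
  })
})

test_that("greedy matching implements the threshold and confidence protocol", {
  gt <- pixel_boxes(0L, 0, 0, 10, 10)
  # IoU 0.6 -> TP
  m <- match_detections(detections(0L, 0, 0, 10, 8, 0.9), gt)
  expect_true(m$det$tp)
  expect_length(m$fn_gt, 0)
  # IoU below 0.5 -> FP and FN
  m <- match_detections(detections(0L, 6, 0, 16, 10, 0.9), gt)
  expect_false(m$det$tp)
  expect_equal(m$fn_gt, 1L)
  # higher-confidence detection claims the GT; the other is FP
  d2 <- detections(c(0L, 0L), c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                   c(0.8, 0.9))
  m <- match_detections(d2, gt)
  expect_equal(m$det$confidence[m$det$tp], 0.9)
  expect_equal(sum(m$det$tp), 1)
  # wrong class never matches class-exact, but does class-agnostic
  m <- match_detections(detections(1L, 0, 0, 10, 10, 0.9), gt)
  expect_false(m$det$tp)
  m <- match_detections(detections(1L, 0, 0, 10, 10, 0.9), gt,
                        class_agnostic = TRUE)
  expect_true(m$det$tp)
})

test_that("greedy matching agrees with exhaustive assignment on small cases", {
  # enumerate all one-to-one same-class assignments, maximize TP count then
  # total IoU; greedy must find an assignment with the same TP count
  withr::with_seed(32, {
    for (rep in 1:50) {
      ng <- sample(0:3, 1); nd <- sample(0:3, 1)
      gt <- if (ng) dplyr::bind_rows(lapply(1:ng, function(i)
        random_pixel_box(50, 50, 30, class_id = sample(0:1, 1)))) else
        pixel_boxes()
      dt <- if (nd) dplyr::bind_rows(lapply(1:nd, function(i) {
        b <- random_pixel_box(50, 50, 30, class_id = sample(0:1, 1))
        dplyr::mutate(b, confidence = round(runif(1), 3))
      })) else detections()
      m <- match_detections(dt, gt)
      best_tp <- 0
      if (ng && nd) {
        idx <- expand.grid(rep(list(0:ng), nd))
        for (r in seq_len(nrow(idx))) {
          assign <- as.integer(idx[r, ])
          used <- assign[assign > 0]
          if (anyDuplicated(used)) next
          tp <- 0
          ok <- TRUE
          for (j in seq_len(nd)) {
            if (assign[j] == 0) next
            g <- assign[j]
            if (dt$class_id[j] != gt$class_id[g]) { ok <- FALSE; break }
            if (box_iou(dt[j, ], gt[g, ]) < 0.5) { ok <- FALSE; break }
            tp <- tp + 1
          }
          if (ok) best_tp <- max(best_tp, tp)
        }
      }
      # greedy equals the exhaustive optimum when each detection has at
      # most one above-threshold same-class candidate (unambiguous case);
      # otherwise it can only be <= the optimum
      ambiguous <- FALSE
      if (ng && nd) {
        for (j in seq_len(nd)) {
          ncand <- sum(vapply(seq_len(ng), function(g) {
            dt$class_id[j] == gt$class_id[g] &&
              box_iou(dt[j, ], gt[g, ]) >= 0.5
          }, logical(1)))
          if (ncand > 1) ambiguous <- TRUE
        }
      }
      if (!ambiguous) expect_equal(sum(m$det$tp), best_tp)
      expect_lte(sum(m$det$tp), best_tp)
      # conservation
      expect_equal(sum(m$det$tp) + length(m$fn_gt), ng)
      expect_equal(nrow(m$det), nd)
    }
  })
})

worked_scenario <- function() {
  # 2 GT of one class; three detections: conf .9 TP, .8 FP, .7 TP
  gt <- dplyr::mutate(pixel_boxes(c(0L, 0L), c(0, 100), c(0, 0),
                                  c(10, 110), c(10, 10)), frame_id = "f")
  preds <- dplyr::mutate(
    detections(c(0L, 0L, 0L), c(0, 50, 100), c(0, 50, 0),
               c(10, 60, 110), c(10, 60, 10), c(0.9, 0.8, 0.7)),
    frame_id = "f")
  list(preds = preds, gt = gt)
}

test_that("AP matches hand-derivable values and the threshold-sweep oracle", {
  s <- worked_scenario()
  rep <- evaluate_detections(s$preds, s$gt)
  expect_equal(rep$ap$ap[1], 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-9)
  expect_equal(rep$ap$ap[1], ap_sweep_oracle(c(0.9, 0.8, 0.7),
                                             c(TRUE, FALSE, TRUE), 2),
               tolerance = 1e-6)

  # perfect detector -> AP 1, mAP 1
  perfect <- dplyr::mutate(s$gt, confidence = 0.99)
  rep_p <- evaluate_detections(perfect, s$gt)
  expect_equal(rep_p$ap$ap[1], 1)
  expect_equal(mean_ap(rep_p), 1)

  # no detections -> AP 0
  rep_0 <- evaluate_detections(s$preds[0, ], s$gt)
  expect_equal(rep_0$ap$ap[1], 0)

  # classes with zero GT are excluded from mAP
  other <- dplyr::mutate(detections(1L, 0, 0, 9, 9, 0.5), frame_id = "g")
  rep_m <- evaluate_detections(dplyr::bind_rows(perfect, other), s$gt)
  expect_equal(mean_ap(rep_m), 1)
  expect_true(is.na(rep_m$ap$ap[2]))
})

test_that("AP is invariant under strictly monotone confidence transforms", {
  withr::with_seed(33, {
    s <- worked_scenario()
    transforms <- list(function(c) c^3, function(c) 0.1 + 0.8 * c,
                       function(c) plogis(5 * c))
    base <- evaluate_detections(s$preds, s$gt)$ap$ap[1]
    for (tr in transforms) {
      p2 <- s$preds
      p2$confidence <- tr(p2$confidence)
      expect_equal(evaluate_detections(p2, s$gt)$ap$ap[1], base)
    }
  })
})

test_that("PR curves have non-decreasing recall and mAP averages per-class APs", {
  withr::with_seed(34, {
    gt <- dplyr::bind_rows(lapply(1:30, function(i) {
      dplyr::mutate(random_pixel_box(200, 200, 40,
                                     class_id = sample(0:2, 1)),
                    frame_id = sprintf("f%02d", i %% 10))
    }))
    preds <- dplyr::mutate(gt[sample(30, 22), ],
                           confidence = runif(22),
                           x0 = x0 + sample(-3:3, 22, TRUE))
    preds <- dplyr::bind_rows(preds, dplyr::mutate(
      random_pixel_box(200, 200, 30, class_id = 1L),
      frame_id = "f01", confidence = 0.5))
    rep <- evaluate_detections(preds, gt)
    for (curve in rep$pr) {
      if (nrow(curve)) {
        expect_true(all(diff(curve$recall) >= -1e-12))
        expect_true(all(curve$precision >= 0 & curve$precision <= 1))
      }
    }
    defined <- rep$ap$ap[!is.na(rep$ap$ap)]
    expect_equal(rep$map, mean(defined))
    # conservation per class: TP + FN = GT, TP + FP = detections
    expect_equal(rep$ap$tp + rep$ap$fn, rep$ap$n_gt)
    expect_equal(rep$ap$tp + rep$ap$fp, rep$ap$n_det)
  })
})

test_that("confusion matrix counts land in the right cells and conserve GT", {
  gt <- dplyr::mutate(pixel_boxes(c(0L, 1L), c(0, 100), c(0, 0),
                                  c(20, 120), c(20, 20)), frame_id = "f")
  # rhino predicted as giraffe; giraffe missed; one spurious human box
  preds <- dplyr::mutate(
    detections(c(1L, 4L), c(0, 60), c(0, 60), c(20, 70), c(20, 70),
               c(0.9, 0.8)), frame_id = "f")
  rep <- evaluate_detections(preds, gt)
  cm <- rep$confusion
  expect_equal(cm["rhino", "giraffe"], 1)
  expect_equal(cm["giraffe", "background"], 1)
  expect_equal(cm["background", "human"], 1)
  expect_equal(sum(cm), 3)
  # every GT appears exactly once in its true-class row
  expect_equal(unname(rowSums(cm)[c("rhino", "giraffe")]), c(1, 1))

  # silent detector: all GT in the background column
  rep_s <- evaluate_detections(preds[0, ], gt)
  expect_equal(unname(rep_s$confusion[, "background"][c("rhino", "giraffe")]),
               c(1, 1))
  # perfect detector: diagonal only
  rep_p <- evaluate_detections(dplyr::mutate(gt, confidence = 1), gt)
  expect_equal(sum(rep_p$confusion), sum(diag(rep_p$confusion)))

  # random scenarios: row sums over predictions equal per-class GT counts
  withr::with_seed(35, {
    for (rep_i in 1:10) {
      g <- dplyr::bind_rows(lapply(1:8, function(i) {
        dplyr::mutate(random_pixel_box(150, 150, 30,
                                       class_id = sample(0:4, 1)),
                      frame_id = sprintf("r%d", i %% 3)) }))
      p <- dplyr::mutate(g[sample(8, 5), ], confidence = runif(5, 0.3, 1),
                         class_id = sample(0:4, 5, TRUE))
      cm2 <- evaluate_detections(p, g)$confusion
      gt_counts <- tabulate(g$class_id + 1, 5)
      expect_equal(unname(rowSums(cm2)[1:5]), gt_counts)
    }
  })
})

test_that("tidy, glance and autoplot expose the report in standard forms", {
  s <- worked_scenario()
  rep <- evaluate_detections(s$preds, s$gt)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("class", "ap", "n_gt") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$map, rep$map)
  expect_s3_class(autoplot(rep, "pr"), "ggplot")
  expect_s3_class(autoplot(rep, "confusion", normalize = "row"), "ggplot")
})
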