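test_that("default grids match the enumerated survey-format layouts", {
  g <- compute_tile_grid(3840, 2160)
  expect_equal(sort(unique(g$ox)), c(0, 960, 1920, 2560))
  expect_equal(sort(unique(g$oy)), c(0, 880))
  expect_equal(nrow(g), 8)

  g <- compute_tile_grid(6000, 4000)
  expect_equal(sort(unique(g$ox)), c(0, 960, 1920, 2880, 3840, 4720))
  expect_equal(sort(unique(g$oy)), c(0, 960, 1920, 2720))
  expect_equal(nrow(g), 24)

  # 1,280 px is not "bigger than 1,280 px": pass-through
  g <- compute_tile_grid(1280, 720)
  expect_equal(nrow(g), 1)
  expect_equal(as.data.frame(g), data.frame(ox = 0L, oy = 0L,
                                            tw = 1280L, th = 720L))
  expect_equal(nrow(compute_tile_grid(1281, 720)), 2)
})

test_that("every pixel of the parent is covered by at least one tile", {
  spec <- tile_spec()
  withr::with_seed(21, {
    for (rep in 1:25) {
      W <- sample(1:7000, 1); H <- sample(1:7000, 1)
      g <- compute_tile_grid(W, H, spec)
      xs <- 0:(W - 1)
      covered_x <- Reduce(`|`, lapply(unique(g$ox), function(o) {
        xs >= o & xs < o + max(g$tw[g$ox == o])
      }))
      ys <- 0:(H - 1)
      covered_y <- Reduce(`|`, lapply(unique(g$oy), function(o) {
        ys >= o & ys < o + max(g$th[g$oy == o])
      }))
      expect_true(all(covered_x) && all(covered_y))
      # interior adjacent tiles overlap by exactly spec$overlap
      ox <- sort(unique(g$ox))
      if (length(ox) > 2) {
        expect_true(all(diff(head(ox, -1)) == spec$stride))
      }
    }
  })
})

test_that("retention decisions and clipped coordinates match the pixel oracle", {
  spec <- tile_spec(tile_size = 128, overlap = 32, tiling_threshold = 128)
  withr::with_seed(22, {
    for (rep in 1:60) {
      W <- sample(129:500, 1); H <- sample(129:500, 1)
      g <- compute_tile_grid(W, H, spec)
      pb <- dplyr::bind_rows(lapply(1:3, function(i) {
        random_pixel_box(W, H, max_side = 60, class_id = i - 1L)
      }))
      placed <- tile_boxes(pb, g, spec)
      for (ti in seq_len(nrow(g))) {
        for (bi in seq_len(nrow(pb))) {
          o <- retention_pixel_oracle(
            c(pb$x0[bi], pb$y0[bi], pb$x1[bi], pb$y1[bi]),
            g$ox[ti], g$oy[ti], g$tw[ti], g$th[ti])
          row <- placed[placed$tile == ti & placed$box == bi, ]
          if (o$ratio > spec$min_retention) {
            expect_equal(nrow(row), 1)
            expect_equal(row$retention, o$ratio)
            expect_equal(c(row$x0 + g$ox[ti], row$y0 + g$oy[ti],
                           row$x1 + g$ox[ti], row$y1 + g$oy[ti]), o$clip)
          } else {
            expect_equal(nrow(row), 0)
          }
        }
      }
    }
  })
})

test_that("a box exactly bisected by a tile edge is dropped (strict > 0.5)", {
  spec <- tile_spec(tile_size = 100, overlap = 20, tiling_threshold = 100)
  g <- compute_tile_grid(180, 100, spec)   # x origins 0, 80
  # box [70, 90): 10 px on tile 1's right edge region... construct exact halves:
  pb <- pixel_boxes(0L, 90, 40, 110, 60)   # [90,110) splits at x=100: half on tile 1
  placed <- tile_boxes(pb, g, spec)
  t1 <- placed[placed$tile == 1, ]
  expect_equal(nrow(t1), 0)                # exactly 0.5 on tile 1 -> dropped
  t2 <- placed[placed$tile == 2, ]         # tile at ox=80 holds it fully
  expect_equal(t2$retention, 1.0)
})

test_that("small boxes (both sides <= overlap) survive intact on some tile", {
  spec <- tile_spec()
  withr::with_seed(23, {
    for (rep in 1:40) {
      W <- sample(1281:6500, 1); H <- sample(1281:6500, 1)
      g <- compute_tile_grid(W, H, spec)
      pb <- random_pixel_box(W, H, max_side = spec$overlap)
      placed <- tile_boxes(pb, g, spec)
      expect_true(any(placed$retention == 1.0))
    }
  })
})

test_that("tile_image crops rasters and re-normalizes labels consistently", {
  spec <- tile_spec(tile_size = 64, overlap = 16, tiling_threshold = 64)
  withr::with_seed(24, {
    img <- array(runif(120 * 200 * 3), dim = c(120, 200, 3))
    pb <- pixel_boxes(c(1L, 3L), c(10, 150), c(20, 60), c(30, 190), c(40, 100))
    frame <- labeled_frame(image = img, frame_id = "p1",
                           boxes = from_pixel(pb, 200, 120))
    tiles <- tile_image(frame, spec)
    g <- compute_tile_grid(200, 120, spec)
    expect_length(tiles, nrow(g))
    for (ti in seq_along(tiles)) {
      tl <- tiles[[ti]]
      expect_identical(tl$image,
                       img[(g$oy[ti] + 1):(g$oy[ti] + g$th[ti]),
                           (g$ox[ti] + 1):(g$ox[ti] + g$tw[ti]), , drop = FALSE])
      expect_equal(tl$background, nrow(tl$boxes) == 0)
      if (nrow(tl$boxes)) {
        expect_true(all(tl$boxes$cx + tl$boxes$w / 2 <= 1 + 1e-9))
        expect_true(all(tl$retention > spec$min_retention))
      }
    }
    # determinism
    tiles2 <- tile_image(frame, spec)
    expect_identical(lapply(tiles, `[`, c("origin", "boxes")),
                     lapply(tiles2, `[`, c("origin", "boxes")))
  })
})

test_that("map_to_parent inverts tiling for uncut boxes and clips cut ones", {
  spec <- tile_spec(tile_size = 64, overlap = 16, tiling_threshold = 64)
  pb <- pixel_boxes(2L, 10, 10, 30, 30)     # inside the first tile
  frame <- labeled_frame(frame_id = "p", boxes = from_pixel(pb, 200, 120),
                         width = 200, height = 120)
  tiles <- tile_image(frame, spec)
  t1 <- tiles[[1]]
  expect_equal(as.data.frame(map_to_parent(t1)), as.data.frame(pb))

  # translation example on a 128 px tile
  spec2 <- tile_spec(tile_size = 128, overlap = 32, tiling_threshold = 100)
  t1 <- tile_image(labeled_frame(frame_id = "big", width = 400, height = 300,
                                 boxes = from_pixel(pb, 400, 300)),
                   spec2)[[1]]
  t1$origin <- c(ox = 960L, oy = 880L)
  got <- map_to_parent(t1, from_pixel(pixel_boxes(2L, 0, 0, 100, 100),
                                      t1$size[["tw"]], t1$size[["th"]]))
  expect_equal(as.data.frame(got),
               as.data.frame(pixel_boxes(2L, 960, 880, 1060, 980)))

  # a clipped box maps to intersection of original with the tile window
  pb2 <- pixel_boxes(0L, 40, 10, 80, 30)    # cut by tile 1's right edge (64)
  frame2 <- labeled_frame(frame_id = "p2", boxes = from_pixel(pb2, 200, 120),
                          width = 200, height = 120)
  tiles2 <- tile_image(frame2, spec)
  on_t1 <- tiles2[[1]]
  if (nrow(on_t1$boxes)) {
    back <- map_to_parent(on_t1)
    expect_equal(c(back$x0, back$y0, back$x1, back$y1),
                 c(max(40, 0), 10, min(80, 64), 30))
  }
  expect_error(tile_spec(overlap = 0), "overlap")
})
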