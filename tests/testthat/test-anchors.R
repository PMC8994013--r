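test_that("anchor counts follow the closed-form level sum", {
  cfg <- anchor_config()
  an <- generate_anchors(cfg, c(128L, 256L))
  expect_identical(nrow(an$boxes), 6138L)  # (512+128+32+8+2) * 9
  expect_true(all(an$boxes[, 3L] > an$boxes[, 1L]))
  expect_true(all(an$boxes[, 4L] > an$boxes[, 2L]))
  set.seed(31)
  for (k in 1:8) {
    hw <- c(sample(40:300, 1L), sample(40:300, 1L))
    an <- generate_anchors(cfg, hw)
    expect_identical(nrow(an$boxes),
                     as.integer(sum(ceiling(hw[1L] / cfg$strides) *
                                    ceiling(hw[2L] / cfg$strides)) * 9L))
  }
})

test_that("each location carries A anchors; the unit anchor is 32x32 at P3", {
  cfg <- anchor_config(aspect_ratios = 1, scale_multipliers = 1)
  an <- generate_anchors(cfg, c(64L, 128L))
  b <- an$boxes[an$level == 3L, ][1L, ]
  expect_equal(unname(b[3L] - b[1L]), 32)
  expect_equal(unname(b[4L] - b[2L]), 32)
  expect_equal(unname((b[1L] + b[3L]) / 2), 4)  # first cell centre, stride 8
  cfg9 <- anchor_config()
  an9 <- generate_anchors(cfg9, c(64L, 128L))
  n_loc <- sum(ceiling(64 / cfg9$strides) * ceiling(128 / cfg9$strides))
  expect_identical(nrow(an9$boxes), as.integer(9L * n_loc))
})

test_that("IoU matches a rasterised pixel-count oracle", {
  expect_equal(iou_matrix(c(0, 0, 10, 10), c(5, 0, 15, 10))[1L, 1L], 50 / 150)
  ## rasterised oracle on a 20x20 unit grid
  raster_iou <- function(a, b) {
    cells <- expand.grid(x = seq(0.5, 19.5), y = seq(0.5, 19.5))
    ina <- cells$x > a[1] & cells$x < a[3] & cells$y > a[2] & cells$y < a[4]
    inb <- cells$x > b[1] & cells$x < b[3] & cells$y > b[2] & cells$y < b[4]
    sum(ina & inb) / sum(ina | inb)
  }
  set.seed(5)
  for (k in 1:20) {
    a <- c(x1 = sample(0:10, 1), y1 = sample(0:10, 1))
    a <- c(a, a[1] + sample(1:9, 1), a[2] + sample(1:9, 1))
    b <- c(x1 = sample(0:10, 1), y1 = sample(0:10, 1))
    b <- c(b, b[1] + sample(1:9, 1), b[2] + sample(1:9, 1))
    expect_equal(iou_matrix(a, b)[1L, 1L], raster_iou(a, b))
  }
  expect_equal(iou_matrix(c(0, 0, 5, 5), c(0, 0, 5, 5))[1L, 1L], 1)
  expect_equal(iou_matrix(c(0, 0, 5, 5), c(6, 6, 9, 9))[1L, 1L], 0)
  expect_equal(iou_matrix(c(0, 0, 0, 5), c(0, 0, 5, 5))[1L, 1L], 0)
})

test_that("assignment follows the positive/ignore/background IoU bands", {
  cfg <- anchor_config()
  gt <- matrix(c(0, 0, 10, 10), 1L)
  ## anchors [0, y, 10, 10+y] have IoU (10-y)/(10+y) with the target
  y_for <- function(iou) 10 * (1 - iou) / (1 + iou)
  anchors <- rbind(c(0, y_for(0.55), 10, 10 + y_for(0.55)),
                   c(0, y_for(0.45), 10, 10 + y_for(0.45)),
                   c(0, y_for(0.30), 10, 10 + y_for(0.30)))
  asg <- assign_anchors(anchors, gt, cfg)
  expect_identical(asg$label, c("positive", "ignore", "background"))
  expect_identical(asg$gt_index, c(1L, NA_integer_, NA_integer_))
  expect_true(all(is.finite(asg$deltas[1L, ])))
  expect_true(all(is.na(asg$deltas[2:3, ])))
  ## no ground truth -> everything background
  asg0 <- assign_anchors(anchors, NULL, cfg)
  expect_true(all(asg0$label == "background"))
})

test_that("delta encoding is exact and inverts through decoding", {
  expect_equal(unname(encode_deltas(c(0, 0, 10, 10), c(0, 0, 10, 10),
                                    delta_norm = rep(1, 4))[1L, ]),
               rep(0, 4))
  d <- encode_deltas(c(0, 0, 10, 10), c(0, 0, 20, 10),
                     delta_norm = rep(1, 4))
  expect_equal(unname(d[1L, ]), c(0.5, 0, log(2), 0))
  set.seed(8)
  a <- cbind(runif(50, 0, 50), runif(50, 0, 50), 0, 0)
  a[, 3L] <- a[, 1L] + runif(50, 2, 40); a[, 4L] <- a[, 2L] + runif(50, 2, 40)
  g <- cbind(runif(50, 0, 50), runif(50, 0, 50), 0, 0)
  g[, 3L] <- g[, 1L] + runif(50, 2, 40); g[, 4L] <- g[, 2L] + runif(50, 2, 40)
  expect_equal(unname(decode_boxes(a, encode_deltas(a, g))), unname(g),
               tolerance = 1e-6)
  expect_equal(unname(decode_boxes(a, matrix(0, 50, 4))), unname(a))
  ## dw = log 2 doubles the width
  out <- decode_boxes(c(0, 0, 10, 10), c(0, 0, log(2), 0),
                      delta_norm = rep(1, 4))
  expect_equal(unname(out[1L, 3L] - out[1L, 1L]), 20)
  expect_error(encode_deltas(c(0, 0, 0, 10), c(0, 0, 10, 10)),
               "zero-extent")
})

test_that("boxes clip to the image and interior boxes are untouched", {
  shp <- c(128L, 256L)
  expect_equal(unname(clip_boxes(c(-5, -5, 10, 10), shp)[1L, ]),
               c(0, 0, 10, 10))
  expect_equal(unname(clip_boxes(c(30, 40, 50, 60), shp)[1L, ]),
               c(30, 40, 50, 60))
  out <- clip_boxes(c(300, 200, 400, 300), shp)
  expect_equal(unname(out[1L, ]), c(256, 128, 256, 128))  # zero-area remnant
})

test_that("detection filtering applies score threshold and greedy NMS", {
  cfg <- anchor_config()
  high_overlap <- rbind(c(0, 0, 10, 10), c(0, 3, 10, 13))  # IoU 0.538
  det <- filter_detections(high_overlap, c(0.9, 0.8), cfg)
  expect_identical(nrow(det$boxes), 1L)
  expect_equal(det$scores, 0.9)
  low_overlap <- rbind(c(0, 0, 10, 10), c(0, 8, 10, 18))   # IoU 0.111
  det <- filter_detections(low_overlap, c(0.8, 0.9), cfg)
  expect_identical(nrow(det$boxes), 2L)
  expect_equal(det$scores, c(0.9, 0.8))  # sorted by score
  det <- filter_detections(low_overlap, c(0.4, 0.4), cfg)
  expect_identical(nrow(det$boxes), 0L)
})
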