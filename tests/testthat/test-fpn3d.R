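test_that("cube IoU matches volume arithmetic", {
  a <- c(10, 10, 10, 10)
  expect_equal(iou_cube(a, a), 1)
  expect_equal(iou_cube(a, c(40, 40, 40, 10)), 0)
  # side-10 cubes offset 5 on one axis: 500 / 1500
  expect_equal(iou_cube(a, c(15, 10, 10, 10)), 1 / 3)
  # symmetry
  b <- c(12, 9, 11, 6)
  expect_equal(iou_cube(a, b), iou_cube(b, a))
})

test_that("anchor assignment follows the IoU thresholds", {
  cfg <- detector_config()
  anchors <- rbind(c(10, 10, 10, 10), c(50, 50, 50, 10), c(14.2, 10, 10, 10))
  none <- assign_anchors(anchors, matrix(0, 0, 4), cfg)
  expect_identical(none$label, rep(0L, 3))

  truth <- matrix(c(10, 10, 10, 10), 1, 4)
  asg <- assign_anchors(anchors, truth, cfg)
  expect_identical(asg$label[1], 1L)   # coincident, IoU 1 -> positive
  expect_identical(asg$label[2], 0L)   # disjoint -> negative
  # anchor 3: IoU = 580/1420 ~ 0.408 > 0.4 -> positive
  expect_identical(asg$label[3], 1L)
  mid <- assign_anchors(matrix(c(17, 10, 10, 10), 1, 4), truth, cfg)
  expect_true(is.na(mid$label[1]))     # IoU 300/1700 ~ 0.18 -> ignored
})

test_that("box encoding and decoding are exact inverses", {
  anchor <- c(20, 20, 20, 10)
  expect_equal(decode_boxes(anchor, c(0, 0, 0, 0)),
               matrix(anchor, 1, 4), ignore_attr = TRUE)
  doubled <- decode_boxes(anchor, c(0, 0, 0, log(2)))
  expect_equal(doubled[4], 20)
  set.seed(11)
  anchors <- cbind(runif(20, 10, 50), runif(20, 10, 50),
                   runif(20, 10, 50), sample(c(3, 5, 10, 15), 20, TRUE))
  truths <- anchors + cbind(matrix(rnorm(60, 0, 3), 20, 3),
                            runif(20, -1, 1))
  truths[, 4] <- abs(truths[, 4]) + 3
  rt <- decode_boxes(anchors, encode_boxes(anchors, truths))
  expect_equal(rt, truths, tolerance = 1e-9)
})

test_that("detection loss matches elementwise arithmetic", {
  cfg <- detector_config()
  anchors <- rbind(c(10, 10, 10, 10), c(40, 40, 40, 5))
  truths <- matrix(c(10, 10, 10, 10), 1, 4)
  asg <- assign_anchors(anchors, truths, cfg)
  # perfect prediction: probability 1 on the positive, 0 on the negative,
  # exact offsets
  perfect <- detection_loss(c(1, 0), matrix(0, 2, 4), asg, anchors, truths)
  expect_equal(unname(perfect["total"]), 0, tolerance = 1e-9)

  # hand-built: p = (0.8, 0.3), offsets off by (0.1 each dim on positive)
  off <- matrix(0, 2, 4)
  off[1, ] <- 0.1
  got <- detection_loss(c(0.8, 0.3), off, asg, anchors, truths)
  cls_hand <- -mean(c(log(0.8), log(1 - 0.3)))
  reg_hand <- mean(0.5 * 0.1^2 * rep(1, 4))
  expect_equal(unname(got["cls"]), cls_hand)
  expect_equal(unname(got["reg"]), reg_hand)
  expect_equal(unname(got["total"]), cls_hand + reg_hand)

  all_ignore <- list(label = rep(NA_integer_, 2),
                     truth_idx = rep(NA_integer_, 2), iou_max = c(0.2, 0.2))
  expect_warning(z <- detection_loss(c(0.5, 0.5), off, all_ignore, anchors,
                                     truths), "ignored")
  expect_equal(unname(z["total"]), 0)
})

test_that("pyramid stages have the contracted grids and channels", {
  cfg <- detector_config()  # 96^3 window, 64-channel pyramid
  set.seed(12)
  par <- pulmo3d:::fpn_par(cfg)
  x <- array(rnorm(96^3, 0, 0.1), dim = c(96, 96, 96))
  fw <- pulmo3d:::fpn_forward(x, par, cfg)
  expect_identical(dim(fw$bb$c1)[1:3], c(96L, 96L, 96L))
  expect_identical(dim(fw$bb$c2)[1:3], c(48L, 48L, 48L))
  expect_identical(dim(fw$bb$c3)[1:3], c(24L, 24L, 24L))
  expect_identical(dim(fw$bb$c4)[1:3], c(12L, 12L, 12L))
  expect_identical(dim(fw$bb$c5)[1:3], c(6L, 6L, 6L))
  for (L in 2:5) {
    P <- fw$plevels[[as.character(L)]]$P
    expect_identical(dim(P)[1:3], rep(96L %/% as.integer(2^(L - 1)), 3L))
    expect_identical(dim(P)[4], 64L)
  }
  # anchors land on their scale levels: {3,5}->P2, {10,15}->P3,
  # {20,25}->P4, {30}->P5
  expect_identical(pulmo3d:::anchor_level(cfg$anchor_sides),
                   c(2L, 2L, 3L, 3L, 4L, 4L, 5L))
})

test_that("sliding-window tiling covers the volume with stated offsets", {
  expect_identical(pulmo3d:::window_starts(160, 96, 32), c(0L, 64L))
  expect_identical(pulmo3d:::window_starts(64, 96, 32), 0L)
  expect_identical(pulmo3d:::window_starts(200, 96, 32), c(0L, 64L, 104L))
  # padded extraction of a short volume
  arr <- array(1, dim = c(4, 4, 4))
  w <- pulmo3d:::extract_window(arr, c(0L, 0L, 0L), 8)
  expect_identical(dim(w), c(8L, 8L, 8L))
  expect_equal(sum(w), 64)
})

test_that("NMS keeps a maximal low-overlap subset ordered by score", {
  one <- data.frame(seriesuid = "s", coordX = 0, coordY = 0, coordZ = 0,
                    diameter_mm = 10, score = 0.5, label = "unfiltered")
  expect_identical(nrow(nms3d(one, 0.1)), 1L)

  two <- rbind(one, one)
  two$score <- c(0.8, 0.9)
  kept <- nms3d(two, 0.1)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)

  # chain of boxes with pairwise IoU below threshold: all kept
  chain <- data.frame(seriesuid = "s", coordX = seq(0, 80, by = 8),
                      coordY = 0, coordZ = 0, diameter_mm = 10,
                      score = runif(11, 0.3, 0.9), label = "unfiltered")
  pair_iou <- iou_cube(c(0, 0, 0, 10), c(0, 0, 8, 10))
  expect_lt(pair_iou, 0.15)
  kept <- nms3d(chain, 0.15)
  expect_identical(nrow(kept), nrow(chain))
  expect_true(all(diff(kept$score) <= 0))

  set.seed(13)
  rnd <- data.frame(seriesuid = "s", coordX = runif(40, 0, 60),
                    coordY = runif(40, 0, 60), coordZ = runif(40, 0, 60),
                    diameter_mm = runif(40, 5, 15),
                    score = runif(40), label = "unfiltered")
  kept <- nms3d(rnd, 0.1)
  expect_true(all(diff(kept$score) <= 0))
  cubes <- cbind(kept$coordZ, kept$coordY, kept$coordX, kept$diameter_mm)
  for (i in seq_len(nrow(cubes) - 1))
    for (j in (i + 1):nrow(cubes))
      expect_lte(iou_cube(cubes[i, ], cubes[j, ]), 0.1)
})
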