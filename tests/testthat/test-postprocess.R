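test_that("IoU and DIoU match analytic and rasterized values", {
  a <- c(0, 0, 2, 2)
  b <- c(1, 1, 3, 3)
  expect_equal(iou(a, a), 1)
  expect_equal(diou(a, a), 1)
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(diou(a, b), 1 / 7 - 1 / 9)
  expect_equal(iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(iou(a, b), raster_iou(a, b), tolerance = 1e-2)
  # far-separated equal boxes drive DIoU toward -1
  expect_lt(diou(a, c(1000, 1000, 1002, 1002)), -0.99)
  expect_error(iou(c(0, 0, 0, 1), a), "degenerate")
})

test_that("IoU is vectorized and symmetric", {
  set.seed(10)
  d <- random_detections(30, 10)
  m <- as.matrix(d[, 1:4])
  ab <- iou(m[1:15, ], m[16:30, ])
  ba <- iou(m[16:30, ], m[1:15, ])
  expect_equal(ab, ba)
  expect_true(all(ab >= 0 & ab <= 1))
  dd <- diou(m[1:15, ], m[16:30, ])
  expect_true(all(dd > -1 & dd <= 1))
})

test_that("decode handles empty, single-peak and grid-offset cases", {
  mk <- function(g, nc = 2) array(-20, c(g, g, 5 + nc))
  # all objectness at -20 (sigmoid ~ 0): nothing decoded
  outs <- list(mk(8), mk(4), mk(2))
  expect_identical(nrow(decode_predictions(outs, c(8, 16, 32), 0.05)), 0L)
  # one peak at cell (3, 5) of the stride-8 map, zero offsets
  hm <- mk(8)
  hm[3, 5, 1:4] <- 0
  hm[3, 5, 5] <- 8
  hm[3, 5, 6] <- 8  # class 1 ("young")
  d <- decode_predictions(list(hm, mk(4), mk(2)), c(8, 16, 32), 0.05)
  expect_identical(nrow(d), 1L)
  # center (col-1+dx)*s = 32, (row-1+dy)*s = 16; w = h = exp(0)*8
  expect_equal(as.numeric(d[1, 1:4]), c(32 - 4, 16 - 4, 32 + 4, 16 + 4))
  expect_identical(d$class_id, 1L)
  expect_gt(d$score, 0.99)
})

test_that("soft DIoU-NMS keeps and decays boxes per the suppression rule", {
  cfg <- nms_config()
  one <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.8,
                    class_id = 1L)
  expect_equal(soft_diou_nms(one, cfg), one, ignore_attr = TRUE)
  # two distant boxes (DIoU < Nt): both untouched
  two <- rbind(one, data.frame(x1 = 30, y1 = 30, x2 = 40, y2 = 40,
                               score = 0.6, class_id = 1L))
  out <- soft_diou_nms(two, cfg)
  expect_equal(sort(out$score), sort(two$score))
  # heavy overlap: exact decay factor exp(-DIoU^2 / sigma)
  ov <- rbind(one, data.frame(x1 = 1, y1 = 1, x2 = 11, y2 = 11,
                              score = 0.7, class_id = 1L))
  d <- diou(c(0, 0, 10, 10), c(1, 1, 11, 11))
  out <- soft_diou_nms(ov, cfg)
  expect_equal(out$score, c(0.8, 0.7 * exp(-d^2 / cfg$sigma)))
  expect_identical(nrow(soft_diou_nms(one[0, ], cfg)), 0L)
})

test_that("soft DIoU-NMS agrees with the brute-force sequential oracle", {
  for (seed in 1:60) {
    n <- sample(1:10, 1)
    dets <- random_detections(n, seed, span = 25)
    out <- soft_diou_nms(dets, nms_config())
    or <- oracle_soft_diou(as.matrix(dets[, 1:4]), dets$score)
    expect_equal(nrow(out), length(or$idx))
    expect_equal(out$score, or$scores, tolerance = 1e-12)
    expect_equal(out$x1, dets$x1[or$idx])
    # scores never increase
    expect_true(all(out$score <= dets$score[or$idx] + 1e-15))
  }
})

test_that("the sigma -> 0 limit of soft suppression is hard DIoU-NMS", {
  for (seed in 1:20) {
    dets <- random_detections(8, seed + 300, span = 25)
    soft <- soft_diou_nms(dets, nms_config(sigma = 1e-9))
    hard <- hard_nms(dets, nms_config(method = "hard_diou"))
    expect_equal(sort(soft$x1), sort(hard$x1))
    expect_equal(sort(soft$score), sort(hard$score))
  }
})

test_that("suppression is order-independent and class-local", {
  dets <- random_detections(9, 77, classes = 2L, span = 20)
  cfg <- nms_config()
  out1 <- soft_diou_nms(dets, cfg)
  perm <- sample(nrow(dets))
  out2 <- soft_diou_nms(dets[perm, ], cfg)
  expect_equal(out1[order(out1$x1), ], out2[order(out2$x1), ],
               ignore_attr = TRUE)
  # identical geometry, different classes: no interaction
  dup <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                    y2 = c(10, 10), score = c(0.9, 0.8), class_id = 1:2)
  expect_identical(nrow(soft_diou_nms(dup, cfg)), 2L)
  expect_equal(soft_diou_nms(dup, cfg)$score, c(0.9, 0.8))
})

test_that("hard NMS removes duplicates and distinguishes IoU from DIoU", {
  dup <- data.frame(x1 = c(0, 0.5), y1 = c(0, 0.5), x2 = c(10, 10.5),
                    y2 = c(10, 10.5), score = c(0.9, 0.8), class_id = 1L)
  expect_identical(nrow(hard_nms(dup, nms_config(method = "hard_iou"))), 1L)
  expect_identical(nrow(hard_nms(dup[0, ], nms_config(method = "hard_iou"))), 0L)
  # offset centers: IoU >= Nt but DIoU < Nt, so only the IoU measure suppresses
  pair <- data.frame(x1 = c(0, 6), y1 = c(0, 0), x2 = c(20, 26),
                     y2 = c(4, 4), score = c(0.9, 0.8), class_id = 1L)
  i <- iou(c(0, 0, 20, 4), c(6, 0, 26, 4))
  d <- diou(c(0, 0, 20, 4), c(6, 0, 26, 4))
  cfgt <- nms_config(method = "hard_iou", threshold = (i + d) / 2)
  expect_identical(nrow(hard_nms(pair, cfgt)), 1L)
  cfgt$method <- "hard_diou"
  expect_identical(nrow(hard_nms(pair, cfgt)), 2L)
})

test_that("detection TSV round trips", {
  dets <- list(img1 = data.frame(x1 = 1.5, y1 = 2, x2 = 20, y2 = 30,
                                 score = 0.75, class_id = 2L))
  f <- tempfile(fileext = ".tsv")
  write_detections_tsv(dets, f)
  back <- read_detections_tsv(f)
  expect_equal(back$img1$score, 0.75)
  expect_equal(back$img1$class_id, 2L)
  expect_equal(back$img1$x1, 1.5)
})
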