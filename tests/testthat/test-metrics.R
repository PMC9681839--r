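# Detection and segmentation metrics, with independent brute-force oracles.

test_that("box IoU covers identity, disjoint, partial and degenerate cases", {
  a <- c(0, 0, 1, 1)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(2, 2, 3, 3)), 0)
  expect_equal(box_iou(a, c(0.5, 0, 1.5, 1)), 1 / 3)
  expect_error(box_iou(a, c(1, 0, 1, 2)), "degenerate")
})

test_that("hand-walked AP cases hold exactly", {
  gt1 <- data.frame(x_min = 0, y_min = 0, x_max = 4, y_max = 4)
  d1 <- cbind(gt1, class = 1, confidence = 0.9)
  expect_equal(average_precision(d1, gt1)$ap, 1)
  # two GTs, one TP (0.9) + one FP (0.8): precision (1, 0.5) at recall
  # (0.5, 0.5) -> AP = 0.5
  gts <- data.frame(x_min = c(0, 10), y_min = c(0, 10),
                    x_max = c(4, 14), y_max = c(4, 14))
  dets <- data.frame(x_min = c(0, 20), y_min = c(0, 20),
                     x_max = c(4, 24), y_max = c(4, 24),
                     confidence = c(0.9, 0.8))
  r <- average_precision(dets, gts)
  expect_equal(r$ap, 0.5)
  expect_equal(r$pr$precision, c(1, 0.5))
  expect_equal(r$pr$recall, c(0.5, 0.5))
  # a duplicate detection on one matched GT is a false positive
  dup <- data.frame(x_min = c(0, 0.1), y_min = c(0, 0.1),
                    x_max = c(4, 4.1), y_max = c(4, 4.1),
                    confidence = c(0.9, 0.8))
  r2 <- average_precision(dup, gt1)
  expect_equal(r2$pr$precision, c(1, 0.5))
  # no GT and no detections: undefined, excluded from mAP
  none <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     confidence = numeric(0))
  expect_true(is.na(average_precision(none, none[0, 1:4])$ap))
  expect_equal(mean_ap(c(0.4, NA, 0.6)), 0.5)
  expect_error(mean_ap(numeric(0)), "empty")
})

test_that("average_precision agrees with the brute-force evaluator", {
  set.seed(99)
  for (case in 1:200) {
    n_gt <- sample(0:4, 1)
    n_det <- sample(0:6, 1)
    gts <- if (n_gt > 0) rand_box(n_gt) else
      data.frame(x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0))
    dets <- if (n_det > 0) cbind(rand_box(n_det),
                                 confidence = runif(n_det)) else
      data.frame(x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0),
                 confidence = numeric(0))
    if (n_gt == 0 && n_det == 0) next
    ap <- average_precision(dets, gts)$ap
    bf <- if (n_det == 0) 0 else brute_force_ap(dets, gts)
    if (n_gt == 0) bf <- 0
    expect_equal(ap, bf, tolerance = 1e-12,
                 label = sprintf("case %d", case))
  }
})

test_that("AP is 1 exactly when every GT is matched before any FP", {
  set.seed(41)
  for (i in 1:20) {
    gts <- rand_box(3)
    dets <- cbind(gts, confidence = runif(3, 0.5, 1))
    fp <- cbind(rand_box(1, lim = 60) + 40, confidence = 0.1)
    ap <- average_precision(rbind(dets, fp), gts)$ap
    expect_equal(ap, 1)
  }
})

test_that("pixel scores reproduce hand confusion counts", {
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  pred <- matrix(c(1, 0, 0, 0), 2, 2)
  s <- pixel_scores(pred, gt)
  c1 <- s[s$class == 1, ]
  expect_equal(c1$precision, 1)
  expect_equal(c1$recall, 0.5)
  expect_equal(c1$f1, 2 / 3)
  c0 <- s[s$class == 0, ]
  expect_equal(c0$precision, 2 / 3)
  expect_equal(c0$recall, 1)
  expect_equal(c0$f1, 0.8)
  # classes absent from both sides score 1 with support 0
  expect_true(all(s$f1[s$class %in% 2:4] == 1))
  expect_true(all(s$support[s$class %in% 2:4] == 0))
  # perfect prediction
  expect_true(all(pixel_scores(gt, gt)$f1 == 1))
  # all-background prediction: recall and f1 collapse for class 1
  s2 <- pixel_scores(matrix(0L, 2, 2), gt)
  expect_equal(s2$recall[s2$class == 1], 0)
  expect_equal(s2$f1[s2$class == 1], 0)
  expect_error(pixel_scores(matrix(0L, 2, 3), gt), "shape")
})

test_that("per-class confusion counts partition the pixel grid", {
  set.seed(123)
  for (i in 1:20) {
    gt <- matrix(sample(0:4, 64, TRUE), 8, 8)
    pred <- matrix(sample(0:4, 64, TRUE), 8, 8)
    s <- pixel_scores(pred, gt)
    tp <- vapply(0:4, function(k) sum(pred == k & gt == k), numeric(1))
    fp <- vapply(0:4, function(k) sum(pred == k & gt != k), numeric(1))
    fn <- vapply(0:4, function(k) sum(pred != k & gt == k), numeric(1))
    expect_equal(sum(tp) + sum(fp), 64)
    expect_equal(s$support, as.integer(tp + fn))
  }
})

test_that("aggregation is mean plus population standard deviation", {
  v <- c(0.7581, 0.7543, 0.7301, 0.7196, 0.6696)
  a <- aggregate_scores(v)
  expect_equal(round(a$mean, 4), 0.7263)
  expect_equal(round(a$std, 3), 0.032)    # divide-by-n, not n-1
  expect_equal(aggregate_scores(rep(0.5, 4))$std, 0)
  expect_error(aggregate_scores(numeric(0)), "empty")
  # translation equivariance / invariance
  b <- aggregate_scores(v + 10)
  expect_equal(b$mean, a$mean + 10)
  expect_equal(b$std, a$std)
})

test_that("the 11-point interpolation alternative stays within bounds", {
  set.seed(7)
  for (i in 1:20) {
    gts <- rand_box(3)
    dets <- rbind(cbind(gts[1:2, ], confidence = c(0.9, 0.7)),
                  cbind(rand_box(2, 60) + 30, confidence = c(0.8, 0.6)))
    all_pt <- average_precision(dets, gts)$ap
    eleven <- average_precision(dets, gts,
                                interpolation = "eleven_point")$ap
    expect_gte(eleven, 0)
    expect_lte(abs(eleven - all_pt), 0.25)
  }
})
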