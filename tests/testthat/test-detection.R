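# Focal / smooth-L1 losses, NMS, anchor assignment, and the mAP-driven
# early-stopping harness.

test_that("focal loss matches its closed forms", {
  expect_lt(focal_value(1 - 1e-9, 1), 1e-6)
  expect_equal(focal_value(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.01 * (-log(0.9)), tolerance = 1e-7)
  expect_equal(focal_value(0.9, 1, alpha = 0.25, gamma = 2), 2.6341e-4,
               tolerance = 1e-3)
  # gamma = 0, alpha = 0.5 reduces to half the binary cross-entropy
  p <- c(0.2, 0.7)
  y <- c(1, 0)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_value(p, y, alpha = 0.5, gamma = 0), 0.5 * bce)
  expect_error(focal_value(0.5, 1, gamma = -1), "nonnegative")
  # nonnegative and decreasing in p for positives
  ps <- seq(0.05, 0.95, 0.1)
  fv <- vapply(ps, function(p) focal_value(p, 1), numeric(1))
  expect_true(all(fv >= 0))
  expect_true(all(diff(fv) < 0))
})

test_that("focal logit gradient matches finite differences", {
  gl <- picswbc:::focal_grad_logit
  for (y in c(0, 1)) {
    for (z in c(-2, -0.3, 0.8, 2.5)) {
      eps <- 1e-6
      f <- function(z) focal_value(1 / (1 + exp(-z)), y,
                                   alpha = 0.25, gamma = 1.5)
      num <- (f(z + eps) - f(z - eps)) / (2 * eps)
      expect_equal(gl(1 / (1 + exp(-z)), y, 0.25, 1.5), num,
                   tolerance = 1e-5)
    }
  }
})

test_that("smooth L1 has the right branches and is smooth at |r| = 1", {
  expect_equal(smooth_l1_value(0), 0)
  expect_equal(smooth_l1_value(0.5), 0.125)
  expect_equal(smooth_l1_value(2), 1.5)
  expect_equal(smooth_l1_value(c(0.5, 2)), mean(c(0.125, 1.5)))
  # continuity and matching one-sided slopes at the boundary
  eps <- 1e-8
  expect_equal(smooth_l1_value(1 - eps), smooth_l1_value(1 + eps),
               tolerance = 1e-7)
  expect_equal(smooth_l1_value(1), 0.5)
  slope_in <- (smooth_l1_value(1) - smooth_l1_value(1 - 1e-4)) / 1e-4
  slope_out <- (smooth_l1_value(1 + 1e-4) - smooth_l1_value(1)) / 1e-4
  expect_equal(slope_in, slope_out, tolerance = 1e-3)
})

test_that("class-wise NMS keeps the strongest of overlapping same-class boxes", {
  b <- data.frame(x_min = c(0, 0), y_min = c(0, 0), x_max = c(4, 4),
                  y_max = c(4, 4), class = c(1, 1),
                  confidence = c(0.9, 0.8))
  out <- nms_classwise(b, 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.9)
  # different classes are not suppressed against each other
  b$class <- c(1, 2)
  expect_equal(nrow(nms_classwise(b, 0.5)), 2L)
  # disjoint same-class boxes both survive
  b2 <- data.frame(x_min = c(0, 10), y_min = c(0, 10), x_max = c(4, 14),
                   y_max = c(4, 14), class = 1, confidence = c(0.9, 0.8))
  expect_equal(nrow(nms_classwise(b2, 0.5)), 2L)
})

test_that("anchor assignment produces consistent targets", {
  pk <- asNamespace("picswbc")
  anchors <- pk$anchor_grid(48, c(10, 16))
  expect_equal(nrow(anchors), 2 * 36)
  gt <- data.frame(x_min = 10, y_min = 10, x_max = 26, y_max = 26,
                   class = 3, confidence = 1)
  tg <- pk$assign_anchors(anchors, gt)
  pos <- which(!is.na(tg$cls) & tg$cls > 0)
  expect_gte(length(pos), 1L)
  expect_true(all(tg$cls[pos] == 3L))
  # decoded positive targets reproduce the GT box exactly
  for (k in pos) {
    a <- anchors[k, ]
    cx <- a$cx + tg$reg[k, 1] * a$w
    cy <- a$cy + tg$reg[k, 2] * a$h
    w <- a$w * exp(tg$reg[k, 3])
    h <- a$h * exp(tg$reg[k, 4])
    expect_equal(c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2),
                 c(10, 10, 26, 26), tolerance = 1e-9)
  }
  # empty ground truth: all background
  tg0 <- pk$assign_anchors(anchors, gt[0, ])
  expect_true(all(tg0$cls == 0L))
})

test_that("the early-stopping harness obeys the published patience rules", {
  # detection rule: patience 10 on validation mAP, highest-mAP snapshot
  seq_map <- c(0.2, 0.3, rep(0.3, 10))
  step <- function(e) list(params = list(epoch = e), train_loss = 1 / e)
  run <- training_run(50, 10, "max",
                      step, function(e, p) seq_map[e])
  expect_equal(nrow(run$log), 12L)             # stops after epoch 12
  expect_equal(run$best_epoch, 2L)
  expect_equal(run$best_params$epoch, 2L)
  expect_equal(run$best_metric, 0.3)
  # patience 1: five increases then one drop returns epoch 5
  seq2 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.45)
  run2 <- training_run(50, 1, "max", step, function(e, p) seq2[e])
  expect_equal(run2$best_epoch, 5L)
  expect_equal(nrow(run2$log), 6L)
  # harness property: returned snapshot's metric equals the log maximum
  expect_equal(run2$best_metric, max(run2$log$val_metric))
})

test_that("a short detector run satisfies the contract", {
  ds <- fixture_dataset()
  split <- list(train_ids = ds$splits$repeats[[1]]$train_ids[1:8],
                val_ids = ds$splits$repeats[[1]]$val_ids[1:2])
  cfg <- detector_config(input_size = 48, base_channels = 4,
                         anchor_sizes = c(10, 16), learning_rate = 1e-3,
                         batch_size = 4, max_epochs = 2,
                         patience_epochs = 2, seed = 17)
  det <- train_detector(ds, split, cfg)
  expect_s3_class(det, "wbc_detector")
  expect_equal(nrow(det$log), 2L)
  expect_equal(det$best_val_map, max(det$log$val_metric))
  img <- loader_brightfield(ds, split$val_ids[1])
  # threshold 1 excludes everything
  expect_equal(nrow(detect(det, img, score_threshold = 1)), 0L)
  d <- detect(det, img, score_threshold = 0)
  if (nrow(d) > 0) {
    expect_true(all(diff(d$confidence) <= 0))
    expect_true(all(d$class %in% 1:4))
    expect_true(all(d$x_min < d$x_max & d$y_min < d$y_max))
    expect_true(all(d$confidence >= 0 & d$confidence <= 1))
  }
  # determinism of the training log
  det2 <- train_detector(ds, split, cfg)
  expect_identical(det$log, det2$log)
})
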