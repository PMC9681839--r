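# WBC localisation and classification: a compact single-scale anchor-based
# detector trained with the compound focal + smooth-L1 loss, mAP-driven
# early stopping (patience on validation mAP, highest-mAP checkpoint kept).
# The detector is deliberately small — a few convolutions at stride 8 with
# per-anchor class logits and box offsets — and is an interface: any model
# with the same train/predict contract can stand in.

#' Focal loss
#'
#' For a positive target (`y = 1`): `-alpha (1-p)^gamma log p`; for a
#' negative (`y = 0`): `-(1-alpha) p^gamma log(1-p)`. Vector inputs are
#' averaged. Probabilities are clamped away from 0/1.
#'
#' @param p predicted probabilities.
#' @param y binary targets (0/1), recycled.
#' @param alpha class-balance weight (default 0.25).
#' @param gamma focusing exponent (default 1.5, the compact-detector
#'   family's default); must be `>= 0`.
#' @return scalar mean focal loss.
#' @export
focal_value <- function(p, y, alpha = 0.25, gamma = 1.5) {
  if (gamma < 0) stop("gamma must be nonnegative")
  p <- clamp_prob(p)
  mean(ifelse(y == 1,
              -alpha * (1 - p)^gamma * log(p),
              -(1 - alpha) * p^gamma * log(1 - p)))
}

# d(focal)/d(logit) with p = sigmoid(logit); used by the training step.
focal_grad_logit <- function(p, y, alpha, gamma) {
  p <- clamp_prob(p)
  ifelse(y == 1,
         alpha * (1 - p)^gamma * (gamma * p * log(p) - (1 - p)),
         (1 - alpha) * p^gamma * (p - gamma * (1 - p) * log(1 - p)))
}

#' Smooth L1 loss
#'
#' `0.5 r^2` for `|r| < 1`, `|r| - 0.5` otherwise; mean over residuals.
#' Continuous and differentiable at `|r| = 1` (value 0.5).
#'
#' @param r numeric residuals.
#' @return scalar mean smooth-L1 value.
#' @export
smooth_l1_value <- function(r) {
  if (length(r) == 0) return(0)
  mean(ifelse(abs(r) < 1, 0.5 * r * r, abs(r) - 0.5))
}

smooth_l1_grad <- function(r) ifelse(abs(r) < 1, r, sign(r))

#' Detector training configuration
#'
#' @param batch_size images per update (default 8).
#' @param learning_rate Adam learning rate (default 5e-5).
#' @param patience_epochs consecutive epochs without a validation-mAP
#'   increase tolerated before stopping (default 10).
#' @param max_epochs epoch budget.
#' @param input_size working resolution (multiple of 8); images and boxes
#'   are rescaled to it.
#' @param base_channels backbone width.
#' @param anchor_sizes anchor side lengths in working-resolution pixels.
#' @param alpha,gamma focal-loss parameters.
#' @param box_weight weight of the smooth-L1 term in the compound loss.
#' @param seed integer seed.
#' @return a `detector_config` list.
#' @export
detector_config <- function(batch_size = 8, learning_rate = 5e-5,
                            patience_epochs = 10, max_epochs = 60,
                            input_size = 64, base_channels = 8,
                            anchor_sizes = c(16, 32), alpha = 0.25,
                            gamma = 1.5, box_weight = 1, seed = 1) {
  stopifnot(patience_epochs >= 1, input_size %% 8 == 0, gamma >= 0)
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 patience_epochs = patience_epochs, max_epochs = max_epochs,
                 input_size = as.integer(input_size),
                 base_channels = base_channels, anchor_sizes = anchor_sizes,
                 alpha = alpha, gamma = gamma, box_weight = box_weight,
                 seed = seed),
            class = "detector_config")
}

N_WBC_CLASSES <- 4L
DET_STRIDE <- 8L

build_detector_net <- function(base, n_anchors) {
  out_ch <- n_anchors * (N_WBC_CLASSES + 4L)
  head <- nn_conv(2 * base, out_ch)
  # prior bias: start class probabilities near 0.1 so the rare positives
  # dominate the focal gradient from the first epochs
  for (a in seq_len(n_anchors)) {
    head$b[(a - 1) * (N_WBC_CLASSES + 4L) + seq_len(N_WBC_CLASSES)] <- -2.2
  }
  list(layers = list(
    b_c1 = nn_conv(3, base), b_n1 = nn_norm(base),
    b_c2 = nn_conv(base, 2 * base), b_n2 = nn_norm(2 * base),
    b_c3 = nn_conv(2 * base, 2 * base), b_n3 = nn_norm(2 * base),
    b_c4 = nn_conv(2 * base, 2 * base), b_n4 = nn_norm(2 * base),
    h_out = head),
    base = base, n_anchors = n_anchors)
}

det_forward <- function(tape, net, x_id) {
  L <- net$layers
  h <- op_act(tape, "relu", op_norm(tape, L$b_n1, "b_n1",
                                    op_conv(tape, L$b_c1, "b_c1", x_id)))
  h <- op_pool(tape, h)
  h <- op_act(tape, "relu", op_norm(tape, L$b_n2, "b_n2",
                                    op_conv(tape, L$b_c2, "b_c2", h)))
  h <- op_pool(tape, h)
  h <- op_act(tape, "relu", op_norm(tape, L$b_n3, "b_n3",
                                    op_conv(tape, L$b_c3, "b_c3", h)))
  h <- op_pool(tape, h)
  h <- op_act(tape, "relu", op_norm(tape, L$b_n4, "b_n4",
                                    op_conv(tape, L$b_c4, "b_c4", h)))
  op_conv(tape, L$h_out, "h_out", h)
}

# Anchor grid at the working resolution: data.frame of box corners plus
# centres/sizes, one row per (cell, size).
anchor_grid <- function(input_size, anchor_sizes) {
  g <- input_size %/% DET_STRIDE
  cells <- expand.grid(gy = seq_len(g) - 1L, gx = seq_len(g) - 1L)
  out <- do.call(rbind, lapply(anchor_sizes, function(s) {
    cx <- (cells$gx + 0.5) * DET_STRIDE
    cy <- (cells$gy + 0.5) * DET_STRIDE
    data.frame(cx = cx, cy = cy, w = s, h = s,
               x_min = cx - s / 2, y_min = cy - s / 2,
               x_max = cx + s / 2, y_max = cy + s / 2)
  }))
  out
}

# Assign ground-truth boxes (already at working resolution) to anchors.
# Returns per-anchor class targets (0 = background, NA = ignore) and
# regression targets for positives.
assign_anchors <- function(anchors, gt, pos_thr = 0.5, neg_thr = 0.4) {
  nA <- nrow(anchors)
  cls <- integer(nA)
  reg <- matrix(NA_real_, nA, 4)
  if (nrow(gt) == 0) return(list(cls = cls, reg = reg))
  iou <- iou_matrix(anchors, gt)
  best_gt <- max.col(iou)
  best_iou <- iou[cbind(seq_len(nA), best_gt)]
  cls[best_iou >= neg_thr & best_iou < pos_thr] <- NA_integer_
  pos <- best_iou >= pos_thr
  for (j in seq_len(nrow(gt))) {     # guarantee one positive per GT
    k <- which.max(iou[, j])
    if (iou[k, j] > 0) { pos[k] <- TRUE; best_gt[k] <- j }
  }
  cls[pos] <- gt$class[best_gt[pos]]
  for (k in which(pos)) {
    g <- gt[best_gt[k], ]
    gw <- g$x_max - g$x_min; gh <- g$y_max - g$y_min
    reg[k, ] <- c(((g$x_min + g$x_max) / 2 - anchors$cx[k]) / anchors$w[k],
                  ((g$y_min + g$y_max) / 2 - anchors$cy[k]) / anchors$h[k],
                  log(gw / anchors$w[k]), log(gh / anchors$h[k]))
  }
  list(cls = cls, reg = reg)
}

# Head output array (g, g, A*(K+4)) -> list of per-anchor class logits
# (nA x K) and box offsets (nA x 4), matching anchor_grid row order.
split_head <- function(out, n_anchors) {
  g <- dim(out)[1]
  K <- N_WBC_CLASSES
  cls <- matrix(0, g * g * n_anchors, K)
  reg <- matrix(0, g * g * n_anchors, 4)
  for (a in seq_len(n_anchors)) {
    rows <- (a - 1) * g * g + seq_len(g * g)
    base <- (a - 1) * (K + 4)
    for (k in seq_len(K)) cls[rows, k] <- as.vector(out[, , base + k])
    for (k in seq_len(4)) reg[rows, k] <- as.vector(out[, , base + K + k])
  }
  list(cls = cls, reg = reg)
}

# Inverse of split_head for gradients.
merge_head_grad <- function(dcls, dreg, g, n_anchors) {
  K <- N_WBC_CLASSES
  out <- array(0, c(g, g, n_anchors * (K + 4)))
  for (a in seq_len(n_anchors)) {
    rows <- (a - 1) * g * g + seq_len(g * g)
    base <- (a - 1) * (K + 4)
    for (k in seq_len(K)) out[, , base + k] <- matrix(dcls[rows, k], g, g)
    for (k in seq_len(4)) out[, , base + K + k] <- matrix(dreg[rows, k], g, g)
  }
  out
}

# Compound loss; both terms are normalised by the number of positive
# anchors (the anchor-detector convention), so the rare foreground targets
# are not washed out by the background anchors.
det_loss_and_grad <- function(head, targets, config) {
  cls_t <- targets$cls
  keep <- !is.na(cls_t)
  p <- 1 / (1 + exp(-head$cls))
  y <- matrix(0, nrow(p), ncol(p))
  pos <- which(!is.na(cls_t) & cls_t > 0)
  y[cbind(pos, cls_t[pos])] <- 1
  n_pos <- max(1, length(pos))
  pk <- p[keep, , drop = FALSE]
  yk <- y[keep, , drop = FALSE]
  loss_f <- focal_value(pk, yk, config$alpha, config$gamma) *
    length(pk) / n_pos
  dcls <- matrix(0, nrow(p), ncol(p))
  dcls[keep, ] <- focal_grad_logit(pk, yk, config$alpha, config$gamma) /
    n_pos
  dreg <- matrix(0, nrow(p), 4)
  loss_r <- 0
  if (length(pos) > 0) {
    r <- head$reg[pos, , drop = FALSE] - targets$reg[pos, , drop = FALSE]
    loss_r <- smooth_l1_value(r) * length(r) / n_pos
    dreg[pos, ] <- config$box_weight * smooth_l1_grad(r) / n_pos
  }
  list(loss = loss_f + config$box_weight * loss_r,
       dcls = dcls, dreg = dreg)
}

#' Train the WBC detector
#'
#' Minimises the compound focal (classification) + smooth-L1 (box
#' regression) loss with Adam. After every epoch the validation mAP is
#' computed; training stops when it has not increased for
#' `patience_epochs` consecutive epochs and the weights with the highest
#' validation mAP are returned.
#'
#' @param dataset a `smear_dataset`.
#' @param split list with `train_ids` and `val_ids`.
#' @param config a [detector_config()].
#' @param loader function(dataset, id) returning the `(H, W, 3)` input
#'   image in `[0, 1]`; defaults to the brightfield rendering.
#' @return a `wbc_detector` with weights, anchors, config and the epoch log.
#' @export
train_detector <- function(dataset, split, config = detector_config(),
                           loader = loader_brightfield) {
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop("empty train or validation set")
  }
  set.seed(config$seed)
  S <- config$input_size
  anchors <- anchor_grid(S, config$anchor_sizes)
  nA <- length(config$anchor_sizes)
  all_ids <- c(split$train_ids, split$val_ids)
  data <- lapply(all_ids, function(i) {
    img <- loader(dataset, i)
    sc <- S / dim(img)[1:2]
    gt <- ds_boxes(dataset, i)
    if (nrow(gt) > 0) {
      gt$x_min <- gt$x_min * sc[2]; gt$x_max <- gt$x_max * sc[2]
      gt$y_min <- gt$y_min * sc[1]; gt$y_max <- gt$y_max * sc[1]
    }
    list(x = resize_array(img, S, S), gt = gt,
         targets = assign_anchors(anchors, gt), size = dim(img)[1:2])
  })
  names(data) <- as.character(all_ids)
  if (sum(vapply(split$train_ids, function(i)
    nrow(data[[as.character(i)]]$gt), numeric(1))) == 0) {
    stop("no annotated WBCs in the training set")
  }
  net <- build_detector_net(config$base_channels, nA)
  state <- adam_init(net_params(net))
  g <- S %/% DET_STRIDE

  step_fn <- function(epoch) {
    losses <- c()
    for (batch in batch_schedule(split$train_ids, config$batch_size)) {
      acc <- NULL
      bloss <- 0
      for (i in batch) {
        d <- data[[as.character(i)]]
        t <- nn_tape()
        out_id <- det_forward(t, net, tp_input(t, d$x))
        head <- split_head(tp_val(t, out_id), nA)
        lg <- det_loss_and_grad(head, d$targets, config)
        bloss <- bloss + lg$loss
        gr <- tp_backward(t, list(list(
          id = out_id, grad = merge_head_grad(lg$dcls, lg$dreg, g, nA))))
        acc <- if (is.null(acc)) gr$params else
          Map(function(a, b) Map(`+`, a, b), acc, gr$params)
      }
      acc <- lapply(acc, function(ps) lapply(ps, function(a) a / length(batch)))
      up <- adam_step(net_params(net), acc, state, config$learning_rate)
      net <<- net_set_params(net, up$params)
      state <<- up$state
      losses <- c(losses, bloss / length(batch))
    }
    list(params = net_params(net), train_loss = mean(losses))
  }

  eval_fn <- function(epoch, params) {
    model <- structure(list(net = net, anchors = anchors, config = config),
                       class = "wbc_detector")
    val_map(model, dataset, split$val_ids, data)
  }

  run <- training_run(config$max_epochs, config$patience_epochs, "max",
                      step_fn, eval_fn)
  net <- net_set_params(net, run$best_params)
  structure(list(net = net, anchors = anchors, config = config,
                 log = run$log, best_epoch = run$best_epoch,
                 best_val_map = run$best_metric),
            class = "wbc_detector")
}

# Validation mAP: detections are collected at a low score cut (0.05) so
# the PR curve, not the operating threshold, determines the metric.
val_map <- function(model, dataset, ids, data) {
  dets <- list(); gts <- list()
  for (i in ids) {
    d <- data[[as.character(i)]]
    det <- detect_on_array(model, d$x, d$size, score_threshold = 0.05)
    det$image_id <- rep(i, nrow(det))
    gt <- ds_boxes(dataset, i)
    gt$image_id <- rep(i, nrow(gt))
    dets[[length(dets) + 1]] <- det
    gts[[length(gts) + 1]] <- gt
  }
  dets <- do.call(rbind, dets)
  gts <- do.call(rbind, gts)
  if (is.null(dets) || nrow(dets) == 0) return(0)
  evaluate_detections(dets, gts)$map
}

#' @export
print.wbc_detector <- function(x, ...) {
  cat(sprintf(
    "wbc_detector: %d anchors/cell at stride %d, best val mAP %.3f (epoch %d/%d)\n",
    length(x$config$anchor_sizes), DET_STRIDE, x$best_val_map,
    x$best_epoch, nrow(x$log)))
  invisible(x)
}

# Decode + NMS on an already-resized input array; returns boxes at the
# original image scale `orig_size`.
detect_on_array <- function(model, x, orig_size, score_threshold = 0.5,
                            nms_iou = 0.5) {
  S <- model$config$input_size
  t <- nn_tape()
  out <- tp_val(t, det_forward(t, model$net, tp_input(t, x)))
  head <- split_head(out, length(model$config$anchor_sizes))
  p <- 1 / (1 + exp(-head$cls))
  cls <- max.col(p)
  score <- p[cbind(seq_len(nrow(p)), cls)]
  keep <- which(score >= score_threshold)
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = integer(0), confidence = numeric(0))
  if (length(keep) == 0) return(empty)
  a <- model$anchors[keep, , drop = FALSE]
  tr <- head$reg[keep, , drop = FALSE]
  cx <- a$cx + tr[, 1] * a$w
  cy <- a$cy + tr[, 2] * a$h
  w <- a$w * exp(pmin(tr[, 3], 4))
  h <- a$h * exp(pmin(tr[, 4], 4))
  boxes <- data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
                      x_max = cx + w / 2, y_max = cy + h / 2,
                      class = cls[keep], confidence = score[keep])
  boxes$x_min <- pmax(boxes$x_min, 0); boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, S); boxes$y_max <- pmin(boxes$y_max, S)
  boxes <- boxes[boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min, ,
                 drop = FALSE]
  boxes <- nms_classwise(boxes, nms_iou)
  sc <- orig_size / S
  boxes$x_min <- boxes$x_min * sc[2]; boxes$x_max <- boxes$x_max * sc[2]
  boxes$y_min <- boxes$y_min * sc[1]; boxes$y_max <- boxes$y_max * sc[1]
  rownames(boxes) <- NULL
  boxes
}

#' Class-wise greedy non-maximum suppression
#'
#' @param boxes data.frame with box corners, `class` and `confidence`.
#' @param nms_iou IoU threshold above which a lower-confidence box of the
#'   same class is suppressed.
#' @return filtered data.frame, sorted by confidence descending.
#' @export
nms_classwise <- function(boxes, nms_iou = 0.5) {
  if (nrow(boxes) == 0) return(boxes)
  keep <- logical(nrow(boxes))
  ord <- order(-boxes$confidence)
  x0 <- boxes$x_min; y0 <- boxes$y_min
  x1 <- boxes$x_max; y1 <- boxes$y_max
  area <- (x1 - x0) * (y1 - y0)
  for (k in unique(boxes$class)) {
    idx <- ord[boxes$class[ord] == k]
    while (length(idx) > 0) {
      i <- idx[1]
      keep[i] <- TRUE
      idx <- idx[-1]
      if (length(idx) > 0) {
        iw <- pmax(pmin(x1[i], x1[idx]) - pmax(x0[i], x0[idx]), 0)
        ih <- pmax(pmin(y1[i], y1[idx]) - pmax(y0[i], y0[idx]), 0)
        inter <- iw * ih
        idx <- idx[inter / (area[i] + area[idx] - inter) <= nms_iou]
      }
    }
  }
  out <- boxes[keep, , drop = FALSE]
  out[order(-out$confidence), , drop = FALSE]
}

#' Run the detector on an image
#'
#' @param model a trained `wbc_detector`.
#' @param image `(H, W, 3)` array in `[0, 1]` (or an `H x W` matrix,
#'   replicated to 3 channels).
#' @param score_threshold minimum class confidence (default 0.5).
#' @param nms_iou class-wise NMS threshold (default 0.5).
#' @return data.frame of detections (`x_min, y_min, x_max, y_max, class,
#'   confidence`), confidence-descending, box coordinates at the input
#'   image's scale.
#' @export
detect <- function(model, image, score_threshold = 0.5, nms_iou = 0.5) {
  image <- as_3ch(image)
  S <- model$config$input_size
  x <- resize_array(image, S, S)
  detect_on_array(model, x, dim(image)[1:2], score_threshold, nms_iou)
}

## Input loaders shared by detector/segmenter training.

#' @rdname train_detector
#' @export
loader_brightfield <- function(dataset, id) ds_load_brightfield(dataset, id)

#' Phase-input loader factory
#'
#' Builds a loader feeding the reconstructed SLIM phase (percentile-scaled,
#' replicated to three channels) to the detector or segmenter.
#'
#' @param dataset a `smear_dataset`.
#' @param stat_ids ids whose phase values define the 1st-99th percentile
#'   scaling.
#' @return function(dataset, id) -> `(H, W, 3)` array.
#' @export
make_slim_loader <- function(dataset, stat_ids) {
  stats <- phase_norm_stats(lapply(stat_ids, function(i)
    reconstruct_phase(ds_load_stack(dataset, i))$delta_phi))
  function(ds, i) {
    phi <- reconstruct_phase(ds_load_stack(ds, i))$delta_phi
    as_3ch(normalize_phase(phi, stats))
  }
}

#' Translated-input loader factory
#'
#' @param translator a trained `wbc_translator`.
#' @return function(dataset, id) -> translated `(H, W, 3)` array.
#' @export
make_translated_loader <- function(translator) {
  function(ds, i) {
    phi <- reconstruct_phase(ds_load_stack(ds, i))$delta_phi
    predict(translator, phi)
  }
}
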