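# Evaluation stack: box IoU, per-class average precision / mAP for
# detection, pixel-wise per-class precision/recall/F1 for semantic maps,
# and the mean +/- population-std aggregation used for multi-test summary
# rows.

#' Intersection-over-union of two axis-aligned boxes
#'
#' Boxes are `(x_min, y_min, x_max, y_max)`, 0-based, half-open.
#'
#' @param a,b numeric length-4 vectors.
#' @return IoU in `[0, 1]`; disjoint boxes give 0.
#' @export
box_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4]) {
    stop("degenerate box (x_min >= x_max or y_min >= y_max)")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  inter / union
}

# Vectorised IoU matrix between detection and ground-truth data.frames.
iou_matrix <- function(dets, gts) {
  iw <- pmin(outer(dets$x_max, gts$x_max, pmin) -
               outer(dets$x_min, gts$x_min, pmax), Inf)
  ih <- pmin(outer(dets$y_max, gts$y_max, pmin) -
               outer(dets$y_min, gts$y_min, pmax), Inf)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_d <- (dets$x_max - dets$x_min) * (dets$y_max - dets$y_min)
  area_g <- (gts$x_max - gts$x_min) * (gts$y_max - gts$y_min)
  inter / (outer(area_d, area_g, `+`) - inter)
}

#' Average precision for one class
#'
#' Detections (one class) are sorted by confidence descending and greedily
#' matched to the unmatched ground-truth box of highest IoU at or above
#' `iou_thr`; each ground truth can be matched once, duplicates count as
#' false positives. AP is the area under the precision-recall curve:
#' all-point interpolation (area under the stepwise precision envelope,
#' default) or the 11-point alternative.
#'
#' Detections and ground truths are data.frames with columns
#' `x_min, y_min, x_max, y_max` (and `confidence` for detections);
#' detections may come from several images, in which case both must carry
#' an `image_id` column and matching is per image.
#'
#' @param dets detections of a single class.
#' @param gts ground-truth boxes of the same class.
#' @param iou_thr IoU threshold for a true positive (default 0.5).
#' @param interpolation `"all_point"` or `"eleven_point"`.
#' @return list with `ap` (`NA` if there is no ground truth and no
#'   detection), and `pr` (a `pr_curve` data.frame: confidence, cumulative
#'   precision and recall).
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5,
                              interpolation = c("all_point",
                                                "eleven_point")) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(gts)
  if (n_gt == 0 && nrow(dets) == 0) {
    return(list(ap = NA_real_, pr = NULL))
  }
  if (nrow(dets) == 0) {
    return(list(ap = 0, pr = data.frame(confidence = numeric(0),
                                        precision = numeric(0),
                                        recall = numeric(0))))
  }
  if (is.null(dets$image_id)) dets$image_id <- 1L
  if (n_gt > 0 && is.null(gts$image_id)) gts$image_id <- 1L
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_used <- logical(n_gt)
  for (i in seq_len(nrow(dets))) {
    if (n_gt == 0) break
    cand <- which(gts$image_id == dets$image_id[i] & !gt_used)
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j) {
      box_iou(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
              as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_thr) {
      tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- if (n_gt > 0) cum_tp / n_gt else rep(0, length(tp))
  pr <- data.frame(confidence = dets$confidence, precision = prec,
                   recall = rec)
  if (n_gt == 0) return(list(ap = 0, pr = pr))
  ap <- if (interpolation == "all_point") {
    mrec <- c(0, rec, 1)
    mpre <- c(0, prec, 0)
    for (i in rev(seq_len(length(mpre) - 1))) {
      mpre[i] <- max(mpre[i], mpre[i + 1])
    }
    idx <- which(mrec[-1] != mrec[-length(mrec)])
    sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
  } else {
    mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p) == 0) 0 else max(p)
    }, numeric(1)))
  }
  list(ap = ap, pr = pr)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of the per-class APs; classes with undefined AP (`NA`,
#' i.e. absent from both ground truth and detections) are excluded.
#'
#' @param per_class_aps numeric vector of per-class APs.
#' @return scalar mAP.
#' @export
mean_ap <- function(per_class_aps) {
  if (length(per_class_aps) == 0) stop("empty AP list")
  v <- per_class_aps[!is.na(per_class_aps)]
  if (length(v) == 0) stop("all APs undefined")
  mean(v)
}

#' Detection mAP of a prediction set against ground truth
#'
#' Convenience wrapper: splits detections and ground truths by class,
#' computes per-class [average_precision()] and the mean.
#'
#' @param dets detection data.frame with a `class` column.
#' @param gts ground-truth data.frame with a `class` column.
#' @param iou_thr IoU threshold.
#' @param n_classes number of classes (default 4).
#' @return list with `map`, `per_class` APs and `pr` curves per class.
#' @export
evaluate_detections <- function(dets, gts, iou_thr = 0.5, n_classes = 4L) {
  per <- lapply(seq_len(n_classes), function(k) {
    average_precision(dets[dets$class == k, , drop = FALSE],
                      gts[gts$class == k, , drop = FALSE], iou_thr)
  })
  aps <- vapply(per, function(p) p$ap, numeric(1))
  list(map = mean_ap(aps), per_class = aps,
       pr = lapply(per, function(p) p$pr))
}

#' Pixel-wise per-class precision, recall and F1
#'
#' Scores every class in `0..n_classes` (background included) between a
#' predicted and a ground-truth semantic map. Classes absent from both maps
#' score 1 with support 0.
#'
#' @param pred,gt integer label matrices of the same shape.
#' @param n_classes number of foreground classes (default 4).
#' @return data.frame with columns `class, precision, recall, f1, support`.
#' @export
pixel_scores <- function(pred, gt, n_classes = 4L) {
  if (!all(dim(pred) == dim(gt))) {
    stop("shape mismatch between prediction and ground truth")
  }
  res <- lapply(0:n_classes, function(k) {
    tp <- sum(pred == k & gt == k)
    fp <- sum(pred == k & gt != k)
    fn <- sum(pred != k & gt == k)
    support <- tp + fn
    if (support == 0 && fp == 0) {
      return(data.frame(class = k, precision = 1, recall = 1, f1 = 1,
                        support = 0L))
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = k, precision = p, recall = r, f1 = f1,
               support = as.integer(support))
  })
  do.call(rbind, res)
}

#' Macro-averaged pixel F1
#'
#' Mean F1 over background plus the four WBC classes, restricted to classes
#' present in the ground truth of the evaluation set.
#'
#' @param scores output of [pixel_scores()] (possibly pooled over images).
#' @return scalar macro F1.
#' @export
macro_f1 <- function(scores) {
  keep <- scores$support > 0 | scores$class == 0
  mean(scores$f1[keep])
}

# Pool pixel scores over a list of (pred, gt) pairs by summing confusion
# counts, then rescore.
pooled_pixel_scores <- function(preds, gts, n_classes = 4L) {
  tp <- fp <- fn <- numeric(n_classes + 1)
  for (i in seq_along(preds)) {
    for (k in 0:n_classes) {
      tp[k + 1] <- tp[k + 1] + sum(preds[[i]] == k & gts[[i]] == k)
      fp[k + 1] <- fp[k + 1] + sum(preds[[i]] == k & gts[[i]] != k)
      fn[k + 1] <- fn[k + 1] + sum(preds[[i]] != k & gts[[i]] == k)
    }
  }
  res <- lapply(0:n_classes, function(k) {
    i <- k + 1
    support <- tp[i] + fn[i]
    if (support == 0 && fp[i] == 0) {
      return(data.frame(class = k, precision = 1, recall = 1, f1 = 1,
                        support = 0L))
    }
    p <- if (tp[i] + fp[i] > 0) tp[i] / (tp[i] + fp[i]) else 0
    r <- if (support > 0) tp[i] / support else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = k, precision = p, recall = r, f1 = f1,
               support = as.integer(support))
  })
  do.call(rbind, res)
}

#' Mean and population standard deviation
#'
#' The aggregation used for summary rows over repeated tests: arithmetic
#' mean and the divide-by-n (population) standard deviation.
#'
#' @param values nonempty numeric vector.
#' @return list with `mean` and `std`.
#' @export
aggregate_scores <- function(values) {
  if (length(values) == 0) stop("empty value list")
  m <- mean(values)
  list(mean = m, std = sqrt(mean((values - m)^2)))
}
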