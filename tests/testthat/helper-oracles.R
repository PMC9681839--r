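# Independent brute-force oracles shared by the metric and fusion tests.
# They deliberately share no code with the package implementations.

# AP by explicit confusion counting at every confidence cut, then the
# all-point interpolated area.
brute_force_ap <- function(dets, gts, iou_thr = 0.5) {
  if (is.null(dets$image_id)) dets$image_id <- 1L
  if (nrow(gts) > 0 && is.null(gts$image_id)) gts$image_id <- 1L
  iou <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    i <- iw * ih
    i / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - i)
  }
  cuts <- sort(unique(dets$confidence), decreasing = TRUE)
  prec <- rec <- numeric(0)
  for (cut in cuts) {
    kept <- dets[dets$confidence >= cut, , drop = FALSE]
    kept <- kept[order(-kept$confidence), , drop = FALSE]
    used <- rep(FALSE, nrow(gts))
    tp <- 0
    for (i in seq_len(nrow(kept))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(gts))) {
        if (used[j] || gts$image_id[j] != kept$image_id[i]) next
        v <- iou(as.numeric(kept[i, 1:4]), as.numeric(gts[j, 1:4]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= iou_thr) { tp <- tp + 1; used[bj] <- TRUE }
    }
    prec <- c(prec, tp / nrow(kept))
    rec <- c(rec, if (nrow(gts) > 0) tp / nrow(gts) else 0)
  }
  if (nrow(gts) == 0) return(0)
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1))) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

rand_box <- function(n = 1, lim = 16) {
  x0 <- runif(n, 0, lim - 2); y0 <- runif(n, 0, lim - 2)
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + runif(n, 1, lim / 2),
             y_max = y0 + runif(n, 1, lim / 2))
}

# Per-pixel fusion oracle: loops over pixels and boxes.
fuse_oracle <- function(mask, dets) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (mask[r, c] == 0) next
      x <- c - 1; y <- r - 1
      best_conf <- -Inf; best_cls <- 0L
      for (j in seq_len(nrow(dets))) {
        d <- dets[j, ]
        if (x >= d$x_min && x < d$x_max && y >= d$y_min && y < d$y_max) {
          if (d$confidence > best_conf ||
              (d$confidence == best_conf && d$class < best_cls)) {
            best_conf <- d$confidence
            best_cls <- as.integer(d$class)
          }
        }
      }
      if (is.finite(best_conf)) out[r, c] <- best_cls
    }
  }
  out
}

rand_fusion_case <- function(size = 16) {
  mask <- matrix(rbinom(size * size, 1, 0.4), size, size)
  nb <- sample(0:4, 1)
  dets <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     class = integer(0), confidence = numeric(0))
  if (nb > 0) {
    x0 <- runif(nb, 0, size - 3); y0 <- runif(nb, 0, size - 3)
    dets <- data.frame(
      x_min = floor(x0), y_min = floor(y0),
      x_max = floor(x0) + sample(2:8, nb, TRUE),
      y_max = floor(y0) + sample(2:8, nb, TRUE),
      class = sample(1:4, nb, TRUE),
      # coarse confidences so exact ties actually occur
      confidence = sample(c(0.3, 0.6, 0.6, 0.9), nb, TRUE))
  }
  list(mask = mask, dets = dets)
}
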