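# Semantic-map generation: pixel-wise combination of detector boxes with
# the binary WBC mask, then pixel-wise majority voting across the model
# ensemble. Label legend (fixed): 0 background, 1 neutrophil,
# 2 eosinophil, 3 lymphocyte, 4 monocyte.

#' Fuse a binary WBC mask with classified boxes into a semantic map
#'
#' Per pixel: outside the mask, background; inside the mask and inside
#' exactly one box, that box's class; inside two or more boxes, the class
#' of the covering box with the highest confidence (exact ties: smallest
#' class label); inside the mask but no box, background. Box membership is
#' half-open (`x_min <= x < x_max`) in 0-based pixel coordinates. Boxes
#' extending beyond the image are clipped with a warning.
#'
#' @param binary_mask integer/logical `H x W` matrix, 1 = WBC pixel.
#' @param detections data.frame with columns
#'   `x_min, y_min, x_max, y_max, class, confidence`.
#' @return integer `H x W` semantic map over `{0..4}`.
#' @export
fuse <- function(binary_mask, detections) {
  H <- nrow(binary_mask); W <- ncol(binary_mask)
  sem <- matrix(0L, H, W)
  if (!any(binary_mask > 0) || nrow(detections) == 0) return(sem)
  best_conf <- matrix(-Inf, H, W)
  best_class <- matrix(0L, H, W)
  ord <- order(detections$confidence, -detections$class)  # later = stronger
  for (i in ord) {
    d <- detections[i, ]
    x0 <- max(0, floor(d$x_min)); y0 <- max(0, floor(d$y_min))
    x1 <- min(W, ceiling(d$x_max)); y1 <- min(H, ceiling(d$y_max))
    if (x1 < d$x_max || y1 < d$y_max || x0 > d$x_min || y0 > d$y_min) {
      warning("box outside image clipped: [", d$x_min, ",", d$y_min, ",",
              d$x_max, ",", d$y_max, "]")
    }
    if (x1 <= x0 || y1 <= y0) next
    rows <- (y0 + 1):y1
    cols <- (x0 + 1):x1
    sub_conf <- best_conf[rows, cols, drop = FALSE]
    take <- d$confidence > sub_conf |
      (d$confidence == sub_conf & d$class < best_class[rows, cols])
    sub_conf[take] <- d$confidence
    best_conf[rows, cols] <- sub_conf
    sub_cls <- best_class[rows, cols, drop = FALSE]
    sub_cls[take] <- as.integer(d$class)
    best_class[rows, cols] <- sub_cls
  }
  inside <- binary_mask > 0 & is.finite(best_conf)
  sem[inside] <- best_class[inside]
  sem
}

#' Pixel-wise majority vote over semantic maps
#'
#' Per pixel, the label occurring most often across the maps; ties are
#' broken towards the smallest label value (background-favouring).
#'
#' @param maps nonempty list of integer `H x W` semantic maps of equal shape.
#' @return integer `H x W` semantic map.
#' @export
majority_vote <- function(maps) {
  if (length(maps) == 0) stop("majority_vote needs at least one map")
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!all(dim(m) == d)) stop("semantic map shape mismatch")
  }
  labels <- sort(unique(unlist(lapply(maps, function(m) unique(as.vector(m))))))
  counts <- lapply(labels, function(l) {
    Reduce(`+`, lapply(maps, function(m) (m == l) + 0L))
  })
  best <- matrix(labels[1], d[1], d[2])
  best_n <- counts[[1]]
  for (j in seq_along(labels)[-1]) {
    take <- counts[[j]] > best_n      # strict: ties keep the smaller label
    best[take] <- labels[j]
    best_n[take] <- counts[[j]][take]
  }
  matrix(as.integer(best), d[1], d[2])
}
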