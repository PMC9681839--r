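# Synthetic Wright-stained blood-smear simulator. Fields contain an RBC
# background (anucleate biconcave discs) and 1..n WBCs from four classes,
# each rendered consistently into (i) an optical-pathlength (phase) map,
# (ii) an RGB brightfield rendering with Wright-stain colours, (iii) a
# four-frame interferogram stack via the phase-shifting forward model, and
# (iv) full ground truth: boxes + class labels, binary WBC mask, semantic
# map. Morphology is caricatured but class-separable: neutrophil = 3-5
# nuclear lobes; eosinophil = bilobed nucleus + red granular cytoplasm;
# lymphocyte = large round nucleus with a thin cytoplasm rim; monocyte =
# kidney-shaped nucleus, largest cell.

WBC_CLASSES <- c("neutrophil", "eosinophil", "lymphocyte", "monocyte")

# Diameter ranges in micrometres; lymphocytes smallest, monocytes largest.
WBC_DIAM_UM <- list(neutrophil = c(10, 14), eosinophil = c(10, 14),
                    lymphocyte = c(8, 10), monocyte = c(14, 18))
RBC_DIAM_UM <- c(6.5, 8)

# Wright-stain palette (RGB in [0,1]).
SMEAR_PALETTE <- list(
  background = c(0.97, 0.95, 0.93),
  rbc        = c(0.93, 0.74, 0.70),
  cytoplasm  = list(neutrophil = c(0.90, 0.82, 0.88),
                    eosinophil = c(0.93, 0.72, 0.66),
                    lymphocyte = c(0.76, 0.81, 0.92),
                    monocyte   = c(0.80, 0.83, 0.90)),
  nucleus    = list(neutrophil = c(0.44, 0.24, 0.55),
                    eosinophil = c(0.50, 0.30, 0.56),
                    lymphocyte = c(0.33, 0.22, 0.60),
                    monocyte   = c(0.56, 0.42, 0.66)),
  granule    = c(0.82, 0.20, 0.22))

#' Configuration of the synthetic smear field
#'
#' Defaults follow the population composition of normal differential counts:
#' class priors are the midpoints of neutrophils 40-60%, eosinophils 1-4%,
#' lymphocytes 20-40%, monocytes 2-8% of total WBCs (renormalised to sum to
#' one). The per-field WBC count is Poisson with mean `wbc_density`,
#' truncated to at least one cell (fields of interest contain a WBC).
#'
#' @param field_size image height and width in pixels, `c(H, W)`.
#' @param pixel_size micrometres per pixel.
#' @param wbc_density mean WBCs per field (truncated Poisson); 0 disables.
#' @param class_priors probability 4-vector over
#'   (neutrophil, eosinophil, lymphocyte, monocyte); must sum to 1.
#' @param rbc_density mean RBC background cells per field (Poisson).
#' @param beta_background scattered-to-incident amplitude ratio used by the
#'   interferometric forward model.
#' @param noise_sigma additive Gaussian intensity noise on interferograms.
#' @param halo_strength strength in `[0, 1]` of the phase-contrast halo
#'   (high-pass shading) applied in the forward model.
#' @param halo_sigma Gaussian low-pass width (pixels) defining the halo.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `smear_config` list.
#' @export
smear_config <- function(field_size = c(256L, 256L), pixel_size = 0.3,
                         wbc_density = 2, class_priors = NULL,
                         rbc_density = 60, beta_background = 0.3,
                         noise_sigma = 0.01, halo_strength = 0.25,
                         halo_sigma = 10, seed = NULL) {
  if (is.null(class_priors)) {
    class_priors <- c(0.50, 0.025, 0.30, 0.05)
    class_priors <- class_priors / sum(class_priors)
  }
  if (length(class_priors) != 4L || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-9) {
    stop("class_priors must be a nonnegative 4-vector summing to 1")
  }
  stopifnot(length(field_size) == 2L, all(field_size > 0),
            wbc_density >= 0, rbc_density >= 0, beta_background >= 0,
            noise_sigma >= 0, halo_strength >= 0, halo_strength <= 1)
  structure(list(field_size = as.integer(field_size),
                 pixel_size = pixel_size, wbc_density = wbc_density,
                 class_priors = class_priors, rbc_density = rbc_density,
                 beta_background = beta_background,
                 noise_sigma = noise_sigma, halo_strength = halo_strength,
                 halo_sigma = halo_sigma, seed = seed),
            class = "smear_config")
}

#' Draw per-class WBC counts
#'
#' Multinomial draw of `n_cells` cells over the four WBC classes.
#'
#' @param n_cells total number of cells (>= 0).
#' @param priors probability 4-vector over
#'   (neutrophil, eosinophil, lymphocyte, monocyte).
#' @return named integer 4-vector summing to `n_cells`.
#' @export
sample_class_counts <- function(n_cells, priors) {
  if (length(priors) != 4L || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9) {
    stop("priors must be a nonnegative 4-vector summing to 1")
  }
  stopifnot(n_cells >= 0)
  cnt <- if (n_cells == 0) integer(4) else
    as.integer(stats::rmultinom(1, n_cells, priors))
  names(cnt) <- WBC_CLASSES
  cnt
}

# Paint a disc (or ellipse-ish blob) into value/colour canvases.
# Returns logical matrix of painted pixels. Canvases are modified in the
# caller via the returned masks, not here.
disc_mask <- function(H, W, cy, cx, r, ecc = 1, theta = 0) {
  y <- matrix(seq_len(H), H, W) - cy
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / r)^2 + (v / (r * ecc))^2 <= 1
}

# Nucleus mask for one WBC of class k (1..4), inside cell disc of radius r.
nucleus_mask <- function(H, W, cy, cx, r, class_idx) {
  m <- matrix(FALSE, H, W)
  if (class_idx == 1L) {                      # neutrophil: 3-5 lobes
    nl <- sample(3:5, 1)
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (j in seq_len(nl)) {
      a <- ang0 + 2 * pi * j / nl
      m <- m | disc_mask(H, W, cy + 0.38 * r * sin(a), cx + 0.38 * r * cos(a),
                         0.30 * r)
    }
  } else if (class_idx == 2L) {               # eosinophil: bilobed
    a <- stats::runif(1, 0, 2 * pi)
    off <- 0.34 * r
    m <- disc_mask(H, W, cy + off * sin(a), cx + off * cos(a), 0.34 * r) |
      disc_mask(H, W, cy - off * sin(a), cx - off * cos(a), 0.34 * r)
  } else if (class_idx == 3L) {               # lymphocyte: large round
    m <- disc_mask(H, W, cy, cx, 0.74 * r)
  } else {                                    # monocyte: kidney shape
    a <- stats::runif(1, 0, 2 * pi)
    body <- disc_mask(H, W, cy, cx, 0.62 * r)
    bite <- disc_mask(H, W, cy + 0.55 * r * sin(a), cx + 0.55 * r * cos(a),
                      0.40 * r)
    m <- body & !bite
  }
  m
}

#' Render one synthetic smear field
#'
#' Generates a complete `smear_sample`: ground-truth phase map (optical
#' pathlength in radians, nucleus > cytoplasm > background), Wright-stain
#' brightfield rendering, four-frame interferogram stack, ground-truth
#' boxes with class labels, binary WBC mask and semantic map (0 background,
#' 1 neutrophil, 2 eosinophil, 3 lymphocyte, 4 monocyte). WBCs are placed
#' by rejection sampling without WBC-WBC overlap; WBC-RBC overlap is
#' allowed (RBCs are painted first).
#'
#' @param config a [smear_config()].
#' @param seed integer seed for this sample; defaults to `config$seed`.
#' @return a `smear_sample` object.
#' @export
render_smear <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "smear_config"))
  if (!is.null(seed)) set.seed(seed)
  H <- config$field_size[1]; W <- config$field_size[2]
  px <- config$pixel_size
  phase <- matrix(0, H, W)
  col <- array(rep(SMEAR_PALETTE$background, each = H * W), c(H, W, 3))
  semantic <- matrix(0L, H, W)

  ## RBC background
  n_rbc <- stats::rpois(1, config$rbc_density)
  for (i in seq_len(n_rbc)) {
    r <- stats::runif(1, RBC_DIAM_UM[1], RBC_DIAM_UM[2]) / 2 / px
    cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
    m <- disc_mask(H, W, cy, cx, r, ecc = stats::runif(1, 0.85, 1),
                   theta = stats::runif(1, 0, pi))
    if (!any(m)) next
    yy <- matrix(seq_len(H), H, W) - cy
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    rr <- sqrt(yy^2 + xx^2) / r
    prof <- 0.9 - 0.45 * exp(-(rr / 0.5)^2)   # biconcave: central pallor
    phase[m] <- pmax(phase[m], prof[m])
    shade <- 1 - 0.35 * exp(-(rr / 0.5)^2)
    for (c in 1:3) {
      ch <- col[, , c]
      ch[m] <- SMEAR_PALETTE$rbc[c] * (2 - shade[m])  # rim darker than pallor
      col[, , c] <- ch
    }
  }

  ## WBCs: draw a count/class/size configuration and place cells without
  ## WBC-WBC overlap by rejection sampling; if a configuration cannot be
  ## packed, redraw it (bounded attempts) before giving up.
  placed <- NULL
  classes <- integer(0)
  for (attempt in seq_len(20L)) {
    n_wbc <- 0L
    if (config$wbc_density > 0) {
      repeat {
        n_wbc <- stats::rpois(1, config$wbc_density)
        if (n_wbc >= 1L) break
      }
    }
    counts <- sample_class_counts(n_wbc, config$class_priors)
    cls_try <- rep(1:4, counts)
    cls_try <- cls_try[sample.int(length(cls_try))]  # shuffle placement order
    pl <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    ok_all <- TRUE
    for (k in cls_try) {
      dr <- WBC_DIAM_UM[[k]]
      r <- stats::runif(1, dr[1], dr[2]) / 2 / px
      ok <- FALSE
      for (try in seq_len(200L)) {
        cy <- stats::runif(1, r + 2, H - r - 1)
        cx <- stats::runif(1, r + 2, W - r - 1)
        if (nrow(pl) == 0 ||
            all(sqrt((pl$cy - cy)^2 + (pl$cx - cx)^2) > pl$r + r + 3)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) { ok_all <- FALSE; break }
      pl <- rbind(pl, data.frame(cy = cy, cx = cx, r = r))
    }
    if (ok_all) { placed <- pl; classes <- cls_try; break }
  }
  if (is.null(placed)) {
    stop(sprintf(
      "could not place WBCs in a %dx%d field at wbc_density %.1f (20 configurations x 200 tries)",
      H, W, config$wbc_density))
  }
  boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = integer(0), confidence = numeric(0))
  for (ci in seq_along(classes)) {
    k <- classes[ci]
    cy <- placed$cy[ci]; cx <- placed$cx[ci]; r <- placed$r[ci]
    body <- disc_mask(H, W, cy, cx, r)
    nuc <- nucleus_mask(H, W, cy, cx, r, k) & body
    cyto <- body & !nuc
    phase[cyto] <- 1.1 + stats::runif(sum(cyto), -0.05, 0.05)
    phase[nuc] <- 2.1 + stats::runif(sum(nuc), -0.1, 0.1)
    cp <- SMEAR_PALETTE$cytoplasm[[k]]; np <- SMEAR_PALETTE$nucleus[[k]]
    for (c in 1:3) {
      ch <- col[, , c]
      ch[cyto] <- cp[c]
      ch[nuc] <- np[c]
      col[, , c] <- ch
    }
    if (k == 2L && any(cyto)) {               # eosinophil granules
      gi <- which(cyto)
      gi <- gi[stats::runif(length(gi)) < 0.35]
      for (c in 1:3) {
        ch <- col[, , c]
        ch[gi] <- SMEAR_PALETTE$granule[c]
        col[, , c] <- ch
      }
    }
    semantic[body] <- k
    ys <- range(which(rowSums(body) > 0)); xs <- range(which(colSums(body) > 0))
    boxes <- rbind(boxes, data.frame(
      x_min = xs[1] - 1, y_min = ys[1] - 1, x_max = xs[2], y_max = ys[2],
      class = k, confidence = 1))
  }

  binary_mask <- (semantic > 0L) + 0L
  phase <- gaussian_blur(phase, 0.8)
  phase[binary_mask == 0L & phase < 0.02] <- 0
  col <- gaussian_blur(col, 0.6)
  col <- col + array(stats::rnorm(length(col), 0, 0.01), dim(col))
  col <- pmin(pmax(col, 0), 1)

  stack <- forward_interferograms(
    phase, beta = config$beta_background, noise_sigma = config$noise_sigma,
    halo_strength = config$halo_strength, halo_sigma = config$halo_sigma,
    brightfield = col, pixel_size = px)

  structure(list(phase_gt = phase, brightfield = col, stack = stack,
                 boxes = boxes, binary_mask = binary_mask,
                 semantic_gt = semantic, config = config, seed = seed),
            class = "smear_sample")
}

#' @export
print.smear_sample <- function(x, ...) {
  cat(sprintf("smear_sample: %d x %d px, %d WBC(s) [%s]\n",
              nrow(x$phase_gt), ncol(x$phase_gt), nrow(x$boxes),
              paste(WBC_CLASSES[x$boxes$class], collapse = ", ")))
  invisible(x)
}

#' Interferometric forward model
#'
#' Produces the four phase-shifted intensity frames from a ground-truth
#' phase field:
#' `I_k = 1 + beta^2 + 2 beta cos(phi_eff + k pi/2) + eps_k`,
#' `eps_k ~ N(0, noise_sigma^2)`, clipped so intensities stay nonnegative.
#' The phase-contrast halo is mimicked by high-passing the phase:
#' `phi_eff = phi - halo_strength * lowpass(phi)` with a Gaussian low-pass
#' of width `halo_sigma`. If a `brightfield` rendering is supplied, frames
#' are modulated per colour channel as `bf_c * I_k / I_0` so that the
#' unshifted frame `k = 0` is exactly the brightfield image (the colour-SLIM
#' configuration); the per-pixel positive scaling leaves the recoverable
#' phase unchanged.
#'
#' @param phase ground-truth phase matrix (radians).
#' @param beta scalar or matrix amplitude ratio, `>= 0`.
#' @param noise_sigma additive intensity noise standard deviation.
#' @param halo_strength halo strength in `[0, 1]`.
#' @param halo_sigma Gaussian low-pass width in pixels.
#' @param brightfield optional `(H, W, 3)` rendering for colour stacks.
#' @param pixel_size micrometres per pixel (metadata).
#' @return an [interferogram_stack()].
#' @export
forward_interferograms <- function(phase, beta, noise_sigma = 0,
                                   halo_strength = 0, halo_sigma = 10,
                                   brightfield = NULL, pixel_size = 1) {
  stopifnot(all(beta >= 0), noise_sigma >= 0,
            halo_strength >= 0, halo_strength <= 1)
  phi_eff <- phase
  if (halo_strength > 0) {
    phi_eff <- phase - halo_strength * gaussian_blur(phase, halo_sigma)
  }
  frames <- lapply(0:3, function(k) {
    I <- 1 + beta^2 + 2 * beta * cos(phi_eff + k * pi / 2)
    if (!is.null(brightfield)) {
      I0 <- 1 + beta^2 + 2 * beta * cos(phi_eff)
      f <- array(0, dim(brightfield))
      for (c in 1:3) f[, , c] <- brightfield[, , c] * I / pmax(I0, 1e-6)
    } else {
      f <- array(I, c(dim(phase), 1L))
    }
    # the colour k = 0 frame is the brightfield rendering itself (its
    # sensor noise is already part of the rendering), so noise is added
    # to the shifted frames only
    if (noise_sigma > 0 && !(k == 0 && !is.null(brightfield))) {
      f <- f + array(stats::rnorm(length(f), 0, noise_sigma), dim(f))
    }
    pmax(f, 0)
  })
  interferogram_stack(frames, pixel_size = pixel_size)
}

#' Train/validation/test splits with repeated random partitions
#'
#' Holds out a fixed test set, then partitions the remaining ids into
#' train/validation `n_repeats` times at the given ratio
#' (`val = floor(remaining / (1 + ratio))`, train = remainder).
#'
#' @param n_images total number of images.
#' @param n_test held-out test images (fixed across repeats).
#' @param train_val_ratio train:val ratio (e.g. 8 for 8:1).
#' @param n_repeats number of random train/val partitions.
#' @param seed integer seed.
#' @return a `dataset_split`: `test_ids` plus a list `repeats` of
#'   `(train_ids, val_ids)`.
#' @export
make_splits <- function(n_images, n_test, train_val_ratio = 8,
                        n_repeats = 5, seed = 1) {
  stopifnot(n_test < n_images, train_val_ratio > 0, n_repeats >= 1)
  set.seed(seed)
  ids <- seq_len(n_images)
  test_ids <- sort(sample(ids, n_test))
  rem <- setdiff(ids, test_ids)
  n_val <- floor(length(rem) / (1 + train_val_ratio))
  repeats <- lapply(seq_len(n_repeats), function(r) {
    val <- sort(sample(rem, n_val))
    list(train_ids = setdiff(rem, val), val_ids = val)
  })
  structure(list(test_ids = test_ids, repeats = repeats, seed = seed),
            class = "dataset_split")
}

#' Generate a synthetic smear dataset on disk
#'
#' Writes, per sample `i`: `img<i>_phase.tif` (float32, radians stored as
#' `(phi + pi) / (2 pi)`), `img<i>_bf.png` (8-bit RGB), `img<i>_s0..3.tif`
#' (float32 interferograms stored as `I / 4`), `img<i>_mask.png` (0/255) and
#' `img<i>_sem.png` (labels 0-4 stored as `label / 255`); plus a COCO-style
#' `annotations.json` (categories 1-4, bbox `[x, y, width, height]`) and
#' `splits.json`.
#'
#' @param out_dir output directory (refuses to overwrite unless `force`).
#' @param n_images number of fields to simulate.
#' @param n_test held-out test images.
#' @param train_val_ratio train:val ratio for the remaining images.
#' @param n_repeats number of repeated train/val partitions.
#' @param config a [smear_config()].
#' @param seed master seed; per-sample seeds are derived from it.
#' @param force overwrite an existing dataset directory.
#' @return a `smear_dataset` handle (directory, ids, splits, annotations).
#' @export
make_dataset <- function(out_dir, n_images = 504, n_test = 50,
                         train_val_ratio = 8, n_repeats = 5,
                         config = smear_config(), seed = 1, force = FALSE) {
  stopifnot(n_test < n_images)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- list(images = list(), annotations = list(),
              categories = lapply(1:4, function(k)
                list(id = k, name = WBC_CLASSES[k])))
  ann_id <- 0L
  for (i in seq_len(n_images)) {
    s <- render_smear(config, seed = derive_seed(seed, "sample", i))
    write_sample(s, out_dir, i)
    d <- dim(s$phase_gt)
    ann$images[[i]] <- list(id = i, file_name = sprintf("img%04d_bf.png", i),
                            height = d[1], width = d[2])
    for (j in seq_len(nrow(s$boxes))) {
      ann_id <- ann_id + 1L
      b <- s$boxes[j, ]
      ann$annotations[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = b$class,
        bbox = c(b$x_min, b$y_min, b$x_max - b$x_min, b$y_max - b$y_min),
        area = (b$x_max - b$x_min) * (b$y_max - b$y_min), iscrowd = 0L)
    }
  }
  splits <- make_splits(n_images, n_test, train_val_ratio, n_repeats,
                        seed = derive_seed(seed, "splits"))
  jsonlite::write_json(ann, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(test_ids = splits$test_ids,
         repeats = lapply(splits$repeats, function(r)
           list(train_ids = r$train_ids, val_ids = r$val_ids)),
         seed = splits$seed),
    file.path(out_dir, "splits.json"), auto_unbox = FALSE, digits = NA)
  smear_dataset(out_dir)
}

write_sample <- function(s, out_dir, i) {
  base <- file.path(out_dir, sprintf("img%04d", i))
  tiff::writeTIFF((s$phase_gt + pi) / (2 * pi), paste0(base, "_phase.tif"),
                  bits.per.sample = 32L, compression = "none")
  png::writePNG(s$brightfield, paste0(base, "_bf.png"))
  for (k in 0:3) {
    f <- s$stack$frames[[k + 1]]
    f <- if (dim(f)[3] == 1L) f[, , 1] else f
    tiff::writeTIFF(pmin(f / 4, 1), sprintf("%s_s%d.tif", base, k),
                    bits.per.sample = 32L, compression = "none")
  }
  png::writePNG(s$binary_mask + 0, paste0(base, "_mask.png"))
  png::writePNG((s$semantic_gt + 0) / 255, paste0(base, "_sem.png"))
  invisible(base)
}

#' Open a smear dataset directory
#'
#' @param dir dataset directory written by [make_dataset()].
#' @return a `smear_dataset` handle.
#' @export
smear_dataset <- function(dir) {
  ann <- jsonlite::read_json(file.path(dir, "annotations.json"))
  sp <- jsonlite::read_json(file.path(dir, "splits.json"),
                            simplifyVector = TRUE)
  splits <- structure(list(
    test_ids = as.integer(sp$test_ids),
    repeats = lapply(seq_len(nrow_or_len(sp$repeats)), function(r)
      list(train_ids = as.integer(sp$repeats$train_ids[[r]]),
           val_ids = as.integer(sp$repeats$val_ids[[r]]))),
    seed = sp$seed), class = "dataset_split")
  structure(list(dir = dir, n_images = length(ann$images),
                 annotations = ann, splits = splits),
            class = "smear_dataset")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' @export
print.smear_dataset <- function(x, ...) {
  cat(sprintf("smear_dataset: %d images at %s (%d test, %d repeats)\n",
              x$n_images, x$dir, length(x$splits$test_ids),
              length(x$splits$repeats)))
  invisible(x)
}

# Loaders for individual dataset members; ids are integer indices.
ds_path <- function(ds, i, suffix) {
  file.path(ds$dir, sprintf("img%04d_%s", i, suffix))
}

ds_load_phase <- function(ds, i) {
  tiff::readTIFF(ds_path(ds, i, "phase.tif")) * 2 * pi - pi
}

ds_load_brightfield <- function(ds, i) {
  img_to_array(png::readPNG(ds_path(ds, i, "bf.png")))
}

ds_load_mask <- function(ds, i) {
  m <- png::readPNG(ds_path(ds, i, "mask.png"))
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) + 0L
}

ds_load_semantic <- function(ds, i) {
  m <- png::readPNG(ds_path(ds, i, "sem.png"))
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

ds_load_stack <- function(ds, i) {
  frames <- lapply(0:3, function(k)
    img_to_array(tiff::readTIFF(ds_path(ds, i, sprintf("s%d.tif", k)))) * 4)
  interferogram_stack(frames)
}

# Ground-truth boxes of image i as a data.frame matching render_smear().
ds_boxes <- function(ds, i) {
  rows <- Filter(function(a) a$image_id == i, ds$annotations$annotations)
  if (length(rows) == 0) {
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = integer(0), confidence = numeric(0)))
  }
  do.call(rbind, lapply(rows, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    data.frame(x_min = bb[1], y_min = bb[2], x_max = bb[1] + bb[3],
               y_max = bb[2] + bb[4], class = as.integer(a$category_id),
               confidence = 1)
  }))
}
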