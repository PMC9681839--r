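# Quantitative-phase reconstruction from four pi/2-shifted interferograms
# (phase-shifting interferometry on a phase-contrast setup, as in SLIM /
# colour SLIM). Frame k carries phase delay k*pi/2 between incident and
# scattered field:
#   I_k = |U_i|^2 + |U_s|^2 + 2 |U_i||U_s| cos(dphi + k*pi/2)
# so  I0 - I2 = 4 |U_i||U_s| cos(dphi),  I3 - I1 = 4 |U_i||U_s| sin(dphi),
# giving dphi unambiguously, and the full-field argument
#   phi = atan2(beta sin dphi, 1 + beta cos dphi),  beta = |U_s|/|U_i|.

#' Build an interferogram stack
#'
#' Bundles four co-registered intensity frames acquired at phase shifts
#' `0, pi/2, pi, 3*pi/2` into an `interferogram_stack`. Frames may be
#' single-channel matrices or `(H, W, 3)` RGB arrays (colour SLIM); all four
#' must share shape and channel count and be nonnegative.
#'
#' @param frames list of exactly four numeric matrices or `(H, W, C)` arrays,
#'   in shift order `k = 0..3`.
#' @param pixel_size physical pixel size in micrometres per pixel (metadata).
#' @return an `interferogram_stack` object.
#' @export
interferogram_stack <- function(frames, pixel_size = 1) {
  if (!is.list(frames) || length(frames) != 4L) {
    stop("an interferogram stack needs exactly 4 frames, got ",
         if (is.list(frames)) length(frames) else 1L)
  }
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) f <- array(f, c(dim(f), 1L))
    if (length(dim(f)) != 3L) stop("frames must be 2-D or (H, W, C) arrays")
    storage.mode(f) <- "double"
    f
  })
  d0 <- dim(frames[[1]])
  for (k in 2:4) {
    if (!identical(dim(frames[[k]]), d0)) {
      stop("frame shape mismatch: frame ", k, " is ",
           paste(dim(frames[[k]]), collapse = "x"), ", frame 1 is ",
           paste(d0, collapse = "x"))
    }
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop("interferogram intensities must be nonnegative")
  }
  structure(list(frames = frames, pixel_size = pixel_size),
            class = "interferogram_stack")
}

#' @export
print.interferogram_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "interferogram_stack: 4 frames, %d x %d px, %d channel(s), %.3g um/px\n",
    d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

# Single-channel four-frame inversion; returns dphi, beta and phi.
recon_one_channel <- function(I0, I1, I2, I3, tol = 1e-12) {
  num <- I3 - I1
  den <- I0 - I2
  G <- sqrt(num * num + den * den) / 4      # |U_i||U_s|
  S <- (I0 + I1 + I2 + I3) / 4              # |U_i|^2 + |U_s|^2
  degen <- G < tol * pmax(S, tol)
  dphi <- atan2(num, den)
  dphi[degen] <- 0
  disc <- pmax(S * S - 4 * G * G, 0)
  ui2 <- (S + sqrt(disc)) / 2               # larger root: incident dominates
  us2 <- pmax(S - ui2, 0)
  beta <- ifelse(ui2 > 0, sqrt(us2 / ui2), 0)
  beta[degen] <- 0
  phi <- atan2(beta * sin(dphi), 1 + beta * cos(dphi))
  phi[degen] <- 0
  list(dphi = dphi, beta = beta, phi = phi)
}

stack_channels <- function(stack, channel_mode) {
  nc <- dim(stack$frames[[1]])[3]
  ch <- function(f, c) matrix(f[, , c], dim(f)[1], dim(f)[2])
  if (channel_mode == "luminance" && nc == 3L) {
    w <- c(0.299, 0.587, 0.114)
    lapply(1:4, function(k) {
      f <- stack$frames[[k]]
      list(ch(f, 1) * w[1] + ch(f, 2) * w[2] + ch(f, 3) * w[3])
    })
  } else {
    lapply(1:4, function(k) {
      lapply(seq_len(nc), function(c) ch(stack$frames[[k]], c))
    })
  }
}

#' Reconstruct the quantitative phase map from a four-frame stack
#'
#' Inverts the four-bucket phase-shifting model. The returned object carries
#' two phase fields: `delta_phi`, the incident-vs-scattered phase difference
#' `atan2(I3 - I1, I0 - I2)` that the four frames determine directly, and
#' `phi`, the full-field argument `atan2(beta sin dphi, 1 + beta cos dphi)`.
#' Both are principal values in `(-pi, pi]`; no unwrapping is applied and the
#' phase-contrast halo is deliberately not corrected. Pixels with vanishing
#' modulation (no scattered field) are set to 0 in all fields.
#'
#' For RGB stacks, `per_channel_mean` reconstructs each colour channel
#' independently and averages the three phase maps; `luminance` first
#' collapses frames to luminance.
#'
#' @param stack an [interferogram_stack()].
#' @param channel_mode `"per_channel_mean"` (default) or `"luminance"`.
#' @return a `phase_map` object with fields `phi`, `delta_phi`, `beta`
#'   (all `H x W` matrices) and `provenance`.
#' @export
reconstruct_phase <- function(stack,
                              channel_mode = c("per_channel_mean",
                                               "luminance")) {
  channel_mode <- match.arg(channel_mode)
  stopifnot(inherits(stack, "interferogram_stack"))
  chans <- stack_channels(stack, channel_mode)
  ncomb <- length(chans[[1]])
  acc <- NULL
  for (c in seq_len(ncomb)) {
    r <- recon_one_channel(chans[[1]][[c]], chans[[2]][[c]],
                           chans[[3]][[c]], chans[[4]][[c]])
    acc <- if (is.null(acc)) r else Map(`+`, acc, r)
  }
  acc <- lapply(acc, function(m) m / ncomb)
  structure(list(phi = acc$phi, delta_phi = acc$dphi, beta = acc$beta,
                 pixel_size = stack$pixel_size,
                 provenance = channel_mode),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf(
    "phase_map: %d x %d px (%s), phi in [%.3f, %.3f] rad\n",
    nrow(x$phi), ncol(x$phi), x$provenance, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Estimate the scattered-to-incident amplitude ratio
#'
#' Per pixel, `G = sqrt((I0-I2)^2 + (I3-I1)^2)/4` estimates `|U_i||U_s|` and
#' `S = (I0+I1+I2+I3)/4` estimates `|U_i|^2 + |U_s|^2`; the two squared
#' amplitudes are the roots of `x^2 - S x + G^2 = 0`, assigned so that
#' `|U_i| >= |U_s|` (the incident field dominates in brightfield-like
#' configurations). Negative discriminants from noise are clamped to zero.
#' RGB stacks are averaged over channels.
#'
#' @param stack an [interferogram_stack()].
#' @return list with matrices `delta_phi` (radians, `(-pi, pi]`) and `beta`
#'   (`|U_s|/|U_i|`, nonnegative).
#' @export
estimate_amplitude_ratio <- function(stack) {
  pm <- reconstruct_phase(stack, "per_channel_mean")
  list(delta_phi = pm$delta_phi, beta = pm$beta)
}

#' Extract the brightfield frame from a colour-SLIM stack
#'
#' In colour SLIM the unshifted frame (`k = 0`) is an ordinary brightfield
#' micrograph; this returns it unchanged, preserving channel count.
#'
#' @param stack an [interferogram_stack()].
#' @return the `k = 0` intensity frame, `(H, W, C)` array.
#' @export
extract_brightfield <- function(stack) {
  stopifnot(inherits(stack, "interferogram_stack"))
  stack$frames[[1]]
}

#' Read an interferogram stack from disk
#'
#' Accepts either a single multi-page TIFF (page order = shift order) or the
#' path of the `k = 0` file in a `_s0.._s3` suffix family.
#'
#' @param path path to a 4-page TIFF, or to the `_s0` file of a four-file set.
#' @param pixel_size micrometres per pixel (metadata).
#' @return an [interferogram_stack()].
#' @export
read_interferograms <- function(path, pixel_size = 1) {
  if (grepl("_s0\\.[A-Za-z]+$", path)) {
    paths <- vapply(0:3, function(k) sub("_s0\\.", sprintf("_s%d.", k), path),
                    character(1))
    frames <- lapply(paths, function(p) {
      if (!file.exists(p)) stop("missing stack file: ", p)
      img_to_array(tiff::readTIFF(p))
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 4L) {
      stop("expected a 4-page TIFF, got ", length(pages), " page(s)")
    }
    frames <- lapply(pages, img_to_array)
  }
  interferogram_stack(frames, pixel_size = pixel_size)
}

#' Write a phase map as 32-bit float TIFF
#'
#' Radians are stored as `(phi + pi) / (2 pi)` to fit the writer's `[0, 1]`
#' float range; [read_phase_map()] inverts the scaling.
#'
#' @param pm a `phase_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_map <- function(pm, path) {
  tiff::writeTIFF((pm$delta_phi + pi) / (2 * pi), path,
                  bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' Read a phase map written by [write_phase_map()]
#'
#' @param path TIFF path.
#' @return matrix of phase values in radians.
#' @export
read_phase_map <- function(path) {
  tiff::readTIFF(path) * 2 * pi - pi
}

img_to_array <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 1L)) else img[, , 1:min(dim(img)[3], 3), drop = FALSE]
}
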