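# Binary WBC-vs-background segmentation with a small U-Net: five
# contracting convolution blocks (pooling after the first four; the fifth
# is the bridge) and four expanding blocks with skip connections, each
# block = (1 or 2) 3x3 convolutions with channel normalisation and
# rectifier activations; sigmoid output head trained against {0,1} masks
# with mean squared error. Early stopping: patience on validation loss,
# lowest-loss checkpoint kept.

#' Mean squared error between a probability map and a binary mask
#'
#' @param pred probability map.
#' @param target binary map of identical shape.
#' @return scalar mean of squared per-pixel differences.
#' @export
mse_value <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) {
    stop("shape mismatch between prediction and target")
  }
  mean((pred - target)^2)
}

#' Segmenter training configuration
#'
#' @param learning_rate Adam learning rate (default 3e-5).
#' @param batch_size images per update (default 2).
#' @param patience consecutive epochs without a validation-loss decrease
#'   tolerated before stopping (default 5).
#' @param max_epochs epoch budget.
#' @param input_size working resolution, divisible by 16 (four poolings).
#' @param base_channels first-level width; channels double per level.
#' @param convs_per_block 1 or 2 convolutions per block (default 2).
#' @param binarize_threshold probability threshold for the output mask.
#' @param seed integer seed.
#' @return a `segmenter_config` list.
#' @export
segmenter_config <- function(learning_rate = 3e-5, batch_size = 2,
                             patience = 5, max_epochs = 40,
                             input_size = 64, base_channels = 8,
                             convs_per_block = 2,
                             binarize_threshold = 0.5, seed = 1) {
  stopifnot(patience >= 1, input_size %% 16 == 0,
            binarize_threshold > 0, binarize_threshold < 1,
            convs_per_block %in% 1:2)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs,
                 input_size = as.integer(input_size),
                 base_channels = base_channels,
                 convs_per_block = convs_per_block,
                 binarize_threshold = binarize_threshold, seed = seed),
            class = "segmenter_config")
}

build_unet <- function(base, convs_per_block = 2, in_ch = 3L) {
  layers <- list()
  chans <- c(base, 2 * base, 4 * base, 4 * base, 4 * base)
  ic <- in_ch
  for (lev in 1:5) {
    for (j in seq_len(convs_per_block)) {
      nm <- sprintf("u_d%d_%d", lev, j)
      layers[[nm]] <- nn_conv(ic, chans[lev])
      layers[[sprintf("u_dn%d_%d", lev, j)]] <- nn_norm(chans[lev])
      ic <- chans[lev]
    }
  }
  for (lev in 4:1) {
    ic <- chans[lev + 1] + chans[lev]      # upsampled + skip
    for (j in seq_len(convs_per_block)) {
      nm <- sprintf("u_u%d_%d", lev, j)
      layers[[nm]] <- nn_conv(ic, chans[lev])
      layers[[sprintf("u_un%d_%d", lev, j)]] <- nn_norm(chans[lev])
      ic <- chans[lev]
    }
  }
  layers$u_out <- nn_conv(chans[1], 1L)
  list(layers = layers, base = base, convs_per_block = convs_per_block)
}

unet_forward <- function(tape, net, x_id) {
  L <- net$layers
  nb <- net$convs_per_block
  block <- function(id, prefix, lev) {
    for (j in seq_len(nb)) {
      id <- op_conv(tape, L[[sprintf("u_%s%d_%d", prefix, lev, j)]],
                    sprintf("u_%s%d_%d", prefix, lev, j), id)
      id <- op_norm(tape, L[[sprintf("u_%sn%d_%d", prefix, lev, j)]],
                    sprintf("u_%sn%d_%d", prefix, lev, j), id)
      id <- op_act(tape, "relu", id)
    }
    id
  }
  skips <- list()
  id <- x_id
  for (lev in 1:4) {
    id <- block(id, "d", lev)
    skips[[lev]] <- id
    id <- op_pool(tape, id)
  }
  id <- block(id, "d", 5)                  # bridge
  for (lev in 4:1) {
    id <- op_concat(tape, op_up2(tape, id), skips[[lev]])
    id <- block(id, "u", lev)
  }
  op_act(tape, "sigmoid", op_conv(tape, L$u_out, "u_out", id))
}

#' Train the binary WBC segmenter
#'
#' Adam on the mean-squared-error loss between the sigmoid probability map
#' and the {0,1} ground-truth mask. Stops when the validation loss has not
#' decreased for `patience` consecutive epochs; returns the lowest-loss
#' snapshot and the epoch log.
#'
#' @param dataset a `smear_dataset`.
#' @param split list with `train_ids` and `val_ids`.
#' @param config a [segmenter_config()].
#' @param loader function(dataset, id) returning the `(H, W, 3)` input
#'   image; defaults to the brightfield rendering.
#' @return a `wbc_segmenter`.
#' @export
train_segmenter <- function(dataset, split, config = segmenter_config(),
                            loader = loader_brightfield) {
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop("empty train or validation set")
  }
  set.seed(config$seed)
  S <- config$input_size
  all_ids <- c(split$train_ids, split$val_ids)
  data <- lapply(all_ids, function(i) {
    x <- resize_array(loader(dataset, i), S, S)
    m <- resize_array(ds_load_mask(dataset, i) + 0, S, S)
    list(x = x, m = (m > 0.5) + 0)
  })
  names(data) <- as.character(all_ids)
  net <- build_unet(config$base_channels, config$convs_per_block)
  state <- adam_init(net_params(net))

  step_fn <- function(epoch) {
    losses <- c()
    for (batch in batch_schedule(split$train_ids, config$batch_size)) {
      acc <- NULL
      bloss <- 0
      for (i in batch) {
        d <- data[[as.character(i)]]
        t <- nn_tape()
        out_id <- unet_forward(t, net, tp_input(t, d$x))
        pred <- tp_val(t, out_id)[, , 1]
        bloss <- bloss + mse_value(pred, d$m)
        dy <- array(2 * (pred - d$m) / length(pred), c(dim(pred), 1L))
        gr <- tp_backward(t, list(list(id = out_id, grad = dy)))
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
    mean(vapply(split$val_ids, function(i) {
      d <- data[[as.character(i)]]
      t <- nn_tape()
      pred <- tp_val(t, unet_forward(t, net, tp_input(t, d$x)))[, , 1]
      mse_value(pred, d$m)
    }, numeric(1)))
  }

  run <- training_run(config$max_epochs, config$patience, "min",
                      step_fn, eval_fn)
  net <- net_set_params(net, run$best_params)
  structure(list(net = net, config = config, log = run$log,
                 best_epoch = run$best_epoch,
                 best_val_loss = run$best_metric),
            class = "wbc_segmenter")
}

#' @export
print.wbc_segmenter <- function(x, ...) {
  cat(sprintf(
    "wbc_segmenter: U-Net base %d, best val MSE %.4f (epoch %d/%d)\n",
    x$config$base_channels, x$best_val_loss, x$best_epoch, nrow(x$log)))
  invisible(x)
}

#' Predict the WBC probability map
#'
#' @param object a trained `wbc_segmenter`.
#' @param image `(H, W, 3)` array in `[0, 1]` (or matrix, replicated).
#' @param ... unused.
#' @return `H x W` probability matrix at the input's resolution.
#' @export
predict.wbc_segmenter <- function(object, image, ...) {
  image <- as_3ch(image)
  S <- object$config$input_size
  x <- resize_array(image, S, S)
  t <- nn_tape()
  pred <- tp_val(t, unet_forward(t, object$net, tp_input(t, x)))[, , 1]
  resize_array(pred, dim(image)[1], dim(image)[2])
}

#' Binarise a segmentation
#'
#' Thresholds the model's probability map; pixels equal to the threshold
#' count as foreground.
#'
#' @param model a trained `wbc_segmenter`.
#' @param image input image.
#' @param threshold probability cutoff; defaults to the model's configured
#'   `binarize_threshold`.
#' @return integer `H x W` map in `{0, 1}`.
#' @export
segment <- function(model, image, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$binarize_threshold
  (predict(model, image) >= threshold) + 0L
}
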