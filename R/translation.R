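# Conditional-GAN phase -> Wright-stain brightfield translation.
# Objective: the discriminator ascends
#   L_cGAN(G, D) = E[log D(x, y)] + E[log(1 - D(x, G(x, z)))]
# while the generator descends the second term plus a weighted L1 term,
# lambda = 100 by default (the pix2pix convention; stabilises training and
# keeps the translation close to the paired target). The noise z is
# realised as train-time dropout in the generator decoder. The generator
# is a depth-3 encoder-decoder with skip connections; the discriminator is
# a small patch classifier. Both are sized for CPU training.

CLAMP_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, CLAMP_EPS), 1 - CLAMP_EPS)

#' Conditional-GAN value
#'
#' `mean(log d_real) + mean(log(1 - d_fake))` over a batch of discriminator
#' probabilities; the discriminator ascends this, the generator descends
#' the second term. Probabilities are clamped to `(eps, 1 - eps)` with
#' `eps = 1e-7` before the logs.
#'
#' @param d_real discriminator probabilities on real (input, target) pairs.
#' @param d_fake discriminator probabilities on (input, generated) pairs.
#' @return scalar value (always `<= 0`, supremum 0).
#' @export
cgan_value <- function(d_real, d_fake) {
  if (length(d_real) == 0 || length(d_fake) == 0) stop("empty batch")
  mean(log(clamp_prob(d_real))) + mean(log(1 - clamp_prob(d_fake)))
}

#' Mean absolute pixel difference
#'
#' @param pred,target numeric arrays of identical shape.
#' @return scalar mean |pred - target| over all pixels and channels.
#' @export
l1_value <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target)) {
    stop("shape mismatch between prediction and target")
  }
  mean(abs(pred - target))
}

#' Generator objective
#'
#' `mean(log(1 - d_fake)) + lambda_l1 * l1_value(pred, target)`; minimised
#' by the generator.
#'
#' @param d_fake discriminator probabilities on generated images.
#' @param pred generated image batch.
#' @param target real image batch.
#' @param lambda_l1 nonnegative L1 weight (default 100).
#' @return scalar objective.
#' @export
generator_objective <- function(d_fake, pred, target, lambda_l1 = 100) {
  stopifnot(lambda_l1 >= 0)
  if (length(d_fake) == 0) stop("empty batch")
  mean(log(1 - clamp_prob(d_fake))) + lambda_l1 * l1_value(pred, target)
}

#' Translator training configuration
#'
#' @param learning_rate Adam learning rate for the generator (the
#'   discriminator mirrors it).
#' @param batch_size images per update.
#' @param input_size working resolution (scalar or `c(H, W)`, multiples
#'   of 8); images are downsampled to it.
#' @param lambda_l1 L1 weight in the generator objective.
#' @param base_channels generator/discriminator width.
#' @param dropout decoder dropout rate realising the noise input z.
#' @param max_epochs epoch budget.
#' @param patience consecutive non-improving epochs tolerated on the
#'   validation loss (`Inf` = train the full budget, keep the best).
#' @param seed integer seed.
#' @return a `translation_config` list.
#' @export
translation_config <- function(learning_rate = 2e-4, batch_size = 2,
                               input_size = 512, lambda_l1 = 100,
                               base_channels = 8, dropout = 0.5,
                               max_epochs = 40, patience = Inf, seed = 1) {
  stopifnot(batch_size >= 1, all(input_size %% 8 == 0), lambda_l1 >= 0)
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 input_size = as.integer(input_size), lambda_l1 = lambda_l1,
                 base_channels = base_channels, dropout = dropout,
                 max_epochs = max_epochs, patience = patience, seed = seed),
            class = "translation_config")
}

build_generator <- function(base, in_ch = 1L, out_ch = 3L) {
  list(layers = list(
    g_e1 = nn_conv(in_ch, base, k = 4, stride = 2, pad = 1),
    g_e2 = nn_conv(base, 2 * base, k = 4, stride = 2, pad = 1),
    g_n2 = nn_norm(2 * base),
    g_e3 = nn_conv(2 * base, 4 * base, k = 4, stride = 2, pad = 1),
    g_n3 = nn_norm(4 * base),
    g_d3 = nn_conv(4 * base, 2 * base),
    g_m3 = nn_norm(2 * base),
    g_d2 = nn_conv(4 * base, base),
    g_m2 = nn_norm(base),
    g_d1 = nn_conv(2 * base, base),
    g_m1 = nn_norm(base),
    g_out = nn_conv(base, out_ch)),
    base = base, in_ch = in_ch, out_ch = out_ch)
}

# Generator forward on a tape; returns output node id.
gen_forward <- function(tape, net, x_id, dropout = 0, training = FALSE) {
  L <- net$layers
  e1 <- op_act(tape, "lrelu", op_conv(tape, L$g_e1, "g_e1", x_id))
  e2 <- op_act(tape, "lrelu",
               op_norm(tape, L$g_n2, "g_n2",
                       op_conv(tape, L$g_e2, "g_e2", e1)))
  e3 <- op_act(tape, "lrelu",
               op_norm(tape, L$g_n3, "g_n3",
                       op_conv(tape, L$g_e3, "g_e3", e2)))
  d3 <- op_act(tape, "relu",
               op_norm(tape, L$g_m3, "g_m3",
                       op_conv(tape, L$g_d3, "g_d3", op_up2(tape, e3))))
  d3 <- op_dropout(tape, d3, dropout, training)
  d2 <- op_act(tape, "relu",
               op_norm(tape, L$g_m2, "g_m2",
                       op_conv(tape, L$g_d2, "g_d2",
                               op_up2(tape, op_concat(tape, d3, e2)))))
  d2 <- op_dropout(tape, d2, dropout, training)
  d1 <- op_act(tape, "relu",
               op_norm(tape, L$g_m1, "g_m1",
                       op_conv(tape, L$g_d1, "g_d1",
                               op_up2(tape, op_concat(tape, d2, e1)))))
  op_act(tape, "sigmoid", op_conv(tape, L$g_out, "g_out", d1))
}

build_discriminator <- function(base, in_ch = 4L) {
  list(layers = list(
    d_c1 = nn_conv(in_ch, base, k = 4, stride = 2, pad = 1),
    d_c2 = nn_conv(base, 2 * base, k = 4, stride = 2, pad = 1),
    d_n2 = nn_norm(2 * base),
    d_c3 = nn_conv(2 * base, 1)),
    base = base, in_ch = in_ch)
}

disc_forward <- function(tape, net, xy_id) {
  L <- net$layers
  p1 <- op_act(tape, "lrelu", op_conv(tape, L$d_c1, "d_c1", xy_id))
  p2 <- op_act(tape, "lrelu",
               op_norm(tape, L$d_n2, "d_n2",
                       op_conv(tape, L$d_c2, "d_c2", p1)))
  op_act(tape, "sigmoid", op_conv(tape, L$d_c3, "d_c3", p2))
}

# Percentile normalisation of SLIM phase inputs: the working range is the
# 1st-99th percentile of the training-set phase values.
phase_norm_stats <- function(phases) {
  v <- unlist(lapply(phases, as.vector))
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-6
  list(lo = q[1], hi = q[2])
}

normalize_phase <- function(phi, stats) {
  pmin(pmax((phi - stats$lo) / (stats$hi - stats$lo), 0), 1)
}

#' Train the phase-to-brightfield translator
#'
#' Alternating discriminator/generator Adam updates per minibatch; the
#' validation metric is the generator objective (GAN + weighted L1) on the
#' validation pairs, and the returned weights are the snapshot with the
#' lowest validation loss.
#'
#' @param dataset a `smear_dataset`.
#' @param split one repeat's split: list with `train_ids` and `val_ids`.
#' @param config a [translation_config()].
#' @return a `wbc_translator` with the trained generator, the phase
#'   normalisation stats and the loss log (`$log`: epoch, train_loss,
#'   val_metric).
#' @export
train_translator <- function(dataset, split, config = translation_config()) {
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop("empty train or validation set")
  }
  set.seed(config$seed)
  hw <- config$input_size
  phases <- lapply(c(split$train_ids, split$val_ids), function(i)
    reconstruct_phase(ds_load_stack(dataset, i))$delta_phi)
  names(phases) <- as.character(c(split$train_ids, split$val_ids))
  nstats <- phase_norm_stats(phases[as.character(split$train_ids)])
  load_pair <- function(i) {
    x <- resize_array(normalize_phase(phases[[as.character(i)]], nstats),
                      hw[1], hw[2])
    y <- resize_array(ds_load_brightfield(dataset, i), hw[1], hw[2])
    list(x = array(x, c(hw, 1L)), y = y)
  }
  pairs <- lapply(c(split$train_ids, split$val_ids), load_pair)
  names(pairs) <- names(phases)

  G <- build_generator(config$base_channels)
  D <- build_discriminator(config$base_channels)
  g_state <- adam_init(net_params(G))
  d_state <- adam_init(net_params(D))
  lam <- config$lambda_l1

  step_fn <- function(epoch) {
    losses <- c()
    for (batch in batch_schedule(split$train_ids, config$batch_size)) {
      gg <- dd <- NULL
      bloss <- 0
      for (i in batch) {
        p <- pairs[[as.character(i)]]
        ## generator forward (train mode), then discriminator on both pairs
        tg <- nn_tape()
        x_id <- tp_input(tg, p$x)
        fake_id <- gen_forward(tg, G, x_id, config$dropout, training = TRUE)
        fake <- tp_val(tg, fake_id)
        ## --- discriminator update (fake detached) ---
        td <- nn_tape()
        real_pair <- tp_input(td, array(c(p$x, p$y), c(hw, 4L)))
        fake_pair <- tp_input(td, array(c(p$x, fake), c(hw, 4L)))
        pr_id <- disc_forward(td, D, real_pair)
        pf_id <- disc_forward(td, D, fake_pair)
        pr <- clamp_prob(tp_val(td, pr_id))
        pf <- clamp_prob(tp_val(td, pf_id))
        ## D minimises -(mean log pr + mean log(1 - pf))
        gd <- tp_backward(td, list(
          list(id = pr_id, grad = -1 / (length(pr) * pr)),
          list(id = pf_id, grad = 1 / (length(pf) * (1 - pf)))))
        dd <- if (is.null(dd)) gd$params else Map(function(a, b)
          Map(`+`, a, b), dd, gd$params)
        ## --- generator update through the (pre-update) discriminator ---
        gxy <- op_concat(tg, x_id, fake_id)
        pg_id <- disc_forward(tg, D, gxy)
        pg <- clamp_prob(tp_val(tg, pg_id))
        l1g <- array(lam * sign(fake - p$y) / length(fake), dim(fake))
        gb <- tp_backward(tg, list(
          list(id = pg_id, grad = -1 / (length(pg) * (1 - pg))),
          list(id = fake_id, grad = l1g)))
        gp <- gb$params[grep("^g_", names(gb$params))]
        gg <- if (is.null(gg)) gp else Map(function(a, b)
          Map(`+`, a, b), gg, gp)
        bloss <- bloss + generator_objective(pg, fake, p$y, lam)
      }
      nb <- length(batch)
      dd <- lapply(dd, function(ps) lapply(ps, function(a) a / nb))
      gg <- lapply(gg, function(ps) lapply(ps, function(a) a / nb))
      up <- adam_step(net_params(D), dd, d_state, config$learning_rate)
      D <<- net_set_params(D, up$params); d_state <<- up$state
      up <- adam_step(net_params(G), gg, g_state, config$learning_rate)
      G <<- net_set_params(G, up$params); g_state <<- up$state
      losses <- c(losses, bloss / nb)
    }
    list(params = net_params(G), train_loss = mean(losses))
  }

  eval_fn <- function(epoch, params) {
    mean(vapply(split$val_ids, function(i) {
      p <- pairs[[as.character(i)]]
      t <- nn_tape()
      x_id <- tp_input(t, p$x)
      fk <- gen_forward(t, G, x_id, 0, training = FALSE)
      fake <- tp_val(t, fk)
      pf <- tp_val(t, disc_forward(t, D,
                                   tp_input(t, array(c(p$x, fake),
                                                     c(hw, 4L)))))
      generator_objective(pf, fake, p$y, lam)
    }, numeric(1)))
  }

  run <- training_run(config$max_epochs, config$patience, "min",
                      step_fn, eval_fn)
  G <- net_set_params(G, run$best_params)
  structure(list(generator = G, config = config, norm = nstats,
                 log = run$log, best_epoch = run$best_epoch,
                 best_val_loss = run$best_metric),
            class = "wbc_translator")
}

#' @export
print.wbc_translator <- function(x, ...) {
  cat(sprintf(
    "wbc_translator: %dx%d working size, best val loss %.4f (epoch %d/%d)\n",
    x$config$input_size[1], x$config$input_size[2], x$best_val_loss,
    x$best_epoch, nrow(x$log)))
  invisible(x)
}

#' Translate a phase map to a brightfield rendering
#'
#' @param object a `wbc_translator`.
#' @param phase `H x W` phase matrix (radians).
#' @param ... unused.
#' @return `(H, W, 3)` RGB array in `[0, 1]` at the input's resolution.
#' @export
predict.wbc_translator <- function(object, phase, ...) {
  hw <- object$config$input_size
  x <- resize_array(normalize_phase(phase, object$norm), hw[1], hw[2])
  t <- nn_tape()
  out <- tp_val(t, gen_forward(t, object$generator,
                               tp_input(t, array(x, c(hw, 1L))),
                               0, training = FALSE))
  resize_array(out, nrow(phase), ncol(phase))
}

#' Write a translator loss log as CSV
#'
#' @param model a `wbc_translator` (or any trainer result with `$log`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(model, path) {
  log <- model$log
  names(log) <- c("epoch", "train_loss", "val_loss")
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
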