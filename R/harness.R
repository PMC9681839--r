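# Shared early-stopping / checkpoint-selection loop used by all three
# trainers. The stopping rules differ only in the monitored metric and its
# direction: the detector stops when validation mAP has not increased for
# `patience` consecutive epochs and keeps the highest-mAP weights; the
# segmenter and translator stop when validation loss has not decreased and
# keep the lowest-loss weights.

#' Early-stopping training loop
#'
#' Runs `step_fn(epoch)` (one training epoch; returns
#' `list(params, train_loss)`) and `eval_fn(epoch, params)` (validation
#' metric) until `max_epochs` or until the metric has failed to improve
#' strictly for `patience` consecutive epochs. The returned snapshot is the
#' one with the best validation metric seen.
#'
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive non-improving epochs tolerated (`Inf` to
#'   disable early stopping).
#' @param mode `"max"` (higher metric is better) or `"min"`.
#' @param step_fn function(epoch) performing one epoch of updates.
#' @param eval_fn function(epoch, params) returning the validation metric.
#' @return list with `best_params`, `best_epoch`, `best_metric` and `log`
#'   (data.frame epoch/train_loss/val_metric).
#' @export
training_run <- function(max_epochs, patience, mode = c("max", "min"),
                         step_fn, eval_fn) {
  mode <- match.arg(mode)
  stopifnot(patience >= 1, max_epochs >= 1)
  best_metric <- if (mode == "max") -Inf else Inf
  best_params <- NULL
  best_epoch <- 0L
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_metric = numeric(0))
  for (e in seq_len(max_epochs)) {
    res <- step_fn(e)
    metric <- eval_fn(e, res$params)
    log <- rbind(log, data.frame(epoch = e,
                                 train_loss = res$train_loss,
                                 val_metric = metric))
    improved <- if (mode == "max") metric > best_metric else
      metric < best_metric
    if (improved) {
      best_metric <- metric
      best_params <- res$params
      best_epoch <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(best_params = best_params, best_epoch = best_epoch,
       best_metric = best_metric, log = log)
}

# Assemble a minibatch schedule over ids for one epoch.
batch_schedule <- function(ids, batch_size) {
  ids <- sample(ids)
  split(ids, ceiling(seq_along(ids) / batch_size))
}
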