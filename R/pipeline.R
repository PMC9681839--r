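# Orchestration of the full flow across the three image versions (slim,
# brightfield, translated) and the repeated train/val partitions: per
# repeat, train detector + segmenter (and translator in translated mode)
# on that repeat's split, predict boxes/masks on the fixed test set, fuse
# them into semantic maps and evaluate; finally majority-vote the
# per-repeat maps and evaluate the combined prediction.

#' Pipeline run configuration
#'
#' All stage seeds are derived from the single `seed` via named substreams
#' (stage x repeat), so a run is reproducible end to end.
#'
#' @param dataset_dir directory written by [make_dataset()].
#' @param image_version `"brightfield"`, `"slim"` or `"translated"`.
#' @param repeats indices of the dataset's train/val partitions to use.
#' @param translation a [translation_config()] (translated mode only).
#' @param detection a [detector_config()].
#' @param segmentation a [segmenter_config()].
#' @param seed master seed.
#' @param out_dir artifact directory (`NULL` = keep everything in memory).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dataset_dir,
                            image_version = c("brightfield", "slim",
                                              "translated"),
                            repeats = 1:5,
                            translation = translation_config(),
                            detection = detector_config(),
                            segmentation = segmenter_config(),
                            seed = 1, out_dir = NULL) {
  image_version <- match.arg(image_version)
  stopifnot(dir.exists(dataset_dir), length(repeats) >= 1)
  structure(list(dataset_dir = dataset_dir, image_version = image_version,
                 repeats = repeats, translation = translation,
                 detection = detection, segmentation = segmentation,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

version_loader <- function(config, dataset, split, repeat_idx) {
  switch(config$image_version,
    brightfield = loader_brightfield,
    slim = make_slim_loader(dataset, split$train_ids),
    translated = {
      tcfg <- config$translation
      tcfg$seed <- derive_seed(config$seed, "translate", repeat_idx)
      tr <- train_translator(dataset, split, tcfg)
      make_translated_loader(tr)
    })
}

#' Run the full pipeline
#'
#' For every requested repeat: train the stage models on that repeat's
#' train/val split of the chosen image version, predict detections, binary
#' masks and fused semantic maps on the fixed test set, and evaluate
#' (detection mAP; pooled pixel-wise macro F1). The per-repeat semantic
#' maps are then combined per test image by pixel-wise majority voting and
#' the combined maps evaluated per class.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: per-repeat scores, per-class voting F1 scores,
#'   mean +/- population-std aggregates, and the per-repeat artifacts.
#' @export
run_pipeline <- function(config) {
  ds <- smear_dataset(config$dataset_dir)
  test_ids <- ds$splits$test_ids
  sem_by_repeat <- list()
  per_repeat <- data.frame(repeat_idx = integer(0), map = numeric(0),
                           val_map = numeric(0), macro_f1 = numeric(0))
  gts <- lapply(test_ids, function(i) ds_load_semantic(ds, i))
  models <- list()
  for (r in config$repeats) {
    split <- ds$splits$repeats[[r]]
    if (!setequal(intersect(test_ids, c(split$train_ids, split$val_ids)),
                  integer(0))) {
      stop("test set leaks into the train/val split of repeat ", r)
    }
    loader <- version_loader(config, ds, split, r)
    dcfg <- config$detection
    dcfg$seed <- derive_seed(config$seed, "detect", r)
    det <- train_detector(ds, split, dcfg, loader)
    scfg <- config$segmentation
    scfg$seed <- derive_seed(config$seed, "segment", r)
    seg <- train_segmenter(ds, split, scfg, loader)

    dets_all <- list()
    sems <- list()
    for (j in seq_along(test_ids)) {
      i <- test_ids[j]
      img <- loader(ds, i)
      # low score cut for the ranking metric (mAP); the configured 0.5
      # operating point for the boxes that enter semantic fusion
      dets <- detect(det, img, score_threshold = 0.05)
      dets$image_id <- rep(i, nrow(dets))
      mask <- segment(seg, img)
      sems[[j]] <- fuse(mask, dets[dets$confidence >= 0.5, , drop = FALSE])
      dets_all[[j]] <- dets
    }
    dets_all <- do.call(rbind, dets_all)
    gt_boxes <- do.call(rbind, lapply(test_ids, function(i) {
      b <- ds_boxes(ds, i)
      b$image_id <- rep(i, nrow(b))
      b
    }))
    rep_map <- if (nrow(dets_all) == 0) 0 else
      evaluate_detections(dets_all, gt_boxes)$map
    rep_f1 <- macro_f1(pooled_pixel_scores(sems, gts))
    per_repeat <- rbind(per_repeat,
                        data.frame(repeat_idx = r, map = rep_map,
                                   val_map = det$best_val_map,
                                   macro_f1 = rep_f1))
    sem_by_repeat[[length(sem_by_repeat) + 1]] <- sems
    models[[length(models) + 1]] <- list(detector = det, segmenter = seg)
    if (!is.null(config$out_dir)) {
      persist_repeat(config$out_dir, r, test_ids, dets_all, sems,
                     rep_map, rep_f1)
    }
  }
  voted <- lapply(seq_along(test_ids), function(j) {
    majority_vote(lapply(sem_by_repeat, function(s) s[[j]]))
  })
  vote_scores <- pooled_pixel_scores(voted, gts)
  report <- structure(list(
    image_version = config$image_version,
    per_repeat = per_repeat,
    voting = vote_scores,
    voting_macro_f1 = macro_f1(vote_scores),
    aggregates = list(map = aggregate_scores(per_repeat$map),
                      macro_f1 = aggregate_scores(per_repeat$macro_f1)),
    test_ids = test_ids,
    models = models,
    semantic_maps = sem_by_repeat,
    voted_maps = voted), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

persist_repeat <- function(out_dir, r, test_ids, dets, sems, map, f1) {
  d <- file.path(out_dir, sprintf("repeat_%d", r))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(seq_len(nrow(dets)), function(i) {
      b <- dets[i, ]
      list(image_id = b$image_id, category_id = b$class,
           bbox = c(b$x_min, b$y_min, b$x_max - b$x_min,
                    b$y_max - b$y_min),
           score = b$confidence)
    }),
    file.path(d, "detections.json"), auto_unbox = TRUE, digits = NA)
  for (j in seq_along(test_ids)) {
    png::writePNG(sems[[j]] / 255,
                  file.path(d, sprintf("sem_%04d.png", test_ids[j])))
  }
  jsonlite::write_json(list(map = map, macro_f1 = f1),
                       file.path(d, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(image_version = report$image_version,
         per_repeat = report$per_repeat,
         voting = report$voting,
         voting_macro_f1 = report$voting_macro_f1,
         aggregates = report$aggregates),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s images, %d repeats, %d test images)\n",
              x$image_version, nrow(x$per_repeat), length(x$test_ids)))
  for (i in seq_len(nrow(x$per_repeat))) {
    cat(sprintf("  repeat %d: test mAP %.4f (val %.4f), macro F1 %.4f\n",
                x$per_repeat$repeat_idx[i], x$per_repeat$map[i],
                x$per_repeat$val_map[i], x$per_repeat$macro_f1[i]))
  }
  cat(sprintf("  mean mAP %.4f +/- %.3f; mean macro F1 %.4f +/- %.3f\n",
              x$aggregates$map$mean, x$aggregates$map$std,
              x$aggregates$macro_f1$mean, x$aggregates$macro_f1$std))
  cls <- c("background", WBC_CLASSES)
  cat("  majority voting F1:",
      paste(sprintf("%s %.3f", cls, x$voting$f1), collapse = ", "),
      sprintf("| average %.3f\n", x$voting_macro_f1))
  invisible(x)
}

#' Run the pipeline on all three image versions
#'
#' Executes [run_pipeline()] for slim, brightfield and translated inputs on
#' identical splits and seeds and combines the per-version rows.
#'
#' @param config a [pipeline_config()]; its `image_version` is ignored.
#' @return list of three `run_report`s plus a combined data.frame
#'   `comparison` (one row per version: per-repeat mAPs, mean, std).
#' @export
compare_versions <- function(config) {
  versions <- c("slim", "brightfield", "translated")
  reports <- lapply(versions, function(v) {
    cfg <- config
    cfg$image_version <- v
    if (!is.null(cfg$out_dir)) cfg$out_dir <- file.path(cfg$out_dir, v)
    run_pipeline(cfg)
  })
  names(reports) <- versions
  comparison <- do.call(rbind, lapply(versions, function(v) {
    r <- reports[[v]]
    row <- as.data.frame(as.list(stats::setNames(
      r$per_repeat$map, paste0("test", r$per_repeat$repeat_idx))))
    cbind(data.frame(version = v), row,
          data.frame(mean = r$aggregates$map$mean,
                     std = r$aggregates$map$std))
  }))
  list(reports = reports, comparison = comparison)
}

#' Reference per-test evaluation scores
#'
#' Published per-test / per-class scores of the cSLIM WBC study for the
#' three image versions, shipped as plain CSVs; used to validate the
#' summary-row aggregation conventions (arithmetic mean, population
#' standard deviation).
#'
#' @param table `"detection_map"` (per-test detection mAPs),
#'   `"semantic_f1"` (per-test semantic-segmentation F1) or `"voting_f1"`
#'   (per-class majority-voting F1).
#' @return data.frame with one row per image version.
#' @export
reference_scores <- function(table = c("detection_map", "semantic_f1",
                                       "voting_f1")) {
  table <- match.arg(table)
  path <- system.file("extdata", "reference", paste0(table, ".csv"),
                      package = "picswbc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
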