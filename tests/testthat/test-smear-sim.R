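# Synthetic smear generator: sampling, rendering invariants, forward model
# and dataset assembly.

test_that("class-count sampling is multinomial over the four WBC classes", {
  expect_equal(unname(sample_class_counts(0, c(0.25, 0.25, 0.25, 0.25))),
               rep(0L, 4))
  expect_equal(unname(sample_class_counts(7, c(1, 0, 0, 0))),
               c(7L, 0L, 0L, 0L))
  expect_error(sample_class_counts(5, c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  set.seed(100)
  priors <- c(0.50, 0.025, 0.30, 0.05) / 0.875
  n <- 10000
  cnt <- sample_class_counts(n, priors)
  se <- sqrt(priors * (1 - priors) / n)
  expect_true(all(abs(cnt / n - priors) <= 3 * se))
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- small_smear_config()
  a <- render_smear(cfg, seed = 31)
  b <- render_smear(cfg, seed = 31)
  expect_identical(a$phase_gt, b$phase_gt)
  expect_identical(a$brightfield, b$brightfield)
  expect_identical(a$boxes, b$boxes)
  expect_identical(a$stack$frames, b$stack$frames)
})

test_that("wbc_density = 0 yields an empty field annotation", {
  s <- render_smear(small_smear_config(wbc_density = 0), seed = 3)
  expect_equal(nrow(s$boxes), 0L)
  expect_true(all(s$binary_mask == 0L))
  expect_true(all(s$semantic_gt == 0L))
})

test_that("annotation invariants hold across rendered samples", {
  cfg <- small_smear_config()
  for (seed in 1:20) {
    s <- render_smear(cfg, seed = seed)
    # semantic labels exactly where the mask is foreground
    expect_identical(s$semantic_gt > 0L, s$binary_mask == 1L)
    expect_true(all(s$semantic_gt %in% 0:4))
    expect_true(all(s$boxes$class %in% 1:4))
    # every nonbackground connected component lies inside exactly one
    # box, whose class is the component's label
    comp <- EBImage::bwlabel(s$binary_mask)
    for (cid in setdiff(unique(as.vector(comp)), 0)) {
      px <- which(comp == cid, arr.ind = TRUE)
      k <- unique(s$semantic_gt[px])
      expect_length(k, 1)
      x0 <- min(px[, 2]) - 1L; x1 <- max(px[, 2])
      y0 <- min(px[, 1]) - 1L; y1 <- max(px[, 1])
      containing <- which(s$boxes$x_min <= x0 & s$boxes$x_max >= x1 &
                            s$boxes$y_min <= y0 & s$boxes$y_max >= y1)
      expect_length(containing, 1)
      expect_equal(s$boxes$class[containing], k)
    }
  }
})

test_that("empirical class fractions stay inside the population ranges", {
  cfg <- small_smear_config()
  set.seed(2024)
  counts <- integer(4)
  seed <- 0
  while (sum(counts) < 1000) {
    seed <- seed + 1
    s <- render_smear(cfg, seed = seed + 5000)
    counts <- counts + tabulate(s$boxes$class, nbins = 4)
  }
  n <- sum(counts)
  frac <- counts / n
  priors <- cfg$class_priors
  se <- sqrt(priors * (1 - priors) / n)
  expect_true(all(abs(frac - priors) <= 3 * se))
  # and inside the stated normal differential ranges (rescaled to 4 classes)
  lo <- c(0.40, 0.01, 0.20, 0.02) / 0.875 - 3 * se
  hi <- c(0.60, 0.04, 0.40, 0.08) / 0.875 + 3 * se
  expect_true(all(frac >= lo & frac <= hi))
})

test_that("cell interiors carry more phase than the background", {
  for (seed in c(8, 88)) {
    s <- render_smear(small_smear_config(), seed = seed)
    bg_median <- stats::median(s$phase_gt[s$binary_mask == 0L])
    expect_gt(stats::median(s$phase_gt[s$binary_mask == 1L]), bg_median)
    # every cell's own interior (eroded by the blur skirt) clears it too
    for (j in seq_len(nrow(s$boxes))) {
      b <- s$boxes[j, ]
      rows <- (b$y_min + 3):(b$y_max - 3) + 1L
      cols <- (b$x_min + 3):(b$x_max - 3) + 1L
      inside <- s$binary_mask[rows, cols] == 1L
      expect_gt(min(s$phase_gt[rows, cols][inside]), bg_median)
    }
  }
})

test_that("the forward model matches its closed form at zero phase", {
  st <- forward_interferograms(matrix(0, 2, 2), beta = 0.5)
  expect_equal(st$frames[[1]][, , 1], matrix(2.25, 2, 2))
  expect_equal(st$frames[[2]][, , 1], matrix(1.25, 2, 2), tolerance = 1e-12)
  expect_equal(st$frames[[3]][, , 1], matrix(0.25, 2, 2))
  expect_equal(st$frames[[4]][, , 1], matrix(1.25, 2, 2), tolerance = 1e-12)
})

test_that("a full-strength halo suppresses constant (DC) phase", {
  phi <- matrix(0.8, 32, 32)
  st <- forward_interferograms(phi, beta = 0.4, halo_strength = 1,
                               halo_sigma = 50)
  rec <- reconstruct_phase(st)
  expect_lt(max(abs(rec$delta_phi[8:24, 8:24])), 0.05)
})

test_that("split arithmetic follows the floor rule on the study sizes", {
  sp <- make_splits(504, 50, 8, 5, seed = 2)
  expect_equal(length(sp$test_ids), 50L)
  rem <- 504 - 50
  expect_equal(rem, 454)
  for (r in sp$repeats) {
    expect_equal(length(r$val_ids), 50L)     # floor(454 / 9)
    expect_equal(length(r$train_ids), 404L)
    expect_length(intersect(r$train_ids, r$val_ids), 0)
    expect_length(intersect(sp$test_ids, c(r$train_ids, r$val_ids)), 0)
    expect_setequal(c(sp$test_ids, r$train_ids, r$val_ids), 1:504)
  }
  # five distinct partitions of the same remainder
  expect_equal(length(sp$repeats), 5L)
  expect_gt(length(unique(lapply(sp$repeats, function(r) r$val_ids))), 1L)
})

test_that("datasets on disk round-trip images, masks and annotations", {
  ds <- fixture_dataset()
  expect_equal(ds$n_images, 32L)
  expect_error(make_dataset(ds$dir, n_images = 2, n_test = 1),
               "exists")
  i <- ds$splits$test_ids[1]
  s <- render_smear(small_smear_config(),
                    seed = picswbc:::derive_seed(424, "sample", i))
  expect_equal(picswbc:::ds_load_mask(ds, i), s$binary_mask,
               ignore_attr = TRUE)
  expect_equal(picswbc:::ds_load_semantic(ds, i), s$semantic_gt,
               ignore_attr = TRUE)
  expect_lt(max(abs(picswbc:::ds_load_phase(ds, i) - s$phase_gt)), 1e-4)
  b <- picswbc:::ds_boxes(ds, i)
  expect_equal(b[order(b$x_min), c("x_min", "class")],
               s$boxes[order(s$boxes$x_min), c("x_min", "class")],
               ignore_attr = TRUE)
  # stacks reload to within float32 quantisation
  st <- picswbc:::ds_load_stack(ds, i)
  expect_lt(max(abs(st$frames[[1]] - s$stack$frames[[1]])), 1e-5)
})
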