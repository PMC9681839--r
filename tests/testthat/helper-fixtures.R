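# Shared fixtures: a small smear configuration and a cached on-disk dataset
# so the trainer tests do not regenerate images per block.

small_smear_config <- function(...) {
  args <- utils::modifyList(
    list(field_size = c(96L, 96L), pixel_size = 0.5, rbc_density = 15,
         noise_sigma = 0.01),
    list(...))
  do.call(smear_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

# 32-image dataset (4 test, 2 repeats), built once per test session.
fixture_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    dir <- file.path(tempdir(), "picswbc-fixture-ds")
    unlink(dir, recursive = TRUE)
    .fixture_env$ds <- make_dataset(dir, n_images = 32, n_test = 4,
                                    n_repeats = 2,
                                    config = small_smear_config(),
                                    seed = 424)
  }
  .fixture_env$ds
}

# Forward model for a single pixel with explicit incident/scattered field.
pixel_frames <- function(ui, us, dphi) {
  lapply(0:3, function(k) {
    matrix(ui^2 + us^2 + 2 * ui * us * cos(dphi + k * pi / 2), 1, 1)
  })
}

random_phase_field <- function(n = 32, sigma = 2, amp = 0.8) {
  picswbc:::gaussian_blur(matrix(rnorm(n * n, 0, amp), n, n), sigma)
}
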