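# Finite-difference verification of the convolutional engine's gradients:
# every op's input gradient, conv/norm parameter gradients, and the full
# generator / U-Net graphs end to end.

pk <- asNamespace("picswbc")

num_input_grad <- function(fwd, x, seed_grad, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    (sum(fwd(x2) * seed_grad) - sum(fwd(x3) * seed_grad)) / (2 * eps)
  }, numeric(1))
}

test_that("every primitive op backpropagates its input exactly", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  conv <- pk$nn_conv(2, 3)
  convs2 <- pk$nn_conv(2, 2, k = 4, stride = 2, pad = 1)
  norm <- pk$nn_norm(2)
  builds <- list(
    conv = function(t, xi) pk$op_conv(t, conv, "c", xi),
    strided_conv = function(t, xi) pk$op_conv(t, convs2, "c", xi),
    norm = function(t, xi) pk$op_norm(t, norm, "n", xi),
    pool = function(t, xi) pk$op_pool(t, xi),
    up2 = function(t, xi) pk$op_up2(t, xi),
    concat = function(t, xi) pk$op_concat(t, xi, xi),
    relu = function(t, xi) pk$op_act(t, "relu", xi),
    lrelu = function(t, xi) pk$op_act(t, "lrelu", xi),
    sigmoid = function(t, xi) pk$op_act(t, "sigmoid", xi),
    tanh = function(t, xi) pk$op_act(t, "tanh", xi))
  for (nm in names(builds)) {
    run <- function(xx) {
      t <- pk$nn_tape()
      xi <- pk$tp_input(t, xx)
      o <- builds[[nm]](t, xi)
      list(t = t, o = o, xi = xi, y = pk$tp_val(t, o))
    }
    f <- run(x)
    seed_grad <- array(rnorm(length(f$y)), dim(f$y))
    gr <- pk$tp_backward(f$t, list(list(id = f$o, grad = seed_grad)))
    idx <- sample(length(x), 6)
    num <- num_input_grad(function(xx) run(xx)$y, x, seed_grad, idx)
    expect_equal(gr$inputs[[f$xi]][idx], num, tolerance = 1e-5,
                 label = paste("input grad of", nm))
  }
})

test_that("conv and norm parameter gradients match finite differences", {
  set.seed(6)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  net <- list(layers = list(c1 = pk$nn_conv(2, 3), n1 = pk$nn_norm(3),
                            c2 = pk$nn_conv(3, 1, k = 4, stride = 2,
                                            pad = 1)))
  run <- function(nn) {
    t <- pk$nn_tape()
    o <- pk$op_act(t, "sigmoid",
      pk$op_conv(t, nn$layers$c2, "c2",
        pk$op_act(t, "relu",
          pk$op_norm(t, nn$layers$n1, "n1",
            pk$op_conv(t, nn$layers$c1, "c1", pk$tp_input(t, x))))))
    list(t = t, o = o, y = pk$tp_val(t, o))
  }
  f <- run(net)
  seed_grad <- array(rnorm(length(f$y)), dim(f$y))
  gr <- pk$tp_backward(f$t, list(list(id = f$o, grad = seed_grad)))
  eps <- 1e-6
  for (sp in list(c("c1", "W"), c("c1", "b"), c("n1", "g"), c("n1", "b"),
                  c("c2", "W"), c("c2", "b"))) {
    arr <- net$layers[[sp[1]]][[sp[2]]]
    for (i in sample(length(arr), min(4, length(arr)))) {
      n2 <- net; n2$layers[[sp[1]]][[sp[2]]][i] <- arr[i] + eps
      n3 <- net; n3$layers[[sp[1]]][[sp[2]]][i] <- arr[i] - eps
      num <- (sum(run(n2)$y * seed_grad) - sum(run(n3)$y * seed_grad)) /
        (2 * eps)
      expect_equal(gr$params[[sp[1]]][[sp[2]]][i], num, tolerance = 1e-4,
                   label = paste(sp[1], sp[2], i))
    }
  }
})

test_that("generator and U-Net graphs backpropagate end to end", {
  set.seed(7)
  # generator: depth-3 encoder-decoder, 8x8 single-channel input
  G <- pk$build_generator(base = 2)
  x <- array(runif(8 * 8), c(8, 8, 1))
  runG <- function(net) {
    t <- pk$nn_tape()
    o <- pk$gen_forward(t, net, pk$tp_input(t, x), 0, FALSE)
    pk$tp_val(t, o)
  }
  t <- pk$nn_tape()
  o <- pk$gen_forward(t, G, pk$tp_input(t, x), 0, FALSE)
  y <- pk$tp_val(t, o)
  seed_grad <- array(rnorm(length(y)), dim(y))
  gr <- pk$tp_backward(t, list(list(id = o, grad = seed_grad)))
  eps <- 1e-6
  for (nm in c("g_e1", "g_d3", "g_out")) {
    i <- 3
    n2 <- G; n2$layers[[nm]]$W[i] <- n2$layers[[nm]]$W[i] + eps
    n3 <- G; n3$layers[[nm]]$W[i] <- n3$layers[[nm]]$W[i] - eps
    num <- (sum(runG(n2) * seed_grad) - sum(runG(n3) * seed_grad)) /
      (2 * eps)
    expect_equal(gr$params[[nm]]$W[i], num, tolerance = 1e-4, label = nm)
  }
  # U-Net: 5 contracting / 4 expanding blocks, 16x16 3-channel input
  U <- pk$build_unet(base = 2, convs_per_block = 1)
  xu <- array(runif(16 * 16 * 3), c(16, 16, 3))
  runU <- function(net) {
    t <- pk$nn_tape()
    pk$tp_val(t, pk$unet_forward(t, net, pk$tp_input(t, xu)))
  }
  t <- pk$nn_tape()
  o <- pk$unet_forward(t, U, pk$tp_input(t, xu))
  y <- pk$tp_val(t, o)
  expect_equal(dim(y), c(16, 16, 1))   # same spatial size out
  seed_grad <- array(rnorm(length(y)), dim(y))
  gr <- pk$tp_backward(t, list(list(id = o, grad = seed_grad)))
  for (nm in c("u_d1_1", "u_d5_1", "u_u2_1", "u_out")) {
    i <- 2
    n2 <- U; n2$layers[[nm]]$W[i] <- n2$layers[[nm]]$W[i] + eps
    n3 <- U; n3$layers[[nm]]$W[i] <- n3$layers[[nm]]$W[i] - eps
    num <- (sum(runU(n2) * seed_grad) - sum(runU(n3) * seed_grad)) /
      (2 * eps)
    expect_equal(gr$params[[nm]]$W[i], num, tolerance = 1e-4, label = nm)
  }
})

test_that("Adam minimises a simple least-squares conv objective", {
  set.seed(8)
  target_layer <- pk$nn_conv(1, 1)
  net <- list(layers = list(c = pk$nn_conv(1, 1)))
  x <- array(rnorm(12 * 12), c(12, 12, 1))
  tgt <- local({
    t <- pk$nn_tape()
    pk$tp_val(t, pk$op_conv(t, target_layer, "t", pk$tp_input(t, x)))
  })
  state <- pk$adam_init(pk$net_params(net))
  loss0 <- NULL
  for (it in 1:200) {
    t <- pk$nn_tape()
    o <- pk$op_conv(t, net$layers$c, "c", pk$tp_input(t, x))
    y <- pk$tp_val(t, o)
    if (is.null(loss0)) loss0 <- mean((y - tgt)^2)
    gr <- pk$tp_backward(t, list(list(
      id = o, grad = 2 * (y - tgt) / length(y))))
    up <- pk$adam_step(pk$net_params(net), gr$params, state, 0.05)
    net <- pk$net_set_params(net, up$params)
    state <- up$state
  }
  t <- pk$nn_tape()
  loss1 <- mean((pk$tp_val(t, pk$op_conv(t, net$layers$c, "c",
                                         pk$tp_input(t, x))) - tgt)^2)
  expect_lt(loss1, loss0 / 100)
})
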