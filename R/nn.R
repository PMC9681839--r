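# Minimal convolutional-network engine: forward ops recorded on a tape,
# gradients by reverse traversal. Arrays are (H, W, C); hot loops
# (im2col/col2im/pooling) live in src/convops.cpp. Only what the four
# networks in this package need: conv, instance-norm, relu/lrelu/sigmoid/
# tanh, 2x2 max-pool, nearest x2 upsample, channel concat, dropout, Adam.

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$vals <- list()
  t$ops <- list()
  t$n <- 0L
  t
}

tp_push <- function(tape, val, parents = integer(0), backward = NULL,
                    pname = NULL) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- val
  tape$ops[[tape$n]] <- list(parents = parents, backward = backward,
                             pname = pname)
  tape$n
}

tp_val <- function(tape, id) {
  force(id)   # id may be a call that pushes onto the tape
  tape$vals[[id]]
}

tp_input <- function(tape, x) tp_push(tape, x)

# seed_grads: list of (id, grad) pairs; returns param grads (named by layer)
# and per-node input grads.
tp_backward <- function(tape, seed_grads) {
  grads <- vector("list", tape$n)
  for (sg in seed_grads) {
    id <- sg$id
    grads[[id]] <- if (is.null(grads[[id]])) sg$grad else grads[[id]] + sg$grad
  }
  pgrads <- list()
  for (id in rev(seq_len(tape$n))) {
    g <- grads[[id]]
    op <- tape$ops[[id]]
    if (is.null(g) || is.null(op$backward)) next
    res <- op$backward(g)
    for (j in seq_along(op$parents)) {
      d <- res$dx[[j]]
      if (is.null(d)) next
      p <- op$parents[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) d else grads[[p]] + d
    }
    if (!is.null(res$dp)) {
      nm <- op$pname
      pgrads[[nm]] <- if (is.null(pgrads[[nm]])) res$dp else
        Map(`+`, pgrads[[nm]], res$dp)
    }
  }
  list(params = pgrads, inputs = grads)
}

## ---- layers (parameter containers) ----

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L) {
  fan_in <- k * k * in_ch
  list(kind = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch,
       W = matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch))
}

nn_norm <- function(ch) {
  list(kind = "norm", g = rep(1, ch), b = numeric(ch))
}

net_params <- function(net) {
  lapply(net$layers, function(l) l[intersect(c("W", "b", "g"), names(l))])
}

net_set_params <- function(net, params) {
  for (nm in names(params)) {
    for (f in names(params[[nm]])) net$layers[[nm]][[f]] <- params[[nm]][[f]]
  }
  net
}

## ---- tape ops ----

op_conv <- function(tape, layer, pname, x_id) {
  force(x_id)
  x <- tape$vals[[x_id]]
  d <- dim(x)
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (d[1] + 2 * p - k) %/% s + 1L
  Wo <- (d[2] + 2 * p - k) %/% s + 1L
  cols <- cpp_im2col(x, d[1], d[2], d[3], k, s, p)
  ymat <- cols %*% layer$W
  ymat <- ymat + rep(layer$b, each = nrow(ymat))
  y <- array(ymat, c(Ho, Wo, layer$out_ch))
  W <- layer$W
  bw <- function(dy) {
    dym <- matrix(dy, Ho * Wo, layer$out_ch)
    list(dx = list(cpp_col2im(tcrossprod(dym, W), d[1], d[2], d[3], k, s, p)),
         dp = list(W = crossprod(cols, dym), b = colSums(dym)))
  }
  tp_push(tape, y, x_id, bw, pname)
}

op_norm <- function(tape, layer, pname, x_id, eps = 1e-5) {
  force(x_id)
  x <- tape$vals[[x_id]]
  d <- dim(x)
  N <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, N, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = N)
  v <- colSums(xc * xc) / N
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = N)
  y <- array(xhat * rep(layer$g, each = N) + rep(layer$b, each = N), d)
  g <- layer$g
  bw <- function(dy) {
    dym <- matrix(dy, N, C)
    dxhat <- dym * rep(g, each = N)
    s1 <- colSums(dxhat) / N
    s2 <- colSums(dxhat * xhat) / N
    dx <- (dxhat - rep(s1, each = N) - xhat * rep(s2, each = N)) *
      rep(istd, each = N)
    list(dx = list(array(dx, d)),
         dp = list(g = colSums(dym * xhat), b = colSums(dym)))
  }
  tp_push(tape, y, x_id, bw, pname)
}

op_act <- function(tape, type, x_id, slope = 0.2) {
  force(x_id)
  x <- tape$vals[[x_id]]
  y <- switch(type,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, slope * x),
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    stop("unknown activation: ", type))
  bw <- switch(type,
    relu = function(dy) list(dx = list(dy * (x > 0))),
    lrelu = function(dy) list(dx = list(dy * ifelse(x > 0, 1, slope))),
    sigmoid = function(dy) list(dx = list(dy * y * (1 - y))),
    tanh = function(dy) list(dx = list(dy * (1 - y * y))))
  tp_push(tape, y, x_id, bw)
}

op_pool <- function(tape, x_id) {
  force(x_id)
  x <- tape$vals[[x_id]]
  d <- dim(x)
  r <- cpp_maxpool2(x, d[1], d[2], d[3])
  idx <- r$idx
  bw <- function(dy) {
    dx <- array(0, d)
    dx[idx] <- dy
    list(dx = list(dx))
  }
  tp_push(tape, r$y, x_id, bw)
}

op_up2 <- function(tape, x_id) {
  force(x_id)
  x <- tape$vals[[x_id]]
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  bw <- function(dy) {
    ho <- seq(1, 2 * d[1], 2); wo <- seq(1, 2 * d[2], 2)
    dx <- dy[ho, wo, , drop = FALSE] + dy[ho + 1, wo, , drop = FALSE] +
      dy[ho, wo + 1, , drop = FALSE] + dy[ho + 1, wo + 1, , drop = FALSE]
    list(dx = list(dx))
  }
  tp_push(tape, y, x_id, bw)
}

op_concat <- function(tape, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tape$vals[[a_id]]; b <- tape$vals[[b_id]]
  da <- dim(a); db <- dim(b)
  y <- array(c(a, b), c(da[1], da[2], da[3] + db[3]))
  bw <- function(dy) {
    list(dx = list(dy[, , seq_len(da[3]), drop = FALSE],
                   dy[, , da[3] + seq_len(db[3]), drop = FALSE]))
  }
  tp_push(tape, y, c(a_id, b_id), bw)
}

# Inverted dropout; the generator's stochastic input z is realised this way
# at train time (the pix2pix convention), identity at inference.
op_dropout <- function(tape, x_id, p, training) {
  force(x_id)
  if (!training || p <= 0) return(x_id)
  x <- tape$vals[[x_id]]
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  bw <- function(dy) list(dx = list(dy * mask))
  tp_push(tape, x * mask, x_id, bw)
}

## ---- optimiser ----

adam_init <- function(params) {
  zl <- lapply(params, function(ps) lapply(ps, function(a) a * 0))
  list(m = zl, v = zl, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g * g
      state$m[[nm]][[f]] <- m
      state$v[[nm]][[f]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

## ---- shared helpers ----

# Channel-replicate a single-channel array to 3 channels; pass 3-channel
# input through.
as_3ch <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  x
}

# Bilinear resize of an (H, W[, C]) array to (h, w).
resize_array <- function(x, h, w) {
  d2 <- length(dim(x)) == 2
  if (d2) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1] == h && dim(x)[2] == w) {
    return(if (d2) x[, , 1] else x)
  }
  y <- EBImage::resize(EBImage::Image(x, dim = dim(x)), w = h, h = w)
  y <- array(EBImage::imageData(y), c(h, w, dim(x)[3]))
  if (d2) y[, , 1] else y
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d2 <- length(dim(x)) == 2
  if (d2) x <- array(x, c(dim(x), 1L))
  radius <- 2 * ceiling(2 * sigma) + 1
  fit <- min(dim(x)[1], dim(x)[2])
  if (fit %% 2 == 0) fit <- fit - 1
  radius <- min(radius, fit)
  if (radius < 3) return(if (d2) x[, , 1] else x)
  y <- EBImage::gblur(EBImage::Image(x, dim = dim(x)), sigma = sigma,
                      radius = radius)
  y <- array(EBImage::imageData(y), dim(x))
  if (d2) y[, , 1] else y
}

# Deterministic sub-seed for a named pipeline stage; keeps values < 2^31.
derive_seed <- function(seed, stage, repeat_idx = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(stage, ":", repeat_idx))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}
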