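# Layer primitives. Feature tensors are (H, W, C, N) arrays; a batch of
# grayscale images is (H, W, 1, N). All gradients mirror parameter shapes.

# Fan-in-scaled uniform init: U(-g/sqrt(fan_in), g/sqrt(fan_in)). ReLU
# convolutions use the He gain (g = sqrt(6)); linear maps use g = 1.
init_uniform <- function(dims, fan_in, gain = 1) {
  b <- gain / sqrt(fan_in)
  array(runif(prod(dims), -b, b), dim = dims)
}

init_conv_block <- function(kh, kw, cin, cout, relu = TRUE) {
  g <- if (relu) sqrt(6) else 1
  list(type = "conv",
       params = list(W = init_uniform(c(kh, kw, cin, cout), kh * kw * cin, g),
                     b = numeric(cout)),
       relu = relu)
}

init_alpha_block <- function(cin, cout) {
  blk <- init_conv_block(5L, 5L, cin, cout, relu = TRUE)
  blk$type <- "conv_pool"
  blk
}

# Single-headed spatial self-attention over hypercolumns. Queries and keys
# are full-width (d_k = c) linear maps of the features; with gamma = TRUE the
# values are linearly transformed and a 1x1 output projection follows the
# aggregation, with gamma = FALSE the values are the raw features so every
# output channel receives the same spatial reweighting. The attended output
# enters through a residual with learnable scalar gain s, initialized to 0 so
# the layer starts as the identity.
init_sa_block <- function(c, gamma) {
  p <- list(Wq = init_uniform(c(c, c), c), bq = numeric(c),
            Wk = init_uniform(c(c, c), c), bk = numeric(c),
            s = 0)
  if (gamma) {
    p$Wv <- init_uniform(c(c, c), c); p$bv <- numeric(c)
    p$Wo <- init_uniform(c(c, c), c); p$bo <- numeric(c)
  }
  list(type = "sa", params = p, gamma = gamma)
}

# The readout starts near zero (gain 0.1): early predictions are then driven
# by learning rather than by random projections of hundreds of features,
# which matters most for the fully connected readout.
init_readout_block <- function(mode, side, c) {
  if (mode == "FCL") {
    list(type = "readout", mode = "FCL",
         params = list(W = init_uniform(c(side, side, c), side * side * c,
                                        gain = 0.1),
                       b = 0))
  } else {
    list(type = "readout", mode = "CTL",
         params = list(W = as.numeric(init_uniform(c, c, gain = 0.1)), b = 0))
  }
}

conv_forward <- function(block, x, keep_patches = TRUE) {
  r <- cpp_conv2d_fwd(x, block$params$W, block$params$b, block$relu,
                      keep_patches)
  list(out = r$out, x = x, p = r$p)
}

conv_backward <- function(block, cache, dout, need_dx = TRUE) {
  g <- cpp_conv2d_bwd(cache$x, block$params$W, dout,
                      if (block$relu) cache$out else NULL, cache$p, need_dx)
  list(grads = list(W = g$dw, b = g$db), dx = g$dx)
}

pool_forward <- function(x) cpp_maxpool2_fwd(x)

pool_backward <- function(cache, dout, xdim) {
  cpp_maxpool2_bwd(cache$idx, dout, as.integer(xdim))
}

# x: (h, w, c, N). Positions are flattened column-major: p = i + h*(j-1).
# The heavy lifting lives in C++ (cpp_sa_fwd / cpp_sa_bwd); the forward
# cache carries the per-image Q, K, attention and value intermediates.
sa_forward <- function(block, x) {
  p <- block$params
  r <- if (block$gamma)
    cpp_sa_fwd(x, p$Wq, p$bq, p$Wk, p$bk, p$s, TRUE, p$Wv, p$bv, p$Wo, p$bo)
  else
    cpp_sa_fwd(x, p$Wq, p$bq, p$Wk, p$bk, p$s, FALSE, NULL, NULL, NULL, NULL)
  r$dims <- dim(x)
  r$x <- x
  r
}

sa_backward <- function(block, cache, dout, need_dx = TRUE) {
  p <- block$params
  r <- cpp_sa_bwd(cache$x, p$Wq, p$Wk, p$s, block$gamma,
                  if (block$gamma) p$Wv else NULL,
                  if (block$gamma) p$Wo else NULL, cache, dout, need_dx)
  g <- r$grads
  for (pn in names(g))
    if (is.null(dim(p[[pn]]))) g[[pn]] <- as.numeric(g[[pn]])
  list(grads = g, dx = r$dx)
}

# Readouts use colSums-based dot products so that a fully connected readout
# whose off-center weights are exactly zero reproduces the center-only
# readout bit-for-bit (zero summands do not perturb the accumulation).
readout_forward <- function(block, x) {
  d <- dim(x)
  n <- d[4]
  if (block$mode == "FCL") {
    feat <- matrix(x, prod(d[1:3]), n)
    pred <- colSums(feat * as.vector(block$params$W)) + block$params$b
  } else {
    ic <- d[1] %/% 2 + 1; jc <- d[2] %/% 2 + 1
    feat <- matrix(x[ic, jc, , , drop = FALSE], d[3], n)
    pred <- colSums(feat * block$params$W) + block$params$b
  }
  list(pred = pred, x = x, dims = d)
}

readout_backward <- function(block, cache, dpred, need_dx = TRUE) {
  d <- cache$dims
  n <- d[4]
  if (block$mode == "FCL") {
    feat <- matrix(cache$x, prod(d[1:3]), n)
    dW <- array(feat %*% dpred, dim = d[1:3])
    dx <- NULL
    if (need_dx) dx <- array(outer(as.vector(block$params$W), dpred), dim = d)
  } else {
    ic <- d[1] %/% 2 + 1; jc <- d[2] %/% 2 + 1
    feat <- matrix(cache$x[ic, jc, , , drop = FALSE], d[3], n)
    dW <- as.vector(feat %*% dpred)
    dx <- NULL
    if (need_dx) {
      dx <- array(0, dim = d)
      dx[ic, jc, , ] <- outer(block$params$W, dpred)
    }
  }
  list(grads = list(W = dW, b = sum(dpred)), dx = dx)
}
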