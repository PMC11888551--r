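#' Assemble an encoding model from its spec
#'
#' Builds the block sequence `alpha1, alpha2, [sa], beta1, beta2, readout`.
#' Alpha blocks are valid 5x5 convolutions (ReLU) followed by 2x2 max pooling
#' with stride 2; beta blocks are valid `k x k` convolutions (ReLU) with no
#' pooling; the readout is linear and emits one scalar per image (one model is
#' fitted per neuron). Weights are drawn from a fan-in-scaled uniform
#' distribution controlled by `seed`; the self-attention residual gain starts
#' at 0 so an attention model is exactly its feedforward trunk at
#' initialization.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `sacnn_model`.
#' @examples
#' m <- assemble_model(model_spec("rf", channels_c = 4), seed = 1)
#' predict(m, array(runif(50 * 50), c(50, 50, 1)))
#' @export
assemble_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sacnn_spec"))
  side <- readout_side(spec)  # errors if input_side is too small
  c <- spec$channels_c
  k <- spec$beta_kernel_k
  blocks <- with_seed(seed, {
    b <- list(alpha1 = init_alpha_block(1L, c),
              alpha2 = init_alpha_block(c, c))
    if (spec$sa_present) b$sa <- init_sa_block(c, spec$sa_gamma)
    b$beta1 <- init_conv_block(k, k, c, c, relu = TRUE)
    b$beta2 <- init_conv_block(k, k, c, c, relu = TRUE)
    b$readout <- init_readout_block(spec$readout, side, c)
    b
  })
  structure(list(spec = spec, blocks = blocks, seed = as.integer(seed)),
            class = "sacnn_model")
}

#' @export
print.sacnn_model <- function(x, ...) {
  cat("<sacnn_model> ", x$spec$family, " (c=", x$spec$channels_c,
      ", input ", x$spec$input_side, "x", x$spec$input_side, ", ",
      count_parameters(x), " parameters)\n", sep = "")
  cat("  blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  invisible(x)
}

block_ids <- function(model) names(model$blocks)

# Pixel intensities are on a [0, 1] scale; inputs are shifted to zero-mean
# (midpoint subtraction) before entering the network. A constant shift does
# not change any input gradient or receptive-field measure.
input_shift <- 0.5

# Coerce stimuli to a (H, W, 1, N) batch array.
as_batch <- function(x) {
  if (inherits(x, "sacnn_stimuli")) x <- x$images
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("stimuli must be an array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) x <- array(x, c(d[1], d[2], 1L, d[3]))
  else if (length(d) != 4) stop("stimuli must be (H, W[, N]) or (H, W, 1, N)")
  if (any(!is.finite(x))) stop("non-finite values in stimuli")
  x
}

model_forward <- function(model, x, keep_cache = FALSE) {
  x <- as_batch(x) - input_shift
  cache <- list(input = x)
  h <- x
  for (id in block_ids(model)) {
    blk <- model$blocks[[id]]
    cc <- switch(blk$type,
      conv_pool = {
        cv <- conv_forward(blk, h, keep_patches = keep_cache)
        pl <- pool_forward(cv$out)
        list(conv = cv, pool = pl)
      },
      conv = conv_forward(blk, h, keep_patches = keep_cache),
      sa = sa_forward(blk, h),
      readout = readout_forward(blk, h))
    h <- switch(blk$type, conv_pool = cc$pool$out, conv = cc$out,
                sa = cc$out, readout = cc$pred)
    if (keep_cache) cache[[id]] <- cc
    else if (blk$type != "readout") cache[[id]] <- NULL
  }
  list(pred = h, cache = if (keep_cache) cache else NULL)
}

# dpred: numeric vector, one entry per image. Returns per-block parameter
# gradients, and the input gradient when need_dx is TRUE.
model_backward <- function(model, cache, dpred, need_dx = FALSE) {
  ids <- rev(block_ids(model))
  grads <- list()
  dh <- dpred
  for (pos in seq_along(ids)) {
    id <- ids[pos]
    blk <- model$blocks[[id]]
    cc <- cache[[id]]
    last <- pos == length(ids)
    want_dx <- !last || need_dx
    res <- switch(blk$type,
      readout = readout_backward(blk, cc, dh, want_dx),
      sa = sa_backward(blk, cc, dh, want_dx),
      conv = conv_backward(blk, cc, dh, want_dx),
      conv_pool = {
        dconv <- pool_backward(cc$pool, dh, dim(cc$conv$out))
        conv_backward(blk, cc$conv, dconv, want_dx)
      })
    grads[[id]] <- res$grads
    dh <- res$dx
  }
  list(grads = grads, dx = if (need_dx) dh else NULL)
}

#' Predict responses for a stimulus batch
#'
#' @param object A `sacnn_model`.
#' @param stimuli A (H, W) image, (H, W, N) stack, or [generate_stimuli()]
#'   output.
#' @param clip Clip predictions at zero (reporting convenience; training and
#'   metrics use raw predictions).
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.sacnn_model <- function(object, stimuli, clip = FALSE,
                                batch_size = 100L, ...) {
  x <- as_batch(stimuli)
  n <- dim(x)[4]
  pred <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    pred[ix] <- model_forward(object, x[, , , ix, drop = FALSE])$pred
  }
  if (clip) pred <- pmax(pred, 0)
  pred
}

#' Forward pass through the alpha stack only
#'
#' @param model A `sacnn_model`.
#' @param stimuli Image(s), coerced as in [predict.sacnn_model()].
#' @return A (h', w', c, N) feature array.
#' @export
alpha_stack_forward <- function(model, stimuli) {
  x <- as_batch(stimuli) - input_shift
  h <- pool_forward(conv_forward(model$blocks$alpha1, x, FALSE)$out)$out
  pool_forward(conv_forward(model$blocks$alpha2, h, FALSE)$out)$out
}

#' Count model parameters
#'
#' @param model A `sacnn_model`.
#' @param per_block If `TRUE`, return a data frame of block descriptors
#'   (block id, trainable flag, parameter count); per-block counts sum to the
#'   total.
#' @return Integer total, or a data.frame when `per_block = TRUE`.
#' @export
count_parameters <- function(model, per_block = FALSE) {
  counts <- vapply(model$blocks, function(b)
    sum(vapply(b$params, length, integer(1))), integer(1))
  if (!per_block) return(sum(counts))
  data.frame(block_id = names(counts), trainable = TRUE,
             parameter_count = unname(counts), row.names = NULL)
}

#' Theoretical receptive-field support of the center readout unit
#'
#' Composes the layer geometry backwards (convolution kernel growth, pooling
#' stride doubling) to give the side of the square input region that can
#' influence the center hypercolumn. For the alpha stack alone this is 16
#' pixels; 1x1 beta convolutions and a center readout add nothing.
#'
#' @param spec A [model_spec()].
#' @param upto `"readout"` (default) or `"alpha2"` for the post-alpha-stack
#'   hypercolumn.
#' @return Integer side in pixels.
#' @export
theoretical_rf_side <- function(spec, upto = c("readout", "alpha2")) {
  upto <- match.arg(upto)
  layers <- list(c(5, 1), c(2, 2), c(5, 1), c(2, 2))  # (kernel, stride)
  if (upto == "readout" && spec$beta_kernel_k > 1)
    layers <- c(layers, list(c(spec$beta_kernel_k, 1),
                             c(spec$beta_kernel_k, 1)))
  size <- 1
  for (ly in rev(layers)) size <- (size - 1) * ly[2] + ly[1]
  as.integer(size)
}

#' Empirical receptive-field support from input gradients
#'
#' Computes the gradient of the scalar output (or of the summed center
#' hypercolumn activation after the alpha stack) with respect to the input,
#' maximizes its magnitude over a batch of random probe images, and returns
#' the bounding box of pixels with non-negligible gradient. Also reports the
#' half-height extent of the row/column profiles, since an empirical
#' receptive-field "size" in physiology is typically a half-height measure
#' and is smaller than the full anatomical support.
#'
#' @param model A `sacnn_model`.
#' @param n_probe Number of random probe images.
#' @param seed Seed for the probes.
#' @param tol Relative gradient-magnitude threshold for "nonzero".
#' @return A list with `box` (row/col ranges), `side` (max box side),
#'   `half_height_side`, and the (H, W) gradient-magnitude `map`.
#' @export
effective_rf_support <- function(model, n_probe = 8L, seed = 1L,
                                 tol = 1e-10) {
  side <- model$spec$input_side
  x <- with_seed(seed, array(runif(side * side * n_probe), c(side, side, 1, n_probe)))
  fw <- model_forward(model, x, keep_cache = TRUE)
  bw <- model_backward(model, fw$cache, rep(1, n_probe), need_dx = TRUE)
  g <- abs(bw$dx)
  map <- apply(g, c(1, 2), max)
  mx <- max(map)
  if (mx == 0) stop("zero gradient everywhere; model not differentiable here")
  nz <- which(map > tol * mx, arr.ind = TRUE)
  box <- list(rows = range(nz[, 1]), cols = range(nz[, 2]))
  rows_p <- apply(map, 1, max); cols_p <- apply(map, 2, max)
  hh <- function(p) sum(p >= max(p) / 2)
  list(box = box,
       side = max(diff(box$rows), diff(box$cols)) + 1L,
       half_height_side = max(hh(rows_p), hh(cols_p)),
       map = map)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (spec + named parameter tensors)
#' stored with `saveRDS`.
#'
#' @param model A `sacnn_model`.
#' @param path File path.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sacnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sacnn_model"))
  m
}
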