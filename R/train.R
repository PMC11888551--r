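#' Training configuration
#'
#' Fixed per-neuron fitting hyperparameters: minibatch Adam on mean squared
#' error. Defaults are the reference settings used throughout (batch size 50,
#' learning rate 0.001, 50 epochs); experiments at desk scale typically lower
#' `epochs`.
#'
#' @param batch_size Images per minibatch.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"`.
#' @param loss Only `"mse"`.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling (and, via [train_model()]
#'   callers, initialization).
#' @return A `sacnn_train_config`.
#' @export
train_config <- function(batch_size = 50L, learning_rate = 0.001,
                         optimizer = "adam", loss = "mse", epochs = 50L,
                         seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "mse")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "sacnn_train_config")
}

adam_init <- function(blocks) {
  lapply(blocks, function(b) lapply(b$params, function(p) {
    z <- p; z[] <- 0; list(m = z, v = z)
  }))
}

# One Adam step over all trainable tensors. Frozen blocks are skipped
# entirely (bit-identity); a block-level $freeze_mask (1 = frozen entry)
# zeroes individual updates, used by the FC1 readout stage.
adam_step <- function(model, grads, state, t, lr, frozen,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (id in block_ids(model)) {
    if (id %in% frozen) next
    blk <- model$blocks[[id]]
    for (pn in names(blk$params)) {
      g <- grads[[id]][[pn]]
      st <- state[[id]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      delta <- lr * mh / (sqrt(vh) + eps)
      mask <- blk$freeze_mask[[pn]]
      if (!is.null(mask)) delta[mask == 1] <- 0
      model$blocks[[id]]$params[[pn]] <- blk$params[[pn]] - delta
      state[[id]][[pn]] <- st
    }
  }
  list(model = model, state = state)
}

#' Fit a model to one neuron's responses
#'
#' Minibatch Adam on MSE between the scalar model output and the single-trial
#' responses, with optional block freezing. The run is reproducible: the same
#' (model, data, config) triple always yields the same trained weights.
#'
#' @param model A `sacnn_model`.
#' @param stimuli Training images, (H, W, N) array or [generate_stimuli()]
#'   output.
#' @param responses Numeric vector, one response per training image.
#' @param config A [train_config()].
#' @param frozen_blocks Character vector of block ids whose parameters must
#'   not change (verified bit-exactly on exit).
#' @return A list with `model` (trained) and `history` (mean training MSE per
#'   epoch).
#' @export
train_model <- function(model, stimuli, responses, config = train_config(),
                        frozen_blocks = character()) {
  x <- as_batch(stimuli)
  n <- dim(x)[4]
  if (n == 0) stop("empty training set")
  responses <- as.numeric(responses)
  if (length(responses) != n)
    stop("need exactly one response per training image (", n, " images, ",
         length(responses), " responses)")
  if (any(!is.finite(responses))) stop("non-finite responses")
  bad <- setdiff(frozen_blocks, block_ids(model))
  if (length(bad)) stop("frozen block(s) not in model: ",
                        paste(bad, collapse = ", "))
  pre <- lapply(model$blocks[frozen_blocks], `[[`, "params")

  state <- adam_init(model$blocks)
  history <- numeric(config$epochs)
  t <- 0
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      sse <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- perm[start:min(start + config$batch_size - 1, n)]
        xb <- x[, , , ix, drop = FALSE]
        yb <- responses[ix]
        fw <- model_forward(model, xb, keep_cache = TRUE)
        resid <- fw$pred - yb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch,
               " (first image index ", ix[1], "); try a smaller learning rate")
        sse <- sse + sum(resid^2)
        bw <- model_backward(model, fw$cache, 2 * resid / length(ix))
        t <- t + 1
        up <- adam_step(model, bw$grads, state, t, config$learning_rate,
                        frozen_blocks)
        model <- up$model
        state <- up$state
      }
      history[epoch] <- sse / n
    }
  })
  post <- lapply(model$blocks[frozen_blocks], `[[`, "params")
  if (!identical(pre, post))
    stop("internal error: frozen blocks changed during training")
  list(model = model, history = history)
}
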