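#' Decompose linear-readout predictions into center and surround
#'
#' For a model with a linear readout, every prediction is an exact sum of the
#' contribution flowing through the center hypercolumn, the contribution from
#' all other (surround) hypercolumns, and the readout bias. For a CTL model
#' the surround series is identically zero.
#'
#' @param model A `sacnn_model`.
#' @param stimuli Images to decompose over.
#' @return A `sacnn_decomposition` list: per-image `center`, `surround`,
#'   scalar `bias`, and `total` (= model predictions).
#' @export
decompose_readout <- function(model, stimuli) {
  ro <- model$blocks$readout
  if (is.null(ro) || ro$type != "readout")
    stop("model has no linear readout")
  x <- as_batch(stimuli)
  feats <- pre_readout_features(model, x)
  d <- dim(feats)
  ic <- d[1] %/% 2 + 1; jc <- d[2] %/% 2 + 1
  if (ro$mode == "CTL") {
    centerfeat <- matrix(feats[ic, jc, , , drop = FALSE], d[3], d[4])
    center <- colSums(centerfeat * ro$params$W)
    surround <- rep(0, d[4])
  } else {
    wc <- array(0, d[1:3]); wc[ic, jc, ] <- ro$params$W[ic, jc, ]
    ws <- ro$params$W; ws[ic, jc, ] <- 0
    fm <- matrix(feats, prod(d[1:3]), d[4])
    center <- colSums(fm * as.vector(wc))
    surround <- colSums(fm * as.vector(ws))
  }
  structure(list(center = center, surround = surround, bias = ro$params$b,
                 total = center + surround + ro$params$b),
            class = "sacnn_decomposition")
}

# Features entering the readout, (h', w', c, N).
pre_readout_features <- function(model, x) {
  h <- as_batch(x) - input_shift
  for (id in setdiff(block_ids(model), "readout")) {
    blk <- model$blocks[[id]]
    h <- switch(blk$type,
                conv_pool = pool_forward(conv_forward(blk, h, FALSE)$out)$out,
                conv = conv_forward(blk, h, FALSE)$out,
                sa = sa_forward(blk, h)$out)
  }
  h
}

#' Per-hypercolumn readout weight map
#'
#' Reduces the readout weights across channels at each spatial position. The
#' default reduction is the sum of absolute weights (a signed sum lets
#' positive and negative channel weights cancel and can hide structure); the
#' signed sum is also available. CTL maps are zero everywhere off center.
#'
#' @param model A `sacnn_model` with a linear readout.
#' @param reduction `"sum_abs"` or `"sum"`.
#' @return An `h' x w'` matrix.
#' @export
readout_weight_map <- function(model, reduction = c("sum_abs", "sum")) {
  reduction <- match.arg(reduction)
  ro <- model$blocks$readout
  f <- if (reduction == "sum_abs") function(v) sum(abs(v)) else sum
  side <- readout_side(model$spec)
  if (ro$mode == "CTL") {
    m <- matrix(0, side, side)
    m[side %/% 2 + 1, side %/% 2 + 1] <- f(ro$params$W)
    m
  } else {
    apply(ro$params$W, c(1, 2), f)
  }
}

#' Attention map for one image and query position
#'
#' Returns the row of the self-attention softmax matrix for the given query
#' hypercolumn: a nonnegative `h x w` map summing to 1 that shows where that
#' position attends on this image.
#'
#' @param model A `sacnn_model` with a self-attention block.
#' @param image A single (H, W) image.
#' @param query_position Integer `c(row, col)` (1-based) in the post-alpha
#'   feature map; defaults to the center hypercolumn.
#' @return An `h x w` matrix of attention weights.
#' @export
attention_map <- function(model, image, query_position = NULL) {
  if (!"sa" %in% block_ids(model))
    stop("model has no self-attention block")
  x <- as_batch(image) - input_shift
  if (dim(x)[4] != 1) stop("attention_map expects a single image")
  h <- pool_forward(conv_forward(model$blocks$alpha1, x, FALSE)$out)$out
  h <- pool_forward(conv_forward(model$blocks$alpha2, h, FALSE)$out)$out
  sa <- sa_forward(model$blocks$sa, h)
  hw <- dim(h)[1:2]
  if (is.null(query_position))
    query_position <- c(hw[1] %/% 2 + 1, hw[2] %/% 2 + 1)
  if (any(query_position < 1) || query_position[1] > hw[1] ||
      query_position[2] > hw[2]) stop("query_position out of range")
  np <- hw[1] * hw[2]
  A <- matrix(sa$A[seq_len(np * np)], np, np)
  pos <- query_position[1] + hw[1] * (query_position[2] - 1)
  matrix(A[pos, ], hw[1], hw[2])
}

#' SmoothGrad input-space saliency
#'
#' Mean absolute gradient of the scalar output with respect to the input,
#' averaged over `n_samples` noisy copies of each image and over images.
#' With `n_samples = 1` and `noise_sd = 0` this is the plain absolute
#' gradient.
#'
#' @param model A `sacnn_model`.
#' @param images (H, W, N) stimulus stack (or a single image).
#' @param n_samples Noisy samples per image.
#' @param noise_sd Gaussian noise standard deviation, in image-intensity
#'   units. Default: 10% of the dynamic range of `images`.
#' @param seed RNG seed.
#' @return An (H, W) saliency matrix.
#' @export
smoothgrad_rf <- function(model, images, n_samples = 20L, noise_sd = NULL,
                          seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  x <- as_batch(images)
  if (is.null(noise_sd)) noise_sd <- 0.1 * diff(range(x))
  d <- dim(x)
  acc <- matrix(0, d[1], d[2])
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      xs <- if (noise_sd > 0) x + array(rnorm(length(x), 0, noise_sd), d)
            else x
      fw <- model_forward(model, xs, keep_cache = TRUE)
      bw <- model_backward(model, fw$cache, rep(1, d[4]), need_dx = TRUE)
      acc <- acc + apply(abs(bw$dx), c(1, 2), mean)
    }
  })
  acc / n_samples
}

#' Population-average rank-ordered decomposition curves
#'
#' For each neuron's decomposition, the center, surround and total series
#' are rank ordered by predicted response and then averaged across neurons
#' image-rank by image-rank, optionally normalizing each neuron's curves by
#' its own peak prediction first.
#'
#' @param decompositions A list of [decompose_readout()] results (one per
#'   neuron), all over the same number of images.
#' @param normalize `"none"` (average on the raw scale) or `"peak"`
#'   (divide each neuron's curves by its maximum total prediction).
#' @return A data frame with columns `rank`, `center`, `surround`, `total`.
#' @export
average_decompositions <- function(decompositions,
                                   normalize = c("none", "peak")) {
  normalize <- match.arg(normalize)
  stopifnot(length(decompositions) >= 1,
            all(vapply(decompositions, inherits, logical(1),
                       "sacnn_decomposition")))
  n <- length(decompositions[[1]]$total)
  acc <- matrix(0, n, 3)
  for (dec in decompositions) {
    if (length(dec$total) != n) stop("decompositions differ in length")
    ord <- order(-dec$total, seq_along(dec$total))
    sc <- if (normalize == "peak") max(abs(dec$total)) else 1
    if (sc == 0) sc <- 1
    acc <- acc + cbind(dec$center[ord], dec$surround[ord],
                       dec$total[ord]) / sc
  }
  acc <- acc / length(decompositions)
  data.frame(rank = seq_len(n), center = acc[, 1], surround = acc[, 2],
             total = acc[, 3])
}
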