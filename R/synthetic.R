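# Synthetic V1 scene: stimuli with natural-image-like statistics and
# ground-truth Gabor-energy neurons whose surround modulation can be switched
# on and off, so center/surround dissociation experiments run without
# recorded data.

#' Generate a seeded stimulus set
#'
#' `pink_noise` images have an approximately 1/f amplitude spectrum (the
#' canonical second-order statistic of natural images); `oriented_texture`
#' scatters localized oriented Gabor elements on a gray background;
#' `mixed` alternates the two. Images are min-max normalized to `[0, 1]`.
#' Regeneration from the same `(kind, n, side, seed)` is bit-identical.
#'
#' @param n Number of images.
#' @param side Image side in pixels.
#' @param kind `"pink_noise"`, `"oriented_texture"` or `"mixed"`.
#' @param seed RNG seed.
#' @param pixels_per_degree Metadata carried with the set (default 15, the
#'   working resolution after 2x downsampling of 30 px/deg stimuli).
#' @return A `sacnn_stimuli` list: `images` (side, side, n), plus metadata.
#' @export
generate_stimuli <- function(n, side = 50L, kind = c("pink_noise",
                                                     "oriented_texture",
                                                     "mixed"),
                             seed = 1L, pixels_per_degree = 15) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, side >= 4)
  images <- with_seed(seed, {
    arr <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
      img <- switch(kind,
        pink_noise = pink_noise_image(side),
        oriented_texture = oriented_texture_image(side),
        mixed = if (i %% 2 == 1) pink_noise_image(side)
                else oriented_texture_image(side))
      rng <- range(img)
      if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
      arr[, , i] <- img
    }
    arr
  })
  structure(list(images = images, pixels_per_degree = pixels_per_degree,
                 kind = kind, side = as.integer(side), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sacnn_stimuli")
}

pink_noise_image <- function(side) {
  w <- matrix(rnorm(side * side), side, side)
  fx <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  f <- sqrt(outer(fx^2, fx^2, `+`))
  f[1, 1] <- 1 / side  # keep the DC term finite
  Re(fft(fft(w) / f, inverse = TRUE)) / (side * side)
}

oriented_texture_image <- function(side, n_elements = 40L) {
  img <- matrix(0, side, side)
  xs <- runif(n_elements, 1, side)
  ys <- runif(n_elements, 1, side)
  ths <- runif(n_elements, 0, pi)
  sfs <- runif(n_elements, 0.1, 0.25)
  amps <- runif(n_elements, 0.5, 1)
  co <- col(img); ro <- row(img)
  for (e in seq_len(n_elements)) {
    dx <- co - xs[e]; dy <- ro - ys[e]
    env <- exp(-(dx^2 + dy^2) / (2 * 2^2))
    carrier <- cos(2 * pi * sfs[e] * (dx * cos(ths[e]) + dy * sin(ths[e])))
    img <- img + amps[e] * env * carrier
  }
  img
}

#' Block-average downsampling with resolution metadata
#'
#' Averages `factor x factor` pixel blocks and divides the pixels-per-degree
#' metadata accordingly: 100x100 stimuli at 30 px/deg downsampled 2x become
#' 50x50 at 15 px/deg.
#'
#' @param stimuli A `sacnn_stimuli`.
#' @param factor Integer downsampling factor.
#' @return A `sacnn_stimuli` at the reduced resolution.
#' @export
downsample_stimuli <- function(stimuli, factor = 2L) {
  stopifnot(inherits(stimuli, "sacnn_stimuli"), factor >= 1)
  side <- stimuli$side
  if (side %% factor != 0) stop("side not divisible by factor")
  s2 <- side %/% factor
  imgs <- stimuli$images
  out <- array(0, c(s2, s2, stimuli$n))
  for (i in seq_len(stimuli$n)) {
    m <- imgs[, , i]
    dim(m) <- c(factor, s2, factor, s2)
    out[, , i] <- apply(m, c(2, 4), mean)
  }
  structure(list(images = out,
                 pixels_per_degree = stimuli$pixels_per_degree / factor,
                 kind = stimuli$kind, side = s2, n = stimuli$n,
                 seed = stimuli$seed),
            class = "sacnn_stimuli")
}

# Zero-mean, unit-norm Gabor patch on a side x side canvas. `box_halfwidth`
# truncates the filter to a square box around its own center (used for the
# classical-RF filters so that, with zero surround gains, the response
# depends on the central patch exactly, Gaussian tails included).
# `exclude_center_halfwidth` instead zeroes the filter inside a square box
# around the IMAGE center (used for the contextual filters, so that flank
# and surround energies draw on pixels strictly outside the classical RF).
gabor_patch <- function(side, cx, cy, theta, sf, sigma, phase,
                        box_halfwidth = Inf, exclude_center_halfwidth = 0) {
  x <- matrix(rep(seq_len(side), each = side), side, side)  # column coord
  y <- matrix(rep(seq_len(side), times = side), side, side) # row coord
  dx <- x - cx; dy <- y - cy
  env <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  g <- env * cos(2 * pi * sf * (dx * cos(theta) + dy * sin(theta)) + phase)
  ic <- (side + 1) / 2
  inside <- abs(dx) <= box_halfwidth & abs(dy) <= box_halfwidth &
    (abs(x - ic) > exclude_center_halfwidth |
     abs(y - ic) > exclude_center_halfwidth)
  g[!inside] <- 0
  g[inside] <- g[inside] - mean(g[inside])
  g / sqrt(sum(g^2))
}

# Half-width of the square box confining a neuron's classical receptive
# field around the image center (pixels on either side of the center point;
# spans 14 pixels on an even-sided canvas, covering the central ~13x13 patch).
center_box_halfwidth <- 7

# Contextual (flank/surround) filters are zeroed inside this box around the
# image center: it covers the 16x16-pixel theoretical input support of the
# encoding models' center hypercolumn, so contextual modulation originates
# strictly outside anything a center-readout model can see.
context_exclusion_halfwidth <- 8

# Quadrature-pair filter bank for one neuron: center pair (truncated to the
# central box), two collinear flank pairs (displaced along the bar axis),
# and an omnidirectional surround bank (8 positions on an annulus x 4
# orientations). Stored as a (side^2 x n_filters) matrix for one GEMM per
# stimulus batch.
neuron_filter_bank <- function(side, theta, sf, sigma, flank_dist,
                               surround_radius) {
  cx <- (side + 1) / 2; cy <- (side + 1) / 2
  fl <- list()
  add_pair <- function(fl, px, py, th, bh = Inf, excl = 0) {
    fl[[length(fl) + 1]] <- gabor_patch(side, px, py, th, sf, sigma, 0, bh,
                                        excl)
    fl[[length(fl) + 1]] <- gabor_patch(side, px, py, th, sf, sigma, pi / 2,
                                        bh, excl)
    fl
  }
  # classical RF: confined to the central patch (centered 14x14 box)
  fl <- add_pair(fl, cx, cy, theta, bh = center_box_halfwidth)
  bar_axis <- c(-sin(theta), cos(theta))
  excl <- context_exclusion_halfwidth
  for (s in c(-1, 1))
    fl <- add_pair(fl, cx + s * flank_dist * bar_axis[1],
                   cy + s * flank_dist * bar_axis[2], theta, excl = excl)
  angles <- seq(0, 2 * pi, length.out = 9)[1:8]
  oris <- (0:3) * pi / 4
  for (a in angles) for (o in oris)
    fl <- add_pair(fl, cx + surround_radius * cos(a),
                   cy + surround_radius * sin(a), o, excl = excl)
  matrix(unlist(fl), side * side, length(fl))
}

#' Construct a synthetic V1 neuron
#'
#' An energy-model neuron: the deterministic firing rate to an image is
#' `rate = A * E_c^p * max(0, 1 + beta_f * F/f0 - beta_s * S/s0)`, where
#' `E_c` is the quadrature-pair Gabor energy of the center patch, `F` the
#' mean collinear flank energy (same orientation, displaced along the bar
#' axis) and `S` the mean omnidirectional energy on a surround annulus.
#' `f0`/`s0` are calibration normalizers (set by [make_neuron_bank()]) that
#' put typical flank/surround energies at 1 so the gains are interpretable;
#' `beta_f` drives collinear facilitation and `beta_s` isotropic surround
#' suppression. The expansive exponent `p >= 1` produces the sharp stimulus
#' selectivity characteristic of V1.
#'
#' @param theta Preferred orientation, radians in `[0, pi)`.
#' @param sf Spatial frequency, cycles/pixel.
#' @param sigma Gaussian envelope SD, pixels. Must satisfy `6 * sigma <= 13`
#'   so the center receptive field fits the central 13x13 patch.
#' @param p Expansive output exponent.
#' @param beta_f,beta_s Facilitation / suppression gains (>= 0).
#' @param side Image side the neuron operates on.
#' @param flank_dist Center-to-flank distance, pixels.
#' @param surround_radius Surround annulus radius, pixels.
#' @param gain Output gain `A`.
#' @param flank_norm,surround_norm Energy normalizers `f0`, `s0`.
#' @param noise_sd_scale Trial-noise scale used by [simulate_responses()].
#' @return A `sacnn_neuron`.
#' @export
synthetic_neuron <- function(theta, sf, sigma, p = 2, beta_f = 0,
                             beta_s = 0, side = 50L, flank_dist = 14,
                             surround_radius = 16, gain = 1,
                             flank_norm = 1, surround_norm = 1,
                             noise_sd_scale = 0.1) {
  stopifnot(sigma > 0, 6 * sigma <= 13.5, p >= 1, beta_f >= 0, beta_s >= 0)
  structure(list(theta = theta, sf = sf, sigma = sigma, p = p,
                 beta_f = beta_f, beta_s = beta_s, side = as.integer(side),
                 flank_dist = flank_dist, surround_radius = surround_radius,
                 gain = gain, flank_norm = flank_norm,
                 surround_norm = surround_norm,
                 noise_sd_scale = noise_sd_scale,
                 filters = neuron_filter_bank(side, theta, sf, sigma,
                                              flank_dist, surround_radius)),
            class = "sacnn_neuron")
}

# Energies for a stimulus matrix (side^2 x n): list(E_c, F, S) vectors.
neuron_energies <- function(neuron, stim_mat) {
  R <- crossprod(neuron$filters, stim_mat)  # n_filters x n
  en <- sqrt(R[seq(1, nrow(R), 2), , drop = FALSE]^2 +
             R[seq(2, nrow(R), 2), , drop = FALSE]^2)
  list(E = en[1, ], F = colMeans(en[2:3, , drop = FALSE]),
       S = colMeans(en[4:nrow(en), , drop = FALSE]))
}

#' Deterministic firing rate of a synthetic neuron
#'
#' @param neuron A [synthetic_neuron()].
#' @param image A single (side, side) image, or a `sacnn_stimuli` /
#'   (side, side, n) stack for vectorized evaluation.
#' @return Numeric rate(s), nonnegative.
#' @export
neuron_response <- function(neuron, image) {
  x <- if (inherits(image, "sacnn_stimuli")) image$images else image
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L)
  if (dim(x)[1] != neuron$side || dim(x)[2] != neuron$side)
    stop("image side does not match neuron (", neuron$side, ")")
  sm <- matrix(x, neuron$side^2, dim(x)[3])
  e <- neuron_energies(neuron, sm)
  mod <- pmax(0, 1 + neuron$beta_f * e$F / neuron$flank_norm -
                   neuron$beta_s * e$S / neuron$surround_norm)
  as.numeric(neuron$gain * e$E^neuron$p * mod)
}

#' Generate a randomized bank of synthetic neurons
#'
#' Orientations are uniform over `[0, pi)`; spatial frequencies, envelope
#' widths and exponents span physiologically reasonable ranges. Modulation
#' gains scale with `modulation_strength`: at 0 every neuron is a pure
#' center-energy cell (surround-independent by construction); at 1 surround
#' suppression typically removes 30-70% of the response and collinear
#' facilitation adds up to ~50%. Each neuron's output gain and its
#' flank/surround normalizers are calibrated once against an internal seeded
#' probe set of pink-noise images (peak probe response = 1), keeping
#' [neuron_response()] fully deterministic.
#'
#' @param n_neurons Number of neurons.
#' @param modulation_strength Scales all surround gains, in `[0, 1]`.
#' @param side Image side.
#' @param seed RNG seed.
#' @param n_probe Probe images used for calibration.
#' @return A `sacnn_neuron_bank` (list of neurons + metadata).
#' @export
make_neuron_bank <- function(n_neurons = 30L, modulation_strength = 1,
                             side = 50L, seed = 1L, n_probe = 200L) {
  stopifnot(modulation_strength >= 0, modulation_strength <= 1)
  pars <- with_seed(seed, data.frame(
    theta = runif(n_neurons, 0, pi),
    sf = runif(n_neurons, 0.125, 0.25),
    sigma = runif(n_neurons, 1.4, 2.1),
    p = runif(n_neurons, 1.5, 2.5),
    beta_f = modulation_strength * runif(n_neurons, 0.4, 0.8),
    beta_s = modulation_strength * runif(n_neurons, 1.0, 1.8),
    noise_sd_scale = rep(0.1, n_neurons)
  ))
  probes <- generate_stimuli(n_probe, side, "pink_noise",
                             seed = (seed + 7919L) %% .Machine$integer.max)
  pm <- matrix(probes$images, side^2, n_probe)
  neurons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    nr <- synthetic_neuron(pars$theta[i], pars$sf[i], pars$sigma[i],
                           p = pars$p[i], beta_f = pars$beta_f[i],
                           beta_s = pars$beta_s[i], side = side,
                           noise_sd_scale = pars$noise_sd_scale[i])
    e <- neuron_energies(nr, pm)
    nr$flank_norm <- mean(e$F)
    nr$surround_norm <- mean(e$S)
    peak <- max(neuron_response(nr, probes))
    if (peak > 0) nr$gain <- 1 / peak
    neurons[[i]] <- nr
  }
  structure(list(neurons = neurons, params = pars,
                 modulation_strength = modulation_strength,
                 side = as.integer(side), seed = as.integer(seed)),
            class = "sacnn_neuron_bank")
}

#' @export
print.sacnn_neuron_bank <- function(x, ...) {
  cat("<sacnn_neuron_bank> ", length(x$neurons), " neurons, modulation ",
      x$modulation_strength, ", side ", x$side, "\n", sep = "")
  invisible(x)
}

#' Simulate recorded responses with trial noise
#'
#' Per repeat, the observed response is `max(0, rate + eps)` with
#' `eps ~ N(0, sd = noise_sd_scale * sqrt(rate + 0.01))`: Gaussian noise
#' whose variance grows with the rate, a pragmatic stand-in for
#' calcium-signal variability. With `noise_sd_scale = 0` every repeat equals
#' the deterministic rate.
#'
#' @param bank A [make_neuron_bank()] (or a single `sacnn_neuron`).
#' @param stimuli A `sacnn_stimuli`.
#' @param n_repeats Repeats per image.
#' @param seed RNG seed.
#' @return A `sacnn_responses` list: `responses` (n_neurons x n_images
#'   trial means), `rates` (noiseless), `repeats` (n_neurons x n_images x
#'   n_repeats array, present iff `n_repeats > 1`), `neuron_ids`, `seed`.
#' @export
simulate_responses <- function(bank, stimuli, n_repeats = 1L, seed = 1L) {
  if (inherits(bank, "sacnn_neuron"))
    bank <- structure(list(neurons = list(bank), side = bank$side,
                           modulation_strength = NA, seed = NA),
                      class = "sacnn_neuron_bank")
  stopifnot(inherits(bank, "sacnn_neuron_bank"),
            inherits(stimuli, "sacnn_stimuli"), n_repeats >= 1)
  nn <- length(bank$neurons)
  ni <- stimuli$n
  rates <- matrix(0, nn, ni)
  for (i in seq_len(nn)) rates[i, ] <- neuron_response(bank$neurons[[i]],
                                                      stimuli)
  sds <- vapply(bank$neurons, `[[`, numeric(1), "noise_sd_scale")
  rep_arr <- NULL
  obs <- with_seed(seed, {
    if (n_repeats == 1L) {
      pmax(rates + rnorm(nn * ni) * sds * sqrt(rates + 0.01), 0)
    } else {
      rep_arr <- array(0, c(nn, ni, n_repeats))
      for (r in seq_len(n_repeats))
        rep_arr[, , r] <- pmax(rates + rnorm(nn * ni) * sds *
                                    sqrt(rates + 0.01))
      apply(rep_arr, c(1, 2), mean)
    }
  })
  structure(list(responses = obs, rates = rates,
                 repeats = if (n_repeats > 1) rep_arr,
                 n_repeats = as.integer(n_repeats),
                 neuron_ids = seq_len(nn), seed = as.integer(seed)),
            class = "sacnn_responses")
}

#' Assemble (or load/store) a train/validation dataset
#'
#' The default scene mirrors the geometry of a macaque two-photon session at
#' roughly one-tenth scale: single-trial training responses to pink-noise
#' stimuli and repeated-trial validation responses to a disjoint stimulus
#' set drawn from the same distribution.
#'
#' @param n_neurons,n_train,n_val,n_repeats Scene geometry.
#' @param modulation_strength Surround-modulation strength of the bank.
#' @param side Image side.
#' @param seed Master seed; stimulus/response/bank seeds are derived from it.
#' @param kind Stimulus kind.
#' @return A `sacnn_dataset` list: `train` (stimuli, responses), `val`
#'   (stimuli, responses with repeats), `bank`, `seed`.
#' @export
synth_dataset <- function(n_neurons = 30L, n_train = 3000L, n_val = 500L,
                          n_repeats = 10L, modulation_strength = 1,
                          side = 50L, seed = 1L, kind = "pink_noise") {
  bank <- make_neuron_bank(n_neurons, modulation_strength, side, seed)
  tr_stim <- generate_stimuli(n_train, side, kind, seed = seed + 1L)
  va_stim <- generate_stimuli(n_val, side, kind, seed = seed + 2L)
  tr_resp <- simulate_responses(bank, tr_stim, 1L, seed = seed + 3L)
  va_resp <- simulate_responses(bank, va_stim, n_repeats, seed = seed + 4L)
  structure(list(train = list(stimuli = tr_stim, responses = tr_resp),
                 val = list(stimuli = va_stim, responses = va_resp),
                 bank = bank, seed = as.integer(seed)),
            class = "sacnn_dataset")
}

#' @rdname synth_dataset
#' @param dataset A `sacnn_dataset`.
#' @param path File path (`.rds`).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sacnn_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname synth_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "sacnn_dataset"))
  ds
}
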