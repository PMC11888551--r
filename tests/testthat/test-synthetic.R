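test_that("stimulus sets are seeded, normalized and reproducible", {
  for (kind in c("pink_noise", "oriented_texture", "mixed")) {
    s <- generate_stimuli(6, 32, kind, seed = 5)
    expect_equal(dim(s$images), c(32, 32, 6))
    expect_true(all(s$images >= 0 & s$images <= 1))
    s2 <- generate_stimuli(6, 32, kind, seed = 5)
    expect_identical(s$images, s2$images)
    s3 <- generate_stimuli(6, 32, kind, seed = 6)
    expect_false(identical(s$images, s3$images))
  }
})

test_that("pink noise has an approximately 1/f amplitude spectrum", {
  s <- generate_stimuli(24, 64, "pink_noise", seed = 2)
  # average amplitude spectrum over images, radially binned
  amp <- 0
  for (i in 1:24) {
    img <- s$images[, , i]
    amp <- amp + Mod(fft(img - mean(img)))
  }
  fx <- c(0:32, -(31:1)) / 64
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  sel <- fr > 0.03 & fr < 0.4
  fit <- stats::lm(log(amp[sel]) ~ log(fr[sel]))
  slope <- unname(coef(fit)[2])
  expect_gt(slope, -1.4)
  expect_lt(slope, -0.6)
})

test_that("downsampling halves resolution and pixel-per-degree metadata", {
  s <- generate_stimuli(3, 100, "pink_noise", seed = 1,
                        pixels_per_degree = 30)
  d <- downsample_stimuli(s, 2)
  expect_equal(d$side, 50L)
  expect_equal(dim(d$images), c(50, 50, 3))
  expect_equal(d$pixels_per_degree, 15)
  # block-mean oracle on one corner
  expect_equal(d$images[1, 1, 1], mean(s$images[1:2, 1:2, 1]),
               tolerance = 1e-12)
  expect_error(downsample_stimuli(d, 3), "divisible")
})

test_that("zero-modulation neurons depend on the center patch only", {
  bank <- make_neuron_bank(4, modulation_strength = 0, seed = 2)
  expect_true(all(bank$params$beta_f == 0))
  expect_true(all(bank$params$beta_s == 0))
  stim <- generate_stimuli(5, 50, "pink_noise", seed = 9)
  hw <- sacnn:::center_box_halfwidth
  cx <- (50 + 1) / 2
  keep <- abs(seq_len(50) - cx) <= hw
  scram <- stim$images
  set.seed(3)
  for (i in 1:5) {
    noise <- matrix(runif(2500), 50, 50)
    img <- scram[, , i]
    img[!keep, ] <- noise[!keep, ]
    img[, !keep] <- noise[, !keep]
    scram[, , i] <- img
  }
  for (nr in bank$neurons)
    expect_identical(neuron_response(nr, stim$images),
                     neuron_response(nr, scram))
})

test_that("blank images evoke no response", {
  bank <- make_neuron_bank(3, modulation_strength = 1, seed = 4)
  blank <- matrix(0.5, 50, 50)
  for (nr in bank$neurons)
    expect_equal(neuron_response(nr, blank), 0, tolerance = 1e-10)
})

test_that("center orientation tuning matches the energy-model oracle", {
  nr <- synthetic_neuron(theta = pi / 4, sf = 0.15, sigma = 1.8, p = 2)
  grating <- function(th) {
    off <- seq_len(50) - 25.5
    phase <- outer(off * sin(th), off * cos(th), `+`)  # rows sin, cols cos
    0.5 + 0.4 * cos(2 * pi * 0.15 * phase)
  }
  img_pref <- grating(pi / 4)
  img_orth <- grating(pi / 4 + pi / 2)
  r_pref <- neuron_response(nr, img_pref)
  r_orth <- neuron_response(nr, img_orth)
  # direct numerical evaluation of the same energy model
  fb <- nr$filters[, 1:2]
  oracle <- function(img) {
    v <- as.vector(img)
    (sqrt((fb[, 1] %*% v)^2 + (fb[, 2] %*% v)^2))^2
  }
  expect_equal(r_pref / r_orth, as.numeric(oracle(img_pref) / oracle(img_orth)),
               tolerance = 1e-8)
  expect_gt(r_pref / r_orth, 3)  # clearly orientation tuned
})

test_that("simulated repeats are seeded and converge to the true rate", {
  bank <- make_neuron_bank(2, modulation_strength = 1, seed = 6)
  stim <- generate_stimuli(20, 50, "pink_noise", seed = 7)
  r1 <- simulate_responses(bank, stim, n_repeats = 3, seed = 8)
  r2 <- simulate_responses(bank, stim, n_repeats = 3, seed = 8)
  expect_identical(r1$repeats, r2$repeats)
  expect_equal(dim(r1$repeats), c(2, 20, 3))

  # sigma = 0 collapses repeats onto the deterministic rate
  bank0 <- bank
  for (i in seq_along(bank0$neurons)) bank0$neurons[[i]]$noise_sd_scale <- 0
  r0 <- simulate_responses(bank0, stim, n_repeats = 3, seed = 9)
  for (k in 1:3) expect_equal(r0$repeats[, , k], r0$rates)

  # law of large numbers at 200 repeats (positive rates; clipping negligible)
  rr <- simulate_responses(bank, stim, n_repeats = 200, seed = 10)
  act <- rr$rates > 0.2
  expect_true(any(act))
  expect_lt(max(abs(rr$responses[act] - rr$rates[act]) /
                (rr$rates[act] + 0.1)), 0.1)
})

test_that("default neuron banks are sharply selective on pink noise", {
  bank <- make_neuron_bank(12, modulation_strength = 1, seed = 11)
  stim <- generate_stimuli(2000, 50, "pink_noise", seed = 12)
  frac <- vapply(bank$neurons, function(nr) {
    r <- neuron_response(nr, stim)
    mean(r > max(r) / 2)
  }, numeric(1))
  expect_lt(median(frac), 0.02)
})

test_that("bank orientation preferences are uniform and seeded", {
  b1 <- make_neuron_bank(300, 0.5, seed = 13)
  b2 <- make_neuron_bank(300, 0.5, seed = 13)
  expect_identical(b1$params, b2$params)
  ks <- suppressWarnings(stats::ks.test(b1$params$theta, "punif", 0, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("datasets round-trip losslessly through the container", {
  ds <- tiny_scene(n_neurons = 2, n_train = 10, n_val = 6)
  f <- tempfile(fileext = ".rds")
  write_dataset(ds, f)
  ds2 <- read_dataset(f)
  expect_identical(ds2$train$stimuli$images, ds$train$stimuli$images)
  expect_identical(ds2$train$responses$responses,
                   ds$train$responses$responses)
  expect_identical(ds2$val$responses$repeats, ds$val$responses$repeats)
  unlink(f)
})
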