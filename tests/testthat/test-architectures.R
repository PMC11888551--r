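test_that("family table fixes kernel size, readout and attention flags", {
  expect_blocks <- function(fam, k, readout, sa, gamma) {
    side <- if (k == 3) 34L else 20L  # k = 3 betas need a larger input
    sp <- model_spec(fam, channels_c = 3, input_side = side)
    expect_equal(sp$beta_kernel_k, k)
    expect_equal(sp$readout, readout)
    expect_equal(sp$sa_present, sa)
    if (sa) expect_equal(sp$sa_gamma, gamma)
    m <- assemble_model(sp, seed = 1)
    ids <- names(m$blocks)
    expected <- c("alpha1", "alpha2", if (sa) "sa", "beta1", "beta2",
                  "readout")
    expect_identical(ids, expected)
    expect_equal(m$blocks$readout$mode, readout)
    expect_equal(dim(m$blocks$beta1$params$W)[1:2], c(k, k))
  }
  expect_blocks("ff", 3L, "FCL", FALSE, NA)
  expect_blocks("ff_sa", 3L, "FCL", TRUE, TRUE)
  expect_blocks("rf", 1L, "CTL", FALSE, NA)
  expect_blocks("rf_sa", 1L, "CTL", TRUE, FALSE)
  expect_blocks("rf_sa_star", 1L, "CTL", TRUE, TRUE)
  expect_blocks("ff_sa_star", 1L, "FCL", TRUE, TRUE)
})

test_that("contradictory spec fields raise errors naming the field", {
  expect_error(model_spec("rf", 8, beta_kernel_k = 3), "beta_kernel_k")
  expect_error(model_spec("ff", 8, readout = "CTL"), "readout")
  expect_error(model_spec("rf_sa", 8, sa_gamma = TRUE), "sa_gamma")
  expect_error(model_spec("nope", 8), "unknown family")
  expect_error(model_spec("rf", 0), "channels_c")
})

test_that("alpha stack follows the valid-conv/pool shape law", {
  m <- assemble_model(model_spec("rf", 4, input_side = 50), seed = 1)
  f <- alpha_stack_forward(m, tiny_batch(3, 50))
  expect_equal(dim(f), c(9, 9, 4, 3))

  shape_oracle <- function(H) {  # stage-by-stage, independent of the code
    s <- H - 4; s <- s %/% 2; s <- s - 4; s %/% 2
  }
  for (side in c(16L, 20L, 34L, 50L, 54L, 64L)) {
    mm <- assemble_model(model_spec("rf", 2, input_side = side), seed = 1)
    ff <- alpha_stack_forward(mm, tiny_batch(1, side))
    expect_equal(dim(ff)[1], shape_oracle(side), info = paste("side", side))
    expect_equal(alpha_output_side(side), shape_oracle(side))
  }
  expect_equal(alpha_output_side(54), 10L)
  expect_equal(alpha_output_side(16), 1L)  # smallest legal input
  expect_error(model_spec("rf", 2, input_side = 14), "input_side")
})

test_that("forward pass yields a finite scalar per image", {
  m <- assemble_model(model_spec("rf", 32), seed = 2)
  p <- predict(m, tiny_batch(2, 50))
  expect_length(p, 2)
  expect_true(all(is.finite(p)))
})

test_that("parameter counts are exact and per-block counts sum to total", {
  # independent arithmetic over the layer shapes
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  sa_n <- function(c, gamma) {
    n <- 2 * (c * c + c) + 1            # Wq, bq, Wk, bk, s
    if (gamma) n <- n + 2 * (c * c + c) # Wv, bv, Wo, bo
    n
  }
  ledger <- list(
    ff = conv_n(5, 1, 32) + conv_n(5, 32, 32) + 2 * conv_n(3, 32, 32) +
      (32 * 5 * 5 + 1),
    rf = conv_n(5, 1, 32) + conv_n(5, 32, 32) + 2 * conv_n(1, 32, 32) +
      (32 + 1),
    ff_sa = conv_n(5, 1, 30) + conv_n(5, 30, 30) + sa_n(30, TRUE) +
      2 * conv_n(3, 30, 30) + (30 * 5 * 5 + 1),
    rf_sa = conv_n(5, 1, 30) + conv_n(5, 30, 30) + sa_n(30, FALSE) +
      2 * conv_n(1, 30, 30) + (30 + 1))
  for (fam in names(ledger)) {
    c0 <- if (fam %in% c("ff", "rf")) 32 else 30
    m <- assemble_model(model_spec(fam, c0), seed = 1)
    expect_equal(count_parameters(m), ledger[[fam]], info = fam)
    pb <- count_parameters(m, per_block = TRUE)
    expect_equal(sum(pb$parameter_count), ledger[[fam]])
  }
  # single conv block: 5x5, 1 -> 32 channels, with bias
  m <- assemble_model(model_spec("rf", 32), seed = 1)
  pb <- count_parameters(m, per_block = TRUE)
  expect_equal(pb$parameter_count[pb$block_id == "alpha1"], 832)
  expect_equal(pb$parameter_count[pb$block_id == "readout"], 33)
})

test_that("attention models are parameter-matched to their baselines", {
  n_ff <- count_parameters(assemble_model(model_spec("ff", 32), 1))
  n_ffsa <- count_parameters(assemble_model(model_spec("ff_sa", 30), 1))
  n_rf <- count_parameters(assemble_model(model_spec("rf", 32), 1))
  n_rfsa <- count_parameters(assemble_model(model_spec("rf_sa", 30), 1))
  expect_lt(abs(n_ff - n_ffsa) / n_ff, 0.10)
  expect_lt(abs(n_rf - n_rfsa) / n_rf, 0.10)
})

test_that("self-attention is the identity at initialization (s = 0)", {
  for (fam in c("rf_sa", "rf_sa_star")) {
    sp <- tiny_spec(fam, 3, 20)
    m_sa <- assemble_model(sp, seed = 9)
    f <- alpha_stack_forward(m_sa, tiny_batch(3, 20))
    out <- sacnn:::sa_forward(m_sa$blocks$sa, f)$out
    expect_identical(out, f)
  }
})

test_that("attention rows are softmax-normalized and 1x1 maps are trivial", {
  m <- assemble_model(tiny_spec("rf_sa_star", 3, 50), seed = 4)
  m <- jitter_params(m, 0.2)
  img <- tiny_batch(1, 50)[, , 1]
  for (qp in list(c(1, 1), c(5, 5), c(9, 3))) {
    a <- attention_map(m, img, qp)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0))
  }
  # 16-pixel input gives a 1x1 post-alpha map: the only attention row is [1]
  m1 <- assemble_model(tiny_spec("rf_sa", 3, 16), seed = 4)
  expect_equal(attention_map(m1, tiny_batch(1, 16)[, , 1]),
               matrix(1, 1, 1))
})

test_that("uniform attention logits average each channel spatially", {
  # force all similarity logits equal (zero Q/K maps), gamma = FALSE:
  # every output position receives input + s * spatial mean per channel
  blk <- sacnn:::init_sa_block(3, gamma = FALSE)
  blk$params$Wq[] <- 0; blk$params$Wk[] <- 0
  blk$params$s <- 0.7
  f <- sacnn:::with_seed(2, array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)))
  out <- sacnn:::sa_forward(blk, f)$out
  # brute-force oracle: loop over all position pairs with uniform weights
  for (im in 1:2) for (ch in 1:3) {
    mn <- mean(f[, , ch, im])
    expect_equal(out[, , ch, im], f[, , ch, im] + 0.7 * mn,
                 tolerance = 1e-12)
  }
})

test_that("gamma = FALSE attention reweights every channel identically", {
  blk <- sacnn:::init_sa_block(4, gamma = FALSE)
  blk <- list(type = "sa", gamma = FALSE,
              params = lapply(blk$params, function(p)
                p + sacnn:::with_seed(5, rnorm(length(p), 0, 0.3))))
  blk$params$s <- 0.9
  f <- sacnn:::with_seed(6, array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2)))
  r <- sacnn:::sa_forward(blk, f)
  np <- 9
  for (im in 1:2) {
    A <- matrix(r$A[(im - 1) * np * np + seq_len(np * np)], np, np)
    M <- matrix(f[, , , im], np, 4)
    out <- matrix(r$out[, , , im], np, 4)
    # value path has no channel mixing: out = M + s * A M, channel by channel
    expect_equal(out, M + 0.9 * A %*% M, tolerance = 1e-12)
  }
  # permuting input channels together with the Q/K projection rows commutes
  perm <- c(3, 1, 4, 2)
  blk_p <- blk
  blk_p$params$Wq <- blk$params$Wq[perm, ]
  blk_p$params$Wk <- blk$params$Wk[perm, ]
  f_p <- f[, , perm, , drop = FALSE]
  out_p <- sacnn:::sa_forward(blk_p, f_p)$out
  expect_equal(out_p, r$out[, , perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("effective receptive field matches theory and an occlusion scan", {
  sp <- tiny_spec("rf", 3, 20)
  m <- jitter_params(assemble_model(sp, seed = 3), 0.1)
  expect_equal(theoretical_rf_side(sp, "alpha2"), 16L)
  expect_equal(theoretical_rf_side(sp, "readout"), 16L)  # 1x1 betas add none
  supp <- effective_rf_support(m, n_probe = 6, seed = 2)
  expect_lte(supp$side, 16L)
  expect_gte(supp$side, 12L)  # most of the theoretical support is active
  expect_lte(supp$half_height_side, supp$side)

  # occlusion oracle: perturbing pixels outside the gradient box never
  # changes the output; at least one inside pixel does
  x <- tiny_batch(1, 20, seed = 8)
  base <- predict(m, x)
  box <- supp$box
  mask <- matrix(TRUE, 20, 20)
  mask[box$rows[1]:box$rows[2], box$cols[1]:box$cols[2]] <- FALSE
  outside <- which(mask, arr.ind = TRUE)
  for (k in seq_len(min(25, nrow(outside)))) {
    xx <- x
    xx[outside[k, 1], outside[k, 2], 1] <- 1 - xx[outside[k, 1], outside[k, 2], 1]
    expect_equal(predict(m, xx), base, tolerance = 1e-12)
  }
  changed <- FALSE
  for (i in box$rows[1]:box$rows[2]) {
    xx <- x
    xx[i, 10, 1] <- 1 - xx[i, 10, 1]
    if (abs(predict(m, xx) - base) > 1e-9) { changed <- TRUE; break }
  }
  expect_true(changed)

  # beta kernels of size 3 widen the theoretical readout support
  expect_gt(theoretical_rf_side(model_spec("ff", 3, input_side = 50)),
            theoretical_rf_side(model_spec("rf", 3, input_side = 50)))
})

test_that("model specs round-trip through YAML and checkpoints through RDS", {
  sp <- model_spec("ff_sa", 12, input_side = 34)
  f <- tempfile(fileext = ".yaml")
  write_model_spec(sp, f)
  expect_equal(read_model_spec(f), sp)
  unlink(f)

  m <- assemble_model(tiny_spec("rf_sa", 3), seed = 11)
  ck <- tempfile(fileext = ".rds")
  write_checkpoint(m, ck)
  m2 <- read_checkpoint(ck)
  expect_identical(m2$blocks, m$blocks)
  expect_equal(m2$spec, m$spec)
  unlink(ck)
})
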