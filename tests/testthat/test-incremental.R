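test_that("weight inheritance reproduces source activations exactly", {
  src <- assemble_model(tiny_spec("rf", 3, 20), seed = 1)
  src <- jitter_params(src, 0.1)
  tgt <- assemble_model(tiny_spec("rf_sa_star", 3, 20), seed = 2)
  tgt <- inherit_weights(src, tgt, c("alpha1", "alpha2"))
  x <- tiny_batch(4, 20)
  expect_identical(alpha_stack_forward(tgt, x), alpha_stack_forward(src, x))

  wrong_c <- assemble_model(tiny_spec("rf", 4, 20), seed = 3)
  expect_error(inherit_weights(src, wrong_c, "alpha1"), "alpha1")
  expect_error(inherit_weights(src, tgt, "sa"), "sa")
})

test_that("readout expansion preserves predictions exactly at init", {
  m <- jitter_params(assemble_model(tiny_spec("rf_sa_star", 3, 20), seed = 4),
                     0.1)
  x <- tiny_batch(6, 20)
  base <- predict(m, x)
  for (mode in c("FC1", "FC2")) {
    ex <- expand_readout(m, mode)
    expect_equal(ex$model$spec$family, "ff_sa_star")
    expect_identical(predict(ex$model, x), base)  # bit-exact, zero surround
    expect_setequal(ex$frozen_blocks,
                    c("alpha1", "alpha2", "sa", "beta1", "beta2"))
  }
  # FC1 carries a freeze mask on the center column and bias; FC2 does not
  expect_false(is.null(expand_readout(m, "FC1")$model$blocks$readout$freeze_mask))
  expect_null(expand_readout(m, "FC2")$model$blocks$readout$freeze_mask)
  # expanding an FCL model is an error; so is a CTL trunk with no FCL family
  expect_error(expand_readout(expand_readout(m, "FC2")$model), "CTL")
  rf <- assemble_model(tiny_spec("rf", 3, 20), seed = 4)
  expect_error(expand_readout(rf), "no FCL family")
})

test_that("FC1 training changes only surround readout weights", {
  ds <- tiny_scene()
  y <- ds$train$responses$responses[1, ]
  parent <- assemble_model(tiny_spec("rf_sa_star", 3, 50), seed = 6)
  parent <- train_model(parent, ds$train$stimuli, y,
                        train_config(epochs = 1, seed = 6))$model
  ex <- expand_readout(parent, "FC1")
  r <- train_model(ex$model, ds$train$stimuli, y,
                   train_config(epochs = 2, seed = 7),
                   frozen_blocks = ex$frozen_blocks)
  side <- dim(ex$model$blocks$readout$params$W)[1]
  ic <- side %/% 2 + 1
  W0 <- ex$model$blocks$readout$params$W
  W1 <- r$model$blocks$readout$params$W
  expect_identical(W1[ic, ic, ], W0[ic, ic, ])                  # center frozen
  expect_identical(r$model$blocks$readout$params$b,
                   ex$model$blocks$readout$params$b)            # bias frozen
  expect_gt(sum(W1[-ic, , ] != W0[-ic, , ]), 0)                 # surround learns
  # pre-readout blocks were frozen too
  expect_identical(r$model$blocks$sa$params, ex$model$blocks$sa$params)
})

test_that("a stationary point leaves FC2 weights untouched", {
  ds <- tiny_scene(n_train = 20)
  m <- jitter_params(assemble_model(tiny_spec("rf_sa_star", 3, 50), seed = 8),
                     0.05)
  ex <- expand_readout(m, "FC2")
  y <- predict(ex$model, ds$train$stimuli)  # targets equal predictions
  r <- train_model(ex$model, ds$train$stimuli, y,
                   train_config(epochs = 1, seed = 8))
  expect_identical(r$model$blocks, ex$model$blocks)
  expect_equal(r$history[1], 0)
})

test_that("stage plans validate ordering and presets have the right shape", {
  expect_error(stage_plan(
    stage_directive("b", tiny_spec("rf_sa_star"),
                    inherit_from = list(stage = "a", blocks = "alpha1")),
    stage_directive("a", tiny_spec("rf"))), "earlier stage")

  p1 <- stage_plan_preset("simul", 3, 20, family = "ff_sa_star")
  expect_length(p1, 1)
  p2 <- stage_plan_preset("incr", 3, 20)
  expect_length(p2, 2)
  p3 <- stage_plan_preset("incr_fc1", 3, 20)
  expect_length(p3, 3)
})

test_that("incremental plans train stage-wise with exact inheritance", {
  ds <- tiny_scene(n_train = 40)
  y <- ds$train$responses$responses[1, ]
  cfg <- train_config(epochs = 1, seed = 9)
  out <- run_plan(stage_plan_preset("incr_fc1", 3, 50), ds$train$stimuli, y,
                  cfg)
  expect_length(out, 3)
  expect_named(out, c("rf", "rf_sa_star", "ff_sa_star_fc1"))
  # stage 2 inherited and froze the stage-1 alpha blocks
  expect_identical(out$rf_sa_star$model$blocks$alpha1$params,
                   out$rf$model$blocks$alpha1$params)
  # stage 3 inherited the whole stage-2 trunk
  expect_identical(out$ff_sa_star_fc1$model$blocks$sa$params,
                   out$rf_sa_star$model$blocks$sa$params)
  out_s <- run_plan(stage_plan_preset("simul", 3, 50, family = "ff_sa_star"),
                    ds$train$stimuli, y, cfg)
  expect_length(out_s, 1)
})

test_that("the expanded readout can only improve the training fit", {
  ds <- tiny_scene(n_train = 60)
  y <- ds$train$responses$responses[1, ]
  cfg <- train_config(epochs = 4, seed = 10)
  out <- run_plan(stage_plan_preset("incr_fc2", 3, 50), ds$train$stimuli, y,
                  cfg)
  # the FC2 stage starts exactly at the stage-2 optimum it inherited, so
  # further training cannot end meaningfully worse
  expect_lte(out$ff_sa_star_fc2$history[4],
             out$rf_sa_star$history[4] * 1.05 + 1e-8)
})
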