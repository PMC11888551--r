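# Shared fixtures: everything is generated in code, at small scale.

tiny_spec <- function(family = "rf", channels = 3L, side = 20L) {
  model_spec(family, channels_c = channels, input_side = side)
}

tiny_batch <- function(n = 4L, side = 20L, seed = 1L) {
  sacnn:::with_seed(seed, array(runif(side * side * n), c(side, side, n)))
}

# Add Gaussian jitter to every parameter so no ReLU pre-activation sits
# exactly on the kink (finite differences straddle kinks otherwise).
jitter_params <- function(model, sd = 0.05, seed = 7L) {
  sacnn:::with_seed(seed, {
    for (id in names(model$blocks))
      for (pn in names(model$blocks[[id]]$params)) {
        p <- model$blocks[[id]]$params[[pn]]
        model$blocks[[id]]$params[[pn]] <- p + rnorm(length(p), 0, sd)
      }
    model
  })
}

# Central finite difference of the mean-squared-error loss with respect to
# one parameter entry.
numeric_param_grad <- function(model, block, pn, i, x, y, eps = 1e-6) {
  lossfn <- function(m) {
    p <- sacnn:::model_forward(m, x)$pred
    mean((p - y)^2)
  }
  m2 <- model; m2$blocks[[block]]$params[[pn]][i] <-
    model$blocks[[block]]$params[[pn]][i] + eps
  m3 <- model; m3$blocks[[block]]$params[[pn]][i] <-
    model$blocks[[block]]$params[[pn]][i] - eps
  (lossfn(m2) - lossfn(m3)) / (2 * eps)
}

# Small synthetic scene reused by the training / attribution tests.
tiny_scene <- function(n_neurons = 2L, n_train = 60L, n_val = 30L,
                       modulation = 1, seed = 3L) {
  synth_dataset(n_neurons = n_neurons, n_train = n_train, n_val = n_val,
                n_repeats = 4L, modulation_strength = modulation,
                side = 50L, seed = seed)
}
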