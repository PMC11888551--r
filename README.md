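# sacnn

Self-attention-augmented convolutional encoding models of primary visual
cortex neurons, in R.

`sacnn` is for computational neuroscientists who fit image-computable
encoding models to single-neuron responses and want to ask *which mechanism
carries contextual (extra-classical-surround) modulation*. It implements a
factorized family of small CNNs in which the three candidate context
mechanisms — successive convolutions, a single-headed spatial self-attention
(SA) layer, and a fully connected readout — can each be switched on or off,
plus the stage-wise incremental training procedure that learns receptive
fields before context, and the evaluation metrics that separate overall
tuning from peak tuning.

## The models

Every variant shares a trunk of two "alpha" blocks (valid 5×5 convolution +
ReLU + 2×2 max pooling) that encode a 1×50×50 image into a c×9×9 feature
tensor, followed by two "beta" blocks (valid k×k convolution + ReLU, no
pooling) and a linear readout emitting one scalar rate prediction per image:

| family       | beta kernel | readout | self-attention |
|--------------|-------------|---------|----------------|
| `ff`         | 3×3         | all hypercolumns (FCL) | — |
| `ff_sa`      | 3×3         | FCL     | yes, value projection (γ = T) |
| `rf`         | 1×1         | center hypercolumn (CTL) | — |
| `rf_sa`      | 1×1         | CTL     | yes, spatial-only (γ = F) |
| `rf_sa_star` | 1×1         | CTL     | yes, γ = T |
| `ff_sa_star` | 1×1         | FCL     | yes, γ = T |

The SA layer computes, over the N = 81 hypercolumns, A = softmax(QKᵀ/√c)
row-wise and adds s·(A V) back through a residual with learnable gain s
(s = 0 at init, so an SA model starts as its feedforward trunk). Attention
models use c = 30 channels against c = 32 for their baselines, matching
parameter counts within 10%. Peak tuning for predictions p against recorded
responses r with threshold t = min(top-1% of r) is

    PT = 100 · #\{top-1% predictions ≥ t\} / #\{responses in the top 1%\},

ranked jointly with the recorded responses (PTJ, stricter) or separately
(PTS). Training is per-neuron minibatch Adam on MSE (batch 50, lr 0.001);
incremental plans inherit and freeze blocks stage by stage, including the
CTL→FCL readout expansion that starts the dense readout exactly at its
center-only parent.

There is no autodiff dependency: the conv/pool/attention forward and
backward passes are implemented in the package (RcppArmadillo kernels),
and are verified against finite differences and brute-force oracles in the
test suite. A seeded synthetic-V1 generator (Gabor-energy neurons with
controllable collinear facilitation and surround suppression, pink-noise
stimuli) provides ground-truth data so every experiment runs at desk scale.

## Worked example

```r
library(sacnn)

# a small synthetic recording session: 3 neurons with surround modulation,
# 1500 single-trial training images, 300 validation images x 10 repeats
ds <- synth_dataset(n_neurons = 3, n_train = 1500, n_val = 300,
                    modulation_strength = 1, seed = 42)

# fit the receptive-field-only model to neuron 3
m <- assemble_model(model_spec("rf", channels_c = 8), seed = 1)
fit <- train_model(m, ds$train$stimuli, ds$train$responses$responses[3, ],
                   train_config(epochs = 12, learning_rate = 0.003, seed = 1))
round(fit$history[c(1, 12)], 4)
#> [1] 0.0396 0.0137

ev <- evaluate_model(fit$model, ds$val$stimuli, ds$val$responses, neuron = 3)
round(ev[, c("corr", "ptj", "pts", "ccnorm")], 3)
#>    corr    ptj    pts ccnorm
#> 1 0.596 33.333 66.667  0.598
```

The history entries are the mean training MSE in the first and last epoch
(falling, as it should). `corr` is the Pearson correlation between the
model's predictions and the repeat-averaged validation responses; `ccnorm`
rescales it by the trial-noise ceiling (0.998 for this neuron, so the two
nearly coincide), and `ptj` / `pts` say what fraction of the top-1%
response peak the model captures at the recorded threshold: of the three
images defining this neuron's peak, one clears the threshold among the
jointly ranked candidates and two among the model's own top predictions.

Incremental training and the readout decomposition:

```r
plan <- stage_plan_preset("incr_fc1", channels_c = 8)
stages <- run_plan(plan, ds$train$stimuli, ds$train$responses$responses[3, ],
                   train_config(epochs = 5, seed = 1))
names(stages)
#> [1] "rf"             "rf_sa_star"     "ff_sa_star_fc1"

dec <- decompose_readout(stages$ff_sa_star_fc1$model, ds$val$stimuli)
all.equal(dec$center + dec$surround + dec$bias, dec$total)
#> [1] TRUE
```

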