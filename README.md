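# rfpursuit

Characterize visual-cortex receptive fields (RFs) from stimulus-response
data. `rfpursuit` is aimed at systems neuroscientists fitting per-neuron
response models to image stimuli — calcium-imaging or electrophysiology
tables of one scalar response per stimulus — and asking not just *how well*
a model predicts, but *which component features* make up a neuron's
receptive field, and whether the neuron is a plain orientation detector or
a higher-order pattern detector.

## What it implements

**Pursuit regression.** Projection pursuit regression (PPR) fits one
kernel at a time: stage *m* chooses a kernel *F* and a quadratic link
*g(z) = a z² + b z + c* to explain the current residual *r*, scored by the
pursuit contribution

> I = 1 − Σᵢ (rᵢ − g(zᵢ))² / Σᵢ rᵢ²,

then updates *r ← r − g(z)*. The model predicts with
ψ(S) = Σₘ gₘ(Fₘ · S). Two convolutional variants replace the dot product
with a translation-tolerant feature — the maximum absolute response of a
small d × d kernel over all valid positions, g(max |F ∗ X|): **CPPR**
optimizes the kernel freely, **CMPR** selects it from a fixed dictionary by
exhaustive search. A 64-kernel convolutional sparse-coding dictionary
expanded through 8 rotations of 45° (512 kernels) is the canonical CMPR
dictionary.

**Fixed-kernel networks.** A single-layer CNN (conv → ReLU → max-pool →
linear readout) in five flavors: `cnn4`/`cnn9` learn their kernels;
**FKCNN** freezes the first layer to 24 complex-shaped sparse-code
kernels, **GCNN** to 24 Gabor wavelets (3 scales × 8 orientations),
**GLCNN** to Gabors plus 3 Laplacian-of-Gaussian channels. Frozen layers
are never updated, so a 24-kernel fixed net learns about as many
parameters as `cnn4` and half as many as `cnn9`. Per-kernel **importance
scores** silence all channels but one and measure the surviving test
correlation.

**Dictionary learning.** `learn_csc_dictionary()` trains a convolutional
sparse code (FISTA coding / projected-gradient dictionary updates) on
image patches; `generate_training_images()` supplies dead-leaves or
1/f-noise imagery as a natural-scene stand-in.

**Synthetic neurons.** Linear-nonlinear neurons with signal-dependent
noise: y = Σ_{s∈S} ReLU(I·s) + η, η ~ N(0, drive/10), with the RF set S
drawn from a kernel bank or cropped from pattern stimuli and zero-padded
into the stimulus canvas. A binary pattern-stimulus generator (bars,
gratings, curves, corners, crosses, compositions at many rotations and
scales) emulates composite pattern stimulus sets.

**Scoring.** Pearson prediction accuracy, OT/HO labeling (a neuron is
orientation-tuned iff some bar stimulus drives it above 50% of its peak),
the complexity score

> score = (Corr_FKCNN − Corr_GCNN) / (Corr_FKCNN + Corr_GCNN),

an exactly-optimal 1-D threshold classifier, and data-efficiency /
convergence protocols.

## Worked example

```r
library(rfpursuit)

bank   <- gabor_bank(3, 8, 9)                       # 24 kernels
neuron <- make_synthetic_neuron(bank, k = 1, stimulus_side = 20, seed = 7)
train  <- gaussian_noise_stimuli(2000, 20, seed = 1)
test   <- gaussian_noise_stimuli(500, 20, seed = 2)
y_tr   <- simulate_responses(neuron, train, noise = TRUE, seed = 3)
y_te   <- simulate_responses(neuron, test, noise = FALSE)

fit <- fit_pursuit(train, y_tr, M = 3, mode = "cmpr", dictionary = bank)
tidy(fit)
#> # A tibble: 1 × 6
#>   stage contribution      a       b     c dict_index
#>   <int>        <dbl>  <dbl>   <dbl> <dbl>      <int>
#> 1     1        0.312 0.0301 0.00998 0.173         10
neuron$source_index
#> [1] 10
```

The fitted stage selected dictionary kernel 10 — exactly the kernel the
synthetic neuron was built from — and its quadratic link curves upward
(`a > 0`), as expected for a rectified drive seen through an
absolute-value feature. The contribution `I` is the fraction of residual
variance the stage explains on the training set. Note that on
*white-noise* stimuli the pooled feature carries little predictive
information even for the true kernel (here test r ≈ 0.11): global
max-abs pooling hides the RF location and discards the stimulus sign, so
matching pursuit *identifies* the kernel long before it *predicts* well —
see the vignette's "Known limitations".

```r
net <- train_network(build_network(net_config("fixed", front_end = bank, seed = 1)),
                     train, y_tr)
glance(net)
#> # A tibble: 1 × 6
#>   variant n_kernels frozen_front_end learnable_params epochs_to_stop best_val_pearson
#>   <chr>       <int> <lgl>                       <int>          <int>            <dbl>
#> 1 fixed          24 TRUE                          385            107            0.734

kernel_importance(net, test, y_te) |> dplyr::arrange(dplyr::desc(importance)) |> head(3)
#> # A tibble: 3 × 3
#>   kernel source_id      importance
#>    <int> <chr>               <dbl>
#> 1     10 gabor_s1_o22.5      0.777
#> 2      9 gabor_s1_o0         0.379
#> 3     19 gabor_s2_o45        0.352
```

The top-importance channel (score 0.777, well clear of the runners-up) is
again the generating kernel.

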