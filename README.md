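# cqcnn

Hybrid classical–quantum convolutional networks for binary classification of
2D brain-MRI slices, with the full supporting pipeline: a 3D-to-2D volumetric
slice extractor, an exact statevector simulator for the parameterized quantum
circuit (PQC), matched-parameter classical control models, training and
evaluation harnesses, and seeded synthetic phantom generators so that every
stage runs end to end with no external data.

## Who this is for

Researchers studying hybrid quantum–classical image classifiers — in
particular the regime where the two classes are visually near-identical
(e.g., non-dementia vs. moderate-dementia structural MRI), which is where
these models are known to stall during optimization. The package lets you
reproduce that convergence phenomenology, and the conditions under which the
models do converge, on self-contained synthetic data.

## The model

A grayscale `1×128×128` slice passes through a small classical front-end and
a quantum head:

```
Conv(1→2, 5×5) → ReLU → MaxPool 2×2          2×124×124 → 2×62×62
Conv(2→4, 5×5) → ReLU → MaxPool 2×2          4×58×58  → 4×29×29
Dropout2D → Flatten                           3364
Dense(3364→4) → Dense(4→ω)                    ω features (ω qubits)
PQC: ZZ feature map → Ry(θ) ansatz → ⟨Z…Z⟩   o₁ = (1 − ⟨M⟩)/2
Dense(1→1) → logistic → γ = (o₁, 1 − o₁)
```

The PQC encodes the ω bottleneck features by angle encoding with pairwise
entangling phases (a ZZ feature map), applies one layer of trainable `Ry(θᵢ)`
rotations, and measures the all-qubit Pauli-Z parity, giving a classical
probability `o₁ ∈ [0, 1]`. Quantum parameters are trained with the exact
parameter-shift rule, `∂o₁/∂θᵢ = [o₁(θᵢ + π/2) − o₁(θᵢ − π/2)]/2`; classical
weights by ordinary backpropagation (cross-entropy loss, Adam, learning rate
0.001, batch size 32 by default). The fixed classical layers hold 13,718
trainable parameters; the bottleneck adds `(4×ω)+ω` and the ansatz `ω` more
(13,730 total at ω = 2) — about 0.05 MB at 32-bit precision. A
`classical-control` variant replaces the quantum block with a classical one
of exactly the same parameter count.

The slice extractor selects `n` evenly spaced slices from the `m` available
along an anatomical plane with interval `i = ⌊m/n⌋`, discarding `k₁` leading
and `k₂` trailing boundary slices: `n_slices = ⌈m/i⌉ − (k₁ + k₂)` with
indices `s = k₁ + j·i` kept while `s < m − k₂`.

## Worked example

```r
library(cqcnn)

# a self-contained two-class image set (visually separable regime)
ds <- make_class_pair(class_pair_recipe(n_per_class = 40, side = 32,
                                        delta = 14, noise_sd = 0.02,
                                        seed = 21))
dplyr::count(ds, label, split)
#>   label split     n
#> 1     0 test      4
#> 2     0 train    36
#> 3     1 test      4
#> 4     1 train    36

model <- build_model(model_config(image_side = 32, omega = 2, seed = 21))
count_parameters(model)
#> ...
#> fixed total: 662  + bottleneck: 10  + circuit: 2  =  674
# (13,718 fixed parameters at the full 128-px input size)

fit <- cq_train(model, ds, train_config(epochs = 20, batch_size = 4,
                                        learning_rate = 0.003, seed = 21))
tail(tidy(fit), 3)
#>   epoch  loss train_accuracy val_accuracy
#> 1    18 0.605          0.833        1
#> 2    19 0.574          0.833        0.875
#> 3    20 0.532          0.931        1

evaluate_model(fit, ds)
#>   precision recall    f1 specificity accuracy     n
#> 1         1      1     1           1        1     8
```

The training history says the separable phantom classes are learned to ~93%
running training accuracy (dropout active) and 100% held-out accuracy within
20 epochs; on `delta = 0` data the same model stays at chance. `autoplot(fit)`
draws the accuracy curves; `run_repeated()` repeats training across seeds and
summarizes between-run variability with a one-way ANOVA, the diagnostic used
to contrast separable and near-identical class pairs.

The quantum pieces are usable on their own:

```r
spec <- encoding_spec(2, dialect = "zz-interaction")
pqc_forward(c(0.4, -0.2), theta = c(0.7, 1.1), spec)   # scalar o1
parameter_shift_grad(c(0.4, -0.2), c(0.7, 1.1), spec)  # exact gradient
```

A command-line interface wraps the same functions
(`inst/cli/cqcnn.R slice | simulate-circuit | generate-data | train |
evaluate | inspect`), writing a JSON run manifest next to every artifact.

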