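---
title: "Hybrid classical-quantum image classification: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid classical-quantum image classification: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqcnn)
```

This vignette is the package's own account of its methods: the slice
extractor, the quantum circuit and its simulator, the hybrid architecture,
the training protocol, what the synthetic generators do and do not emulate,
and the design choices made where several readings were defensible.

## 1. Volumetric slice extraction

A 3D MRI volume `V` is viewed along one of the three anatomical planes
(axial, coronal, sagittal). To draw `n` evenly spaced slices from the `m`
available along a plane normal, the extractor computes the interval

\[ i = \lfloor m / n \rfloor , \]

discards `k1` leading and `k2` trailing slices (MRI boundary slices are
mostly empty space or non-brain tissue), and retains

\[ n_{\mathrm{slices}} = \lceil m / i \rceil - (k_1 + k_2) \]

slices at indices \(s = k_1 + j\,i\), \(j = 0, \dots,
n_{\mathrm{slices}}-1\), subject to the trailing guard \(s < m - k_2\).
Indices are 0-based. Two consequences worth knowing:

* The retained count is **not guaranteed to equal the requested `n`** — the
  arithmetic above is authoritative. `plan_slices()` reports both, and the
  command-line tool warns when they differ rather than silently re-fitting.
* When `k1 + k2` reaches \(\lceil m/i \rceil\), the plan is empty and
  construction fails loudly.

Defaults `k1 = k2 = 2` reflect "a few empty slices on each side"; both are
exposed everywhere. Array axis 1 is treated as the sagittal normal, axis 2
coronal, axis 3 axial, overridable through `axis_map`; the NIfTI affine is
read only to warn on oblique orientations, since orientation correction is
out of scope. Intensity normalization for export is per-slice min–max (a
constant slice maps to zero), the simplest scheme consistent with 8-bit PNG
output; resizing is bilinear.

## 2. The parameterized quantum circuit

The register has \(\omega\) qubits (2 or 3 in practice); qubit 0 is the
least-significant bit of the basis index. The data-encoding circuit is a ZZ
feature map: Hadamards on all qubits, a per-qubit phase \(P(2 x_i)\), then
an entangling block. Two dialects are implemented because the defining
equation and the circuit diagram it accompanies disagree:

* `"eq3-cz"` — a bare controlled-Z on every pair \(i < j\) (the closed-form
  expression, taken literally);
* `"zz-interaction"` (default) — a controlled phase of
  \(2(\pi - x_i)(\pi - x_j)\) on the \(|11\rangle\) component of every pair,
  the standard pairwise ZZ interaction the circuit diagram depicts. The
  diagram's printed phase uses the same index twice, which we read as a
  typographical slip for distinct \(i, j\).

The ansatz applies \(R_y(\theta_i)\) to each qubit,
\(R_y(\theta) = \begin{pmatrix} \cos\theta/2 & -\sin\theta/2 \\
\sin\theta/2 & \cos\theta/2 \end{pmatrix}\), one repetition by default (the
executed circuit shows a single layer). Measurement is exact (statevector):
probabilities \(p_i = |\langle i|\psi\rangle|^2\), eigenvalues
\(l_i = (-1)^{\mathrm{popcount}(i)}\) for the all-qubit Pauli-Z parity,
expectation \(\langle M\rangle = \sum_i l_i p_i\), and the unit-interval
output

\[ o_1 = \frac{1 - \langle M \rangle}{2} \in [0, 1]. \]

The parity observable was chosen because it uses the measurement identity
directly and lands in \([0,1]\); a first-qubit-only observable
(`observable = "z0"`) is available as the alternative reading. Shot sampling
is opt-in with an explicit seed; every default computation is exact, which
is what makes training bit-reproducible.

Gradients of \(o_1\) with respect to the ansatz angles use the
parameter-shift rule, exact for \(R_y\) generators:
\(\partial o_1 / \partial\theta_i = [o_1(\theta_i + \pi/2) -
o_1(\theta_i - \pi/2)]/2\). Gradients with respect to the circuit *inputs*
(needed to backpropagate into the classical layers) use central finite
differences with step \(h = 10^{-4}\); with exact expectations the resulting
error is far below the \(10^{-4}\) tolerance the end-to-end gradient checks
enforce.

Feature scaling into angles: the dense layer feeding the encoder is
unbounded, so its outputs pass through \(x \mapsto \pi\,\tanh(x)\) before
use as phases, keeping them in \((-\pi, \pi)\) and preventing aliasing
across the \(2\pi\) period. `feature_scaling = "identity"` disables this for
direct circuit experiments.

## 3. The hybrid architecture and its accounting

At the reference input size (128 px) the layer schedule and trainable
parameters are:

| Layer   | Output shape | Parameters |
|---------|--------------|-----------|
| Conv 5×5, 1→2 | 2×124×124 | 52 |
| MaxPool 2×2   | 2×62×62   | 0 |
| Conv 5×5, 2→4 | 4×58×58   | 204 |
| MaxPool 2×2   | 4×29×29   | 0 |
| Dropout2D     | 4×29×29   | 0 |
| Flatten       | 3364      | 0 |
| Dense 3364→4  | 1×4       | 13,460 |
| Dense 4→ω     | 1×ω       | (4×ω)+ω |
| PQC           | 1×1       | ω |
| Dense 1→1     | 1×1       | 2 |

Fixed total 13,718; grand total \(13{,}718 + 5\omega + \omega\) (13,730 at
\(\omega = 2\)), i.e. ~0.05 MB at 32-bit precision. Other input sizes are
supported whenever both pooling stages see even extents; the flatten width
and Dense1 count then change accordingly.

Design choices in the head:

* The 1→1 output layer is followed by a **logistic squash** before forming
  \(\gamma = (o_1', 1 - o_1')\): a linear layer is unbounded, and the
  two-class output must be a probability pair for the cross-entropy to be
  well defined.
* **Head calibration at initialization.** Weights use the uniform
  Kaiming-style bound \(1/\sqrt{\text{fan-in}}\) (the parameterization
  standard deep-learning frameworks apply to conv and linear layers), ansatz
  angles start uniform on \((0, \pi)\) (one \(R_y\) half-period), and the
  output bias is set to \(-w_{\text{out}}/2\) so that a mid-range circuit
  output \(q = 0.5\) maps to probability 0.5. Without this, the single
  output bias starts miscalibrated by an arbitrary offset, and Adam at the
  reference learning rate (0.001) spends several hundred updates re-centering
  one scalar before any class separation is visible — a pure artifact of the
  head's initialization, not of the data or the circuit.
* Dropout2D rate 0.25 (common default; does not affect parameter counts).
* The classical control replaces [Dense(4→ω) → PQC → Dense(1→1)] with
  Dense(4→ω) → a bias-free ω→1 sigmoid unit → Dense(1→1). The bias-free
  middle layer holds exactly ω scalars, so the control's trainable count
  equals the quantum model's, which tests assert exactly.

## 4. Training protocol and diagnostics

Defaults reproduce the reference classification configuration: batch size
32, learning rate 0.001, Adam, cross-entropy. The quantum angles receive
parameter-shift gradients chained through the head; everything else is
ordinary backpropagation. Optimizers `sgd`, `rmsprop`, `adagrad` are
available for the ablation in which only Adam converges; `lbfgs` runs
full-batch `stats::optim` L-BFGS-B with a few quasi-Newton iterations per
epoch (its curvature memory resets at epoch boundaries — adequate for the
ablation's qualitative point, not a production optimizer). Per-epoch
*training* accuracy is the running accuracy accumulated batch-by-batch as
the parameters move (the convention of mainstream frameworks, and with
dropout active); validation accuracy is computed after each epoch in
deterministic evaluation mode.

`evaluate_model()` scores argmax predictions: precision, recall, F1,
specificity, accuracy from the 2×2 confusion table, with zero-denominator
ratios reported as 0 and flagged. The positive class defaults to label 1,
the minority clinical class in the motivating task. `run_repeated()` trains
across seeds derived from the base seed by a fixed counter and summarizes
between-run variability with a one-way fixed-effects ANOVA over each run's
last three per-epoch accuracies (the grouping window is a documented choice;
`k` is an argument). Degenerate cases are defined explicitly: zero
between-group variance gives \(F = 0, p = 1\); distinct means with zero
within-group variance give \(F = \infty, p = 0\).

## 5. What the synthetic generators emulate

`make_volume()` builds an ellipsoidal phantom whose interior slices all
contain foreground while a configurable margin of boundary slices is exactly
empty — the property that motivates the `k1`/`k2` trims. `make_class_pair()`
builds two-class image sets from a shared central blob plus a secondary blob
displaced horizontally by `delta` pixels in class 1, with per-image jitter
and pixel noise, split 90:10 into train/test. `delta = 0` makes the class
distributions identical; increasing `delta` monotonically increases
between-class mean distance and the accuracy of a nearest-centroid oracle.

What this does **not** emulate: anatomy, scanner physics, intensity
inhomogeneity, registration error, or the diffusion-based oversampling used
for clinical class imbalance. Passing tests therefore demonstrate that the
architecture, gradients, and optimization behave as specified and that the
similarity-driven convergence failure is reproducible — not that any
particular clinical accuracy would be attained on real MRI.

Study conditions for the end-to-end checks were fixed once: 500 images per
class at 128 px (900 training images after the 90:10 split, matching the
roughly thousand-image scale of the clinical training sets emulated), `delta
= 20` for the separable ("MNIST-like") regime and `delta = 0` for the
near-identical ("MRI-like") regime, reference training configuration, 10
epochs. Under these conditions the ω = 2 quantum model and the classical
control both exceed 0.95 training accuracy, while `delta = 0` training
stays within 3 points of chance over the first two epochs. The scaled-down
property tests use 32-px phantoms with batch size 4 and learning rate 0.003
so that a short run still performs a few hundred optimizer updates; the
vignette notes this as a problem-size choice for the test harness, with the
study-condition runs unchanged.

## 6. Numerical conventions and degenerate inputs

* Statevector norm is asserted to 1e-10 after every gate; probabilities are
  renormalized only against floating-point drift.
* Cross-entropy clamps its log argument at 1e-12, so a certain-but-wrong
  prediction yields a large finite loss.
* Max-pooling ties break toward the first of the four window positions in a
  fixed order, making runs bit-reproducible.
* Constant slices normalize to all-zero images rather than dividing by zero.
* Checkpoints store parameters as base64-encoded IEEE-754 doubles inside a
  JSON header, so save/load round trips are bit-exact and a corrupted or
  foreign file fails with a format error before any partial model escapes.
* All generators and training runs are pure functions of their seeds in
  exact-expectation mode; shot sampling requires an explicit seed.

## 7. Known limitations

* The simulator targets small registers (the models use 2–3 qubits); beyond
  ~10 qubits the dense statevector approach is inappropriate by design.
* `input_grad()` is finite-difference, not analytic; its error is negligible
  at the default step but it costs two circuit evaluations per input
  component.
* The L-BFGS option restarts its memory each epoch (see §4).
* Only binary classification heads are provided; multi-class extension is
  out of scope.
* PNG export is 8-bit grayscale.
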