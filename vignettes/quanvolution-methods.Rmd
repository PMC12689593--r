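---
title: "Quanvolution and knowledge distillation: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quanvolution and knowledge distillation: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quanvolve)
```

This vignette is the package's account of the science it implements:
the hybrid quantum–classical classification pipeline, the distillation
objective, the synthetic benchmark that exercises them, and the design
decisions taken where the method family leaves choices open.

## The pipeline at a glance

An input grayscale image (values in $[0,1]$) is resized to
`target_side` (default 28), and a centered `roi_side` × `roi_side`
region of interest (default 14×14) is cropped with 0-based, half-open
index arithmetic: the top-left corner is
$(\lfloor (H-r)/2 \rfloor, \lfloor (W-r)/2 \rfloor)$. The ROI is tiled
into non-overlapping 2×2 patches (49 of them for a 14×14 ROI). Each
patch contributes two scalars, which drive a 2-qubit circuit; the two
measured Pauli-Z expectations become the two channels at that patch's
grid position, giving a 7×7×2 *quantum feature map* with entries in
$[-1, 1]$. A compact CNN (the *student*) classifies the feature maps.
A larger CNN (the *teacher*) classifies a standardized classical view
of the same images and can transfer knowledge to the student through
temperature-softened distillation.

## The quantum core

The simulator is a dense statevector implementation. A register of $n$
qubits is a complex amplitude vector of length $2^n$ with unit norm;
**qubit 0 is the most significant bit** of the basis index, so for two
qubits the order is $|00\rangle, |01\rangle, |10\rangle, |11\rangle$
with qubit 0 the left bit. Tests pin this convention against an
independent oracle that builds each gate's full matrix by Kronecker
products and multiplies them out.

Two gates suffice for the pipeline:

$$RY(\theta) = \begin{pmatrix} \cos\theta/2 & -\sin\theta/2 \\
\sin\theta/2 & \cos\theta/2 \end{pmatrix}, \qquad
\mathrm{CNOT}: |q_c, q_t\rangle \mapsto |q_c,\, q_c \oplus q_t\rangle.$$

Pauli-Z expectations are computed from amplitudes,
$\langle Z_j \rangle = \sum_b (\pm 1)\,|a_b|^2$, sign by qubit $j$'s
bit. For a single RY on $|0\rangle$ this gives the closed form
$\langle Z\rangle = \cos\theta$, which anchors several tests.

**Angle encoding.** The two reduced patch values $v \in [0,1]$ enter as
$\theta = \pi v$. The scale $\pi$ (not $2\pi$) keeps the encoding
injective: $\cos(\pi v)$ is strictly monotone on $[0,1]$, so distinct
patch intensities map to distinct expectations. Out-of-range values are
clipped with a warning rather than rejected, since interpolation can
produce tiny excursions.

**Patch reduction.** A 2×2 patch must yield two angles; which two
values is a genuinely open choice. The default `row_mean` uses all four
pixels (mean of each row); `first_two` takes the first row literally.
`row_mean` is the default because it is insensitive to single-pixel
noise and makes the feature map a smooth function of the patch.

**The entangling block.** After encoding, each layer applies one RY per
qubit followed by a CNOT chain ($q \to q+1$; a single CNOT $0 \to 1$
for two qubits). Depth and angle initialization are unspecified in the
quanvolution literature's "random layers" recipe, so both are
configuration with documented defaults: `n_layers = 2`, angles drawn
uniformly on $[0, 2\pi)$ from a stored seed. The block is **frozen by
default** — feature maps are then a fixed deterministic transform and
can be precomputed and cached (the archive stores a configuration hash
and refuses to serve stale caches). Setting `trainable = TRUE` enables
parameter-shift gradients,
$\partial_\theta f = [f(\theta + \pi/2) - f(\theta - \pi/2)]/2$, which
is exact for RY-generated expectations (verified against central
finite differences at $10^{-6}$); caching is refused in that mode
because the map changes as $\theta$ moves.

## The classical models

Both roles share one architecture, differing only in width:

    Conv(f1, 3×3, same) → ReLU → MaxPool(2×2) → Conv(f2, 3×3, same)
    → ReLU → Flatten → Dense(64) → ReLU → Dropout(0.5) → Dense(K)

with teacher $(f_1, f_2) = (128, 256)$ and student $(64, 128)$.
Softmax is applied only at the loss/inference level. On a 7×7 input
only one 2×2 pool fits before the spatial grid collapses, so pooling
follows the first convolution only and both convolutions use same
padding; the pool uses floor semantics (a trailing odd row/column is
dropped) and first-slot tie-breaking. `dense_units = 64` is our
choice; the reference recipe leaves it open. Weights are
Glorot-uniform from a run-level seed.

There is no R deep-learning framework in this package's dependency
set; the forward/backward passes are written directly, with im2col
turning each convolution into one BLAS matrix product. Backpropagation
is verified coordinate-wise against numerical gradients on a small
network, and the analytic softmax–cross-entropy gradient $(p - y)$ is
checked against finite differences. Training is minibatch Adam
(learning rate $10^{-3}$, batch 8), at most 100 epochs with early
stopping on validation loss (patience 10, best weights restored —
the stopping criterion itself is our choice). Inverted dropout makes
evaluation passes deterministic. With a fixed seed the entire
trajectory — shuffling, initialization, dropout masks — is
bit-reproducible.

**Teacher input.** The teacher's input modality is open in this model
family. The default here is the per-image standardized
($X' = (X - \mu)/\sigma$, with an $\varepsilon$ guard on $\sigma$)
14×14 centered ROI: the same spatial support the student's quantum
features see, which makes the with/without-KD comparison
like-for-like rather than confounding distillation with a wider field
of view. `teacher_input = "image"` (full standardized canvas) and
`"quantum"` (the teacher also reads feature maps) are available.
Note the encoder reads the raw $[0,1]$ ROI, not the standardized one:
standardization can leave $[0,1]$ and would break the injective angle
range; the standardized view feeds only the classical teacher.

## Distillation

The student minimizes

$$\mathcal{L} = \alpha\,\mathrm{CE}(y, \mathrm{softmax}(S)) +
(1-\alpha)\,\mathrm{KL}\!\left(\mathrm{softmax}(T/\tau)\,\|\,
\mathrm{softmax}(S/\tau)\right)$$

with temperature $\tau = 5$ and $\alpha = 0.5$ by default. The KL
direction places the teacher as reference — the standard distillation
convention. The classical formulation multiplies the KL term by
$\tau^2$ to balance gradient magnitudes; the plain combined loss above
omits it, and a `squared_T_scaling` flag restores it. The teacher is
frozen: its logits are computed once, and a weight checksum before and
after training enforces the contract. Per-epoch histories record the
total loss and its CE and KL components separately.

Identities that pin the implementation (all tested): the loss is
linear in $\alpha$ and reduces to pure CE at $\alpha = 1$ and pure KL
at $\alpha = 0$; the KL term vanishes iff student and teacher softened
distributions coincide, where its gradient also vanishes; softened
probabilities approach uniform as $\tau \to \infty$ and the maximum
probability decreases strictly in $\tau$ for non-uniform logits.

## The phantom benchmark

The generator emulates the *statistical shape* of an imbalanced
ordinal severity-grading task, not MRI physics. Class $k \in
\{0,\dots,3\}$ is a bright elliptical ring around a dark cavity on a
faint parenchyma disc; cavity radius and ring thickness grow
monotonically with $k$ — a ventricle-enlargement proxy that makes
class confusions interpretable (adjacent grades look most alike).
Geometry is deterministic per class; the only generative randomness is
additive Gaussian pixel noise (`noise_sd`, default 0.05 on a $[0,1]$
scale — enough to perturb every pixel visibly without threatening ring
topology), clipped to $[0,1]$. Default canvas 28×28: the quanvolution
reads only a 14×14 centered ROI, so larger canvases would only add
empty margin; the side is configurable upward.

Class proportions default to $(0.14, 0.01, 0.50, 0.35)$, reproducing
the reference cohort's imbalance (896/64/3200/2240 at $n = 6400$);
counts are floor-rounded with the remainder assigned to the largest
class. Augmentation (rotation ±15°, horizontal flip $p = 0.5$, zoom
±10%, shift ±10% of the side — standard mild magnitudes, unspecified
in the source recipe) is a single inverse-mapped bilinear affine
resample, so zero limits give the exact identity and a flip is an
exact involution. Rebalancing tops up deficit classes with augmented
copies of their own members and subsamples surplus classes without
replacement. Post-augmentation class targets are exposed as
`target_counts` rather than hard-coded, because published
augmentation multipliers in this family are class-specific and
undisclosed.

**What passing tests show — and don't.** The phantoms are separable by
construction (a nearest-centroid baseline must beat chance + 0.20, and
the trained student reaches accuracy ≥ 0.90 and macro-F1 ≥ 0.85 on the
imbalanced 1,600-image study; in practice both arms saturate near
1.0). This validates the *machinery* — encoding, simulation, feature
assembly, training, evaluation — under a controlled signal. It says
nothing about performance on real MRI, where class overlap, scanner
variation and registration error dominate; headline accuracies
reported for real cohorts are expressly out of scope here.

## Evaluation protocol

Repeated stratified hold-out: 20% test, 10 repeats by default, repeat
$r$ seeded as `base_seed + r`; stratification (our choice; the
protocol's source is silent) preserves the imbalance in every split.
From the confusion matrix (rows = true): $P_k = TP/(TP+FP)$,
$R_k = TP/(TP+FN)$, $F1_k = 2PR/(P+R)$; macro averages are unweighted
class means, weighted averages are support-weighted. Zero denominators
yield 0 with a warning (never exercised by well-formed runs; a
convention had to be fixed). Weighted recall is accumulated in the
algebraically cancelled form $\sum_k TP_k / n$, so the identity
*weighted recall = accuracy* holds exactly in floating point, not just
to rounding. One-vs-rest AUC uses the Mann–Whitney rank statistic with
half-credit for ties — exact, tie-safe, and invariant under monotone
score transforms, unlike thresholded trapezoid schemes. All metrics
are cross-checked against caret and pROC at $10^{-10}$ in the suite.

## Numerical choices and degenerate inputs

- Probabilities are clipped at $10^{-12}$ inside CE and KL, so
  vanishing true-class probability yields a large finite loss.
- Softmax is max-shifted; logits up to ±50 are tested.
- `standardize` guards $\sigma$ with $\varepsilon = 10^{-8}$: constant
  images map to zero rather than dividing by zero.
- Simulator unitarity is preserved to $10^{-10}$ over random circuits;
  RY/CNOT circuits have real amplitudes, and the imaginary parts are
  asserted to be numerically zero.
- Augmentation samples outside the canvas read as 0 (background).
- The feature-map cache is keyed by a hash of (circuit seed, angles,
  layer count, reduction, ROI/target sides); a mismatch raises an
  error naming both hashes instead of recomputing silently.

## Problem sizes used by the checks

The shipped verification uses sizes chosen to keep a full run on one
CPU comfortable while still exercising every code path at its default
configuration: 200 random circuits against the dense oracle, a 10×10
encoding grid for the closed form, 50 parameter-shift configurations,
100 random label/score sets for the metric oracle, a 1,600-image
end-to-end study (rebalanced to 800 per class) with the student
trained up to 20 epochs, and a 240-image two-arm reproducibility run.
The experiment runner scales to larger studies unchanged.

## Known limitations

- The simulator targets small registers (the pipeline needs 2 qubits);
  it stores dense amplitude vectors and is not meant beyond ~10 qubits.
  No mixed states, noise channels, or shot sampling.
- Quanvolution is non-overlapping with stride = patch side; strided or
  overlapping variants are out of scope, as is amplitude encoding of
  flattened feature vectors.
- The CNN trainer is single-threaded apart from BLAS and implements
  exactly the architecture family described above; it is a faithful
  small trainer, not a general framework.
- Trainable-circuit mode computes parameter-shift gradients but the
  experiment runner keeps the circuit frozen by default, reflecting
  common quanvolution practice; joint end-to-end circuit+CNN training
  is exposed at the API level only.
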