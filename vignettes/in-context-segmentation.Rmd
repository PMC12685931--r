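---
title: "In-context segmentation with cross-attention support sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-context segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `icseg`, the reasoning
behind the design choices that were genuinely open, the synthetic data the
package trains and evaluates on, and what the desk-scale experiments do and
do not establish.

## The problem and the model

Universal (in-context) segmentation replaces one-model-per-task training
with conditioning: an episode pairs a query image with a support set of S
annotated `(image, mask)` examples that define the task, and the model
predicts the query's mask in one forward pass. The central hypothesis is
that not all support regions are relevant to a given query region, and that
relevant regions may sit at arbitrary spatial offsets; the architecture
therefore computes an explicit, global query-to-support attention map and
uses it as the only conduit between support annotations and the prediction.

Three encoders share a simplified multi-scale convolutional blueprint:

* the **Attention Mapper Encoder** embeds the query image;
* its **EMA twin** (exponential moving average of the online weights)
  embeds the support images — using a slowly-moving teacher for the
  support side prevents the attention from collapsing onto a single
  support location;
* the **Support Set Encoder** embeds image+mask pairs (2 input channels,
  image first, mask second) and is the only pathway by which mask
  information reaches the decoder;
* the **Segmentation Encoder** (same blueprint as the support encoder, 1
  input channel) provides the query-side skip connections.

### Receptive-field control

The blueprint deliberately keeps encoder receptive fields small so that a
feature vector describes only its immediate neighbourhood: attention maps
between such features stay spatially specific, which is what makes them
legible as explanations. All convolutions are 1×1 except (i) the stem's two
3×3 convolutions (strides 2 and 1), (ii) each stage's 3×3 stride-2
downsampler, and (iii) one 3×3 depthwise convolution in the first
feed-forward block of each stage. Under the standard accumulation
`r ← r + (k−1)·j; j ← j·s`, this layout pins the receptive field after
stem/stages 1–4 at 7/19/43/91/187 px on a 256-px axis — 2.7 %, 7.4 %,
16.8 %, 35.5 %, 73.0 % of the input — for *any* stage depths, because the
depth only adds pointwise layers. `theoretical_receptive_field()` computes
the accumulation from the recorded layer sequence;
`empirical_receptive_field()` cross-checks it by gradient masking on a
linearized probe (uniform positive kernels, identity activations, no
normalization), for which the gradient support equals the convolutional
receptive field exactly. Normalization layers are excluded from this
accounting, as is conventional: a per-sample z-score couples all positions
through two scalar statistics but carries no spatial pattern.

Stage depths and widths are not pinned by the receptive-field constraint;
the `paper` preset uses depths (3,3,5,2) and widths (64,128,256,512)
(≈21M parameters over the full model), the `tiny` preset (1,1,1,1) ×
(8,16,24,32) (≈86k parameters) for CPU-scale experiments. All pyramid
levels emitted as skip connections pass through a LayerNorm that z-scores
each sample jointly over channels and space, so every decoder input arrives
normalized.

### Coarse attention and registry tokens

At output stride 32 the query features `X^q` (HW×d) and EMA support
features `X^s` (SHW×d) enter a one-head attention with learnable
projections and temperature:

    A_i = softmax( X_i^q W_Q W_K' [X^s; t^s]' / (δ·T) )[, 1:SHW]

* W_Q and W_K are initialized near the identity (plus 0.02 noise), so the
  bilinear form starts as a plain similarity between the LayerNorm-scaled
  features and the coarse map is informative from the first training step;
* δ = 0.1·d is recomputed from the width, never stored;
* T = exp(τ) with τ learnable, initialized to 0 (T = 1). The
  exponential parametrization keeps T positive without constraints. The
  softmax argument is divided by the product δ·T exactly as written.
* `t^s` are `n_registry` learnable synthetic key rows (default 4,
  configurable; small counts suffice in the registry-token literature).
  Their softmax mass is discarded, so a row's support mass can drop below
  1 when the support set has nothing relevant — the decoder then simply
  adds less support evidence at that location.

Masks never enter this computation, so changing the annotation on fixed
images leaves `A` bit-identical.

### Attention upsampling

Recomputing attention at finer strides would scale quadratically in HW, so
the coarse map is upsampled instead. One upsampler stage, in order:

1. per-row attention mass `A_mass = rowSums(A)`;
2. 2× interpolation of the support axes (per support example) with the
   learnable mix `c·I_nn + (1−c)·I_lin`; `c = logistic(u)` with `u`
   initialized to 0 (c = 0.5, unbiased between nearest and bilinear) and
   guaranteed to stay in [0,1];
3. the same interpolation of the query axes (transpose, interpolate,
   transpose back);
4. the same interpolation of `A_mass` on the query grid, then each row is
   rescaled to its upsampled mass — interpolation must not manufacture or
   destroy support relevance;
5. the top-K entries per row (ties broken toward the lower flattened
   support index, for determinism) are refined individually:
   `A_ij ← A_ij · (1 + ELU(y))`, where y is produced by a two-layer GELU
   feed-forward network reading `(A_ij, query feature i, support feature
   j)` at the finer pyramid level. The factor `1 + ELU(y)` is positive, so
   refinement rescales but never flips sign; the FFN's last layer is
   zero-initialized so refinement starts as the identity. Non-top-K
   entries keep their interpolated values: a low coarse attention value is
   unlikely to become important by doubling the resolution, which is what
   makes the sparse refinement safe;
6. rows are rescaled to the upsampled mass again.

K quadruples from one upsampler stage to the next, matching the 4×
growth in locations (base K = 8 at inference → 32 and 128 refined
locations at strides 16 and 8; training uses base 5 and later 24 per the
schedule). When K exceeds the number of support locations — which happens
at small working geometries — it is clamped with a warning.

Interpolation uses the half-pixel-centre convention, edge-clamped, for both
the nearest and bilinear matrices; the same fixed matrices define the dense
oracle used in the tests, so oracle agreement checks the sparse bookkeeping
(reshapes, mass rescaling, top-K gathering), not the convention itself.

A fixed flattening convention is used everywhere: spatial positions are
row-major (h outer, w inner) and support examples are concatenated in the
given order. Exported attention maps carry this convention in their JSON
sidecars.

### Decoder

Five residual stages plus a head. Stage 1 fuses at stride 32 using the
coarse map directly; stages 2–3 upscale with 3×3 stride-2 transposed
convolutions, add an identity-initialized 1×1 projection of the segmentation
skip, upsample the attention, and fuse; stages 4–5 use query skips only;
the head upscales stride 2 → 1 and projects to one sigmoid channel.
Fusion is the Provided-Attention block

    X_i^q := X_i^q + (A_i · X^s) W_p + b_p

with `W_p`, `b_p` zero-initialized. Decoder stage widths mirror the
corresponding encoder stage widths. Every inner residual block's last layer is zero-initialized (the skip
projections, which are not residual last layers, start as the identity so
multi-scale detail is visible immediately); a structural consequence —
verified in the tests — is that
gradients reach the attention parameters only after the first optimizer
step has made `W_p` nonzero. Because weighted sums over support locations
are order-free, the final mask is exactly invariant to support permutation,
and zeroing the attention maps provably severs all influence of the support
masks.

## Training

The loss is squared-denominator DICE (weight 1) plus pixel-mean binary
cross-entropy (weight 0.25); BCE is computed from logits for numerical
stability. The reference protocol — AdamW, 155k steps, base learning rate
1e-4 halved at 75k/100k, weight decay 1e-3, S = 16, top-K 5 → 24 at 125k,
validation every 5k steps with early stopping — is the `train_config()`
default; desk-scale runs shrink the schedule proportionally (see below).
The EMA teacher (decay 0.999, a standard teacher value; updated once per
optimizer step; shadow initialized as a copy) tracks the online attention
encoder.

Augmentations: horizontal/vertical flips, rotations (±30°, bilinear for
images, nearest for masks), contrast (gamma in [0.7, 1.4]), intensity flip
(1 − x), Gaussian blur (σ in [0.5, 1.5] px), Gaussian noise (σ up to 0.05),
and mask-edge-as-target. Geometric transforms are drawn once per episode
and applied identically to every raster. Each augmentation fires
independently with probability 0.25, except mask-edge at 0.1 — it
redefines the episode's target (all masks are replaced by their 1-px
boundary band, the mask minus its 3×3 erosion), so it is kept rarer.
Magnitudes and probabilities are package choices; only the augmentation
*list* is fixed by the protocol.

## Synthetic episodes

`generate_task()` samples a task: a shape family (disk, rectangle, ring,
blob-union, thin-vessel), a foreground/background intensity pair (either
polarity, separated by ≥ 0.2), a noise level (σ ∈ [0.02, 0.06]), a
query-vs-support offset range (up to 25 % of the image width, exercising
the global attention), a size range, and 0–2 same-intensity distractor
shapes from other families (so that appearance alone cannot solve the
task). Episodes render each scene with a slight blur (σ 0.6 px) to avoid
unrealistic hard edges, enforce a 10-pixel minimum target area, and
translate the query target relative to the support targets. Held-out tasks
are generated with a flag that training streams refuse.

What this emulates: task-structured episodic data with appearance-defined
semantics, spatial offsets, and decoys. What it does not: anatomical shape
statistics, imaging physics, inter-annotator noise, 3D context. Passing the
desk-scale tests therefore demonstrates that the architecture's mechanisms
work (conditioning, mass conservation, retrieval), not clinical-grade
performance.

## Desk-scale study conditions

The expensive checks train one tiny model at 64×64 geometry — all stride
arithmetic scales; 256×256 remains the native geometry — on 96 tasks (each
backed by a finite pool of 24 rendered scenes, from which queries and fresh
support combinations are drawn, as one would from a finite set of annotated
slices) with S = 4, for 2000 steps (base lr 1e-3, halved at 1500/1800;
validation every 200 steps on 8 fixed episodes, patience 5). The top-K
schedule raises the base from 5 to the inference base 8 at step 1600: the
reference late value 24 is geometry-bound (it would exceed the 64-px
support grid and degenerate to dense refinement). The EMA decay is 0.99 at
this scale — a 0.999 teacher would never leave its initialization within
2000 steps — while 0.999 remains the default for long runs.
Evaluation uses 6 held-out tasks, 4 queries per (task, S) cell with fresh
support resampling per query, S ∈ {2, 4, 8, 16}, and two-level averaging
(queries within task, then tasks). The retrieval experiment uses a
two-cluster pool (two tasks with opposite intensity polarity), N = 20,
M = 8, 3 repetitions at S = 4 and S = 16 — scaled down from the reference
N = 150 / M = 100 / 10 repetitions, which remain the `retrieval_config()`
defaults.

## Numerical choices and degenerate inputs

* Softmax rows are max-shifted; zero-mass rows in renormalization are left
  at zero rather than divided.
* DICE on empty-vs-empty masks is defined as 1 (agreement that nothing is
  present), empty-vs-nonempty as 0; predictions are binarized at 0.5 for
  metric computation.
* The squared-denominator DICE loss carries an ε = 1e-7 guard.
* LayerNorm uses ε = 1e-6; on a constant input it returns zeros.
* GELU uses the tanh approximation throughout (training-speed choice, and
  self-consistent between forward and backward).
* `empirical_receptive_field()` measures a width-2 clone of the layout:
  receptive fields are width-invariant, and the thin probe keeps the
  check fast.
* All randomness flows through R's RNG; training, generation, evaluation
  and retrieval are reproducible given a seed (single worker).

## Retrieval design

The index stores, per pool image and coarse cell, the EMA encoder feature
projected by `W_K`; query-side contour locations are projected by `W_Q`,
matching the bilinear form inside the attention softmax. Contour points
(default 8; the count is a package choice) are sampled from the boundary of
the *predicted* mask under the generic support — the draft prediction is
what a user would have before annotating. Matches from multiple contour
points are combined by ranking pool images by match frequency and then best
similarity; ties fall to the lower image index. When fewer than S distinct
images are matched, the remainder is padded with the pool images most
similar overall.

## Known limitations

* The autodiff engine is single-threaded and eager; the `paper` preset is
  practical for inference and receptive-field analysis but not for training
  at full scale in R.
* The 32/128 refined-location consequence of base K = 8 requires the native
  256-px geometry; at 64 px the top-K clamps to the available locations.
* The attention upsampler's learnable mix is shared across the support,
  query and mass interpolations within a stage (one `c` per stage).
* Retrieval quality depends on the trained encoder; on an untrained model
  only strong appearance contrasts separate clusters.
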