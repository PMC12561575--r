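---
title: "Methods: attention-augmented stage classification for rat vaginal cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-augmented stage classification for rat vaginal cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The rat estrous cycle has four stages — proestrus (P), estrus (E), metestrus
(M) and diestrus (D) — that are routinely read from stained vaginal smears by
the mixture of cell types present: diestrus smears are dominated by
leukocytes with few nucleated epithelial cells; proestrus by nucleated
epithelial cells with a small number of cornified (keratinized, anucleated)
cells and no leukocytes; estrus contains only cornified cells; metestrus is a
mixture of all three kinds. Manual staging is slow and subjective, which
motivates an image classifier. This package implements such a classifier —
a compound-scaled MBConv convolutional network whose per-block
squeeze-excitation attention is replaced by a joint channel–spatial attention
block (SECA) and whose head carries a non-local self-attention block — along
with the surrounding pipeline: bicubic rescaling, stochastic augmentation,
a 6:2:2 split, AdamW training with early stopping, multiclass evaluation
statistics, an ablation harness, and analytic complexity accounting.

Because curated cytology images are not redistributable, the package also
ships a synthetic smear simulator so that every stage of the pipeline is
exercisable with labeled data generated in code.

## The network

The backbone is the canonical mobile inverted-bottleneck (MBConv) layout at
compound-scaling exponent zero: a 3×3 stride-2 stem (32 channels), 16 MBConv
blocks in seven stages (output channels 16, 24, 40, 80, 112, 192, 320;
expansion 1 for the first stage, 6 elsewhere; kernels 3 or 5), a 1×1 head
convolution to 1280 channels, global average pooling, dropout 0.2, and a
4-class linear layer. Batch normalization (ε = 10⁻³, momentum 0.1) and SiLU
activations follow every convolution. With a 4-class head the baseline counts
4,012,672 trainable parameters (4.01 M).

Compound scaling multiplies depth, width and resolution by α^Φ, β^Φ, γ^Φ
with (α, β, γ) = (1.2, 1.1, 1.15), whose constraint value α·β²·γ² = 1.92 is
checked against the admissible band [1.8, 2.2]. `width_mult`/`depth_mult`
give additional direct multipliers used for reduced desk-scale models.

### Joint channel–spatial attention (SECA)

Each MBConv block's squeeze-excite module is replaced by a two-branch gate:

* **Channel branch**, at the squeeze-excite position (on the expanded
  features after the depthwise convolution): the feature map is spatially
  average-pooled to a per-channel descriptor and passed through a
  1D-convolution gate with a sigmoid. Two readings of "local 1D convolutions
  replacing the fully connected layers" are implemented:
  `seca_channel = "local"` (a single k-wide kernel slid across the channel
  axis, k chosen adaptively as the nearest odd integer to log2(C)/2 + 1/2,
  at least 3) and `seca_channel = "bottleneck"` (a pointwise-1D-convolution
  squeeze/excite pair with reduction ratio 4, parameter-identical to the
  squeeze-excite module it replaces). The figure the two readings must be
  disambiguated against is the published parameter budget of the full model
  (14.19 M): the local reading yields 13.77 M (−2.9 %), the bottleneck
  reading 14.41 M (+1.55 %). The bottleneck reading is the closest-achieving
  configuration and is the default; the deviation is reported rather than
  absorbed.
* **Spatial branch**, at the block output (after the 1×1 projection): a 7×7
  convolution reducing C channels to max(8, ⌈C/4⌉), SiLU, a second 7×7
  convolution to a single channel, and a sigmoid, giving an H×W map that
  multiplies the features. Placing this branch on the expanded features
  instead would exceed 100 M parameters, which the published budget rules
  out; the block-output placement is the only reading compatible with it.
  The minimum reduced width of 8 avoids 1-channel bottlenecks in early
  narrow blocks.

The two branches are applied sequentially (channel first, then spatial on
the channel-gated features); both gates lie strictly inside (0, 1), so
gating never increases elementwise magnitude. The residual connection of the
MBConv block wraps the gated output.

### Non-local head block

Between the head convolution and the pooling layer, the 1280×7×7 feature map
is flattened to N = 49 positions × C = 1280 channels and passed through
scaled dot-product self-attention, `softmax(QKᵀ/√dk)V` with `Q = XWq`,
`K = XWk`, `V = XWv`, a `dk×C` output projection `Wz`, and a residual
connection. The softmax is taken row-wise (over keys) with max-subtraction
stabilization, so each output position is a convex combination of value
rows; the block is permutation-equivariant over spatial positions (there is
no positional encoding). Design choices where the block's wiring is
underdetermined: square projections `dk = C` (required to approach the
published 14.19 M budget — reduced-`dk` variants undershoot it), `Wz`
initialized to zero so the block is exactly the identity at the start of
training, no normalization inside the block, and a single block placed
exactly at the stated position.

## Preprocessing

**Bicubic rescaling.** Images are resized to 224×224 with the
cubic-convolution kernel

W(x) = (a+2)|x|³ − (a+3)|x|² + 1 for |x| ≤ 1; a|x|³ − 5a|x|² + 8a|x| − 4a
for 1 < |x| < 2; 0 otherwise,

evaluated over each output pixel's 4×4 source neighbourhood, channels
independent, output clamped to [0, 255]. The default sharpness constant is
a = −0.5 (the Keys kernel), which satisfies partition of unity — the four
neighbour weights sum to 1 at any fractional offset — so constant images are
reproduced exactly; a = 1 is also supported. Coordinates use half-pixel
centers, which makes same-size resizing the identity, and out-of-grid
neighbours are clamped to the edge, avoiding dark halos at image borders.

**Augmentation.** Training images are jittered on the fly: brightness
multiplied by u ~ U[0.85, 1.15] (up to 15 %), per-channel contrast
(p − mean)·c + mean with c ~ U[0.90, 1.10] (up to 10 %), optional horizontal
and vertical flips, and a rotation drawn from {0°, 90°, 180°, 270°} —
right-angle rotations only, so no interpolation or border fill is involved.
Results are clamped to [0, 255]. Jitter is treated as per-epoch
augmentation (not a one-off corpus edit) so validation and test
distributions stay fixed; a switch (`augment = NULL`) disables it.

**Split.** Records are globally permuted by a seeded RNG and cut 6:2:2 with
largest-remainder rounding; 2655 records give exactly 1593/531/531. The
split is global rather than class-stratified, which is what reproduces those
printed sizes.

## The synthetic smear simulator

`sample_scene()` draws per-kind cell counts from Poisson distributions with
stage-specific means — D: 120 leukocytes, 8 nucleated; P: 60 nucleated, 6
cornified; E: 70 cornified; M: 30/25/40 — and rejects any draw violating the
qualitative composition rule of its stage, so the invariants hold surely.
These means are simulator choices, not biological measurements: they are set
with wide margins so the qualitative cytological rules (the only quantitative
guidance available) hold with overwhelming probability. Geometry follows the
relative size ordering of the cell types: leukocytes are 3–6 px discs,
nucleated epithelial cells 10–18 px discs with a nucleus at 35 % radius,
cornified cells 18–30 px irregular polygons (8 vertices with radial wobble).
Rendering paints cells back-to-front (large pale cornified first, small dark
leukocytes last) with anti-aliased edges over an off-white background in
methylene-blue-like hues, modulated by a low-frequency multiplicative
illumination field, plus Gaussian luminance noise; overlap is allowed with
no collision resolution. The canvas default is 448×448 so that the bicubic
resize to 224 is a genuine downscale.

What the simulator does **not** emulate: real staining chemistry and its
variability, out-of-focus blur, debris and mucus, transitional-stage smears,
and the fine texture of chromatin. Passing the end-to-end check therefore
demonstrates that the pipeline can learn stage-discriminating composition
and morphology signals from images — not that it reaches any particular
accuracy on real cytology data.

## Training and evaluation

The reference recipe is AdamW (decoupled weight decay 0.01, betas 0.9/0.999
— the accepted defaults for the optimizer, which the source recipe leaves
unstated), learning rate 0.01, batch size 16, cross-entropy loss, at most
130 epochs with early stopping on validation accuracy at patience 20, and
restoration of the best-validation weights (including normalization
statistics). The learning-rate schedule is constant, as nothing else is
stated. Weight decay applies to convolution and linear weights only.
Undefined precision/recall (zero denominators) is reported as 0 with an
explicit flag. Multi-seed summaries use Student-t 95 % intervals
(t₀.₉₇₅,ₙ₋₁·s/√n; standard for n = 5; seeds 0–4 by default), paired t-tests
on per-class F1 against a comparator paired by seed, and report both the
per-class p-values and their average — averaging p-values is statistically
unconventional, so the per-class listing is always emitted alongside. Pairs
identical in every run give p = 1 with a degeneracy flag (a no-effect
convention); pairs with constant nonzero differences give p = 0, likewise
flagged. ROC/AUC and PR/AP use the one-vs-rest reduction; AUC is
threshold-grouped trapezoidal integration (equal to the pairwise
Mann–Whitney statistic with ties at ½) and AP is stepwise
precision-at-recall-increment summation. Confusion-matrix class order
follows the conventional E, M, D, P presentation.

### Desk-scale problem sizes

The end-to-end check trains a width-0.5 variant on 150 synthetic images per
class, generated directly at 224 px (360 train / 120 val / 120 test after
the 6:2:2 split), for at most 5 epochs at a constant learning rate of 10⁻³,
batch size 8, without augmentation. The reference rate of 0.01 (tuned for
130-epoch runs on real data) is unnecessarily aggressive at this scale. The
synthetic classes are fully separable — a multinomial logistic regression
on two dozen pooled color statistics classifies the held-out split
perfectly, and the same network trained for 15 epochs under the same
constant rate reaches test macro-F1 1.000 — so the target of macro-F1 ≥ 0.9
is a separability property of the simulator, not a claim about real data.
Within a short schedule the network solves estrus and diestrus first and
acquires the metestrus/proestrus distinction last (it emerges around
epochs 6–10), so the 5-epoch benchmark sits below the full-training
ceiling: the reference 5-epoch run reaches test macro-F1 0.85. Refreshing
the normalization running statistics before evaluation
(`recalibrate_bn()`) is essential in the memorization unit test, where one
optimizer step per epoch leaves the running averages far behind the
weights, but it *lowered* held-out accuracy in the benchmark — restoring
the best-validation epoch already pairs the weights with the statistics
they were selected under — so the benchmark leaves it off by default.

## Complexity accounting

`count_parameters()` counts trainable scalars exactly; the closed-form
per-layer arithmetic is verified in the tests. `count_flops()` counts
operations analytically per layer: convolutions and linear layers contribute
2·(k²·C_in)·C_out·H_out·W_out (multiply and add counted separately),
attention contributes its projection and matrix-product terms, channel gates
their pooled-descriptor products; normalization, activations, pooling and
elementwise gating multiplies are excluded. The reference complexity table
this implementation is dimensioned against reports 6.58 G for the baseline —
far above any single standard analytic convention for this backbone (the
2-ops-per-MAC count is 0.77 G) — so `flops_report()` treats the absolute
scale as an explicit calibration: one constant rescales the analytic counts
so the baseline lands on the 6.58 G anchor, and the full model is reported
under the same calibrated convention. The relative increase is the
convention-robust quantity. Note that the full model's analytic cost is
about 3.06× the baseline's — the 7×7 spatial-gate convolutions at full
feature resolution and the square-projection non-local head at 1280 channels
dominate — so the calibrated full-model figure (~20 G) is far above the
reference table's 9.35 G (+42 %): under the parameter budget that same table
prints, no uniform operation-counting convention can yield only a 42 %
increase, and this implementation reports the computed value rather than
absorbing the discrepancy. Inference wall-clock time is reported (mean of 5
runs) for information only; it is hardware-dependent and never asserted.

## Numerical choices and degenerate inputs

* Batch normalization uses biased batch variance for normalization and for
  the running statistics, ε = 10⁻³.
* Softmax and sigmoid computations subtract the row maximum / use the
  numerically stable forms; attention outputs are finite whenever inputs
  are.
* Weight init: fan-out-scaled normal for convolutions, N(0, 0.01) for the
  classifier, zeros for gate and projection biases, `Wz = 0`. The spatial
  gate's output convolution is also zero-initialized so every gate starts
  flat at ½ (the same neutral-start convention as `Wz = 0` for the
  non-local head): randomly initialized gates produce patchy, near-binary
  sigmoid masks that repeatedly blank spatial information across the 16
  stacked blocks and measurably stall optimization.
* Stochastic depth / drop-connect is omitted (unstated in the source
  recipe; omission improves reproducibility of parameter and behavior
  tests).
* Degenerate inputs are rejected with informative errors: images smaller
  than 4 px for resizing, canvases below 64 px for rendering, unknown stage
  labels, non-summing split ratios, empty training splits, even channel
  kernels, negative dataset counts.
* Everything is seeded: scene sampling, rendering noise, splits, weight
  init, shuffling, dropout and augmentation draws all flow from explicit
  seeds, and the full pipeline is bit-reproducible on one machine.

## Known limitations

* The simulator's realism gap (above) means synthetic results bound only
  the pipeline's correctness, not clinical performance.
* Training runs on the CPU in double precision; the desk-scale benchmark is
  sized accordingly. Full-scale (width 1.0, 130-epoch) training is
  supported by the same code but is not a desk-scale exercise.
* Only the Φ = 0 backbone is trained; larger compound exponents are
  supported by the scaling machinery but untested end to end.
* The published complexity table's FLOP figures are internally inconsistent
  with its parameter budget (see above); the package reports computed
  values under a documented calibration instead of matching both.
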