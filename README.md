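# slenet

Estrous-stage classification of vaginal smear images with a compound-scaled
convolutional network that combines joint channel–spatial attention inside
every inverted-residual block with a non-local self-attention head. The
package implements the full pipeline in R — a cytology image simulator,
preprocessing, the network and its attention modules, training, and
statistical evaluation — with the heavy numerical kernels in
Rcpp/RcppArmadillo.

## The scientific problem

The rat estrous cycle passes through four stages — proestrus (P), estrus
(E), metestrus (M) and diestrus (D) — that are routinely identified by the
cellular composition of stained vaginal smears: proestrus is dominated by
round nucleated epithelial cells, estrus by irregular anucleated cornified
cells, metestrus shows all three cell types together, and diestrus is
dominated by small leukocytes. Staging by eye is slow and subjective, which
motivates automated classification of smear photomicrographs.

This package provides:

* **`cytosim`** — a parametric generator of synthetic smear images. Each
  stage draws per-cell-type counts from stage-specific Poisson means
  (rejection-sampled so the defining composition rules always hold), renders
  leukocytes, nucleated epithelial and cornified cells as soft-edged shapes
  in methylene-blue-like hues over an uneven illumination field, and adds
  luminance noise. Generation is deterministic given a seed, so labelled
  datasets of any size can be reproduced exactly.
* **Preprocessing** — bicubic resizing to the network input size (the
  standard separable convolution kernel, `a = -0.5`, with a brute-force
  oracle in the tests), stochastic augmentation (brightness ±15 %, contrast
  ±10 %, flips, right-angle rotations) and a stratified 6:2:2
  train/validation/test split.
* **The model** — an inverted-residual (MBConv) backbone with compound
  scaling (`width ∝ 1.2^φ`, `depth ∝ 1.1^φ`, `resolution ∝ 1.15^φ`). The
  baseline uses squeeze-excite channel attention; the full model replaces it
  with a joint channel–spatial gate in every block (a 1D-convolutional
  channel branch plus a 7×7 convolutional spatial-mask branch) and appends a
  non-local self-attention block — softmax-normalized scaled dot-product
  attention over all spatial positions, initialized to the identity — before
  global pooling and the 4-class linear head.
* **Training and evaluation** — AdamW (decoupled weight decay) with early
  stopping on validation accuracy; confusion matrices; per-class and macro
  precision/recall/F1; one-vs-rest ROC-AUC (pairwise Mann–Whitney with ties
  at ½) and average precision; multi-seed summaries with Student-t 95 %
  confidence intervals and paired per-class F1 t-tests; and a four-variant
  ablation grid over the two attention components.

Everything is written against hand-derived backpropagation (no external
deep-learning framework); every module's gradient is verified against
central finite differences in the test suite, and the convolution, resize,
attention and AUC implementations are each checked against independent
brute-force oracles.

## Worked example

Simulate a small labelled dataset, inspect it, and look at the two model
variants:

```r
library(slenet)

man <- generate_dataset(c(P = 4L, E = 4L, M = 4L, D = 4L),
                        tempfile("smears"), seed = 42)
class_counts(man)
#> P E M D
#> 4 4 4 4
split <- split_manifest(man, seed = 42)
table(split$split)
#>
#>  test train   val
#>     3    10     3
```

```r
base <- build_model(model_config(attention = "se"), seed = 1)
full <- build_model(model_config(attention = "seca", use_nonlocal = TRUE),
                    seed = 1)
full
#> <slenet_model> seca attention, with non-local head
#>   input 224 x 224 | head 1280 | classes 4
#>   parameters: 14,410,504
count_parameters(base)
#> [1] 4012672
count_parameters(full)
#> [1] 14410504
fr <- flops_report(base, full)
c(fr$base_gflops, fr$full_gflops, fr$ratio)
#> [1]  6.580000 20.139270  3.060679
```

The operation counts are reported under a documented calibration (a single
constant scales the analytic 2-ops-per-multiply-accumulate counts so the
baseline lands on the 6.58 G reference anchor); the full model costs about
3.06× the baseline under any uniform convention.

Run the desk-scale benchmark end to end — 150 simulated images per class
at 224 px, 6:2:2 split, the width-0.5 network with both attention
components, 5 epochs of AdamW at a constant learning rate of 10⁻³, batch
size 8 (about 15–20 minutes on one core):

```r
res <- synthetic_benchmark(n_per_class = 150L, seed = 0L, width_mult = 0.5,
                           epochs = 5L)
res$history
#>   epoch train_loss   val_acc
#> 1     1  1.0772612 0.2833333
#> 2     2  0.8182890 0.4833333
#> 3     3  0.7283170 0.7750000
#> 4     4  0.6306175 0.8083333
#> 5     5  0.4512596 0.8666667
res$metrics
#> <metrics_report> accuracy 0.8500 macro-F1 0.8535
#>  class precision    recall        f1 undefined
#>      E 1.0000000 1.0000000 1.0000000     FALSE
#>      M 0.9500000 0.5277778 0.6785714     FALSE
#>      D 1.0000000 1.0000000 1.0000000     FALSE
#>      P 0.5952381 0.9615385 0.7352941     FALSE
```

Estrus and diestrus are classified perfectly after five epochs; the
metestrus/proestrus distinction is acquired last (extending the same
constant-rate run to 15 epochs reaches test macro-F1 1.000, and a
multinomial logistic regression on pooled color statistics separates the
four simulated stages perfectly, so the remaining confusion is training
budget, not class overlap). `ablation_grid()` runs the four attention
variants (baseline / joint gate / non-local / both) under identical seeds
and data and reports means, confidence intervals and paired p-values
against the baseline.

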