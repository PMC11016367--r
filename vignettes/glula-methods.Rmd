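---
title: "Compact linear-attention networks for wearable-sensor activity recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact linear-attention networks for wearable-sensor activity recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glula)
```

## The problem

Human activity recognition (HAR) from body-worn sensors classifies short
windows of multichannel time series — 3-axis accelerometer, gyroscope and
magnetometer streams sampled at tens to hundreds of Hz — into activities
such as walking, running or postures, or clinical events such as gait
freezes in Parkinson's disease. Two constraints shape the model family this
package implements: the networks must run on embedded and mobile hardware,
so parameter count and inference cost matter as much as accuracy; and HAR
datasets are small by deep-learning standards, so regularization carries
much of the weight.

## The architecture

Each input window is a $W \times C$ matrix (timesteps $\times$ channels).
The network, built by `build_model()`, processes it as follows:

1. **Embedding.** A per-timestep affine projection maps $C$ channels to a
   fixed width $d$. The rule `embedding_dim_for()` sets
   $d = m \cdot 2^{\lceil \log_2 C \rceil}$ with multiplier
   $m \in \{1, 2\}$ and a floor of 8: the smallest power of two covering the
   channels, doubled for very low-dimensional sensor sets so the model keeps
   enough capacity. Powers of two keep $d$ divisible by the head count.
2. **Class token.** A learnable $d$-vector is prepended at position 0
   (`prepend_class_token()`). Its final state is the *only* input to the
   classifier, which keeps the head tiny: two dense layers
   $d \to d \to K$ with Mish in between.
3. **Axial positional embedding.** Instead of a full $(W{+}1) \times d$
   table, two axis matrices $A \in \mathbb{R}^{r \times d}$ and
   $B \in \mathbb{R}^{c \times d}$ with $rc \ge W{+}1$ are combined
   additively: position $p = ic + j$ receives $A_i + B_j$. We use the
   near-square factorization $r = \lceil \sqrt{W+1} \rceil$, which makes the
   positional parameter count $O(\sqrt{W})$ rather than $O(W)$.
4. **Main block: gated causal convolutions.** With layer norm applied
   before the block and a residual around it, the block computes
   $(X * W + b) \otimes \mathrm{Mish}(X * V + c)$, where $*$ is causal
   convolution (inputs left-padded with $k-1$ zeros so position $t$ never
   sees the future) and $\otimes$ is the elementwise gate. Both
   convolutions map to a bottleneck width and a pointwise projection
   returns to $d$.
5. **Branched convolutions.** Two parallel causal branches — a pointwise
   (kernel-1) branch at width $d$ and a kernel-3 branch at width $d/4$,
   channel-padded before the merge — each pass through Mish and are summed,
   then a kernel-9 depthwise separable causal convolution projects back to
   $d$, with a residual around the whole block.
6. **Additional block.** One of three interchangeable mechanisms, selected
   by `model_config(additional_block = ...)`:
   - *softmax attention*: per head,
     $\mathrm{softmax}(QK^\top / \sqrt{d_k})V$, quadratic in sequence
     length;
   - *linear attention*: the kernelized form
     $\mathrm{out}_i = \phi(q_i)^\top \left(\sum_j \phi(k_j) v_j^\top\right)
     / \left(\phi(q_i)^\top \sum_j \phi(k_j)\right)$ with
     $\phi(x) = \mathrm{elu}(x) + 1 > 0$, computed through the summed
     key–value statistics so cost is linear in length;
   - *a second GLU block*.

   The three variants are called GLU-HAR, GLUSA-HAR and GLULA-HAR. Both
   attention flavours share one parameter layout (three input projections
   plus the output projection, all $d \times d$ with biases), so swapping
   them never changes the trainable-parameter count — a property the test
   suite enforces for every preset.

Attention here is deliberately **non-causal** while the convolutions are
causal. The class token sits at position 0; with causal convolutions it can
see only itself, so the attention block is the single mechanism by which
global window context reaches the classifier. A causal attention mask would
blind the token and is therefore not offered.

## Parameter accounting and the budget-pinning widths

`count_parameters(model, "per_block")` reports exact per-block counts that
sum to the total. Two sizing decisions were genuinely open and are pinned by
the parameter budgets the architecture is designed around (at most ~4.0K
parameters at the compact 6-channel/$d{=}16$ reference configuration, and
under 50K at the 52-channel/$d{=}64$ configuration):

- GLU bottleneck width $d/4$ (a $d/2$ bottleneck overshoots the compact
  budget);
- branch merge width $d$ with the kernel-3 branch at $d/4$ (an
  Evolved-Transformer-style $2d$ merge overshoots both budgets).

Both are `model_config()` fields (`bottleneck_ratio`, `narrow_ratio`), so
wider settings remain available. With the defaults the reference counts are
3,496 (compact) and 47,612 (large). Changing the window length alters only
the axial positional parameters — everything else depends on $d$, not $W$.

The per-block breakdown also records that the additional-block GLU variant
is *smaller* than the attention blocks under this sizing (472 vs 1,088
parameters at $d = 16$): a GLU additional block saves the four projection
matrices but spends nothing on new convolutions beyond its bottleneck.

## Dataset presets

`dataset_profile()` encodes the five benchmark-shaped presets the
architecture targets:

| preset | channels | rate (Hz) | window (s) | $d$ | heads | classes |
|---|---|---|---|---|---|---|
| pamap2 | 52 | 100 | 5 | 64 | 2 | 12 |
| skoda | 60 | 98 | 2.5 | 64 | 2 | 11 |
| opportunity | 113 | 30 | 5 | 128 | 2 | 18 |
| uschad | 6 | 100 | 1 | 16 (doubled) | 1 | 12 |
| daphnet | 9 | 64 | 5 | 16 | 1 | 2 |

Channel counts for SKODA (60) and OPPORTUNITY (113) are the conventional
ones for those benchmarks; the remaining settings follow the standard
protocols for these datasets. Real recordings are consumed through the
generic CSV dialect (`read_recording_csv()`); no dataset-specific parsers
are included.

## Preprocessing

`interpolate_nans()` repairs sensor dropouts by per-channel linear
interpolation between nearest finite neighbours, filling leading/trailing
gaps with the nearest finite value (the choice for edge gaps is ours; no
neighbour exists on one side). `fit_normalization()` computes per-channel
z-score statistics — population (divide-by-$N$) convention so pooled moments
reproduce bit-for-bit — on *training* subjects only; applying them to a
held-out subject generally leaves a nonzero mean, which is correct and
tested, not a bug. `sliding_windows()` segments with 50% overlap by default;
window coordinates are 0-based half-open, `step = round(W(1-overlap))`, and
the window count is $\lfloor (T-W)/\mathrm{step} \rfloor + 1$. Each window's
label is the majority vote of its timestep labels with ties broken toward
the lowest class index — a deterministic convention, since a window can
straddle an activity transition. `class_balance_weights()` provides
inverse-frequency sampling weights used only by the training sampler, never
by evaluation.

## Training

`train()` minimizes soft-label cross-entropy with the AdaBelief optimizer
(an Adam-family method whose second moment tracks the deviation of the
gradient from its running mean), under a one-cycle learning-rate policy:
cosine ramp from `max_lr/div` to `max_lr` over the first `pct_start`
fraction of steps, then cosine anneal to `max_lr/final_div`. Defaults —
peak $10^{-3}$, `pct_start` 0.3, `div` 25, `final_div` $10^4$, betas
(0.9, 0.999), $\varepsilon = 10^{-16}$, no weight decay — are the common
choices for this optimizer/schedule pairing and are exposed in
`train_plan()`. Batch size defaults to 64 and the multi-seed protocol
(`run_protocol()`) defaults to five seeds, reporting mean and standard
deviation of weighted and macro F1.

**Manifold mixup** (`mixup_config()`, applied inside `train()`): per batch,
draw $\lambda \sim \mathrm{Beta}(\alpha, \alpha)$ and a hook layer uniformly
from the eligible set, then replace the hidden state $h$ at that layer by
$\lambda h + (1-\lambda) h_{\mathrm{perm}}$ and the one-hot labels by the
same convex combination; gradients flow through the whole mixed graph.
Decisions made here: $\alpha = 2$ (the usual manifold-mixup default, never
printed for this architecture); the partner batch is the same minibatch
re-shuffled (simpler and deterministic; the algorithm permits either); and
the eligible layers are the embedding output and the output of the main
block — mixing after the attention block would blend class tokens across
samples, defeating the token readout, so later hooks are excluded by
design. The degenerate identities ($\lambda \in \{0, 1\}$) hold exactly at
every eligible layer and are tested; because the embedding stage is affine,
input-layer mixup coincides exactly with mixing the raw windows, which the
suite uses as an oracle.

All gradients are derived by hand and verified against central finite
differences for all three variants (including through the mixup hooks) to a
relative error below $10^{-4}$ on every tested coordinate.

## Evaluation

`f1_scores()` computes per-class precision/recall/F1 with the 0/0
$\rightarrow$ 0 convention for empty denominators (the formulas do not cover
absent classes; this is the standard choice), the weighted F1
$\sum_i w_i F1_i$ with $w_i$ the class's support share *in the evaluated
split* (whether weights come from train or test supports is unspecified in
the protocol this mirrors; test-split supports are used and documented), and
the macro F1. `loso_folds()` implements leave-one-subject-out
cross-validation; normalization and balancing statistics are refit within
each fold on training subjects only, and the suite verifies by window
signatures that no test window ever appears in a training set.
`chunk_folds()` covers the single-subject case: the recording is cut into
`n_chunks` *contiguous* non-overlapping chunks (boundaries at
$\lfloor iT/n \rfloor$, so lengths differ by at most one timestep) randomly
assigned to folds. Contiguity is our choice — random timestep-level
assignment would leak information between folds through the 50% window
overlap.

`benchmark_inference()` times single-instance forward passes (untimed
warm-up, then the mean over `reps` timed passes, in milliseconds). Timings
are hardware-dependent and informational only; the analytic
multiply-accumulate counts from `op_count()` are reported alongside, and
those — not wall-clock values — carry the complexity claims: the linear
attention core is $\Theta(N d^2/h)$ and the softmax core $\Theta(N^2 d)$ in
sequence length $N$.

## The synthetic-data generator

No public generator exists for this family of benchmarks, so the package
defines one (`generator_config()`, `generate_dataset()`) that reproduces the
properties the model exploits: local temporal patterns plus global window
context. Recordings are concatenations of activity bouts (lengths uniform
on 150–400 timesteps at 50 Hz, i.e. 3–8 s, the scale of natural activity
bouts); within a bout of class $c$ every channel carries
$a_c g_j s_j \sin(2\pi f_c t + \varphi_j) + b_c$ plus iid Gaussian noise,
where $f_c, a_c, b_c$ are class frequency/amplitude/postural baseline,
$\varphi_j, g_j$ fixed channel phase/gain signatures, and $s_j$ a
multiplicative log-normal per-subject channel scale — the minimal mechanism
that makes leave-one-subject-out genuinely harder than a random split.
Missing values are inserted as contiguous runs (geometric length, mean 5)
per channel, mimicking sensor dropouts rather than iid missingness, and
never cover a whole channel. Defaults: 5 subjects, 4 classes with
frequencies $0.8 \cdot 1.55^c$ Hz and unequal class weights (40/30/20/10%),
noise sd 0.4, 2% missingness, 300 s per subject — about 2,300 windows of
64 timesteps at 50% overlap, a deliberately small-data regime.

What the generator does *not* emulate: biomechanically realistic motion,
slow heart-rate-style channels at a different sampling rate, sensor
drift/recalibration, or label noise. Tests passing on this data therefore
demonstrate the pipeline's correctness and the architecture's capacity to
exploit class-dependent spectral structure under subject shift — not
state-of-the-art accuracy on real benchmarks, which require the original
datasets.

## Numerical choices and degenerate inputs

- Layer norm uses $\varepsilon = 10^{-5}$; the linear-attention denominator
  is stabilized by $10^{-6}$ (harmless since $\phi > 0$ makes it strictly
  positive anyway).
- Softmax attention subtracts the row max before exponentiating.
- Mish is computed through a softplus that switches to the identity beyond
  $x = 20$, avoiding overflow while staying within $10^{-6}$ of the exact
  value.
- Constant channels are recorded with sd 0 and guarded by the stats epsilon
  at apply time, normalizing to exactly zero.
- A recording shorter than one window yields an *empty* batch plus a
  warning, not an error.
- Weight initialization is uniform with Glorot-style limits (convolutions
  use fan-in $k \cdot C_{\mathrm{in}}$); token and positional tables are
  Gaussian with sd 0.02; all biases start at zero, which makes every
  residual block the identity at zero block weights — also a test.

## Problem sizes used by the test suite

The suite builds everything it needs programmatically: oracle comparisons
run on instances of length 3–8 and width 4–8; causality is checked by
perturbing all 32 positions of a $32 \times 8$ sequence; metric fuzzing
uses 1,000 random label vectors; the end-to-end check trains the compact
linear-attention model (3,296 parameters at $W = 64$) for 30 epochs on
~1,870 windows from four synthetic subjects and requires weighted F1
$\ge 0.90$ on the held-out fifth subject in at least two of three seeds.
Training-behaviour tests (loss halving, the mixup-vs-no-mixup macro-F1
guard) use a 60 s-per-subject variant of the same generator — scaled-down
study conditions chosen to exercise identical code paths.

## Known limitations

- Depth is fixed at one main block plus one additional block, matching the
  reference design; the configuration object is extensible but stacking is
  not implemented.
- Only z-score normalization is provided; per-dataset normalization
  variants are out of scope.
- No resampling between sampling rates: windows are expressed in timesteps
  derived from seconds at the recording's own rate.
- Training is CPU-only and single-threaded R; it is intended for the
  synthetic-scale experiments above, not for full benchmark training runs.
- Checkpoints and window containers use R's native serialization, and are
  not interchangeable with other frameworks.
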