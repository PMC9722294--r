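---
title: "Methods: adaptive quinary texture codes, multilayer dense-net features, and their fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive quinary texture codes, multilayer dense-net features, and their fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpheno)
```

# The problem and the model

Cell phenotype recognition in fluorescence microscopy is dominated by
micro-texture: two phenotypes can occupy the same cell outline yet differ
completely in the local arrangement of bright structures (filaments,
puncta, meshes, rings). `cellpheno` classifies such images with two
complementary representations, fused before classification:

1. a *handcrafted* descriptor — the improved local quinary pattern (ILQP)
   with thresholds estimated per image, and
2. a *learned* representation — globally pooled intermediate feature maps
   from a densely connected CNN, tapped at dense blocks 2–4.

## ILQP

Each pixel with a complete neighborhood contributes one quinary pattern.
For neighbor intensities $g_i$ around center $g_c$ and thresholds
$T_1 \le T_2$:

$$\rho(g_c, g_i) = \begin{cases}
2 & g_i \ge g_c + T_2\\
1 & g_c + T_1 \le g_i < g_c + T_2\\
0 & g_c - T_1 \le g_i < g_c + T_1\\
-1 & g_c - T_2 \le g_i < g_c - T_1\\
-2 & \text{otherwise.}
\end{cases}$$

Branches are evaluated in this order with first match winning; this makes
the map total for every threshold pair, including the degenerate
$T_1 = T_2$ and $T_1 = 0$ cases (a constant image has both thresholds zero,
every digit becomes $2$, and the whole $B_2$ histogram mass lands on code
$2^P - 1$ — a useful smoke invariant). The four channel indicators $B_2,
B_1, B_{-1}, B_{-2}$ are read as $P$-bit codes (bit $i$ weighted $2^i$) and
histogrammed, so per scale the descriptor is $4 \cdot 2^P$ counts.

The thresholds are statistics of the image itself:

* $T_1 = \mathrm{GMAD} = \mathrm{median}_k\,|\,\mathrm{lmad}_k -
  \mathrm{median}(\mathrm{lmad})\,|$, where $\mathrm{lmad}_k =
  \mathrm{median}_i\,|\,g_i - \mathrm{median}(G)\,|$ over neighborhood $k$;
* $T_2 = \mathrm{GSV}$, the mean over neighborhoods of
  $\mathrm{LSV} = \tfrac1P \sum_i |g_c - g_i|$.

Both are medians/means of absolute differences, hence shift-equivariant and
positively homogeneous: adding a constant to the image changes nothing at
all, and multiplying by $k > 0$ scales thresholds and differences together,
leaving every digit unchanged. The test suite asserts both invariances
exactly, and checks the whole descriptor bin-for-bin against a deliberately
naive double-loop reference.

### Design choices in the descriptor

* **Aggregation of local MADs.** One common description of GMAD calls it
  the *average* of local MADs, while the formula we implement takes the
  median absolute deviation of the lmad set. We follow the formula as the
  default (`gmad_mode = "mad_of_lmads"`) and expose the mean as
  `"mean_of_lmads"` — the discrepancy is user-visible, never silent.
* **GSV denominator.** The textbook normalization divides the LSV sum by
  the full image area $M \times N$, although only $(M-2R)(N-2R)$
  neighborhoods exist. A mean should average over terms that exist, so the
  default divides by the count of valid neighborhoods
  (`gsv_denominator = "valid"`); the literal image-area variant stays
  reachable (`"image_size"`).
* **Threshold canonicalization.** If GMAD exceeds GSV (possible on unusual
  intensity distributions), the pair is swapped so that $T_1 \le T_2$,
  which the five intervals require to be disjoint and exhaustive.
* **Geometry.** The default scale $(P, R) = (8, 1)$ uses the exact 3×3
  square ring read clockwise from the top-left — the classic LBP
  convention, and the one under which a brute-force oracle can match
  bit-for-bit. General $(P, R)$ places neighbors on a circle at angles
  $2\pi k/P$ (clockwise from 12 o'clock) with bilinear interpolation.
* **Borders.** Only complete neighborhoods are coded; there is no padding.
  Padding would invent intensities and break the shift-invariance proof.
  Consequently every channel histogram sums to exactly $(M-2R)(N-2R)$.
* **Medians of even-length sets** use the mean of the two middle order
  statistics, fixed so oracles agree exactly.
* **Histogram size guard.** Scales with $P > 12$ (e.g. the 65 536-bin
  $P = 16$ case) are refused unless `allow_large = TRUE`; silent
  65 536-dimensional blocks are a foot-gun.
* **Normalization.** Counts by default; L1 frequencies (`normalize = TRUE`)
  when image sizes vary across a dataset.

## Multilayer dense-net features

The backbone follows the canonical dense-connectivity design. Stem: 7×7/2
convolution, BN, ReLU, 3×3/2 max pool. Dense layer: BN–ReLU–1×1 conv (to
$4g$ channels)–BN–ReLU–3×3 conv (to $g$ channels), each layer consuming the
concatenation of the block input and all previous layers' outputs, so layer
$\ell$ sees $c_{in} + (\ell - 1)g$ channels. Transition: BN–ReLU–1×1 conv
with compression 0.5, then 2×2/2 average pool. The four named variants
differ only in per-block layer counts: 121 → [6, 12, 24, 16],
169 → [6, 12, 32, 32], 201 → [6, 12, 48, 32], 264 → [6, 12, 64, 48]; growth
rate 32, stem width 64, input 224 px (the 112² post-stem map fixes the
input side). The closed-form block outputs
$c_{out}(b) = c_{in}(b) + L_b g$, $c_{in}(b{+}1) = \lfloor 0.5\,
c_{out}(b)\rfloor$ are verified in tests against the constructed networks'
actual weight shapes.

The classification head is removed. Features are taken at the *end of each
dense block, before its transition* — block 4 has no transition, so this is
the only uniform choice — passed through global average pooling per channel
(the "dimension reduction"; flattening is then a plain reshape), and
concatenated in block order. Block 1 is excluded by default: its low-level
content is what the texture descriptor already supplies.

One-vs-rest fine-tuning attaches an independent sigmoid output per class on
the pooled final block and minimizes the summed per-class focal loss
$-\alpha_t (1 - p_t)^\gamma \log p_t$ with $\gamma = 2$, Adam, a two-phase
learning rate ($10^{-5}$ then $10^{-6}$) and weight decay $10^{-2}$, the
package's default schedule. $\alpha_t$ is the
per-batch inverse class frequency ($n/(2 n_{pos})$ for positives,
$n/(2 n_{neg})$ for negatives — a 90/10 split weights the minority 9×),
switchable to uniform; the class-imbalance motivation for focal loss makes
the balanced form the natural default. $p_t$ is clamped to
$[10^{-7}, 1]$ for log stability. The fine-tuned or stock network feeds the
same extractor; both paths are first-class so users can compare them.

**Why a built-in engine?** No deep-learning framework is available in the
package's dependency footprint, and the networks needed here are small
enough that an im2col-based engine in plain R (convolutions become BLAS
matrix products) is entirely adequate. The full backward pass is verified
against central-difference numeric gradients end to end (stem convolution,
dense-block concatenation, batch norm, head) at relative error ~1e-9 in the
test suite — a much stronger correctness guarantee than visual loss
inspection.

## Fusion and evaluation

Texture and deep blocks are concatenated and standardized per feature
(subtract train mean, divide by train *population* standard deviation; a
constant feature maps to 0). Normalization statistics are fitted inside
each training fold only — a property test perturbs the held-out fold and
asserts the fitted statistics are untouched. The classifier bank fixes
hyperparameters for reproducibility rather than tuning them: k-NN with
k ∈ {1, 3, 5} (neighbor ties resolved by training index, vote ties by
smallest class index); an MLP with one hidden layer of 100 ReLU units
trained by full-batch Adam to loss-change tolerance $10^{-4}$ (implemented
in-package: quasi-Newton fitters need memory quadratic in the weight count,
hopeless for $10^3$-dimensional fused features × 100 hidden units); a
100-tree random forest; an RBF SVM with $C = 1$.

Metrics come from the pooled per-fold confusion matrix: accuracy
$= 100 \cdot \mathrm{trace}/\mathrm{total}$, per-class precision
$TP/(TP+FP)$ and recall $TP/(TP+FN)$, $F1 = 2PR/(P+R)$, macro-averaged
(unweighted over classes). A class never predicted in a fold has undefined
precision; it is set to 0 with a warning rather than propagating NaN into
the macro mean. Aggregation over folds reports mean ± sample standard
deviation. Stratified 5-fold is the declared default for K, configurable.

# The synthetic phenotype generator

Real benchmark collections cannot be redistributed with the package, so a
generator produces labelled grayscale images whose classes differ in
micro-texture the way fluorescence phenotypes do:

| family     | emulates                | key parameters (defaults) |
|------------|-------------------------|---------------------------|
| filament   | cytoskeletal fibres     | ~Pois(25) segments, orientation 45° ± 20°, length 40 px, ridge blur σ 1.2, amplitude 0.8 |
| punctate   | vesicles / speckles     | Pois(30) spots, Gaussian radius σ 1.5 px, amplitude U(0.5, 1) |
| blob       | nucleus-like masses     | 2 smooth peaks, scale σ 20 px, amplitude 0.9 |
| reticular  | ER-like mesh            | band-pass filtered noise, inner scale 4 px (outer 3×), amplitude 0.8 |
| ring       | nucleolar / membrane annuli | ~Pois(8) rings, radius 7 ± 3 px, width σ 1.5, amplitude 0.8 |

All families share background 0.1, additive Gaussian noise σ 0.05, an
optional signal-dependent noise term, intensities clamped to [0, 1] and
quantized to the 16-bit grid (so disk round trips are bit-exact). Images
default to 128² — large enough for ~16 000 neighborhoods per image, small
enough that the full 200-image study set regenerates in about a second.
Per-image seeds derive deterministically from the master seed, making the
whole dataset a pure function of `(specs, n, side, seed)`.

The defaults were chosen once so that the five classes are separable by
texture alone while keeping deliberately hard cases: the blob class is
nearly texture-free (its ILQP histograms resemble background), and small
blurred annuli share local structure with spots. The generator emulates
*micro-texture contrast between classes under additive noise*; it does not
emulate cell segmentation artefacts, optics beyond Gaussian blur,
illumination gradients, scale variation, or intra-class biological
heterogeneity. Tests passing on these images therefore demonstrate that
the pipeline's machinery is correct and that the descriptor separates
texture families as designed — not that any particular accuracy carries
over to real collections.

# Numerical choices and degenerate inputs

* Quinary branch order is first-match-wins, making coding total for all
  threshold values; thresholds are swapped into $T_1 \le T_2$ before use.
* Images must be finite, non-negative matrices at least $(2R+1)$ px per
  side for every requested scale; violations are errors naming the scale,
  never silent truncation.
* Preprocessing for the network resizes bilinearly to the input side, maps
  to [0, 1] (÷255 or ÷65535 when the input looks 8-/16-bit), replicates the
  gray channel threefold and standardizes with the fixed constants
  mean (0.485, 0.456, 0.406), sd (0.229, 0.224, 0.225).
* Batch norm uses batch statistics in training and running statistics
  (initialized to 0/1, momentum 0.1, ε 1e-5) in evaluation; a zero-weight
  network is therefore exactly the zero map in evaluation mode, which the
  tests exploit.
* Adam uses bias correction and applies weight decay to convolution and
  head weight matrices only (not biases or BN parameters).
* All randomness flows through explicit seeds: build seed (initialization),
  training seed (head init + shuffling), fold seed, per-image seeds. Two
  runs of the pipeline with one configuration produce byte-identical report
  JSON.

# Problem sizes

Routine runs use the compact backbone ([2, 2, 2, 2] blocks, growth 8,
64 px input — 96-dimensional deep features with taps {2, 3, 4}) and the
128 px / 40-images-per-class synthetic study set; these sizes were chosen
so a complete end-to-end run takes seconds on one CPU core while exercising
every code path of the full-size variants, whose channel arithmetic is
verified exactly. The standard 121/169/201/264 backbones are fully
constructible and runnable, just slower.

# Known limitations

* Random-initialization deep features are weak descriptors; the deep block
  earns its keep with pretrained or fine-tuned weights, which the package
  accepts but does not ship.
* The in-package engine is single-threaded R; fine-tuning the full
  DenseNet-169 at 224 px is out of its intended envelope.
* The 2-epoch training smoke moves weights only slightly at the default
  learning rate of $10^{-5}$; its epoch-loss decrease is reliable at the
  smoke experiment's fixed seed but sits near noise level across arbitrary
  seeds.
* Multi-scale ILQP beyond $P = 12$ produces very high-dimensional
  histograms; the guard forces that choice to be explicit.
* k-NN tie-breaking by smallest class index is deterministic but
  order-dependent by construction; it matters only on exact vote ties.
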