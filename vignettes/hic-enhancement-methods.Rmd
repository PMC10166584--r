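---
title: "Enhancing Hi-C contact matrices with a dilated fully convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing Hi-C contact matrices with a dilated fully convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdcn)
```

## The problem

A Hi-C experiment measures pairwise contact frequencies between genomic
loci; binned at a fixed resolution (here 10 kb), one chromosome yields a
square symmetric matrix of read-pair counts. Fine structures — chromatin
loops, topologically associating domains (TADs), sub-domain boundaries —
are only visible when sequencing is deep enough that each 10 kb bin pair
carries signal. Most public Hi-C libraries are far shallower. `hicdcn`
learns a mapping from a shallow ("low-resolution") contact matrix to a deep
("high-resolution") one, trained on pairs produced by down-sampling deep
data, and then applies that mapping to whole chromosomes in a single pass.

## The model

The enhancer is a 10-layer fully convolutional residual network operating
on a single-channel matrix $L$:

* **Encoding module.** A 3×3 vanilla convolution $C_e$ followed by two 3×3
  dilated convolutions $D$, joined by a residual skip:
  $F_e = C_e(L) + D(D(C_e(L)))$.
* **Mapping module.** Two residual components, two further dilated
  convolutions, and a final 1×1 convolution $C_m$:
  $F_m = C_m(D(D(R(R(F_e)))))$, where each residual component applies two
  dilated convolutions and adds the intermediate back,
  $R(F) = D_1(F) + D_2(D_1(F))$.
* **Merge layer.** The output is $S = F_m + L$: the network learns a
  residual correction to the input.

Channels per layer are $[32, 32, 32, 64, 64, 128, 128, 256, 256, 1]$
(1,181,185 trainable parameters), dilation 2 on layers 2–9 (a grid of 2, 5,
7, 9 is supported via `model_spec(dilation_rate =)`), and ReLU after layers
1–9. Every convolution is zero-padded to "same" size, so the operator
accepts any input side length; the receptive-field radius is 17 entries at
dilation 2 (9 for the all-vanilla ablation, `swap_to_vanilla()`).

Two design points were genuinely open and resolved as follows:

* **Final-layer activation.** The 1×1 output layer is *linear*. Since
  $S = F_m + L$, a ReLU-capped $F_m$ could never decrease an entry of $L$,
  which would make denoising of over-sampled entries impossible.
* **Weight sharing.** All 10 layers have independent weights; the channel
  progression forces this for the residual additions to be shape-consistent
  (32+32, 64+64, 128+128), which is validated at build time.

The forward and backward passes are implemented in C++ (single precision,
tap-wise shifted GEMMs riding on the linked BLAS) so that training runs at
practical speed on one CPU and whole chromosomes are enhanced without
materializing an im2col buffer. Patch tensors are single precision by
construction; whole-matrix outputs are returned in double with the input
added back in double precision, so a zero-weight model is exactly the
identity.

## Training

Patches are 40×40 blocks tiled without overlap at block-aligned offsets
from the (high, low) matrix pair, keeping upper-triangle block pairs whose
entries all lie within 2 Mb genomic distance (`b − a ≤ 4` at 10 kb: the
farthest entry of an offset-4 pair is 1.99 Mb). The 2 Mb cap reflects that
TADs rarely exceed 1 Mb; restricting training to the band keeps the
training distribution on the structure-bearing region. Trailing bins that
do not fill a block are dropped rather than padded — inference is
whole-chromosome anyway, so padded patches would serve nothing.

The loss is the pooled mean absolute error
$\frac{1}{n}\sum_{ij} |H_{ij} - S_{ij}|$ over all entries of a batch.
Optimization is Adam (learning rate $10^{-4}$, conventional
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), shuffled
mini-batches, no learning-rate schedule, weight decay, or early stopping.
Patches are split 9.5:0.5 into training and validation
(`split_train_val()`), and after every epoch the validation MAE is
computed; the returned checkpoint is the epoch minimizing it. The reference
schedule is batch 128 for 500 epochs; desk-scale runs lower both (see
below). Training on raw counts (not normalized) is deliberate: the
down-sampled input and deep target live on the same count scale, and the
merge layer's identity path is only meaningful if both sides share units.

Network outputs are neither symmetric nor non-negative by construction, so
at the contact-matrix boundary (`enhance()`) the output is symmetrized as
$(S + S^\top)/2$ and negatives are clamped to zero. This happens only
there — the training loss sees the raw network output.

## The synthetic generator

`simulate_hic()` draws one chromosome whose expected intensity is

$$e(i,j) = \text{scale} \cdot (1+|i-j|)^{-\alpha}
  \cdot (1 + \beta_{TAD}\,\mathbf{1}[\text{same TAD}])
  \cdot (1 + \beta_{loop}\,k(i,j)),$$

with counts drawn as independent Poisson variables on the upper triangle
and mirrored, and `scale` fixed so the expected matrix total equals the
configured depth. The defaults are chosen once as a realistic deeply
sequenced 8 Mb arm at 10 kb: $\alpha = 1$ (the classic $s^{-1}$
contact-probability decay), TAD sizes uniform in 100 kb–1 Mb tiling the
chromosome, a 2× within-TAD enrichment ($\beta_{TAD} = 1$), 40 loop anchor
pairs sampled 30–300 kb apart with Gaussian bumps of radius 1 bin at 4×
enrichment, and $2\times 10^6$ expected read pairs — near-diagonal bins
then carry a few hundred counts, long-range bins a handful, matching the
character of deep 10 kb maps. Poisson noise is a modeling choice (the
dispersion of Hi-C counts is not settled); a negative-binomial alternative
is available via `nb_dispersion`.

Shallow sequencing is emulated by `downsample_reads()`: every
upper-triangle count is replaced by a $\mathrm{Binomial}(c, r)$ draw and
mirrored — identical in distribution to retaining each read pair
independently with probability $r$, and far cheaper than resampling an
explicit read list. The study rates are 1/8 to 1/100 with 1/16 as the main
rate. Diagonal entries are thinned like any other entry.

What the generator does **not** emulate: A/B compartment checkerboards,
trans contacts, restriction-fragment granularity, mappability and GC bias,
copy-number steps, or the correlated noise of real libraries. Passing
tests on synthetic data therefore demonstrate that the implementation
learns and evaluates correctly under the assumed structure — not that the
trained weights transfer to real tissue data; for that, train on real
matrix pairs imported via the I/O layer.

## Evaluation metrics

For a ground truth $H$ and comparison $S$: MSE; PSNR
$= 10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$ with $\mathrm{MAX}$ the
largest entry of $H$ (reported as `Inf` when $S = H$); and SSIM evaluated
as a *single global window* with $c_1 = 0.01$, $c_2 = 0.03$ and dynamic
range defaulting to $\max(H) - \min(H)$ — fidelity to the printed formula
rather than the sliding-window image variant, which remains available via
`hic_ssim(window =)`. Correlation tracks group upper-triangle entries by
genomic distance and compute Pearson and Spearman (mid-rank ties) per
distance up to 2 Mb; zero-variance groups yield `NA` rather than an error.

Interaction recovery compares two significant-interaction sets (e.g.
Fit-Hi-C calls at q < 10⁻⁶ on the true versus enhanced matrix, restricted
to the 30–300 kb band; both band bounds are inclusive, the source range
being stated without openness). Precision, recall, and F1 are standard set
arithmetic; the false-positive *rate* is defined as
$\mathrm{FP}/|\text{predicted}|$ — the proportion of predicted calls that
are spurious — since no formula accompanies the term in the source
literature. The package exports Fit-Hi-C's input files
(`export_fithic()`) and parses its output (`read_fithic_interactions()`),
but the significance model itself is external.

## Desk-scale problem sizes

The package's end-to-end experiment (tests and `scripts/acceptance.R`)
uses three 800-bin synthetic chromosomes: two for training (180 patches,
171/9 split), one held out. Training runs 12 epochs at batch 32, learning
rate $10^{-4}$ — the batch and rate follow the reference schedule scaled
to the patch count, and 12 epochs is where the validation MAE is still
falling smoothly while a run completes in minutes on one CPU. Under these
conditions the enhanced held-out chromosome improves on its low-resolution
input in MSE, PSNR, SSIM, and mean distance-stratified Pearson
correlation. Numbers are computed at run time by the scripts; none are
hard-coded.

## Numerical choices and degenerate inputs

* Single-precision arithmetic in the network; double elsewhere. The
  identity fixed point (zero weights ⇒ output = input) is exact because
  the residual is added to the input in double.
* Zero padding realizes "same" convolutions; consequently outputs are only
  trustworthy beyond the receptive-field radius from a crop border, which
  the crop-consistency test quantifies.
* Weight initialization is He-style fan-in truncated normal (truncation at
  2 sd), seeded; biases start at zero.
* Symmetrization on read mirrors the upper triangle when only it is
  present; the diagonal is taken as-is, never doubled. Triplet dialect
  (bin indices vs bp positions) is auto-detected — any coordinate ≥
  resolution implies bp — and overridable.
* Empty patch lists assemble to a zero matrix; duplicate blocks at one
  position are an error, not a silent overwrite.
* An empty predicted interaction set has undefined precision (`NA`) and
  F1 = 0. Constant matrices need an explicit SSIM dynamic range.
* Training aborts with a diagnostic on non-finite loss rather than
  returning garbage weights.

## Limitations

* The global-window SSIM is not comparable to sliding-window SSIM values
  from image-processing toolboxes (use `window =` for those).
* Training two identical runs bit-identically assumes the same BLAS and
  thread count; across platforms, expect agreement only to accumulation
  order.
* Whole-chromosome enhancement of very large chromosomes (≳25,000 bins)
  holds several float activation maps of size $n^2 \times 256$; memory,
  not correctness, is the constraint, and a banded/tiled fallback is
  deliberately not the default because tiling is what the architecture
  set out to remove.
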