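---
title: "Counting axons by density-map regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting axons by density-map regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axodense)
```

## The counting problem

Optic-nerve cross sections imaged by light microscopy contain thousands of
retinal ganglion cell axons. In glaucoma research the number of
"normal"-appearing axons — an intact, continuous myelin sheath around a
homogeneous light interior — is a primary outcome, and the gold standard is
manual annotation: trained counters place one point per axon. Segmenting
individual axons at light-microscopy resolution is hard, especially in
damaged tissue, so this package instead regresses a *count density*: a
nonnegative per-pixel field whose integral over any region is the expected
number of axons in that region. Counting then reduces to integrating the
predicted field over the image.

## From point annotations to training targets

For an image annotated by $K$ counters, the annotation matrix is

$$D(i,j) = \frac{1}{K} \sum_{k=1}^{K} c_k(i,j),$$

where $c_k(i,j)$ is 1 when counter $k$ marked pixel $(i,j)$. Entries are
multiples of $1/K$ and the matrix total equals the mean of the counters'
per-image counts. `rasterize_annotations()` builds $D$;
`blur_density()` then distributes each point mass over the axon's physical
extent with an isotropic Gaussian ($\sigma = 8$ px, 33-px kernel), giving
the target density $D_{dist}$.

Two numerical choices matter here:

* **Kernel normalization.** A $\sigma = 8$ Gaussian truncated at $\pm 16$
  px retains only about 91% of its two-dimensional mass. The truncated
  kernel is renormalized to unit sum so that an annotation at least 16 px
  from every border contributes *exactly* 1 to the integral — the map's
  total must reproduce the mean manual count, and the test suite pins this
  conservation to $10^{-9}$.
* **Boundary mass is dropped.** The blur is a zero-padded convolution
  cropped to the image: density pushed past the border is lost, so an axon
  annotated near the edge counts fractionally. This is deliberate — a
  partially visible object should not count as a whole one. Because
  annotation matrices are point masses, the convolution is implemented as
  exact kernel stamping at the annotated pixels rather than a generic
  filtering call with the wrong (circular or replicated) boundary rule.

The network halves the spatial dimensions four times, so inputs must have
side lengths divisible by $2^4 = 16$. `resize_with_points()` resizes
bilinearly to the *nearest* multiple of 16 (ties round up; the native
187-px frames become 192 px) and rescales the points; density targets are
always built from the rescaled points at the final resolution, never by
interpolating a density map, because bilinear interpolation does not
conserve integrals.

## Architecture and input contract

`build_unet()` allocates a U-Net encoder/decoder with half the filter
width of the original segmentation architecture (`base_filters = 32`
against 64, doubling at each of the four levels), padded 3x3 convolutions
throughout so feature maps keep their size, and a rectified-linear 1x1
head: a ReLU output is linear over its active range, which suits density
regression, where a sigmoid would saturate toward 0 or 1. The decoder
upsamples by nearest neighbour followed by a 3x3 convolution (pinned in
the spec object as `"nearest+conv3x3"`); transposed convolution would be
an equally faithful reading of the original design, and the choice is
recorded so weights are never mixed across conventions. No batch
normalization or dropout is used. Because no deep-learning framework is
part of this package's dependency set, the convolutions, pooling,
upsampling and their gradients are implemented in the package's own
compiled kernels (im2col + BLAS matrix products), and the training loop
verifies its backward pass against numerical differentiation in the test
suite.

Inputs are normalized per image: subtract the mean, divide by twice the
standard deviation, clip to $[-1, 1]$. This maps everything within
$\pm 2$ SD of the mean into the working range, is invariant to
acquisition gain/offset, and sends a constant image to zeros.

Images are reflect-padded by 16 px per side (192 → 224) before entering
the network — reflection without repeating the edge pixel — so border
axons get plausible context; the training loss is evaluated only on
non-mirrored pixels.

## Training recipe

`train_unet()` minimizes the masked mean squared error

$$L = \frac{1}{N}\sum_n \left[\hat D(X_n) - m \, D_{dist}(X_n)\right]^2$$

with Adam at learning rate $10^{-4}$, batch size 1, 25 epochs by default,
and density scaling factor $m = 1000$; predictions are divided by $m$ at
inference. The scaling lifts per-pixel targets (order $10^{-3}$) into a
range where the regression converges well. Augmentation applies one of
the eight square symmetries to image and target jointly (preserving the
target integral exactly) plus elementwise multiplicative noise, uniform
in $[0.85, 1.15]$, to the image only. The multiplicative noise is applied
*after* normalization: `normalize_image()` is affine-invariant, so
pre-normalization scaling by a constant would be a no-op, and per-pixel
noise before normalization would merely be rescaled — applying it after
is the reading under which the augmentation does something.

Two numerical safeguards sit outside the recipe proper. Adam moves every
weight by roughly the learning rate regardless of gradient magnitude, so
the first full-size steps from a fresh initialization — when the
`m`-scaled loss is enormous — can drive the rectified head negative at
every pixel: a dead network that predicts zero density forever, with no
gradient to recover. `train_unet()` therefore ramps the learning rate
linearly over the first `warmup_steps` (default 30) optimizer steps, and
`build_unet()` initializes the head's bias slightly positive (0.5) so
the rectifier starts in its active regime. Neither affects converged
training.

Because extreme counts are rare but scientifically important, the
training set is resampled toward a uniform count histogram: 10 equal-width
bins of the per-image mean manual count, with every image in a bin
replicated `round(max_bin / bin_size)` times (whole-image replication
only, originals always retained, empty bins skipped). An epoch is one
pass over the expanded multiset; augmentation is drawn per step.
Validation loss uses the same masking and no augmentation.

## Whole-nerve inference

A full nerve cross section is far larger than a training frame.
`count_full_nerve()` normalizes the mosaic once (so tiles share one
intensity scale), partitions it into `tile_px` cores (default 192), pads
each tile with `context_px` (default 16) of *true* neighbouring pixels
where they exist — no context is attached along the mosaic boundary,
where the prediction step's own 16-px edge mirroring provides the padding
instead — predicts each padded tile, crops back to the core, and
stitches. A consequence of attaching context per side only where real
pixels exist is that `context_px` must itself be a multiple of 16, so
every tile stays network-compatible; a single-tile mosaic then reduces
*exactly* to a plain `predict_density()` call. Every
mosaic pixel is predicted exactly once, stitched cores reassemble the
input bit-exactly, and with at least 16 px of true context the tiled
count agrees with a single whole-image pass to within a few percent
(the test suite requires < 2% on a 576-px synthetic mosaic). Mosaics
whose sides are not multiples of `tile_px` are covered by right/bottom-
aligned overlapping tiles whose cores are clipped to the remainder,
preserving the partition property without any resizing. The paper-scale
tile geometry is not printed anywhere authoritative, so `tiling_scheme()`
exposes both numbers as configurable defaults chosen to mirror training
conditions.

## Bias correction and agreement statistics

Automated counters show a reproducible, approximately linear bias. On a
validation subset `fit_correction()` regresses automated on mean manual
counts, $AC = a\,MC + b$, and `apply_correction()` inverts it,
$AC_{corrected} = (AC - b)/a$, for images outside the fitting subset.
Agreement is then summarized by `agreement_report()`:

* mean absolute error and $R^2$ of corrected vs manual counts;
* Bland-Altman bias and limits of agreement, mean error
  $\pm 1.96 \cdot$ SD of error, benchmarked against the inter-counter
  limits (`inter_counter_loa()`);
* a success rate: the fraction of four-counter images whose corrected
  count falls inside the t-based 95% CI of the mean manual count
  ($\bar{MC} \pm t_{0.975,3} \cdot SD/2$). The source methodology does
  not say which interval it used; the t-interval of the mean is the
  conventional reading for $n = 4$ and is the one implemented. Sample
  (n−1) standard deviations are used throughout, the small-sample
  convention for observer data.
* the inter-counter coefficient of variation (per-image SD/mean of the
  manual counts, median across images).

## What the synthetic generator does and does not emulate

`generate_axon_image()` renders "normal" axons as light-core/dark-ring
annuli with per-axon radius and contrast jitter over a noisy background
with a gentle illumination gradient. `damage_level` adds shape
irregularity, myelin discontinuities, and "abnormal" distractors
(collapsed dark cores, broken rings) at half the normal density, which
are drawn but never annotated — mimicking the real counting rule that
only "normal"-appearing axons are counted. The border rule is
operationalized geometrically: an axon disk is counted iff it is fully
inside the frame, or crosses the top or left border with strictly more
than half its area inside (disks touching the right or bottom border are
never counted, so adjacent frames cannot double-count). `axon_density`
is the Poisson mean of *counted* axons; border-excluded axons are placed
at the rate implied by continuing the same spatial process beyond the
frame.

Within a dataset (`generate_dataset()`), whole nerves — never individual
images — are apportioned to train/validation/test by largest-remainder
rounding of the split fractions, emulating the animal-level exclusivity
of the reference datasets. Each nerve draws a health state (expected
density, damage level), and each sub-image additionally varies its local
density by a uniform ±50% factor, reflecting how strongly local axon
density varies across a real cross section; without this within-nerve
spread a validation subset of few nerves would have an unrealistically
narrow count distribution.

Simulated counters drop true points (miss probability drawn per counter
from $N(\mu_{miss}, \sigma_{counter})$, truncated), add spurious points,
and jitter retained points. With everything at zero they reproduce the
ground truth exactly. The default $\sigma_{counter} = 2\,\mu_{miss}$ was
calibrated once, by simulation at the reference settings (density 40,
four counters, miss 0.08, spurious 0.05, jitter 1 px), to put the median
per-image coefficient of variation near the 0.12 observed between trained
human counters; the calibration is exposed as parameters, not hard-coded,
because only the summary statistic of the real counting process is known.

The generator is deliberately *not* photorealistic: no glia, vasculature,
staining chemistry, or myelin texture. Passing tests on synthetic data
demonstrates that the pipeline's plumbing, losses, geometry and
statistics are correct and that the regression can learn a counting rule
from consistent imagery; it does not certify accuracy on real tissue,
which requires training on real annotated nerves.

## Problem sizes used by the test suite

The packaged checks run the full recipe at reduced scale, chosen so a
complete run is comfortable on a single CPU: 96-px synthetic frames
(128 px after mirroring), a width-8 variant of the architecture
(`base_filters = 8`; the level structure, skip connections and head are
identical to the full-width model), 10 nerves at 10 images each with a
60–20–20 split, and 10 epochs. Two settings scale with the frame: the density
blur, whose width follows the axon size ($\sigma = 4$, 17 taps at 96 px
— half of the native-resolution $\sigma = 8$, 33 taps, keeping the
kernel matched to "the full axon" it is meant to cover; with the
full-size kernel on half-size frames the targets of dense images smear
into one near-uniform field and the regression systematically
undercounts them), and the learning rate, raised to 2e-4 because the
default 1e-4 pairs with 25 epochs over a thousand-image dataset while a
10-epoch run over ~100 resampled examples needs a proportionally faster
schedule. Both were selected on the validation subset, the same role
the validation data plays in the full-scale recipe. The single-image overfit
probe — train on one repeated image, verify the count error collapses
below one axon — runs at the native 192-px resolution with lr 1e-3,
a pure convergence exercise in which generalization plays no role. The
full-width, full-resolution configuration with the default recipe
remains the intended setting for real use.

## Known limitations

* Counts cover the full frame; masking non-nerve background is out of
  scope, so mosaics with large empty margins include whatever the model
  predicts there (near zero for models trained with background present).
* Bitwise reproducibility is promised only per platform/BLAS; seeded
  runs reproduce loss histories on one machine.
* The linear correction is fitted per dataset and does not transfer
  across imaging protocols; recalibrate on a validation subset for each
  new application.
* Only "normal"-appearing axons are counted, as in the reference manual
  protocol; an "abnormal" appearance does not imply non-functionality.
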