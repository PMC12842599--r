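---
title: "Evaluating enhancement-detection interactions in underwater imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating enhancement-detection interactions in underwater imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwbench)
```

`uwbench` studies a deceptively simple question: does enhancing an
underwater image help a detector find the organisms in it? Averaged over a
dataset the answer is often "no", yet individual images can benefit
dramatically. The package therefore evaluates at two granularities — a
distribution-level composite quality index, and a per-image detection
score — and joins them through an oracle "mixed set" that quantifies how
much selective enhancement could recover. This vignette documents the
models, the conventions and the genuinely open design choices.

## The composite quality index

No clean reference image exists for field imagery, so quality is scored
with four established no-reference metrics: UIQM, UCIQE, CCF and grayscale
Shannon entropy. The index is *not* a new perceptual metric; it is an
analytical device for putting four incommensurate scales onto one bounded
axis so that distribution shifts under enhancement become visible.

Construction is strictly three steps, in this order:

1. **Outlier removal** per metric over the pooled records of *all*
   variants (original included): a value is dropped when
   $|x - \mathrm{med}(x)| > 3 \cdot 1.4826 \cdot \mathrm{MAD}_{raw}$.
   The constant 1.4826 makes the scaled MAD a consistent estimator of the
   standard deviation under normality, matching the behaviour of the
   widely used scaled-MAD outlier routines. The median itself can never be
   flagged, so the filter cannot empty a metric.
2. **Global min-max rescaling** of each metric using the bounds of the
   surviving values. Pooling the variants before rescaling is what makes
   Q-index values comparable across variants; rescaling per variant would
   erase exactly the shifts the index exists to show.
3. **Weighted aggregation**, equal weights by default. Equal weighting is
   deliberate: without reference images there is no ground truth to fit
   weights against, and any data-driven weighting would bias the index
   toward whichever metric happens to vary most.

Three conventions are worth spelling out because the construction does not
force them:

* *Outlier scope.* The filter could plausibly run per variant or per
  dataset. It runs on the pooled set, for the same reason rescaling does:
  steps 1 and 2 should see the same population. A record that loses any
  metric to the filter is dropped from aggregation entirely and listed in
  `excluded` — imputing a value the data never contained seemed worse than
  losing a record, and the loss is reported, not silent.
* *Degenerate scales.* A metric whose surviving values are all equal
  carries no ranking information; rescaling it is a 0/0. This raises an
  error naming the metric rather than silently emitting 0.5, because a
  silent constant would shift every Q-index by a quarter of its weight.
* *Missing baselines.* `delta_qindex()` errors when an enhanced record has
  no variant-0 partner in the *input*; if the partner was removed by the
  outlier filter (a fact recorded in `excluded`) the enhanced records are
  dropped from the delta table with a message instead, since that loss is
  a documented consequence of step 1.

The ±25 % sensitivity probe (`weight_sensitivity()`) scales one weight at
a time by $1 \pm 0.25$, renormalises, and reports per-variant medians plus
the largest per-record change. A perturbation of exactly 0 is allowed (it
reproduces the baseline and is useful as a null check); values of 1 or
more are rejected because a weight would vanish or the probe would stop
being a perturbation. Quality bins partition $[0,1]$ into ten equal
intervals, left-closed, with the last bin right-closed so an index of
exactly 1 is binned; bin indices are 0-based and empty bins are reported
rather than omitted.

## The per-image detection protocol

The detection score mirrors the standard COCO evaluation, applied to one
image at a time. Matching is greedy in descending confidence: each
detection claims the unmatched ground-truth box with the highest IoU at or
above the threshold, each ground-truth box is claimed at most once, and
ties in confidence keep input-file order so results are reproducible
bit-for-bit. The PR curve is integrated with COCO's 101-point interpolated
precision. The protocol description leaves the interpolation rule open
("area under the PR curve"); 101-point was chosen because every other
convention in the protocol is COCO's, and an all-breakpoint trapezoid
variant is available behind `interpolation = "trapezoid"` for sensitivity
checks — on the test fixtures the two differ by at most a few percent and
never change a ranking.

Two conventions deserve emphasis because the single-image setting forces
decisions that pooled evaluation never faces:

* *Category averaging.* AP is averaged over the categories present in the
  image's ground truth. A category with ground truth but no detections
  contributes 0; detections for a category absent from that image's ground
  truth contribute nothing (they would be false positives in a pooled
  evaluation, but per image there is no recall axis to charge them
  against). This is the minimal reading consistent with COCO's
  per-category design, and it is a documented limitation: per-image scores
  slightly favour over-triggering detectors.
* *Images without ground truth* have no recall axis at all, so their score
  is undefined (`defined = FALSE`) and they are excluded from set means
  and from the mixed-set size $N$, rather than scored 0 or 1.

IoU thresholds are built as `seq(50L, 95L, 5L) / 100` so that rational IoU
values (e.g. a box pair engineered to overlap at exactly 0.60) compare
exactly against the 0.60 threshold in floating point. No confidence floor
and no detections-per-image cap are applied by default; both exist in COCO
tooling for efficiency at scale, not correctness, and the single-image
setting does not need them.

The conventional pooled `dataset_map()` is included for comparison; on a
one-image dataset containing every annotated category it coincides with
the per-image score, which the tests assert.

## The mixed-set upper bound

Given the score matrix $\mathrm{mAP}_{n,v}$, the oracle keeps for each
image the best variant, ties broken in favour of the original and then the
lowest variant index. The tie rule matters more than it looks: per-image
APs are frequently exactly equal (both perfect, or both zero), and
enhancement is an intervention — when it buys nothing, the right default
is not to intervene. The mixed mean is then an upper bound for *any*
selection strategy over the same variants, and by construction dominates
every single-variant column mean; the tests verify dominance and the
equality with row maxima on tie-free matrices. Relative improvement over
the original set is reported both at full precision and rounded to integer
percent.

## The synthetic generator

No public generative model exists for enhancement-detection interactions,
so the generator is this package's own design, chosen minimal enough that
tests can pin expectations analytically:

* **Latent quality.** Original quality $q_0$ is drawn from a two-component
  normal mixture (defaults: means 0.40 and 0.56, sds 0.05 and 0.06,
  weights 0.35/0.65, clamped to $[0.02, 0.98]$), reproducing the roughly
  bimodal quality distribution seen in real underwater survey collections.
* **Response law.** Enhancement shifts quality piecewise-linearly toward a
  crossover point (default 0.5): images below it gain
  $0.8\,(0.5 - q_0)$, images above it lose $0.6\,(q_0 - 0.5)$, each
  enhancer applying the shift at its own gain (defaults 0.85–1.0) with
  per-image noise (sd 0.03). This encodes the central empirical pattern:
  low-quality images benefit, high-quality images over-enhance.
* **Detection law.** Each ground-truth box is missed with probability
  $p_{miss}(q)$, survivors are jittered by $\sigma(q)$ pixels, and
  $\mathrm{Poisson}(\lambda(q))$ false positives are added. All three are
  straight lines in $q$ specified by their values at $q = 0$ and $q = 1$
  and *clamped* into their valid ranges, so endpoints outside the range
  create saturation. The defaults
  ($p_{miss}: 1.0 \to -2/3$, $\sigma: 12 \to -6$ px,
  $\lambda: 1.5 \to -0.5$) make detection essentially perfect above
  $q \approx 0.6$. Saturation is deliberate: images in the good-quality
  regime then tie at a perfect score across variants, the tie-break
  returns them to the original, and the mixed-set composition reproduces
  the qualitative fingerprint of real studies — the original is the
  plurality source, with each enhancer contributing a modest share.
  With three enhancers those shares land around 10–20 %, larger than the
  few-to-12 % reported for nine-enhancer studies simply because the
  benefiting images are split three ways instead of nine.
* **Confidences** decrease with the realised jitter magnitude plus small
  noise, so ranking carries localisation information; false positives draw
  lower confidences. Pseudo quality-metric records (noisy monotone
  transforms of $q$ on each metric's natural scale) are emitted alongside
  so the Q-index pipeline can run on the same cohort.

Everything is generated under one seeded RNG stream and restores the
caller's RNG state; identical seeds give bit-identical scenarios.

What the generator does *not* emulate: the visual signature of any
specific enhancement algorithm, detector-specific failure modes (the
detection law is box-wise independent, real detectors fail structurally),
annotation error, and the weak, noisy coupling between appearance metrics
and detection found in real data — the synthetic coupling is deliberately
strong so that structure-recovery tests have signal. Passing tests
therefore demonstrate that the *pipeline* recovers planted structure, not
that real enhancement behaves like the response law.

`generate_degraded_image()` serves the image-metric tests: a seeded
sinusoid-mixture texture degraded by channel-wise attenuation (red
absorbed most), affine compression toward a veil level (haze), and
additive noise. Full haze provably collapses entropy to 0, and increasing
haze monotonically lowers the UCIQE luminance-contrast component, which
the tests sweep.

## Metric implementations

The literature states the composite metrics as weighted sums but rarely
pins every implementation detail; the package fixes the following and
records all coefficients in `iqa_coefficients()` and
`inst/extdata/iqa-coefficients.yaml`:

* **UIQM** $(c_1, c_2, c_3) = (0.0282, 0.2953, 3.5753)$; UICM trims 10 %
  of each tail of the opponent channels; block-based terms use 10×10
  blocks with partial border blocks truncated; the Sobel magnitude is
  computed on the valid interior; EME uses natural log with non-positive
  block extrema contributing 0; UIConM is a log-AMEE on the luma image,
  sign-fixed so larger is more contrast.
* **UCIQE** $(0.4680, 0.2745, 0.2576)$ in CIELab via
  `grDevices::convertColor` (sRGB, D65); luminance contrast is the 99th
  minus 1st percentile of $L$; saturation is $C/\sqrt{C^2 + L^2}$, zero
  where both vanish; $L$ and $C$ scales are normalised by 100.
* **CCF** $(0.17593, 0.61759, 0.33988)$ over an opponent-channel
  colorfulness statistic (normalised by 85.59), the population standard
  deviation of the luma in $[0,1]$ units, and a clarity term
  $1 - \overline{\min_c I_c}/255$ (one minus the mean pixel-wise channel
  minimum — a 1×1 dark channel), so a dense uniform veil scores near 0.
  The fog-density estimator behind the published metric is not specified
  to implementation level anywhere; the dark-channel form was chosen as
  the simplest estimator with the right monotonicity, and it is exercised
  by the haze sweep in the tests.
* **Entropy** is the base-2 Shannon entropy of the 256-bin histogram of
  the Rec. 601 luma rounded to integer levels, with $0 \log 0 := 0$.

Images are processed at stored resolution — resizing is a detector-input
concern, not a quality-scoring one. Because white point, gamma and
rounding conventions differ across published implementations, numerical
identity with any particular published table is *not* claimed; what the
test suite pins instead is exact agreement with independent straight-line
reimplementations of every component formula, to $10^{-6}$ relative, on a
20-image synthetic corpus plus fixed hand-analysable patterns.

## Problem sizes and runtime

The shipped tests and the acceptance script use cohorts of 120–150 images
with 3 enhanced variants, 1–6 boxes per image, and a 600-image cohort
(about 2000 boxes) for the recall-recovery check; these sizes give
Monte-Carlo error comfortably inside the asserted tolerances while keeping
a full run in the low tens of seconds on a single core. Scaling the same
code to the size of a real survey dataset is linear in images × variants ×
thresholds.

## Known limitations

* Per-image scores ignore cross-category confusion and cannot charge
  false positives on unannotated categories (see above).
* The mixed set is an oracle: it bounds selective enhancement, it does not
  implement a selector. Learning when to enhance is explicitly out of
  scope.
* The Q-index inherits every blind spot of its four components; it is a
  bounded summary for distribution analysis, not a validated perceptual
  scale.
* JPEG/TIFF input requires `EBImage`; the package's first-class on-disk
  image format is PNG.
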