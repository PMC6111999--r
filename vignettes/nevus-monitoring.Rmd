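---
title: "Methods: from body photo to nevus alert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from body photo to nevus alert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dermoscan` chains five stages: scale-space key-point detection, key-point
screening, cluster extraction, histogram triage, and a from-scratch
convolutional classifier. This vignette explains the model behind each
stage, the parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Image conventions

Colour images are `h x w x 3` arrays of integers in `[0, 255]`; pixel
`(x, y)` is column `x`, row `y`, origin top-left. Grayscale conversion is
the plain channel mean with floor rounding, `C = floor((R + G + B) / 3)`.
All other pixel arithmetic rounds half up and clamps to `[0, 255]`; fixing
the rounding mode makes every stage bit-reproducible across platforms. The
contrast stretch `F (C - 128) + 128` with
`F = 259 (omega + 255) / (255 (259 - omega))` is clamped, not taken modulo
255: wraparound would turn the darkest pixels white and defeat the stated
purpose of the step (suppressing small low-contrast structure before region
growth). Resizing is bilinear with pixel-centre alignment, so resizing to
the original size is an exact identity and integer downscaling averages
blocks.

## Key-point detection

The detector is a difference-of-Gaussians (DoG) scale-space detector in the
SIFT family. Parameters (`sift_params()`):

* `sigma0 = 1.6`, `k = 2^(1/3)`, `levels_per_octave = 3`, `octaves = 4` —
  the classical pyramid layout; each octave holds `s + 3` Gaussian planes
  so that extrema can be searched on `s` scales per octave. Four octaves
  cover blob diameters up to roughly 100 px on a 800 x 600 frame, beyond
  the largest lesion the generator plants.
* `contrast_threshold = 0.03` — minimum interpolated `|D|`, defined on
  intensities normalized by the *image maximum*. Normalizing by the
  per-image maximum (rather than a fixed 255) makes detection exactly
  invariant to global intensity rescaling: doubling all intensities changes
  no key point.
* `r = 10` — edge rejection: a candidate is dropped when the 2 x 2 spatial
  Hessian satisfies `det H <= 0` or `tr(H)^2 / det(H) >= (r + 1)^2 / r`
  (the standard form; a straight step edge has `det H ~ 0` and is always
  removed).

A candidate must be strictly larger (or smaller) than all 26 neighbours in
its own and the two adjacent DoG planes. A within-plane-only 3 x 3 test
would flood the output with points that are not scale-selective; the
26-neighbour rule keeps only blob-like structure. Strictness has a
noteworthy consequence on synthetic fixtures: a mathematically perfect blob
centred exactly between pixels produces four tied central values and no
strict extremum — test fixtures therefore place blobs slightly off the
grid's symmetry axes, which is also the generic position for real data.

Localization solves the 3-D stationary condition of the local quadratic
expansion; when any offset component exceeds 0.5 the candidate is
re-anchored to the neighbouring pixel (at most 5 retries), and singular
Hessians are counted separately as unstable rejections. Orientation uses
the gradient magnitude/direction formulas on the Gaussian plane nearest the
key point's scale, accumulated over the 3 x 3 neighbourhood into 36 bins
weighted by magnitude times an isotropic Gaussian of the pixel distance;
every histogram peak reaching 80% of the maximum emits its own key point.
The 3 x 3 orientation window is deliberately small; at a blob *centre* the
gradient vanishes and the orientation is intrinsically noisy — orientation
information is meaningful for asymmetric structure, which is exactly what
the pipeline cares about. Descriptors take a 16 x 16 neighbourhood rotated
to the key point's orientation, 4 x 4 cells with 8 orientation bins each,
L2-normalized (zero stays zero on flat patches).

## Key-point screening

Three filters remove points that cannot be skin marks. The background
filter deletes points whose rounded position lies within `pos_tol = 2` px
of an entry of a stored reference (key points of photos of the empty scene,
with their colours) and whose colour agrees within `color_tol = 20` per
channel; exact matching would be brittle under sensor noise, so both
tolerances are configurable. The palette filter keeps a point only when the
median colour of its 3 x 3 neighbourhood is within tolerance of one of the
palette anchors; the shipped default palette (12 anchors, tolerance 40)
spans light-to-dark skin tones *and* nevus browns — it is a stand-in, not a
clinical standard, and fully user-overridable. The shape filter grows the
same-colour region at each point and removes it when the region's
bounding-box aspect ratio exceeds 5: border lines, straps and seams are
long and thin; nevi are not.

## Cluster extraction

Each surviving key point is cut out as a window of `15%` of the image width
and height, flattened (grayscale, gamma `1.2`, contrast `128`), and the
same-colour region (intensity within `10` of the seed on the processed
window) is grown 4-connectedly from the key point with an explicit queue —
recursion would overflow on large regions. 8-connectivity was rejected
because it leaks through diagonal pixel chains on noisy fixtures. The
strong contrast setting pushes all nevus shades far below skin, so a
variegated lesion still grows as one region. A region covering more than
30% of the *crop window* means the window is homogeneous (plain skin or
wall) and the key point is dropped; a floor of 9 px drops single-pixel
noise. The printed form of this rule references `30% w h` immediately after
the sentence that defines the crop bitmap; reading it against the full
image area would make the rule unsatisfiable for any region inside a 15%
window (2.25% of the image), i.e. dead code, so the window-relative reading
is implemented. Accepted regions are cropped to their bounding box, the
original colours are restored over those coordinates, and the crop is
resized to `64 x 64` (no aspect-ratio padding; the classifier sees the same
anisotropic stretch at training and prediction time). Overlapping regions
from neighbouring key points (> 50% of the smaller region) are
deduplicated, keeping the stronger detector response.

## Histogram triage

Clusters are compared against an exemplar database holding unit-normalized
256-bin histograms (gray, R, G, B) of nevus images and of plain skin. The
similarity is the mean histogram intersection over the four channels —
symmetric, bounded in `[0, 1]`, equal to 1 exactly at equal distributions,
and insensitive to cluster size thanks to the normalization. A cluster is
forwarded when its best nevus similarity reaches its best skin similarity
(margin 1.0 by default), and also whenever the two similarities are within
0.02 of each other: the system's purpose is alerting, so ambiguity resolves
toward the classifier, not away from it. Forwarded clusters are blurred
with the fixed `(1/16)[1 2 1; 2 4 2; 1 2 1]` kernel before classification;
comparison happens on the un-blurred cluster.

## Classifier

The network is written from scratch: valid-region multi-channel
convolutions (`(N - m)/S + 1` output side, no padding, no bias), 3 x 3
non-overlapping max pooling (border tiles completed by edge replication;
pooling has no trainable parameters and routes gradients to the argmax),
and dense tanh layers `y_k = tanh(sum_j w_jk x_j)`. The default
architecture is conv(8 x 3 x 3) - pool - conv(16) - pool - dense(32) -
dense(2) on a `64 x 64 x 4` input: the gray plane plus R, G, B, each
scaled to `[0, 1]`. The loss is mean squared error on the two tanh outputs
against targets `+/- 0.9`; staying off the tanh asymptotes keeps
`phi' = 1 - tanh^2` well conditioned. Gradients follow the chain rule
end-to-end, and the core correctness test compares every analytic gradient
of a small model against central finite differences (agreement better than
1e-4 relative; observed ~1e-7).

Training is plain seeded mini-batch gradient descent from uniform(-0.1,
0.1) initial weights: learning rate 0.05, batch 16, 30 epochs by default,
bit-reproducible for a fixed seed. Plain gradient descent on this loss has
a genuinely rough landscape at small sample sizes — below roughly 50
clusters per class a run can stall in a one-sided solution — so the
package's reference conditions use 100 clusters per class for 30 epochs,
where training is consistently stable. Prediction maps the two outputs to
`[0, 1]` via `(y + 1)/2`, renormalizes them to sum 1, and labels by the
larger probability; an exact tie resolves to benign with a warning (a tie
carries no evidence, and the alert channel should not fire on it). Named
fixed kernels (the 3 x 3 Gaussian blur and the emboss filter) are available
as frozen or trainable convolution initializations. Models serialize to
JSON with weights printed as `%.17g` decimal strings, which round-trips
IEEE doubles exactly; a reloaded model predicts bit-identically.

## Synthetic data

The generator renders what the pipeline consumes, with full ground truth.
Scenes (`make_scene()`, default 800 x 600 — the resolution of a typical
indoor camera frame) contain a skin-textured region covering at least half
the frame (low-frequency tone variation plus Gaussian noise, sd 2.5), a
wall-textured remainder with rectangular clutter in distinctly non-skin
colours, and nevi rendered as rotated ellipses whose parameters mirror the
ABCDE signs: asymmetry deforms the two halves' semi-axes (mask area
`pi r^2 (1 - a/2)`), border fuzz sets the width of the alpha ramp at the
boundary, `n_shades` draws concentric irregular shade zones, and the
diameter is in millimetres at `px_per_mm = 10`, an explicit convention that
maps the 6 mm criterion to 60 px. The generator's labelling rule mirrors
the warning signs: diameter > 6 mm, asymmetry > 0.5 or >= 3 shades forces
the suspicious label. Scene-level suspicious nevi use 6.2-7.2 mm with
asymmetry 0.55-0.8 — above the diameter criterion yet small enough that a
compact region inside a 15% crop window survives the 30% budget at
800 x 600; benign nevi use 2-4 mm. An optional paired-scene mode (same
seed, enlarged nevus) emulates the evolving criterion, but the pipeline
performs no temporal comparison.

Cluster datasets (`make_cluster_dataset()`) render one nevus per 64 x 64
skin patch — benign: near-round, single shade, sharp border, lighter brown,
filling 50-70% of the frame; suspicious: asymmetric, fuzzy, 3-4 shades,
darker, filling 75-95% — and then pass each patch through the *same*
normalization the live clusterer applies (flatten, region-grow from the
centre, bounding-box crop, colour restore, resize). This keeps the training
distribution aligned with what the pipeline actually emits; without it, a
classifier trained on full rendered patches systematically misreads
extracted crops. Because the crop-and-resize step destroys absolute size,
diameter is not a usable feature after extraction — the classes separate on
asymmetry, border, variegation and darkness, which is also true of the live
pipeline.

What the generator does **not** emulate: hair, specular highlights,
perspective and lens distortion, shadows cast by the subject, camera noise
beyond i.i.d. Gaussian, and real lesion morphology. Green tests on
synthetic scenes therefore demonstrate that the pipeline's stages compose
correctly and recover planted structure under controlled conditions; they
are not evidence of clinical performance on photographs.

## Evaluation

`evaluate_predictions()` derives the nine standard measures from TP/TN/FP/
FN; ratios with a zero denominator are `NA`, never 0, and the identities
`precision + FDR = 1`, `Se + FNR = 1`, `Sp + fall-out = 1` and the harmonic
F-measure relation hold wherever defined (property-tested over random
confusion matrices). The published quality table this package's evaluation
mirrors contains one internally inconsistent column (a fall-out entry that
is not `1 - Sp`); the implementation enforces the identities rather than
reproducing the inconsistency. Train/test protocol is a seeded stratified
70/30 split (the source material does not state one). The optional loader
for the PH2 dermoscopy archive maps clinical diagnoses {common nevus,
atypical nevus} to benign and {melanoma} to suspicious; treating atypical
nevi as benign is a screening choice, exposed to the user, not a clinical
judgement.

## Problem sizes used by the tests

The equation-level oracles run exhaustively on small inputs (convolution up
to 8 x 8, region growth up to 16 x 16, extremum scans on 32 x 32 stacks);
the gradient check uses a 12 x 12 two-conv toy model (154 parameters); the
end-to-end recovery test trains on 200 normalized clusters for 30 epochs
and analyzes ten 800 x 600 scenes with one planted suspicious nevus each.
These sizes were chosen so the whole suite exercises every stage at the
generator's reference conditions while remaining comfortable to run on a
laptop CPU.

## Known limitations

* The orientation window (3 x 3) is far smaller than in standard
  descriptor pipelines; orientations at symmetric blob centres are noisy.
* A large, strongly fuzzy-bordered lesion with weak internal contrast can
  evade the detector entirely (no DoG extremum above threshold at its
  scale); one of the ten reference scenes exhibits exactly this miss.
* Plain gradient descent without momentum can stall on small training
  sets; use the reference training sizes.
* The skin palette and nevus colours are synthetic stand-ins; real
  deployments must supply their own palette and exemplar database.
* BMP support covers the uncompressed 24-bit variant only (sufficient for
  the dermoscopy archive layout the loader targets).
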