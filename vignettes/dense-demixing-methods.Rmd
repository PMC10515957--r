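---
title: "Methods: demixing dense calcium imaging movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demixing dense calcium imaging movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densedemix)
```

## The problem and the model

Dense imaging schemes (Bessel-beam volumetric projection being the
motivating case) deliberately mix many neurons into each pixel to enlarge
the recorded population, and push the cells-per-pixel density `Rc` into a
regime where pure-pixel or pure-frame separability assumptions fail: almost
every pixel and almost every frame carries several cells. The observed
movie is modeled as `Y = AC + B + E` with nonnegative footprints `A`,
nonnegative traces `C`, background `B`, and white noise `E` that is
independent across pixels and frames.

The package's central idea is that although the *raw* movie violates the
pure-frame assumption, a **denoised and temporally sparsened** version of
it does not: calcium indicators smear a spike over tens of frames (AR(1)
decay `g ~ 0.9` at typical frame rates), so deconvolution concentrates each
transient back into a handful of frames, and in those frames individual
somata reappear as isolated objects that an instance detector can find.
The detected footprints then initialize a constrained NMF, which does the
actual demixing on the full (compressed) movie.

## Stage by stage

### Noise normalization

Every downstream threshold is calibrated in noise units, so the first step
scales each pixel trace by an estimate of its noise sd. The default
estimator is the square root of the median periodogram ordinate over the
upper half of the frequency axis, corrected by `log(2)` for the
exponential distribution of periodogram ordinates; slow calcium signal
lives at low frequencies and does not bias it. Movies shorter than 32
frames fall back to `mad(diff(y))/sqrt(2)`. Zero-variance pixels are
floored at `1e-9` with a warning.

### Rigid registration

Frames are aligned to a global template (mean frame, refined by 3 rounds
of register-then-average; the round count is a convergence choice, two is
usually already stable). Shifts come from the FFT cross-correlation peak
refined to 0.1 px by an upsampled discrete Fourier transform in a 1.5 px
neighborhood; frames are shifted back by bilinear interpolation with edge
replication. Shifts beyond `max_shift` are clipped and flagged rather than
trusted. Piecewise-rigid and non-rigid warping are out of scope.

### Compression and denoising

Overlapping spatial patches (default 32 x 32, 50% overlap) are
individually decomposed by a truncated randomized SVD (oversampling 10,
two power iterations, internally seeded so results are reproducible and
the caller's RNG is untouched). Because the input has unit noise, the
singular values of a pure-noise patch concentrate below
`sqrt(p) + sqrt(T)`; a component is kept only if its singular value
exceeds that edge times `1 + rank_margin` (default margin 0.05). This
replaces a tuning parameter with a statistic of the data — rank adapts per
patch. Patch spatial vectors are multiplied by a bilinear taper
renormalized so the taper weights of the patches covering any pixel sum
to one, which removes block artifacts; each column of `U` therefore lives
on one patch and `U` is very sparse.

Per-pixel temporal means are removed before the SVD and stored on the
`pmd` object. This spends no rank on static baseline and makes the whole
pipeline invariant to affine intensity rescaling (e.g. after integer TIFF
round trips); the means re-enter only through the static background and
in reconstruction/rendering.

### Sparsening and re-denoising

Two deconvolution paths share the AR(1) model `s_t = c_t - g c_{t-1}`:

* **Active-set path**: per pixel, the sparse nonnegative problem
  `min ||c - (y - b)||^2 / 2 + lambda ||s||_1, s >= 0` is solved exactly
  by pool-adjacent-violators merging (the L1 term folds into the target;
  negative pools clamp at zero, which is optimal because a negative pool
  can only occur at the head of the solution). `b` is a constant
  percentile baseline (default 20th). Default `lambda = 1` in noise
  units.
* **Naive path (default)**: the same differencing applied *to the rows of
  V*, which by linearity equals pixelwise naive deconvolution of `U V` at
  O(KT) cost. It has no `lambda` and keeps negative values; rectification
  happens only when frames are rendered for detection, keeping the
  operator linear and the projection exact.

Deconvolution amplifies high-frequency noise, so the deconvolved movie is
projected back onto `U` (`P = (U'U)^{-1} U' Z`, ridge `1e-8 I` if the Gram
matrix is ill-conditioned) and kept factorized as `U P`; dense frames are
materialized only one patch at a time.

`g` is estimated as the median over the 100 highest-energy pixel traces of
lag-2-to-lag-1 autocovariance ratios, clipped to `[0, 0.999]`: white noise
inflates only lag 0, so the ratio is robust; on noise-only input the ratio
is heavy-tailed around zero and the clip keeps the estimate small.

### Detection

Per 20 x 20 patch, frames are ranked by the maximum rectified sparsened
value over the patch and the top `n = 100` frames are rendered on the
patch padded by 8 px (half a soma diameter) so border cells appear whole.
The detector interface maps an image to `(mask, confidence)` proposals;
two implementations exist:

* `baseline_blob_detector()` — threshold at 30% of the frame maximum,
  8-connected components sized 30-500 px, confidence = component peak over
  frame max. Deterministic, no training, used throughout the tests.
* the wrapper `blob_detector()` adds two gates the plain thresholder
  lacks and a trained segmentation network would provide implicitly: masks
  clipped at the padded render border are dropped (the neighboring patch
  sees that cell whole), and masks filling less than 60% of their
  bounding-box ellipse are dropped (a single soma is compact; a dumbbell of
  two co-active somata is not). Without these, patch-boundary duplicates
  and co-activation composites inflate the false positive count.
* `generate_training_examples()` emits (frame, instance masks) pairs from
  simulated movies for training a network detector; the training loop
  itself is out of scope, and any such detector plugs in via `detector()`.

Candidates are accepted if confidence exceeds `cmin = 0.7`, their weighted
footprint cosine against all accepted components stays below
`treal = 0.65`, their binary support cosine stays below `tbin = 0.65`
(midpoints of the working range 0.5-0.8), and their mask cosine against
other same-frame detections is at most 0.2 ("well isolated" made
concrete). Patch lists are merged globally by re-running the same filter
in patch-index-then-brightness order — deterministic, and the quadratic
candidate comparisons stay patch-local so the cost per patch does not grow
with the field of view.

### Demixing

`run_localnmf()` alternates, per pass: HALS sweeps (exact per-component
nonnegative coordinate updates of every trace, then every footprint
restricted to its frozen support — detection mask dilated by 2 px) against
the background-subtracted target; then a background refit; after the
pass's iterations (default 3 x 2 sweeps), a superpixel search of the
residual seeds new components for the next pass (default 2 passes; the
final pass refines rather than seeds, so every reported component has been
through HALS). The objective `||UV - AC - B||^2` is non-increasing within
every HALS block — asserted in the tests — and is computed entirely from
`K x K`, `K x N` and `N x N` Gram matrices: no dense pixels-by-time array
is ever allocated (a guard test runs the heavy operations on a
160,000-pixel instance inside a few-hundred-MB budget).

**Background.** `Bs` is the per-pixel temporal mean of the residual, so
the model baseline (including the stored pixel means) lives here and never
in the traces. `Bf` follows a simplified ring model: each pixel's neuropil
trace is the average of the pixels at Chebyshev distance `ring_radius`
(default 8 px, about 1.5 median soma radii), excluding any pixel inside a
footprint support, renormalized over the survivors; a single nonnegative
scalar per pixel is fit by 1-D least squares and **capped at 2**. The cap
is a model statement, not a tuning: a genuinely smooth background is close
to its own ring average (weight of order 1), while a large weight means
the ring is amplifying a faint copy of a signal absent at that scale —
typically an unmodeled soma that the residual pass should recover instead.
Without the cap, a withheld neuron can be silently absorbed with fitted
weights in the hundreds. The fitted `Bf` is projected onto `U` and stored
as `K x T` coefficients.

**Superpixels.** Residual correlations between 4-neighbor pixels are
computed through the same Gram factorization; edges above `corr_thresh`
(default 0.7) among pixels whose residual trace sd exceeds 0.15 noise
units form superpixels (connected components of at least 20 px), each
factorized into a nonnegative rank-1 pair by rectified power iteration and
gated through the detection cosine filters. The sd floor is this
package's "more robust" ingredient: correlation is scale-invariant, so a
well-fit residual otherwise seeds spurious components from
subspace-correlated noise.

### Evaluation

Ground-truth neurons are processed in descending brightness
(`max(a) * max(c)`); candidates are estimates with footprint cosine at
least 0.5 (the spatial gate), and the winner is the unmatched candidate
with the highest temporal cosine, ties to the lowest index. Recovery
accuracy is the mean matched temporal similarity over all true neurons
(unmatched = 0); FPC is the number of estimates never matched. The greedy
order-and-gate scheme coincides with exhaustive optimal assignment when
footprints do not overlap (tested by brute force up to 6 neurons); under
heavy overlap it is a deterministic approximation. The oracle baseline
(`oracle_demix()`) receives the true footprints and estimates traces by
HALS-to-convergence nonnegative regression (relative tolerance `1e-8`) —
an upper bound on achievable trace recovery.

## What the simulator does and does not emulate

Footprints are random 3D ellipsoids (radius uniform on 4-7 px, mild
anisotropy) voxelized and collapsed through the PSF — a Bessel beam sums
over depth (a sphere projects to its chord-length profile), a two-photon
Gaussian weights a thin slab around a random focal offset — then blurred
(sd 0.5 px), thresholded at 5% of peak, and peak-normalized. Traces are
AR(1)-filtered Bernoulli(0.01/frame)-exponential spike trains scaled
log-uniformly on [3, 10] (clearly supra-noise transients: the high-SNR
regime); noise is Gaussian with variance `1 + 0.5 * signal`. Density is
controlled by accumulating footprints until the realized
`Rc = sum |supp(a_i)| / d` reaches the target (within one footprint, so
well inside 15%), or by a Poisson count when no target is given. All
randomness flows from one seed; identical seeds reproduce the ground truth
bit for bit.

Deliberately absent: neuropil / fluctuating background (the fluctuating
panel of an exported demixing video is empty on simulated data), Poisson
photon statistics, dendrites and axons beyond the soma ellipsoid, motion,
and bleaching. Passing tests on these movies therefore demonstrate the
pipeline's demixing behavior under controlled density and SNR, not
robustness to every artifact of real recordings; the ring background and
registration stages are exercised by their own constructed fixtures
instead.

Label generation for detector training deconvolves each true trace with
the naive rectified operator and keeps activity at or above the row's
`p`-th percentile of positive values (default 60, recommended band
40-80); a neuron is a positive instance in every frame where its
thresholded trace is nonzero.

## Numerical choices and degenerate inputs

* Randomized SVD: oversampling 10, 2 power iterations, per-patch rank cap
  50 — ample for tens of overlapping cells per patch.
* Ill-conditioned `U'U`: ridge `1e-8 I` fallback.
* Deconvolution pools: values are compared with exact floating-point
  arithmetic; `s` entries within `1e-12` of zero are snapped to zero.
* Zero-variance pixels, all-zero footprint columns, empty candidate sets,
  empty ring rows, and `K = 0` decompositions all degrade to explicit
  warnings or documented zero results rather than errors.
* Component pruning drops footprint-trace pairs below `1e-6` of the
  largest product norm.
* Tie-breaks are fixed everywhere (stable frame ordering, lowest-index
  match winner, patch-then-brightness merge order), so the detection and
  demixing paths are bit-reproducible; the only RNG use is the seeded SVD
  range finder and the simulator.

## Problem sizes in the test suite

The end-to-end checks simulate 64 x 64 x 1000 movies: two replicates at
density 0.4 (near-oracle recovery, small FPC) and five at density 1.5
(detection-initialized demixing versus superpixel-only initialization,
where the detection path's advantage is the package's raison d'être).
These sizes keep a full suite run under two minutes while leaving every
stage's behavior measurable; the algorithms themselves are
dimension-agnostic and the factorized demixer has been exercised on
400 x 400 px instances in the allocation-guard test.

## Known limitations

* The baseline blob detector has no learned shape prior; at high density
  its composite-blob and duplicate rejections are heuristic, and the FPC
  it yields (typically a few per movie at density 0.4, several at 1.5) is
  the main gap to a trained instance-segmentation detector.
* Supports are frozen after detection (dilated 2 px); a footprint that was
  detected partially cannot grow beyond the dilation.
* The constant-weight ring model cannot represent background whose spatial
  correlation length is shorter than the ring radius.
* The superpixel-only initialization is provided as a comparison baseline;
  at high density connected residual regions merge and it recovers few
  components — which is precisely the failure mode the detection-first
  design addresses.
* HDF5 input is not supported in this build; movies travel as multi-page
  TIFF (16-bit stacks are read at native integer scale, 32-bit on the
  stored [0, 1] scale), and CLI intermediates are RDS files.
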