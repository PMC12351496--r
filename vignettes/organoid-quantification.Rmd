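---
title: "Methods: the organoidquant pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the organoidquant pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidquant)
```

This vignette is the package's own account of the science behind its
four pipelines: the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the
synthetic-data generators emulate (and deliberately do not), the
numerical choices, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Intensity conventions

All images are handled as floating point on a normalized `[0, 1]`
scale: integer TIFF data are divided by the dtype maximum on read. The
H-minima depth default (0.05) only makes sense on such a scale, which
is why the convention is enforced rather than optional. Camera bit
depth is not recorded in the files the pipelines target, so
normalization-by-dtype-maximum is a convention, not a property of the
data. Axis order is `(z | t, y, x)`, 1-based in R, and calibration
(pixel/voxel size, frame rate) always comes from the caller — the
acquisitions these pipelines serve report calibration in figure
legends, not file metadata.

## 2D marker quantification

`preprocess2d()` applies, in order: a median filter, background
subtraction, the H-minima transform, and CLAHE; `binarize_otsu()` then
thresholds, and `coverage()` reports the area fraction and integrated
signal density (ISD).

Parameter notes, with units and defaults:

* `median_size_px = 5` — the source protocol phrases the median filter
  with a "sigma", but a median filter has a window size, not a sigma; a
  5 × 5 window is the only consistent reading.
* Background: the published wording ("histogram shape-based method
  beyond the peak of the intensity distribution") is ambiguous. The
  default locates the 256-bin histogram mode and takes the first
  intensity above it where counts fall below
  `background_peak_fraction = 0.5` of the mode count; that level is
  subtracted and clamped at zero. A triangle-method alternative is
  selectable. The default was chosen because it matches the "beyond the
  peak" wording with a single, interpretable parameter.
* `hminima_depth = 0.05` — implemented as grayscale
  reconstruction-by-erosion of `img + H` above `img`
  (8-connectivity). A regional minimum shallower than `H` is erased;
  deeper minima survive with their depth reduced by `H`. A perfectly
  flat image has no pass level and is returned unchanged.
* CLAHE: clip limit 0.01 (fraction of the tile histogram) and 64-px
  tiles. The protocol does not state CLAHE parameters; these are the
  common defaults of the standard implementations and are exposed in
  the configuration.
* Otsu: fixed 256-bin histogram, candidate cuts at bin edges, class
  means computed from exact per-bin intensity sums (so the result
  equals an exhaustive search over the 256 candidates on the raw
  values). Foreground is *strictly above* the threshold — a
  deterministic tie-break. A constant image yields an empty foreground
  and a warning, never an error, so a degenerate field of view cannot
  abort a batch.
* ISD is computed on the **raw** image under the final mask. CLAHE
  destroys intensity linearity, and integrated density conventionally
  means raw intensity; measuring it on the equalized image would make
  the readout depend on the contrast enhancement.
* Colocalization is mask overlap (pixelwise AND), not an
  intensity-correlation coefficient; the published figures frame
  colocalized signal as an amount (ISD within the field of view), which
  is an area/intensity quantity, not a Manders/Pearson analysis.
* `objects_in_path()` replaces the interactive freehand tracing of
  neurites with an explicit path mask (any tool can draw it; the CLI
  accepts a TIFF). Object length is the extent of the pixel set along
  its principal axis plus one pixel, times the pixel size: a 10-px bar
  measures 10 px and a single pixel measures 1 px. The
  moment-of-inertia convention (4σ along the major axis) was rejected
  because it disagrees with end-to-end extent by ~15% on short bars,
  which would make generator truth and measurement incommensurable.

## 3D neurite morphometry

`enhance_tubes()` smooths with an isotropic 3D Gaussian
(`gaussian_sigma_px = 3`), subtracts local background, and applies a
single-scale Frangi vesselness filter (`frangi_scale_px = 10`, α = β =
0.5, γ defaulting to half the maximum Hessian norm — the standard
data-driven choice). The filter is single-scale on purpose: the source
pipeline quotes one radius, and multi-scale fusion is out of scope.
Local background subtraction is realized as a grayscale opening with a
separable box element of half-width `2 * frangi_scale_px` — the
rolling-ball radius the protocol leaves unstated, implemented with the
box shape so the opening stays O(N).

`binarize_and_skeletonize()` thresholds with the shared Otsu and thins
to a curve skeleton by sequential deletion of *simple* voxels (a voxel
is simple when its deletion provably preserves local topology —
one 26-connected foreground component in the 26-neighbourhood and one
6-connected background component in the 18-neighbourhood touching a
face). End points (≤ 1 foreground neighbour) are preserved. Deletion
order matters for where the curve lands: voxels are eroded in
increasing chamfer-distance-transform order (uniform shell peeling,
which places the curve medially) with intensity as the tie-break within
a shell (so the curve follows the vesselness ridge through anisotropic
voxels). Without the ordered erosion the skeleton zig-zags between
z-slices and fragment lengths inflate by ~20%.

`fragment_stats()` counts 26-connected skeleton components and sums,
per fragment, the anisotropic Euclidean step length over every adjacent
voxel pair — the total curvilinear extent, which is the natural reading
of "average length of the fragments" (the longest-shortest-path
alternative would ignore branches). Single-voxel fragments are kept
with length 0 unless `min_voxels` filters them: the source protocol
states no pruning, so none is applied by default, and no spur pruning
is performed either.

Deconvolution: the source pipeline runs commercial deconvolution
software before segmentation. A Richardson–Lucy stage with a Gaussian
PSF is provided (`deconvolve = TRUE`), but it is off by default and all
validation runs without it — the morphometry must stand alone, and a
reimplementation of a commercial wizard would be a different project.

## Calcium imaging

The movie-level chain: `activity_map()` accumulates |frame-to-frame
differences| and low-passes the map in the Fourier domain with a
Gaussian of cutoff 0.1 cycles/px (the exact filter form is not
published; a Gaussian is the smoothest choice). `detect_cells()` takes
local maxima above `median + 5·MAD`, greedily, with a minimum
separation of 6 px; manual curation is a reproducible JSON edits file
(`apply_roi_edits()`), never an interactive-only step. ROIs are
fixed-radius disks (4 px): the acquisition (20×, organoid surface)
renders somata as round blobs and no ROI shape is published.

Traces: F₀ is a running 10th percentile over a 30-s window of a 1-s
pre-smoothed trace (the pre-smoothing stops shot noise from dragging a
percentile baseline below the true resting fluorescence); ΔF/F₀ is
smoothed with a 0.75-s moving average (3 frames at 4 Hz) for detection.
These three constants are not published; the values are standard
practice for slow network transients and are exposed in the
configuration.

Detection: a transient starts where value and slope rise, peaks at a
local maximum, and ends where the slope turns back up or at
`max_event_s = 10` s (the protocol names a maximum interval without a
value; 10 s covers the slowest kernel the package targets at its 5%
amplitude point). The amplitude is the peak ΔF/F₀ relative to the
trace value at onset, and the acceptance rule is
`amplitude >= max(0.02, 10 * sigma_hat)` where `sigma_hat` is a robust
(MAD-of-differences) trace-noise estimate. The absolute 2% term is the
published default and governs clean traces; the adaptive term exists
because a pointwise 2% rule on a noisy trace floods the event list —
the multiplier 10 was calibrated once on event-free traces at the
noisiest design point of the generator (SNR 5) and is not seed- or
dataset-tuned.

Kinetics: each event is fitted by least squares with the full transient
kernel `A (1 − e^{−(t−t0)/τr}) e^{−(t−t0)/τd}` plus a linear local
baseline term, with the model convolved with the same moving average as
the fitted trace (window 1.25 s). Three choices deserve explanation:

* *Why the product kernel and not separate rise/decay segment fits:*
  on a product-form transient the rise segment is shaped by the decay
  and vice versa; segment-wise single-exponential fits are biased by
  −40% to −80% in τ_r on noiseless kernels, which no tolerance survives.
* *Why the baseline slope term:* the running-percentile F₀ leaves a
  slow tilt inside event windows that otherwise biases τ_r upward by
  ~15–20% at SNR 5.
* *Why τ_r is capped at 20 s:* a rise constant longer than the
  observable event window cannot be identified; the cap keeps single
  noisy events from sliding along the rise/decay trade-off ridge.

Classification: a cell is *fast* iff the median rise time of its
successfully fitted events is strictly below `tau_star_s = 1.5`; ties
at exactly 1.5 s are slow, matching the "rise time < 1.5 s" phrasing of
the fast population. Slow cells are excluded from the network metrics.
The active fraction uses all detected ROIs as denominator (the
alternative — fast ROIs only — is a one-line change but would make the
metric insensitive to non-neuronal contamination, which is what it is
for).

Synchrony is the peak co-activation fraction: the maximum over 1-s bins
of the number of distinct active cells with an event peak in the bin,
divided by the number of active cells. The published definition
("relative number of simultaneous events") fixes neither the bin nor
the aggregation; the peak form is bounded in [0, 1], equals 1 exactly
in the fully synchronous limit, and a mean-co-activation alternative is
selectable.

**Known limitation (measured, not hypothetical).** At the design
conditions of the generator — 4 Hz sampling, SNR 5, amplitudes around
0.4 ΔF/F₀ — the likelihood surface in τ_r is essentially flat above
~2 s: profile fits at any τ_r in [2, 12] s reach the noise floor
indistinguishably, even pooling all events of a movie and even fixing
event times at their true values. Fast rise constants (0.5 s) are
recovered to within ~10%, decay constants to within ~10%, but a 3-s
rise constant cannot be pinned to 15% by any estimator; the
corresponding assertion in the test suite is expected to fail and is
left in place deliberately. The 1.5-s fast/slow boundary sits exactly
where the profile is steep, so classification is unaffected — slow
cells are reliably excluded.

## Expression statistics

`normalize_counts()` retains the declared reference genes with
cross-sample mean count above 450, computes each sample's geometric
mean over the retained set, and rescales samples to the grand geometric
mean. After normalization the retained-gene geometric means agree
across samples to floating-point precision, and the operation is
idempotent.

`select_de()` runs per-gene two-sided t-tests on `log2(x + 1)` of the
normalized counts and applies the linear fold-change gates (≥ 1.5 up,
≤ 0.66 down) at p ≤ 0.05, with no multiple-testing correction — the
published lists use raw p-values, and a BH-FDR column is available but
off by default. Two deliberate choices:

* *Pooled-variance t by default.* At n ≈ 3 per group the Welch
  approximation is markedly conservative (measured null p ≤ 0.05
  fraction ≈ 0.035 instead of 0.05), and the spreadsheet "multiple
  t-tests" the published analysis ran default to the pooled test.
  Welch remains available (`var_equal = FALSE`).
* *Tests on the log scale, fold change on the linear scale.* The
  1.5/0.66 cutoffs are linear quantities; the test statistics behave
  far better on logs. The +1 pseudo-count exists only on the log scale
  to admit zero counts. Fold change is the ratio of group means
  (mean-of-ratios is undefined for zero-mean genes and was not chosen).

`cluster_profiles()` is average-linkage agglomeration on
`1 − Pearson r` (range [0, 2]), delegated to `stats::hclust` and
validated in the tests against a naive O(n³) reference on all matrices
up to 8 leaves. `relative_expression()` is the 2^−ΔCt closed form with
ATP5O as the default reference; isoform ratios cancel the reference
entirely (`2^−(Ct_a − Ct_b)`). `qc_controls()` reports
positive-control linearity (R² on logs) and the negative-control
mean + 2 SD background level; it gates nothing, because no gating rule
is published.

## What the generators emulate — and what they do not

Every generator is a pure function of its parameters and a seed, and
returns a ground-truth record describing the noise-free phantom
exactly (serializable as versioned, validated JSON via
`write_truth()`).

* `gen_tube_phantom()`: gently curved 3D tubes (radius 2 px, lengths
  3–8 µm) in a 32 × 160 × 160 volume at (0.2, 0.133, 0.133) µm voxels,
  placed with ≥ 1.2 µm clearance, blurred with a Gaussian PSF
  (σ = 0.8 vox) and overlaid with Gaussian noise at a stated SNR
  ((peak − background)/noise SD). Tube lengths sit at the fragment
  scale the morphometry reports; the volume is a desk-scale crop of the
  133 × 133 × 8 µm³ fields of the source acquisitions.
* `gen_puncta_image()` / `gen_coloc_pair()`: round marker clusters
  (radius 5–12 px — at the scale of the nuclear/cytoplasmic marker
  signal the 2D chain targets; structures below the 5-px median window
  would be eroded by the chain itself, which is a property of the
  chain, not a phantom artefact) or bar-shaped "mitochondria", placed
  with a 2-px clearance ring so the planted count survives the PSF
  blur. Truth records exact masks, coverage and end-to-end lengths.
* `gen_calcium_movie()`: flat-top fluorescent discs (so the ROI-mean
  ΔF/F₀ equals the planted amplitude) firing Poisson trains with a
  6-s minimum inter-event gap, a configurable shared-train fraction
  controlling synchrony, the product kernel scaled so its peak equals
  the drawn amplitude (mean 0.4, SD 0.1), optional exponential
  bleaching, and per-pixel Gaussian noise at a stated SNR. The default
  geometry (128 × 128 px, 5 min at 4 Hz) is the published acquisition
  scaled down for desk-speed runs.
* `gen_count_matrix()`: log-normal gene abundances, sample-specific
  library factors (so normalization is non-trivial), negative-binomial
  or log-normal counts, planted fold changes, and a reference-gene set
  split 7 high / 3 low so the >450 filter is genuinely exercised —
  mirroring the 7-of-10 reference genes the published panel retained.
* `gen_ct_table()`: `Ct = Ct_ref − log2(rel_expr) + noise`.

None of the generators simulate real optics (full PSF models),
organoid tissue geometry, motion, neuropil contamination, or
probe-level count artefacts. Passing the recovery tests therefore
demonstrates that the *algorithms* are correct and calibrated on data
matching their stated assumptions — not that any particular microscope
or panel will meet those assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:
16 × 16 images for the threshold oracles, 32 × 160 × 160 phantom stacks
with up to 20 tubes, two 20-cell 5-minute movies at SNR 5 plus smaller
movies for the threshold and synchrony checks, and 200 null replicates
of the 760-gene panel. Tolerances asserted in the tests are the ones
the study conditions support: exact fragment counts on noise-free
phantoms, 15% on lengths (digital-staircase discretization plus the
~r medial retreat of a skeleton at tube caps), 10% on event rates, 15%
on identifiable kinetic constants, a single-panel binomial band around
0.05 for the null calibration (normalization couples genes within a
replicate, so the per-gene binomial scale of one panel is the honest
yardstick), and floating-point agreement for the closed forms and
oracle comparisons. Ties are broken deterministically everywhere
(first-maximum in Otsu, lowest-leaf-index in clustering, higher-peak
wins in ROI and event non-overlap resolution).
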