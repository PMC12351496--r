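# organoidquant

Quantification pipelines for iPSC-derived cortical organoid studies, as
one tested R package. It reimplements the four bespoke analysis chains
such studies rely on — 2D fluorescence marker quantification, 3D neurite
skeleton morphometry, calcium-imaging transient and network analysis,
and NanoString-style count normalization with fold-change
differential-expression selection — together with synthetic-data
generators that emit ground-truth records, so every pipeline can be
validated end to end without any raw microscopy or count data.

It is written for imaging and molecular-biology groups who have these
analyses scattered across MATLAB scripts, ImageJ macros and
spreadsheets, and want them scriptable, versioned and testable.

## What the pipelines compute

**2D marker quantification.** A mean z-projection over *n* planes is
passed through the published chain — median filter (5 px), histogram
shape-based background subtraction, H-minima transform (H = 0.05 on the
normalized intensity scale), CLAHE — then binarized with Otsu's
threshold (the cut *t* maximizing the between-class variance
σ²_B(t) = ω₀ω₁(μ₀ − μ₁)² over 256 candidate cuts). The readouts are the
area fraction |mask|/|FOV| and the integrated signal density
ISD = Σ_mask I_raw; mask overlap (pixelwise AND) quantifies synaptic
marker colocalization, and connected components restricted to a neurite
path mask give mitochondria counts and lengths (principal-axis extent ×
pixel size).

**3D neurite morphometry.** 3D Gaussian smoothing (σ = 3 px), local
background subtraction, and a single-scale Frangi vesselness filter
(r = 10 px; V = (1 − e^(−R²_A/2α²)) · e^(−R²_B/2β²) · (1 − e^(−S²/2γ²))
from the Hessian eigenvalues) enhance tube-like structures; Otsu
binarization and homotopy-preserving 3D thinning produce a one-voxel
curve skeleton. Fragments are 26-connected components; a fragment's
length sums the anisotropic Euclidean steps between adjacent skeleton
voxels.

**Calcium imaging.** Cells are detected as local maxima of the
low-pass-filtered cumulative frame-difference map; ΔF/F₀ traces use a
running-percentile baseline; transients are detected at a 2% ΔF/F₀
amplitude threshold and fitted with
A (1 − e^(−(t−t₀)/τ_r)) e^(−(t−t₀)/τ_d); cells are *fast* (neuronal) iff
their median rise time is below τ\* = 1.5 s, and network metrics
(active fraction, frequency, amplitude, synchrony = peak co-activation
fraction in 1-s bins) are computed over fast cells.

**Expression statistics.** NanoString-style normalization equalizes the
per-sample geometric mean of the housekeeping genes whose average count
exceeds 450; per-gene two-sided t-tests plus the linear fold-change
gates FC ≥ 1.5 (up) / ≤ 0.66 (down) at p ≤ 0.05 select DE genes;
hierarchical clustering uses average linkage on 1 − Pearson r. qPCR
relative expression is 2^−ΔCt against ATP5O, and isoform ratios
(e.g. 4R/3R tau) are ratios of relative expressions.

## A worked example

```r
library(organoidquant)

# a synthetic 5-min, 4-Hz movie with 20 cells firing ~2 events/min
g   <- gen_calcium_movie(n_cells = 20, rate_per_min = 2, snr = 5, seed = 7)
res <- analyze_calcium(g$movie)
res
#> <calcium_result> 20 ROIs, 168 events; active fraction 1, synchrony 0.15
glance(res)
#> # A tibble: 1 x 6
#>   n_cells_total n_active_fast active_fraction mean_frequency_per_min ...
#> 1            20            20               1                   1.68
head(tidy(res), 3)
#>   roi_id onset_idx peak_idx offset_idx amplitude rise_time_s decay_time_s ...
#> 1      1        83       92        114     0.379       0.554         2.09
#> 2      1       153      162        193     0.490       0.632         1.78
#> 3      1       268      274        293     0.294       0.483         1.84
```

All 20 planted cells are found, their event rate (1.68/min) matches the
post-thinning planted rate, and the fitted kinetics recover the planted
kernel (τ_r = 0.5 s, τ_d = 2 s) within a few percent.

```r
# NanoString-style counts: 760 genes + 10 reference genes, 4 vs 4
gn <- gen_count_matrix(n_per_group = 4, de_fraction = 0.05, fc = 3, seed = 7)
nn <- normalize_counts(gn$cm)
nn$report
#> <normalization_report> 7 housekeeping genes retained (average count > 450);
#>   scale factors 1.117, 1.145, 0.8921, 0.9007, 1.008, 1.435, 0.64, 1.052
glance(select_de(nn$counts))
#> # A tibble: 1 x 6
#>   n_genes  n_up n_down alpha fc_up fc_down
#> 1     770    18     39  0.05   1.5    0.66

# a 3D tube phantom through the full morphometry chain
gt <- gen_tube_phantom(12, snr = 10, seed = 7)
analyze_neurites3d(gt$stack,
                   tube_enhance_params(gaussian_sigma_px = 1,
                                       frangi_scale_px = 2))
#> # A tibble: 1 x 3
#>   n_fragments mean_length_um volume_um3
#> 1          12           5.89      2898.
```

All 12 planted tubes are recovered exactly, with the mean skeleton
length within discretization error of the planted centerline lengths.

`autoplot()` methods render volcano plots for DE tables, offset trace
rasters for calcium results and fragment-length histograms for skeleton
statistics; `plot_activity_map()` overlays detected ROIs on the
activity map.

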