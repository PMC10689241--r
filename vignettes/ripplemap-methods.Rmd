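---
title: "Topological analysis of ripple waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of ripple waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hippocampal sharp-wave ripples (SWRs) are transient events in the CA1
local field potential: a fast (70–400 Hz) oscillation at the pyramidal
layer (SP) riding on a slower sharp wave at stratum radiatum (SR). Their
waveforms vary widely, and the usual spectral summaries (peak frequency,
amplitude) compress that variability into a handful of numbers chosen in
advance. `ripplemap` instead treats each detected, peak-centered,
band-filtered ripple trace as a point in a *waveform space* — one
dimension per time sample (127 dimensions at the default 2,500 Hz and
±25 ms window) — and asks data-driven questions about the shape of the
resulting cloud: is it one continuum or several categories (persistent
homology), how many coordinates does it really have (intrinsic
dimension), how are physiological features laid out over it (Structure
Index, voxel correlation, density contours), and how much layer-resolved
synaptic information it carries (CSD decoding).

## Detection and features

Detection follows the consensus recipe: band-pass 70–400 Hz with an
order-512 FIR applied forward and backward (zero phase), envelope =
analytic-signal magnitude smoothed by a fourth-order Savitzky–Golay
filter (33.4 ms) and two moving means (2.3, 6.7 ms), threshold at
mean + k·s.d. of the envelope with k restricted to [2, 5], events closer
than 15 ms merged (strictly closer: an exactly-15 ms gap stays
separate), and each event centered on the trace minimum within ±15 ms of
the envelope peak. Noisy epochs are masked beforehand whenever the sum
of two separated channels leaves ±10 s.d. inside a 1-s epoch (epoch
length is our choice; the artifact criterion needs whole-epoch
granularity to catch chewing artifacts that straddle threshold
crossings).

Per-event features: spectral peak after subtracting a fitted exponential
decay from the 10 Hz-binned periodogram (with a log-linear 1/f fallback
when the nonlinear fit diverges); spectral entropy of the sum-normalized
binned spectrum; envelope amplitude (maximum within ±25 ms — the
envelope value at the trough itself oscillates with carrier phase, the
local maximum does not); two duration proxies; 1–10 Hz slopes to/from
the peak; and a multi-unit index from 300–400 Hz power. The current
source density (CSD) is the discrete second spatial derivative of the
laminar potential, sinks negative, with per-layer summaries only when at
least 8 contiguous channels span SO→SLM.

## Synthetic data: what it emulates and what it does not

Every quantitative claim in the tests is anchored in three generators
whose ground truth is known exactly.

*Ripple sets.* A synthetic ripple is a Gaussian-windowed sinusoid
`A · exp(−t²/2σ²) · sin(2πft − π/2)` with frequency, amplitude and
envelope width drawn independently and uniformly (defaults 80–240 Hz,
2–5 a.u., 0.5–2 × a 10 ms base width). The trough sits at the window
center, matching trough-centered detection. Three free parameters make
the noiseless cloud a 3-manifold; a clustered mode draws frequency from
three disjoint bands (80–100, 130–150, 190–210 Hz). The amplitude range
deserves a note: waveform-space distances scale multiplicatively with
amplitude, so too wide an amplitude spread (e.g. 5:1) collapses
low-amplitude events of different frequencies together and the clustered
cloud stops being three components in any metric sense. A 2.5:1 spread —
the shape of a typical 5th-to-95th-percentile amplitude range in
recordings — keeps the clusters cleanly separated while leaving the
continuous cloud's intrinsic dimension at 3.

*Geometric objects.* Line, plane, Swiss roll, torus (radii 1.0/0.3) and
a 5-ball are sampled uniformly from their parametric forms, carried into
127 dimensions by a seeded orthonormal frame (distances preserved), and
perturbed by isotropic Gaussian noise whose *total* s.d. is 0.01. We
deliberately interpret the noise level as the norm of the ambient
perturbation rather than a per-coordinate s.d.: at 127 dimensions a
per-coordinate 0.01 has norm ≈ 0.11, larger than the k-NN neighborhood
radius of any unit-scale object, and every local estimator (ABID
included) would then report noise dimension, not object dimension. The
line spans length 10 because 1D samples are so dense that neighborhoods
of k = 50 points otherwise stay inside the noise floor.

*Laminar sessions.* An 8-channel SO→SLM probe at 100 µm spacing. Per
event, a target CSD profile is programmed as a linear function of the
drawn features (defaults: SR sink coupled to frequency and amplitude, SO
source to amplitude, SLM sink to duration, SP uncoupled), and the
potential is obtained by solving the discrete Poisson equation with
grounded boundary channels — so `compute_csd()` recovers the programmed
values exactly at interior channels and the potential stays bounded
(naive double integration grows quadratically across channels and would
trip the artifact mask). The ripple itself is added on the SP channel;
white noise (s.d. 0.05 a.u. against amplitudes 2–5) on all channels.
Events are spaced ≥ 800 ms so that the event-driven part of the envelope
does not inflate the detection threshold; real SWR rates are sparser
still, so this is the conservative direction.

None of these generators emulate theta epochs, spike leakage,
non-stationary noise, electrode drift, or the expert validation step of
real pipelines — passing tests therefore demonstrate correctness of the
algorithms under the stated model, not detection performance on raw
recordings.

## Persistent homology at desk scale

No Rips backend exists in this R environment, so the package implements
Vietoris–Rips persistence (H0–H2) directly (`src/rips.cpp`): H0 by
union-find over the full edge filtration (exact single-linkage deaths,
with the size of the dying component recorded at every merge), H1/H2 by
boundary-matrix reduction over Z/2 with simplices enumerated up to a
truncation radius. The engine is validated against closed-form barcodes
(hexagon, square, octahedron) and `hclust(method = "single")`.

Full-threshold complexes in dimension 2 are infeasible at any scale, so
the filtration is truncated at 3× (maxdim ≤ 1) or 2× (maxdim 2) the
median 15-NN distance; classes still alive there are right-censored and
always counted as significant. The truncation radius comfortably exceeds
the death radius of sample-scale features while keeping the tetrahedron
count tractable; a censored bar is by construction more persistent than
anything that died below it.

Subsampling policy: loops and cavities are computed on farthest-point
(maxmin) landmark sets thinned to ≤ 75% of the cloud (and ≤ 450 points
for maxdim 2, ≤ 1,500 otherwise) — coverage-uniform landmarks resolve the
torus's minor-circle features that uniform random subsamples of the same
size miss, and the thinning is essential because an un-thinned landmark
set inherits the cloud's spacing tail. Component counting uses uniform
random subsamples, which preserve the density information that separates
clusters from coverage gaps.

Bar significance is a rule we had to choose (barcodes are read by eye in
the source literature). The default, after validating alternatives on
the ground-truth objects: an H0 merge is a separate component when its
radius is ≥ 2.5× the median merge radius *and* the dying component
carries ≥ 5% of the points — radius alone is defeated by Poisson-gap
stragglers, which merge late but carry no mass. H1/H2 bars are
significant above the largest relative persistence break (≥ 1.6×) in the
upper half of the spectrum: noise persistences decay smoothly with
consecutive ratios near 1, real features sit a multiplicative break
above them. A plain largest-gap rule and a half-of-longest rule remain
available (`rule = "gap"`, `"frac"`) for sensitivity checks; the
largest-gap rule in particular mis-reads the torus, whose censored outer
loop dwarfs the genuine second loop.

## Intrinsic dimension (ABID)

For each point, the k = 50 nearest neighbors define unit difference
vectors; isotropic directions in d dimensions satisfy E[cos²θ] = 1/d, so
`d̂(x) = k(k−1) / Σ_{i≠j} cos²θ_ij` with self-pairs excluded (the
variant with self-pairs included biases low; the chosen variant passes
the full object suite). The aggregate is the median over points —
invariant to rotation, translation and uniform scaling by construction,
and stable (±10%) across window lengths on synthetic ripples. Curvature
biases the torus slightly upward (≈ 2.3–2.5) and boundary effects bias
the 5-ball slightly downward (≈ 4.9); both stay within ±0.5 of truth at
n ≥ 1,000.

## Structure Index

Feature values are split into ten equal-width bins (the literal reading
of "ten equal bins"; equal-count binning is available and makes the SI
invariant to monotone feature transforms). For each ordered bin pair
(U, V), the overlap score is the fraction of the k nearest neighbors of
points of U — searched within U ∪ V minus the query point — that belong
to V; the diagonal is defined as zero. SI = max(0, 1 − mean scaled
out-degree) ∈ [0, 1]: 1 for perfectly separated bins, 0 for random
mixing. k defaults to 3 × n_bins (the source does not state k; the value
is recorded in every result) and is clamped per bin pair so it never
exceeds the restricted set size minus one. Significance comes from
permuting feature values over points; the p-value is a one-sample
one-sided t-test of the shuffle distribution against the observed SI
(an empirical-rank option exists). A brute-force enumeration oracle
(explicit distance matrix, explicit neighbor lists) matches the
production path exactly for N ≤ 50, and the type-I error of the shuffle
test calibrates to α over 200 simulated null runs.

## Embedding geometry

UMAP (uwot, spectral initialization, all other parameters at backend
defaults, recorded), Isomap (vegan) and PCA reduce the cloud to the
ABID-informed dimension (4 for experimental-like data). UMAP and PCA
keep a fitted handle so new events can be projected later; projection
error baselines come from a pooled re-embedding of reference plus
control events, rigidly aligned back to the reference frame on the
shared events (alignment error = displacement of the reference events,
fitting error = displacement of projected controls).

Voxel spatial correlation partitions the embedding into cubes anchored
at the coordinate-wise minimum (minimum occupancy 5 events; both are our
choices, the source states only "voxels of different resolutions"), and
Pearson-correlates per-voxel feature means. The voxel size is validated
by simulating, on the actual embedding, an anticorrelated pair (smooth
spatial field ± unit noise; expected R² = 1) and a random pair (expected
R² = 0), scoring each candidate size by (R²_anti − 1)² + R²_rand²:
too-small voxels average too few events and inflate the random R²,
too-large voxels erase spatial structure.

Density contours: a bivariate Gaussian KDE (Scott bandwidth) on a
200 × 200 grid over the events in a feature range, normalized to unit
mass, partitioned into 10 iso-proportion levels *of density mass*
(cumulative-mass thresholds; "same density proportion" also admits a
height reading — mass makes level j enclose exactly j/10 of the
probability). ROI membership is decided on the grid; conjunctive
categories are intersections of per-feature ROIs.

Centroid statistics use Euclidean distances between group mean
coordinates, in 2D projections or the full space; bootstrap resamples
equal counts per group, shuffles permute labels, and the p-value is the
shuffle exceedance fraction. Rigid alignment between two embeddings
pairs the centers of mass of 20 shared feature bins and solves the
orthogonal-Procrustes/Kabsch problem in closed form with the determinant
forced to +1.

## Decoding

Per-layer CSD values, scaled by their s.d. without mean subtraction
(polarity is physiological), are predicted from event coordinates by
support-vector regression (radial kernel, backend defaults; Wiener,
Wiener-cascade and gradient-boosted alternatives are provided) under
tenfold cross-validation. When decoding from the reduced space the
embedding is refit on each training fold and the test fold projected
into it, keeping folds independent; the per-fold refit uses UMAP by default,
with PCA as a fast deterministic alternative. Goodness of
fit is the explained variance 1 − var(y − ŷ)/var(y); a shuffled-target
run with the same folds defines the chance band. The origin classifier
is a C-SVC (radial kernel, C = 1) with tenfold accuracy and label
shuffles; class equalization on a covariate is histogram-bin subsampling
over 10 bins.

A caveat specific to the synthetic sessions: because the generator
programs each layer's CSD as a linear function of the three drawn
parameters, the measured feature space (frequency, amplitude, entropy,
duration) contains the decoding targets almost by construction, and it
decodes essentially as well as the original 127D space at any noise
level we simulated. In recordings, where CSD depends on waveform detail
that four summary features cannot carry, the reduced waveform space is
expected to outperform the feature space; under this generator it does
not, and only the remainder of the ordering (original ≥ reduced, both
far above chance for coupled layers, chance for uncoupled) is
reproducible. The tests state the full ordering and record this
structural limitation.

## Problem sizes and numerical choices

Analyses run at n = 2,000 events per cloud, 450-point landmark sets for
dimension-2 persistence (about 40 s each), 1,500-point subsamples for
component counting, 200 calibration runs for the shuffle test, and
tenfold decoders on ~400 events. Zero-persistence bars are dropped;
duplicate points contribute no direction vectors to ABID (excluded per
neighborhood); slightly negative raw SI values are clamped to 0; CSD
boundary channels are reported as absent rather than extrapolated; ties
in SP-channel selection break to the lowest index.

## Known limitations

The persistence engine is a plain reduction, not a cohomology-optimized
one: point counts beyond ~500 at maxdim 2 are out of reach, so the
3,500-point bootstrap replicates of the original analysis are reproduced
only in scaled-down form. Component counting from single-linkage radii
is intrinsically ambiguous for sparsely sampled 1-manifolds (a large
coverage gap *is* a disconnection at that scale); the mass criterion
resolves every case in the validation battery but inputs far outside
those conditions deserve a look at the barcode itself. ABID inherits a
small curvature bias upward and boundary bias downward. Isomap
embeddings carry no out-of-sample transform, so new events cannot be
projected into them.
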