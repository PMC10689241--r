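# ripplemap

Topological analysis of hippocampal sharp-wave ripple (SWR) waveforms in
R.

SWRs — transient 70–400 Hz oscillations at the CA1 pyramidal layer
riding on a stratum-radiatum sharp wave — vary far more than their usual
spectral summaries capture. `ripplemap` treats every detected,
peak-centered, band-filtered ripple as a point in a *waveform space*
with one dimension per time sample (127 dimensions at 2,500 Hz and
±25 ms), and characterizes the resulting point cloud directly:

- **Detection** of ripple events on the pyramidal channel (zero-phase
  70–400 Hz FIR, smoothed analytic envelope, 2–5 s.d. threshold, 15 ms
  merging, trough centering), plus per-event spectral/temporal features
  and current-source-density (CSD) summaries from laminar probes.
- **Topology**: Vietoris–Rips persistent homology (H0–H2, implemented in
  C++ and validated against closed-form barcodes), Betti numbers with an
  explicit bar-significance rule, and density-outlier removal. Answers
  "is the cloud one continuum or several categories?"
- **Intrinsic dimension** by the angle-based (ABID) estimator:
  `d̂(x) = k(k−1) / Σ_{i≠j} cos²θ_ij` over the k nearest neighbors,
  using E[cos²θ] = 1/d for isotropic directions.
- **Structure Index (SI)**: feature values are binned (10 equal bins);
  the k-NN overlap between bin groups forms a directed graph and
  `SI = max(0, 1 − mean scaled out-degree)` ∈ [0, 1] quantifies how much
  a feature is laid out as a gradient over the cloud, with a shuffle
  test for significance.
- **Embedding geometry**: UMAP / Isomap / PCA reduction to the
  ABID-informed dimension, voxel-based spatial correlation of feature
  pairs (with a toy-model voxel-size validation), kernel-density contour
  categorization, centroid statistics with bootstrap/shuffle controls,
  closed-form rigid (Kabsch) alignment of embeddings, and projection of
  new events into a fitted embedding.
- **Decoding**: tenfold support-vector regression predicting per-layer
  CSD values from waveform-space coordinates, scored by explained
  variance `1 − var(y − ŷ)/var(y)` against a shuffled-target chance
  band, and an SV classifier for event origin.
- **Synthetic data** with exact ground truth: Gaussian-windowed
  sinusoid ripples (continuous or 3-cluster frequency distributions),
  geometric objects (line, plane, Swiss roll, torus, 5-ball) embedded in
  127D, and laminar LFP sessions whose per-layer CSD is a programmed
  function of the ripple features.

## Worked example

```r
library(ripplemap)

# synthetic ripples: 2,000 events, three independent parameters
rs <- generate_ripple_set(2000, noise_rms = 0, seed = 1)

# intrinsic dimension of the 127D cloud
abid_dimension(rs$cloud, k = 50)$estimate
#> [1] 2.977316        # rounds to 3: frequency, amplitude, duration

# topology: one continuum, no holes
fo <- remove_outliers(rs$cloud, k = 10, pct = 95)
bc <- persistence_barcodes(fo$X, maxdim = 0, seed = 1)[[1]]
betti_numbers(bc)
#> b0
#>  1
#> attr(,"rule")
#> [1] "dominance"

# the 3-cluster construction shows three components instead
cl <- generate_ripple_set(2000, mode = "clustered", noise_rms = 0, seed = 1)
fc <- remove_outliers(cl$cloud, k = 10, pct = 95)
betti_numbers(persistence_barcodes(fc$X, maxdim = 0, seed = 1)[[1]])
#> b0
#>  3
#> attr(,"rule")
#> [1] "dominance"

# Structure Index of frequency over a 4D UMAP embedding
emb <- reduce_embedding(rs$cloud, method = "umap", d = 4, seed = 1)
si_significance(emb$coords, rs$features$frequency, seed = 1)$si
#> [1] 0.9678933      # strong gradient; a shuffled copy scores near 0
```

The first number says the noiseless ripple cloud occupies a
three-dimensional manifold — exactly its three generative parameters.
The Betti counts distinguish the continuous cloud (one connected
component) from the clustered construction (three). The SI near 0.97
says frequency is laid out as an almost perfectly separated gradient
across the embedding; a value near 0 would mean random mixing.

The numbered scripts under `analysis/` run the full study on synthetic
data — simulation, detection fidelity, topology and intrinsic dimension,
embedding geometry and SI tables, CSD decoding — writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_features.R
Rscript analysis/03_topology.R
Rscript analysis/04_embedding_si.R
Rscript analysis/05_decoding.R
```

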