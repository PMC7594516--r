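# rsoda

Statistical object distance analysis (SODA) for two-channel
super-resolution (STED-class) images of protein clusters, in R.

Synaptic proteins appear in nanoscopy images as fields of small
(~30–300 nm) fluorescent clusters. Whether two proteins are functionally
associated shows up not as pixel overlap but as a reproducible
centroid-to-centroid distance of 30–150 nm between their clusters —
below the reach of classical colocalization analysis. `rsoda`
implements the SODA approach: segment both channels, bin all
cross-channel cluster distances into 16 concentric 15 nm rings, compare
the boundary-corrected ring counts (in Ripley's K units, so that under
complete spatial randomness E[G_i] = π(r_i² − r_{i−1}²)) with their
CSR null distribution, keep rings whose standardized excess passes the
universal threshold T(N) = 2 log N, and convert the excess into a
per-pair **coupling probability**

P(x, y) = σ_i G⁰_i / G_i  for a pair in significant ring i  (else 0),

which with an identity ring-correction matrix is just
(G_i − μ_i)/G_i — the fraction of ring-i pairs in excess of chance.

The package covers the full workflow of the associated high-throughput
analysis framework:

- **segmentation** — à-trous B3-spline wavelet spot detection (scales
  3–4, MAD thresholds, intersection), area/extent filtering, raw-image
  weighted centroids, morphology features, localization-error
  propagation, Lorentzian FWHM QC;
- **soda core** — ring statistics with angle-sampled boundary
  correction, seeded Monte-Carlo null moments, thresholding, coupling
  probabilities/distances/indices;
- **population statistics** — randomization tests on means and
  F-statistics, chi-square subtype-prevalence tests, per-neuron
  histograms and cumulative-frequency curves;
- **subtype analysis** — 7-D feature space (5 morphology + coupling
  distance and probability of coupled clusters), min-max scaling, UMAP
  embedding (25 neighbours, min_dist 0.05; via the co-installed
  `python`/`umap-learn`, with a PCA fallback), per-condition KDE maps,
  local-maxima prototypes, Ward/silhouette grouping, nearest-prototype
  assignment and cross-dataset mapping (>40% links highlighted);
- **synthetic data** — a fully seeded generator of two-channel images
  with known coupling fraction/distance, PSF, Poisson noise and
  dendrite-shaped ROIs, used as ground truth by the entire test suite;
- **cli** — `simulate`, `soda`, `subtypes`, `stats` subcommands with
  resolved-config JSON provenance, CSV/TIFF/JSON output (a minimal
  baseline TIFF reader/writer is built in).

## Worked example

```r
library(rsoda)

# a synthetic two-channel field: 300 clusters/channel on a dendrite-
# shaped ROI, every channel-1 cluster coupled at 45 +/- 5 nm
cfg <- simulation_config(image_shape = c(2048, 2048),
                         n_clusters_ch1 = 300, n_clusters_ch2 = 300,
                         coupling_fraction = 1,
                         coupling_distance_mean = 45, seed = 35)
truth <- simulate_cluster_pairs(cfg)
imgs  <- render_image_pair(truth, cfg)

mask <- compute_foreground_mask(imgs$ch1, imgs$ch2)
c1 <- segment_channel(imgs$ch1, mask, cfg$pixel_size, channel = 1)
c2 <- segment_channel(imgs$ch2, mask, cfg$pixel_size, channel = 2)
res <- soda_analysis(c1, c2, mask, cfg$pixel_size, seed = 36)
res$summary
```

```
SODA coupling summary
  coupling index: ch1 0.955, ch2 0.951
  coupled pairs: 273, mean coupling distance: 44.8 nm
  per-ring mean coupling probability (coupled pairs):
    (30, 45] nm: P = 0.986 (n = 148)
    (45, 60] nm: P = 0.977 (n = 125)
```

Reading: ~95% of the segmented clusters in each channel found a
significantly coupled partner (the shortfall is mostly cluster merging
at a 70 nm PSF), the coupled pairs sit almost entirely in the
(30, 60] nm rings — bracketing the simulated 45 nm offset — and the
per-ring coupling probabilities near 1 say that at those distances
essentially no pairs are explained by chance. For two *independent*
channels the same analysis returns coupling probabilities of ~0
everywhere (the T(16) ≈ 5.5σ threshold makes false rings rare).

## Command line

```sh
Rscript inst/scripts/rsoda simulate --out sim --seed 7
Rscript inst/scripts/rsoda soda --ch1 sim/ch1.tif --ch2 sim/ch2.tif --out out
Rscript inst/scripts/rsoda subtypes --features a.csv,b.csv --out subtypes
Rscript inst/scripts/rsoda stats --values groupA.csv,groupB.csv --out stats
```

Every run writes `resolved_config.json` next to its outputs. See
`vignettes/soda-methods.Rmd` for the model, parameter and validation
details.
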