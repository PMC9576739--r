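# stormcoloc

Quantification of two-color STORM localization data for the spatial
relationship between cortical F-actin and clathrin-coated structures
(CCSs). Single-molecule localization microscopy yields point sets, not
images; this package analyzes those point sets directly:

1. **Fine channel registration** — fiducial beads are detected by
   temporal persistence (they emit in nearly every frame; fluorophores
   blink), each bead is reduced to a center by a maximum-likelihood
   isotropic 2-D Gaussian fit, centers are paired across channels by
   mutual nearest neighbor, and the moving channel is corrected by the
   average displacement. With *n* beads of center noise σ the correction
   error per axis is σ√2/√*n* (≈ 2 nm for 50 beads at σ = 10 nm).
2. **Voronoi cluster segmentation** — each channel's localizations are
   tessellated; a localization is "dense" when its Voronoi cell area
   falls below the channel threshold (0.05 µm² for clathrin, 2.0 µm² for
   actin), and a cluster is a connected component of dense localizations
   under shared-Voronoi-edge adjacency.
3. **Polygon colocalization** — around each clathrin cluster footprint a
   local area is built by expanding the polygon symmetrically by one
   pixel (117 nm). Within it, the percentage of actin localizations
   inside the clathrin footprint (colocalized) and inside the
   joint-minus-clathrin "yellow" zone (non-colocalized, clustered actin)
   are computed, along with the localization densities of both zones.
   Per ROI this yields pooled percentages and per-cluster mean ± SD.
4. **Synthetic scenes** — a generator plants CCS disks, peripheral actin
   filaments, background, fiducials, a channel shift and a known
   colocalized actin fraction, with full ground truth, so every stage is
   verified by parameter recovery against a brute-force oracle.

Intended users: microscopists and image analysts working with two-color
SMLM point data who need cluster-level colocalization statistics rather
than pixel-overlap measures.

## Worked example

```r
library(stormcoloc)

# a synthetic study: 60 CCSs, peripheral actin, 25% of actin planted
# inside CCS disks, channel misalignment of (150, -230) nm
params <- scene_params(n_frames = 1000, planted_coloc_fraction = 0.25,
                       true_shift_nm = c(150, -230), rng_seed = 1)
scene  <- simulate_scene(params)

result <- run_pipeline(pipeline_config(), scene$clathrin, scene$actin)
print(result)
#> <coloc_result> 60 clathrin clusters in 1 ROI(s)
#>   full_field: pooled 27.68% coloc, mean 49.15 +/- 36.46% (n = 60)

oracle_coloc_fraction(scene$actin, scene$truth)
#> [1] 24.74323
```

The pooled percentage (27.7%) is the ROI-level statistic — summed
colocalized actin counts over summed local actin counts across the 60
clusters — and sits within three percentage points of the ground-truth
oracle (24.7%), which classifies true, noise-free actin positions
against the true CCS disks. The per-cluster mean ± SD (49 ± 36%) is the
other aggregation convention; it differs from the pooled value because
clusters contribute equally regardless of how much actin they attract —
clusters that attract little actin swing their percentage on a handful
of localizations. The estimated registration shift is recoverable from
`result$shift` (here (−149.97, +230.12) nm, the negated planted
misalignment).

The numbered scripts under `analysis/` run the same study as a
step-by-step narrative (simulate → register → segment → colocalize →
report), writing their tables under `results/`.

## Documentation

The methods vignette
(`vignettes/storm-colocalization-methods.Rmd`) describes the model and
its assumptions, every tunable parameter with units and rationale, what
the scene generator does and does not emulate, the numerical choices,
and known limitations.
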