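# morphodyn

Quantitative analysis of single-cell morphodynamics in early embryogenesis,
built for 4D (3D + time) labeled segmentations of *C. elegans* embryos and
for anyone who needs tested, reusable implementations of the standard
morphodynamic measurements: per-cell volume, surface area, sphericity and
centroid dynamics; cell-cell contact areas and durations; mitotic rounding
and swelling detection; daughter-volume asymmetry with a
segmentation-uncertainty band; cross-embryo contact reproducibility; and
pairwise variability metrics with lineage, generation, time and contact
analyses.  Segmentation itself (membrane watershed, nucleus detection,
image restoration) is out of scope — labeled volumes, lineage tables and
nucleus coordinates are the inputs.

Because real recordings are large and externally hosted, the package ships
a first-class synthetic-embryo generator: cells are convex regions of a
power diagram (weighted Voronoi partition) inside an ellipsoidal eggshell,
with an invariant Sulston-style lineage, per-embryo developmental-rate
factors, division-timing jitter, programmed daughter volume ratios,
programmed mitotic rounding/swelling, and stable spatial neighborhoods.
Every analysis stage is tested against this generator's ground truth and
against independent brute-force oracles.

## The measurements

* **Sphericity** — Wadell sphericity `psi = pi^(1/3) (6V)^(2/3) / A`, 1 for
  a perfect sphere.  Surface area `A` comes from a marching-tetrahedra mesh
  of the smoothed binary mask on the anisotropic voxel grid; volume `V`
  from voxel counting.
* **Mitotic rounding / swelling** — per cell type, dynamics are registered
  at the end of metaphase (t = 0, from the lineage table's anaphase
  timings) and averaged across embryos.  The rounding window is the span
  from the minimum of the all-cell average (about −7 min) to t = 0; a
  paired t-test compares per-embryo window means at the beginning (−7.5 to
  −6.5 min) and end (−1 to 0 min) of that window.
* **Contacts** — two cells touch at a frame iff a 6-connected voxel-face
  pair carries their labels; contact area is the summed physical face
  area.  Reproducibility of a contact is the fraction of embryos forming
  it among those where both cells complete their cycles; the integral area
  is the frame sum of contact areas over the cell cycle.
* **Division asymmetry** — the ratio (≥ 1) of the daughters' median
  cell-cycle volumes, called significant when `ratio − 1` exceeds an
  uncertainty band built from each daughter's one-voxel boundary layer.
* **Variability** — for two embryos' homologous cells with time-normalized
  feature dynamics `f_a(t)`, `f_b(t)` (cubic-spline resampled to 50 points
  / 25 min after size normalization):
  `v = (1/n) * sum_t |f_a(t) − f_b(t)| / (f_a(t) + f_b(t))`, in `[0, 1)`,
  0 for identical dynamics.  Volume variability uses
  `Mv = |V_A − V_B| / (V_A + V_B)` on median cycle volumes, and neighbor
  conservation compares 5%-surface-area-filtered neighbor sets between
  embryos (Jaccard overlap, maximum over the cycle).
* **Lineage annotation** — unannotated nucleus clouds are PCA-aligned,
  swept through candidate rotations, scaled per axis to each size-matched
  annotated reference, matched by the Hungarian algorithm on Euclidean
  cost, and traced backward through the lineage, restarting from an
  earlier frame when the tracing contradicts the tree.

## Worked example

```r
library(morphodyn)

cohort <- simulate_cohort(8, celegans_program(), embryo_spec(), master_seed = 1)

reg <- register_at_metaphase_end(cohort, "ABal", feature = "sphericity")
test_window_increase(reg)
#>   cell    feature n begin_mean  end_mean percent_increase     p_value
#> 1 ABal sphericity 8  0.7535049 0.8347196         10.77825 1.39404e-10
#>   significant underpowered truncated
#> 1        TRUE        FALSE     FALSE

estimate_rounding_window(lapply(c("ABal","ABar","ABpl","ABpr","MS","E"),
  function(cl) register_at_metaphase_end(cohort, cl, "sphericity")))
#> [1] -7

norm <- lapply(cohort, function(e) normalize_embryo_time(e$features, e$tree))
pv <- pairwise_variability(norm, feature = "volume")
variability_by_group(pv, cohort[[1]]$tree, grouping = "lineage")$summary[, 1:3]
#>   group   n  median
#> 1    AB 420 0.00552
#> 2     C  48 0.00565
#> ...
```

ABal's sphericity rises by ~10.8% between the start and end of the mitotic
rounding window (paired t-test across the 8 embryos), the cohort-averaged
sphericity minimum sits 7 minutes before anaphase onset — the generator's
programmed rounding onset — and per-lineage volume variability is uniform
here because the cohort was simulated with homogeneous noise.

A thin command-line front end wraps the simulate / extract / annotate
stages:

```sh
Rscript inst/cli/morphodyn.R simulate --out out/ --seed 1 --embryos 4
Rscript inst/cli/morphodyn.R extract  --labels out/ --lineage out/embryo001_lineage.json --out feats/
Rscript inst/cli/morphodyn.R annotate --target target.csv --refs refs/ --out named.csv
```

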