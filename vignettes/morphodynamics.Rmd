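---
title: "Measuring cell morphodynamics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell morphodynamics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what `morphodyn` computes and why each numerical
choice was made.  The package analyzes 4D labeled segmentations of early
*C. elegans* embryos: each voxel carries a cell label (0 = exterior), a
lineage table names the cells and provides division (anaphase-onset)
timings, and nucleus coordinate sets support identity annotation.  All
design choices described below are the package's own; where a published
convention exists we follow it, and where it does not we state the default
and make it configurable.

## Morphometry

**Volume** is voxel counting times the physical voxel volume — exact by
definition, and additive: per-frame cell volumes always sum exactly to the
embryonic-region volume.

**Surface area** has no canonical voxel definition.  Raw voxel-face
counting overestimates curved surfaces by up to 50% (a digitized ball's
staircase has ~1.5x the true area), which would push sphericity far below
its analytic value.  We therefore mesh the 0.5-isosurface of the binary
cell mask by marching tetrahedra (each grid cube split into six tetrahedra
around its main diagonal) after a single 3x3x3 box smoothing of the mask.
The smoothing moves the iso-crossing to the mid-surface; on digitized
balls of radius 10–20 voxels the estimate lands within 0.5% of `4*pi*r^2`
(the test suite asserts 3%).  Without smoothing the same mesh overestimates
a ball's area by ~27%.  For cells so small that the smoothed field never
reaches 0.5 (a few voxels), the raw mask is meshed instead so the area
stays finite.  Voxel anisotropy is handled by meshing in physical
coordinates, never by resampling.

**Sphericity** is Wadell's `pi^(1/3) (6V)^(2/3) / A`: 1 for a sphere,
`(pi/6)^(1/3) ≈ 0.806` for a cube.  Power-diagram cells in the synthetic
embryos measure ~0.8, matching the polyhedral geometry of packed cells.

**Contacts** use strict 6-connectivity: a shared voxel face normal to x
contributes `dy*dz`, and so on.  Diagonal (18/26-connectivity) adjacency is
excluded because a diagonal "contact" has no physical shared area, and the
face convention keeps the area semantics exact.  The compiled kernel is
verified against a brute-force R enumeration on random grids.

## Synthetic embryos

The generator exists to give every downstream analysis a known ground
truth; it makes no claim to biomechanical realism (no actomyosin, no
adhesion, no fluorescence or PSF model).

*Geometry.* Cells are the regions of a power diagram over per-cell seed
points inside an ellipsoidal eggshell (semi-axes 23 x 15 x 15 um by
default, rasterized at 0.5 um isotropic voxels on a 96 x 64 x 64 grid —
sizes chosen so a full 120-frame embryo renders in ~20 s and the whole
test suite stays in single-digit minutes).  Weights are solved per frame
by damped fixed-point iteration (`w <- w + lr * r^2 * log(target/actual)`,
`lr = 0.5`, warm-started from the previous frame; a cold retry at
`lr = 0.25` guards the occasional oscillation) until every cell of at
least 500 voxels is within 5% of its programmed volume.  Convex cells
packed in an ellipsoid give realistic contact graphs and stable
neighborhoods for free.

*Lineage.* A stylized early lineage with Sulston names: division times
compress the real timing order into a one-hour movie from the two-cell
stage; the germline (P) divisions carry programmed volume ratios
(P1 1.45, EMS 1.25, P2 1.55, P3 1.65), AB divisions are symmetric.
Per-embryo developmental rates are drawn from [1/1.1, 1.1] so the
fastest/slowest ratio is 1.2; division frames get Gaussian jitter
(default sd 1 frame); the karyokinesis-to-cytokinesis lag defaults to 2
frames (nuclear division precedes membrane closure).

*Mitotic programs.* Each cell's sphericity and volume follow: a slow
interphase decline (defaults 4% and 3% across the cycle — stand-ins for
gradual deformation by neighbors, and there so the pre-mitotic minimum is
a well-defined event rather than a noise-selected point), then a linear
rise over the last 7 min before anaphase with amplitudes 12% (sphericity)
and 9.6% (volume).  ABa/ABp carry a plateau variant (rise completes 4.5
min early, then relaxes 3%), and Ea/Ep are programmed non-swelling.  The
interphase base sphericity is a deterministic hash of the cell name
(0.78–0.84), because interphase cell shape is stereotyped across embryos —
making it embryo-random would wrongly inflate intra-type distances.
Measurement noise is multiplicative lognormal per frame (default sd 1%),
optionally lineage-specific, time-growing, or shared within cell groups
(to emulate contact-coupled variability).

*What passing tests do and do not show.* Feature-level cohorts are
generated from the programs directly, so parameter-recovery tests
demonstrate that the analysis pipeline is an unbiased reader of its
inputs, not that it would denoise a bad segmentation; rendered cohorts
additionally exercise the voxel pipeline but inherit the power diagram's
convex-cell geometry, which real blastomeres only approximate.
Segmentation errors, anisotropic PSF effects and tracking mistakes are
outside the generator's vocabulary.

## Normalization

Embryo size differences (up to ~1.4x in volume between wild-type embryos)
are removed by a linear factor `(mean/median-volume)^(1/3)` applied by
dimensional analysis — volumes x f^3, areas x f^2, lengths x f,
sphericity untouched.  Scaling features instead of resampling images is
exact for these quantities and avoids interpolation artifacts; image-level
scaling would only matter for features we do not compute (e.g. local
curvature).  Cell-cycle lengths are normalized by resampling each
completed cell's dynamics to 50 points spanning a nominal 25 min with a
natural cubic spline (boundary second derivatives zero — the least
assumptive choice when nothing is known beyond the cycle ends).  Cells
with incomplete cycles, or fewer than 4 frames, are excluded and logged.

## Mitotic rounding and swelling

"End of metaphase" is operationalized as the last frame at or before the
lineage table's anaphase-onset frame; division frames in the lineage input
are assumed cytokinesis-correct, so anaphase onset is `division − lag`.
Registration is pure indexing — no interpolation — and volume dynamics are
divided by their t = 0 value so swelling reads as a relative excursion.
The rounding window is defined by the minimum of the all-cell-type
averaged dynamics within [−10, 0] min (ties resolve to the earliest
offset, logged); the per-cell test averages each embryo's values inside
the begin (−7.5 to −6.5 min) and end (−1 to 0 min) windows and applies a
paired t-test across embryos.  Window means, not single frames, are used
because each window spans 2–3 frames of 30 s data and the mean halves the
frame noise; whether to pool frames or windows is the one place the
procedure is genuinely underdetermined, and window means are the
conservative reading.  A degenerate paired test (all differences zero) is
defined non-significant with p = 1.  Under flat null programs the
empirical rejection rate at p < 0.05, measured over 1000 reduced cohorts
of 8 embryos, is 0.035 — within two points of nominal; the mild
conservativeness traces to heterogeneous window coverage across embryos
and is accepted rather than corrected.

## Division asymmetry

The ratio of the daughters' median cycle volumes (median, not birth
volume, to damp mitotic excursions and boundary noise) is compared against
an uncertainty band built from the one-voxel boundary layer: with `L` a
daughter's median layer volume and `V` its median volume, the band is the
mean of the two relative layer fractions `u = (L_A/V_A + L_B/V_B)/2` (a
`sum` variant is available by argument).  The mean is the default because
the two layer fractions estimate the same boundary-displacement
uncertainty on the shared membrane and averaging, not adding, reflects
that; the published construction this mirrors does not print its exact
combination rule, so both are provided.  The band shrinks with cell size,
making small-cell ratios appropriately hard to call.

## Contacts across embryos

Reproducibility divides the embryos forming a contact by the embryos in
which both partners complete their cycles — embryos where a partner is
unobserved can neither confirm nor deny a contact.  The integral area is a
plain frame sum in um^2 (a per-minute variant exists); it deliberately
scales with frame rate, matching the convention under which the 1000 um^2
biphasic threshold is stated.  Variable contacts are attributed to
division-timing variability when, in every non-contact embryo, the two
cells simply fail to co-exist and a shift of at most 2 frames (bracketing
the 1-frame timing jitter) would make them overlap; cells that co-exist
without touching indicate a different cell arrangement instead.
False-detection candidates (integral area below a floor and single-frame
duration) are flagged and reported separately, never deleted — deleting
them would silently bias the category shares.  Neighbor conservation
filters contacts below 5% of the cell's surface area, compares neighbor
sets at 50 cycle points as `|intersection|/|union|` (a `min`-denominator
variant exists), and takes the maximum over the cycle — "the high value
across the cell cycle" read literally; both readings and the per-time mean
were considered, and the maximum is the only one that yields exactly 1 for
identical sets and 0 for always-disjoint sets.

## Variability and similarity

The pairwise variability of two equal-length positive dynamics is
`v = (1/n) sum |f_a − f_b| / (f_a + f_b)` — the only reading of the
metric's typeset form that is bounded in [0, 1), zero on identity and
symmetric.  Integral RMSD between two cells sums, over features, the RMSE
of the normalized dynamics divided by the mean of the two cells' pooled
values; the normalization makes it invariant to common rescaling, and the
score is not guaranteed metric, so the distance-matrix export counts and
reports triangle-inequality violations instead of pretending there are
none.  Distinguishability of cell types is decided by a one-sided Welch
test (intra-type distances smaller than inter-type, p < 0.05); the
published result states the outcome but not the test, and Welch on the
two distance samples is the least parametric choice that respects unequal
variances.  Lineage/generation comparisons use Welch two-sample t-tests at
p < 0.01 on groups of per-cell scores; calibration is measured on
two-embryo null cohorts (one embryo pair per cell) because with more
embryos the scores share embryos and are not independent — at 400 null
cohorts the empirical rate is 0.0125 against a nominal 0.01.  Mock contact
pairs are same-generation never-contacting pairs, count-matched and
sampled with a fixed seed.

## Lineage annotation

Targets and references are PCA-aligned (axis signs fixed deterministically
by the largest loading, frames forced right-handed — without the
handedness constraint the relative transform can be an unreachable
reflection and matching collapses); candidate rotations sweep 0–358°
around PC1 in 2° steps crossed with ±4° swings in 2° steps about PC2/PC3
(the swing magnitude is unstated in the method this follows; ±4° is the
default and a parameter), times the four right-handed sign combinations.
Cost is plain Euclidean distance — "distance" unqualified — and ties
resolve to the first combination in the documented iteration order.
Backward tracing restarts from one frame earlier whenever the propagated
names contradict the tree; the restart count is reported.

## Problem sizes

The test suite and acceptance checks run, by choice, at: 32-embryo
feature-level cohorts (~20 complete cell types) for parameter recovery;
32 rendered single-division embryos for the voxel-counted 2.9 ratio; 1000
8-embryo cohorts for paired-t calibration; 400 2-embryo cohorts for Welch
calibration; 50 annotation trials at jitter 0.05x the minimum nucleus
distance.  Every number a test asserts is computed at run time from these
cohorts; none is imported from external data.

## Known limitations

Power-diagram cells are convex, so concave cell shapes (ingressing Ea/Ep)
and thin membrane protrusions are unrepresented; contact areas between
synthetic cells are correspondingly cleaner than segmented ones.  The
generator's noise is lognormal and frame-independent, so temporally
correlated segmentation errors are untested.  Surface areas inherit a
small smoothing-dependent bias for cells under ~30 voxels.  The annotation
sweep is exhaustive rather than optimized; for clouds beyond ~150 nuclei
with the full ±4° swing it becomes the slowest step.
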