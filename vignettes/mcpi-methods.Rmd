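---
title: "Methods: a process-based coastal protection index for mangroves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a process-based coastal protection index for mangroves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpir)
```

## The model

The package quantifies the intrinsic capacity of a mangrove belt to protect
the coast behind it as the product of three saturating factors, scaled for
readability:

$$\mathrm{MCPI} = A \cdot B \cdot \mathrm{NDVI} \cdot S, \qquad S = 1000.$$

**Wave attenuation, `A`.** Field and modelling studies of flow through
mangrove stands support an exponential decay of incident wave energy with
belt width. We use $A = 1 - e^{-rW}$ with $W$ the average cross-shore
width in kilometres and $r = 0.29\ \mathrm{km^{-1}}$, a rate calibrated to
field-scale current-attenuation observations rather than small-wave flume
studies (which would suggest far narrower saturation widths; turbulent
dissipation at storm scales is strongly nonlinear, so the field-scale rate
is the conservative choice). Under this rate the half-attenuation width is
$\ln 2 / 0.29 \approx 2.4$ km and roughly three quarters of the attenuation
is reached near 4.6 km.

**Biomass barrier, `B`.** Frontal drag against wind and surge is better
captured by above-ground biomass than by height alone. Classical mangrove
allometry gives biomass $\propto (d^2 h)^{0.85}$ with breast-height
diameter $d$ roughly proportional to height $h$ for stands up to about
10 m, hence biomass $\propto h^{2.55}$. We normalize by the 10 m validity
limit and cap:

$$B = \min\{(h/10)^{2.55},\, 1\}.$$

The cap is deliberate and conservative — above 10 m the diameter-height
relation breaks down — but it means the index is flat in height beyond
10 m: degradation of very tall stands is invisible until they drop below
the cap. Tests assert this flatness literally.

**Greenness.** NDVI enters directly (clipped to $[0,1]$; negative values
arise over water-contaminated pixels and are treated as "no vegetation").
An optional min-max rescaling switch exists in `enrich_records()` but is
off by default: the factor statistics that accompany the index (mean NDVI
near 0.6 feeding mean MCPI near 80 on real-world-like inputs) are only
consistent with raw NDVI, so raw is the default.

## Transect sampling

All geometry is planar (projected metres); geographic reprojection is out
of scope. The working coastline is the *outer wrap* of the mangrove mask:
the seaward face of the most seaward mangrove pixel per column, simplified
by Douglas–Peucker with a user tolerance (default half a pixel). This
automates a step that would otherwise be manual coastline editing; it is an
approximation, and the tolerance is exposed.

Transects are anchored every `spacing` metres (default 1000) of arc length
along that polyline, pointing along the local normal, oriented landward by
probing the ocean mask on both sides of the anchor (the generator
guarantees an explicit ocean mask, so samplers never guess the seaward
direction). Tangents are estimated from a chord of half-width one mean
segment length, which keeps transects perpendicular to smooth coasts to
well under a microradian on finely sampled curves. The default transect
length is 30 km — beyond the widest belts reported anywhere — and transects
are clipped at the raster edge.

Sampling walks each transect at pixel-size steps (step midpoints,
nearest-pixel lookup under a half-open pixel convention, so boundary ties
are deterministic). `N` counts the steps landing on mangrove pixels; gaps
contribute nothing, so `C·N` is the summed length of the mangrove segments
the line crosses. Per-region aggregation is a mean of per-transect
statistics: width is the mean of `C·N`, and height/NDVI are means of
per-transect means (not pooled pixel means — the two differ whenever
transect lengths differ, and tests pin the distinction). Transects that
contain no mangrove are excluded from all three means by default, so width
reflects the effective width of the mangrove portions; an
`include_empty_transects` switch exists for sensitivity analysis because
the alternative reading of the per-region average is defensible.

## Trends and change rates

Width trends are ordinary least squares of width on *calendar year* (the
study-year layouts of interest are unevenly spaced, and a slope in metres
per year requires real time), with the classical two-sided t test on the
slope at $\alpha = 0.05$; series failing the test are flagged as having no
linear trend. No autocorrelation correction is applied. Exactly collinear
series (zero residual variance) are assigned $p = 0$ for a nonzero slope
rather than the NaN the t formula produces.

The reported *total change* is the endpoint difference of the observed
series, and the annual percent rate divides it by the initial width and the
span. This convention is the only one that reconstructs the reference
arithmetic we verify (a −63.11 m change on an initial 2122 m over 24 years
giving −0.124 %/yr, with an OLS slope of −2.34 m/yr that is deliberately
*not* the change divided by the span); the fitted-line change
(slope × span) is exposed alongside. The two-epoch dynamic-change rate
$K = (U_b - U_a)/U_a \cdot T^{-1} \cdot 100$ is kept as a separate
operation with the same initial-value base.

## Cluster exchange network analysis

To summarize how factor profiles redistribute between two epochs, the
(region, epoch) rows of normalized AMW, ACH and NDVI are clustered
*pooled across epochs* — min-max scaling is computed over the union of both
epochs so that identical physical profiles receive identical coordinates in
either epoch; per-epoch scaling would make labels incomparable across
years, which is the whole point of the exchange analysis.

The clustering is one flat level of k-medoids (PAM build + swap, via the
`cluster` package) with $k = 8$ under the *cosangle* distance
$d(x, y) = 1 - \cos\angle(x,y)$. The full hierarchical
ordered-partitioning-and-collapsing machinery that cosangle is usually
associated with adds a recursive hierarchy we do not use; one level of
eight maximally homogeneous clusters captures the functionality exercised
here. A square-root chordal variant $\sqrt{2(1-\cos)}$ is available behind
a switch, since reference implementations differ; nothing in the package
asserts one against the other.

Two properties of this metric shape both the implementation and what users
should expect:

- it is **magnitude-blind** — clusters separate profiles by *shape*
  (relative mix of width, height, greenness), not by overall level. A
  uniformly small profile points in the same direction as a uniformly
  large one. Synthetic cluster fixtures therefore plant shape-contrasting
  archetypes, and real interpretations should read cluster profiles as
  mixes, not sizes;
- the **zero vector has no direction** — a region at the pooled minimum of
  all three factors simultaneously cannot be placed and is dropped with a
  warning, as is conventional for angular metrics.

Cluster numbering is made reproducible by relabelling clusters in
decreasing order of mean normalized height, so "cluster 1" always denotes
the tallest-profile cluster. Fuzzy memberships come from a non-parametric
bootstrap: rows are resampled with replacement, the model is refitted,
replicate clusters are matched to the original ones greedily by
nearest-medoid distance (ties to the lowest index), and every original row
is assigned to its nearest matched medoid; membership is the assignment
frequency, so rows sum to one. Replicates with fewer distinct rows than
clusters are skipped. The exchange matrix is then a plain cross-tabulation
of per-region labels in epoch A (rows) against epoch B (columns); its
marginals equal the per-epoch cluster sizes by construction, and the
off-diagonal entries are the directed flows drawn as the exchange network.

## Storm-response validation

The index is validated behaviourally: storms with maximum sustained winds
*strictly* above 64 kn whose tracks intersect the coastline are buffered by
5 km; mangrove pixels inside a buffer form the impact zone, split by region
tile; the NDVI change between a before and an after snapshot (pixels
missing in either snapshot excluded pairwise) is paired with the region's
pre-storm MCPI; and the association is measured by tie-corrected Spearman
rank correlation (t approximation by default, exact permutation null
available for $n \le 10$). "One month before/after" is represented by the
two snapshots being supplied explicitly; temporal compositing of image
stacks is out of scope. ΔNDVI is computed over the buffer-mangrove
intersection, and each (storm × region) pair yields its own record, so
overlapping storms at one region give separate records.

The synthetic end-to-end experiment builds the protective hypothesis into
the generator: `damage_scene()` lowers NDVI inside impact zones by
$\mathrm{severity} \cdot (1 - \mathrm{MCPI}/\mathrm{MCPI_{max}})$ plus
noise, taking the worst single storm per pixel rather than compounding
overlapping zones (compounding saturates NDVI at its floor and destroys
the planted ordering, which is a measurement artefact rather than a
property of the hypothesis). Damage scales against the *observed* index
range because on desk-scale scenes MCPI occupies a small fraction of
$[0, S]$ and a fixed-$S$ scaling would leave the planted signal inside the
noise. The pipeline then recovers a positive, significant rank correlation
at 53 zones — the structural analogue of the real-data validation, which
requires external imagery and is explicitly not reproduced here.

## The synthetic generator: what it does and does not emulate

`generate_scene()` builds a shore-parallel mangrove band on a planar
raster: straight or sinusoidal coastline (ocean on the decreasing-y side by
convention, with an explicit ocean mask), per-region cross-shore widths
(constant, per-region, or lognormal), constant/per-region/gradient canopy
height, target NDVI realized by fixing red reflectance and solving the
NDVI definition for NIR (so the reflectance-to-NDVI code path is
exercised, not bypassed), and Bernoulli gap pixels at a configurable
fragmentation rate. Regions are rectangular alongshore tiles — the
desk-scale analogue of 1° grid cells. Recorded ground truth per region is
the discretized configured width (before fragmentation) and the realized
mean height and NDVI over the band. Multi-epoch pairs share one random
draw so that differences between epochs are exactly the planted change
(multiplicative factors plus optional dieback patches), and gap-pixel
draws are made identically at every fragmentation rate so scenes differing
only in that rate differ only in the gaps.

Noise levels are free parameters defaulting to zero: no published noise
model exists for the emulated inputs, so noisy settings are exploratory,
not calibrated claims. The generator does not emulate tides, sediment
transport, species composition, cloud artefacts, lidar footprint geometry,
or island/lagoon coastline topologies; passing tests on these scenes
demonstrate correctness of the measurement and analysis machinery, not
performance on real imagery.

## Numerical choices and problem sizes

- Pixel convention: half-open; geotransform maps pixel centres; boundary
  points belong to the upper pixel. Step midpoints make transect counts
  exact on aligned bands.
- Quartiles: linear interpolation between order statistics
  (`quantile` type 7); sample standard deviation.
- Widths are discretized to whole pixels (`round(w/C)`), so all closure
  guarantees are "within one pixel" (30 m by default).
- Degenerate inputs fail loudly: empty masks, zero-length coastlines,
  non-positive pixel sizes, fewer rows than clusters, sub-3-point trend
  series, zero feature vectors.
- Test and demo problem sizes were chosen so the full suite runs in well
  under a minute on one core: scenes of 200–1500 × 100–160 pixels at 30 m,
  4–60 regions, bootstrap sizes of 25–40, 200 null and 500 signal
  replicates for the trend calibration checks. These sizes are where the
  closure, recovery and calibration properties stabilize; enlarging them
  tightens nothing that the tests assert.

## Known limitations

- The outer-wrap coastline is an automated stand-in for expert manual
  editing; on convoluted coasts it can over- or under-sample obliquely
  crossed bands, and no de-duplication of transects crossing the same band
  twice is attempted.
- The 10 m cap hides degradation of tall stands (by design of the
  allometry's validity range).
- Min-max normalization ties CENA coordinates to the pooled extremes, so a
  single outlier region rescales everyone's coordinates.
- The attenuation and biomass constants are fixed calibrations, not fitted
  to the data at hand; they are exposed as `index_constants()` for local
  adaptation.
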