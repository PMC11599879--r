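# mcpir — a process-based Mangrove Coastal Protection Index

Mangrove belts shield coasts from waves, storm surge and erosion, but how
much protection a given stretch of forest provides depends on more than its
mapped area: the cross-shore width of the belt, the height (hence biomass)
of the canopy, and the health of the vegetation all matter. `mcpir`
implements a transect-based assessment of that intrinsic protective
capacity for anyone working with co-registered coastal rasters (a mangrove
extent mask, canopy height, and red/NIR surface reflectance): spatial
ecologists, coastal-hazard modellers, and conservation planners comparing
regions or epochs.

## The index

For each region (grid cell along the coast), shore-perpendicular transects
are cast at 1 km intervals from an outer-wrapped coastline. With pixel size
`C` (30 m by default) and `N_i` mangrove pixels on transect `i`:

- **AMW** (average cross-shore mangrove width, m): mean over
  mangrove-containing transects of `C × N_i` (gaps excluded — the sum of
  the segmented mangrove lengths along each transect);
- **ACH** (average canopy height, m): mean over mangrove-containing
  transects of the per-transect mean height (a mean of transect means);
- **NDVI**: `(ρ_NIR − ρ_red) / (ρ_NIR + ρ_red)`, averaged the same way.

These feed three factors in `[0, 1]`:

    A = 1 − exp(−0.29 · W)            W = AMW in km   (wave attenuation)
    B = (h / 10)^2.55, capped at 1    h = ACH in m    (biomass barrier)
    NDVI, clipped to [0, 1]                           (vegetation health)

    MCPI = A · B · NDVI · 1000

`A` saturates with width (half-attenuation near 2.4 km, ~75% near 4.6 km);
`B` is an allometric biomass proxy that saturates above a 10 m canopy;
the product is scaled by `S = 1000`.

Around the index, the package provides: width-trend regression with
significance tests and annual percent rates; a single-factor dynamic-change
rate between two epochs; a Cluster Exchange Network Analysis (CENA) —
one-level k-medoids (k = 8) of pooled-epoch min-max-normalized factor
profiles under a cosangle metric, bootstrap fuzzy memberships, and the
k × k cross-epoch exchange matrix; and a storm-response validation (severe
storms above 64 kn crossing the coast, 5 km track buffers, before/after
NDVI change, Spearman rank correlation against MCPI). A synthetic-scene
generator with known ground truth makes the whole pipeline testable without
any external data.

## Worked example

```r
library(mcpir)

cfg <- scene_config(nx = 200, ny = 120, pixel_size = 30,
                    band_width = c(600, 900, 1500, 2400),
                    heights    = c(4, 8, 12, 6),
                    ndvi       = c(0.55, 0.7, 0.8, 0.62),
                    region_size_px = 50)
scene   <- generate_scene(cfg, seed = 1)
records <- enrich_records(extract_regions(scene, spacing = 300))
print(records, digits = 4)
#>   region_id epoch amw_m ach_m ndvi m n      a       b   mcpi
#> 1         1  2019   600     4 0.55 5 5 0.1597 0.09666   8.49
#> 2         2  2019   900     8 0.70 5 5 0.2297 0.56608  91.03
#> 3         3  2019  1500    12 0.80 5 5 0.3527 1.00000 282.19
#> 4         4  2019  2400     6 0.62 5 5 0.5014 0.27182  84.51
```

The sampler recovers each region's configured width, height and greenness
exactly on this noiseless scene. Region 3 dominates the index: its 12 m
canopy saturates the biomass barrier (`b = 1`). Region 4 is wider (2.4 km,
so `a = 0.50`) yet scores lower than region 2 because its 6 m canopy keeps
`b` at 0.27 — the index deliberately decouples protective capacity from
area/width alone.

Width-trend arithmetic on a global-style series:

```r
fit_width_trend(data.frame(
  year  = c(1996, 2007:2010, 2015:2020),
  amw_m = c(2122, 2100, 2095, 2088, 2085, 2070, 2068, 2066, 2064, 2060, 2059)))
#> trend: slope -2.789 m/yr (p = 1.847e-09, significant), change -63.00 m over 24 yr (-0.124 %/yr)
```

`run_pipeline(default_run_config())` chains every stage (simulate →
sample → index → trend → cena → validate) on a bundled demo configuration,
writes all intermediates as plain text (ASCII grids, GeoJSON, CSV) plus a
hash manifest, and is reproducible hash-for-hash for a fixed seed. The
same stages are scriptable via `inst/cli/mcpi.R`.

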