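---
title: "Partnership scaling of biodiversity adaptation indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partnership scaling of biodiversity adaptation indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(partnerscape)
```

## The question the package answers

Protected areas (PAs) are fixed in place while species' climate niches move.
One pragmatic response is *conservation partnership*: a PA coordinates
management with neighbouring land — other PAs, or any land at all — so the
effective conservation unit grows without formally expanding the PA.
`partnerscape` quantifies what a PA stands to gain from partnering at a given
spatial scale, using five indicators computed in a circular moving window
around every focal cell:

* **A — land and freshwater area** (km²): the count of potential partner
  cells times cell area. More area, more room for species to persist and
  move.
* **L — latitudinal range** (degrees): max minus min latitude of partner
  cells, irrespective of longitude; breadth available for pole-ward range
  shifts.
* **E — elevational range** (m): max minus min cell elevation of partner
  cells; breadth for upslope shifts.
* **H — relief-weighted hydrologic area** (km²): over partner cells lying on
  the hydrologic network, the sum of each cell's elevation above the *window
  minimum* (taken over **all** partner cells, not only network cells),
  treated as a dimensionless weight on cell area. High H means a dense
  drainage network spread across large relief — valley-bottom habitat for
  aquatic and riparian species.
* **V — climate-area velocity** (1/yr), computed separately for annual mean
  temperature and annual precipitation:

  $$V = \frac{\left|\overline{\Delta T / \Delta t}\right|}{\sigma(T) + c}$$

  The numerator is the window mean of the per-cell change rate (future minus
  baseline, divided by the elapsed years), with the absolute value taken
  outside the mean so the sign of change is discarded. The denominator is
  the *population* standard deviation of the baseline climate across partner
  cells, plus a floor constant `c = 0.1` (in the variable's units) added
  unconditionally, so the single-cell limit (σ = 0) is the continuous limit
  of the same formula rather than a special case. V reads as the factor per
  year by which partnership area must grow to retain the current climate
  space: climatically heterogeneous windows absorb change locally and have
  low V. This replaces gradient-based climate-change velocity, whose
  local-slope denominator is not computable for windows far larger than a
  pixel neighbourhood.

The window radius *r* is the partnership scale — the maximum distance
between partnering locations. The standard ladder is
r = 3, 9, 27, 81, 243, 729 km, bracketing established partnerships from a
few hundred km² to over a million; `area_to_radius()` converts partnership
areas to equivalent circular radii (e.g. the 5th-percentile established
partnership, 3.3×10⁴ km², corresponds to r ≈ 102 km).

## Scenarios and null models

`run_scenario()` evaluates four partnering assumptions:

* `pa_partnership`: focal PA cells partner with PA cells within r.
* `pa_nonpa_partnership`: focal PA cells partner with *all* land within r —
  the idealized, boundary-blind scenario.
* `pixel_null`: no partnering; every cell acts alone (r = 0), so A = one
  cell area, L = E = H = 0 and V = |rate|/0.1 exactly.
* `pa_null`: partnering only inside each administratively distinct PA; each
  indicator is reduced once over the PA's full cell set and broadcast to its
  cells.

By default indicators are reported for PA focal cells (the "what does my PA
gain" framing); `focal = "all"` computes every land cell for map products.
Scenario means feed `comparison_factor()`, which prints a ratio ≥ 1 as a
factor increase and a ratio < 1 as the negative reciprocal (a decrease by x
prints −x). Because the pixel-null means of L, E and H are exactly zero,
their factors against the pixel null are undefined and `compare_scenarios()`
reports them as `NA` rather than inventing a number.

`partner_composition()` asks *who* the partners would be: per focal cell,
the percentage of window land cells that are PA, summarized separately for
PA and non-PA focal cells (mean percentage, and the share of cells whose
window is majority-PA).

`combine_potential()` max-normalizes each indicator over all computed focal
cells, inverts velocity (1 − x, after normalization, so it points the same
way as the others), and averages five layers — A, H, L, E, and the two
velocity variables merged (averaged) into one before inversion, so exactly
five indicators enter the mean. Merging is the package's documented choice
for combining the two climate variables; `velocity = "split"` averages six
layers instead. `zonal_mean()` then summarizes the [0, 1] potential surface
by biome/ecoregion-style zones, flagging empty zones instead of dropping
them.

## The moving-window engine

`build_kernel(r, cell_km)` includes an offset (i, j) when the cell-centre
distance satisfies (i² + j²)·cell² ≤ r². This rule reproduces the 29-cell
window at r = 3 km on 1 km cells; it is fixed and recorded in every run
manifest because alternative inclusion rules (cell overlap, rounded
continuous area) give different counts at larger radii. Windows are
truncated at grid edges — no padding or wraparound, matching continental
rasters bordered by ocean nodata. A window with zero qualifying cells
yields nodata, never zero, since zero is a meaningful indicator value.
`sd` is the population standard deviation (divisor n), the raster
focal-statistics convention, computed in two passes (window mean, then
squared deviations) so the optimized offset-sweep is reproducible bit for
bit against a sequential per-window evaluation — the property the test
suite asserts on randomized grids.

## What the synthetic landscapes emulate

`synthetic_landscape()` generates the full co-registered input bundle so the
pipeline is testable end to end without external rasters:

* **Terrain**: a sum of `n_hills` random Gaussian bumps (random centre,
  width 5–25% of the grid, random sign), rescaled linearly to span exactly
  `[0, relief_m]`. This gives smooth nested valleys that route plausibly
  under D8 — simpler than spectral synthesis and exactly reproducible.
* **Drainage**: D8 steepest descent with flats broken by adding
  10⁻⁶·(row·n_cols + col) before routing; upstream accumulation from high to
  low cells; network cells are those at or above an accumulation threshold
  (default `max(8, n_rows)` cells, a sparse valley network).
* **PA mosaic**: `n_pas` seeded blobs grown by random 4-neighbour frontier
  expansion to `round(pa_fraction × cells)` cells, so each PA id is one
  contiguous component. The default cover of 14% mirrors the approximate
  global terrestrial PA share.
* **Climate**: temperature = 25 °C + lapse·elevation + gradient·(lat −
  lat_origin) + i.i.d. noise, with defaults −0.0065 °C/m and −0.8 °C per
  degree latitude on a ramp starting at 45° N; precipitation = 800 mm +
  0.5 mm/m of elevation + noise. Futures add a spatially smooth delta
  surface (Gaussian-smoothed white noise standardized to
  `delta_spatial_sd`, plus the mean change; defaults +4.3 °C and −60 mm).
  Over the default 95-year interval — the midpoint of a 1950–2000 baseline
  to a 2070 future — the +4.3 °C default corresponds to a ≈0.045 °C/yr
  rate, the order of magnitude of a high-emission trajectory.
* **Partnership sizes**: log-normal areas centred near the median
  established-partnership scale (1.8×10⁵ km²) with spread reaching from
  order 10⁴ to order 10⁶ km².

These fixtures deliberately do **not** reproduce real WDPA size
distributions, real hypsometry, or the spatial covariance of climate-model
ensembles. Passing tests therefore demonstrate algorithmic correctness and
the qualitative scaling behaviour (indicators grow with partnership scale,
velocity falls when climate varies with elevation), not the magnitudes of
any real-world analysis. Generator parameters are conveniences, chosen once
for realism, not estimates of any dataset.

## Numerical choices and degenerate inputs

* Latitude is carried as a per-row vector in decimal degrees (L needs
  nothing more); grids are abstract regular lattices with a cell size in km,
  addressed row-major with cell (1, 1) at the north-west corner. Global
  means weight cells equally rather than by latitude-dependent true cell
  area.
* Δt defaults to 95 years (baseline midpoint 1975 to 2070).
* The velocity floor 0.1 is added unconditionally; reported baseline σ
  values are the raw population sds (the floor enters only the ratio).
* H's window minimum is over all partner cells, not just network cells, so
  a network cell perched above a low non-network valley still counts its
  full relief; windows with partners but no network cells give H = 0.
* Normalization requires a positive finite maximum and errors on all-zero
  layers; it is idempotent, and inversion happens after normalization so
  values stay in [0, 1] without a second pass.
* `aggregate_presence()` implements any-presence coarsening (one fine
  presence cell in the block suffices), the rule that retains protected
  areas smaller than a single coarse cell when moving from a 250 m
  rasterization to a 1 km analysis grid.
* Comparison factors require strictly positive means; the comparison table
  reports undefined entries as NA.
* `simulate_climate_space_retention()` draws the current sample first, then
  the future sample, from one seed — the documented order the closed-form
  oracle in the test suite relies on. Note that retention compares future
  draws to the *realized range* of the current sample, so it approaches 1
  for large n at moderate shifts; the informative regime is shift of a few
  baseline sds.

## On-disk formats

Rasters use a plain-text ESRI-ASCII-style dialect (`ncols`, `nrows`,
`cellsize`, `NODATA_value`, plus optional `lat_top`/`lat_step` keys carrying
the latitude ramp), written at full `%.17g` precision so fixtures round-trip
bit-exactly. Zone maps are an id raster plus a two-column label table.
`run_pipeline()` writes a deterministic product tree (indicator rasters per
scenario and radius, summary and comparison tables, the potential surface,
zonal means) plus a manifest recording every numerical convention above;
reruns with the same configuration and seed are bit-identical.

## Problem sizes used in the checks

The test suite exercises the oracle equivalences on randomized grids up to
16×16 with radii up to 4 km, the scaling behaviour on a 128×128 landscape
at radii 3–27 km, and the retention simulation at 10⁴–10⁵ draws; the
bundled acceptance script runs the full pipeline on a 96×96 landscape.
These sizes were chosen to exercise every code path at desk scale; the
implementation itself accepts arbitrary grids, with cost proportional to
(kernel cells) × (grid cells) per statistic.

## A small worked run

```{r example, eval = FALSE}
ls <- synthetic_landscape(landscape_params(n_rows = 64, n_cols = 64,
                                           n_pas = 6, seed = 42))
iset <- run_scenario(ls, "pa_nonpa_partnership", radius_km = 9)
tidy(iset)
compare_scenarios(ls, radius_km = 9)
pot <- combine_potential(iset)
glance(pot)
# autoplot(pot)   # potential surface map
```

## Known limitations

* No geodesic kernels and no reprojection: distances are lattice distances
  in km, appropriate for equal-area grids; per-row latitude is the only
  geographic coordinate.
* No vector (polygon) processing: PA input begins at the rasterized id
  stage.
* The gradient-based climate-change-velocity of small fixed windows is not
  implemented; the window-sd formulation is the package's metric.
* Real-data magnitudes (global indicator means, comparison-table factors)
  depend on the real global rasters and are out of scope for the synthetic
  fixtures.
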