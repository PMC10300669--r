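---
title: "Line-of-sight and viewshed analysis for receiver arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-of-sight and viewshed analysis for receiver arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sightline)
```

## The problem

Telemetry systems that localise animal-borne tags from signal arrival at
several stationary receivers — reverse-GPS radio arrays on land, acoustic
receiver grids under water — only work where a tag has an unobstructed
straight path, a *line of sight* (LOS), to enough receivers at once
(typically three or more for a time-of-arrival fix). Deploying such an
array without a coverage analysis risks blind spots, wasted towers and
lost data. `sightline` answers the planning questions directly from a
digital elevation model (DEM) or a bathymetric grid:

* which cells does one tower see, for a target at a given height above the
  surface (a perching owl at 5 m behaves differently from a ground-dwelling
  lapwing at 0.3 m);
* how many of a chosen set of towers see each cell (*cumulative*
  viewshed);
* which cells are seen by all towers in one set and by none in another
  (*subtractive* viewshed — the tool of choice for narrowing the search
  area of a tag that only two towers still hear);
* the same questions for submerged receivers over bathymetry, where the
  seabed is the blocking surface and some target-depth specifications are
  simply impossible.

## The LOS model

A tower at position $p_1$ with eye height $h_1$ above ground sees a target
at $p_2$ with height $h_2$ iff no terrain sample between them is strictly
above the straight segment joining

$$A = e(p_1) + h_1 \qquad\text{and}\qquad B = e(p_2) + h_2 - \frac{D^2}{2R},$$

where $e(\cdot)$ is the DEM elevation, $D$ the horizontal ground distance
and $R$ the Earth radius. The last term is the curved-Earth correction:
on a sphere, a point at ground distance $d$ from the observer drops
$d^2/(2R)$ below the observer's tangent plane (the second-order Taylor
expansion of the exact spherical drop, excellent while $d \ll R$). The
same drop is subtracted from every terrain sample at its own distance, so
the curved model simply replaces $e(d)$ by $e(d) - d^2/(2R)$ with the
tower as zero-drop origin. With `curved = FALSE` the drop is zero and the
model is a flat Earth.

The magnitude matters at telemetry ranges: at 5 km the drop is almost 2 m,
at 11 km it exceeds 9 m. The package's worked pair — a 2 m tower and a
ground-level target 11 km apart on perfectly flat terrain — is visible
under the flat model and blocked under the curved one, with the terrain
topping the sight line by about 1.4 m at mid-path.

### Sampling and tie rules

Terrain along the segment is sampled at a fixed spacing (default: half the
smaller cell dimension) with nearest-cell elevation lookup; both endpoints
are always included. Three deliberate rules:

* **Strict blocking.** A sample blocks only when it is *strictly* above
  the sight line; grazing contact does not. This keeps flat-over-flat
  sight lines at equal heights visible rather than undefined.
* **Endpoint exclusion.** Samples within half a cell of either endpoint
  never block, so a tower's or target's own cell cannot occlude itself.
* **Missing data never block.** A nodata sample in the interior is
  ignored; a nodata *endpoint* makes the whole question invalid (reported
  as `valid = FALSE`, which is different from "not visible").

Distances are horizontal ground distances, not 3-D slant distances — the
standard viewshed convention; at realistic height-to-range ratios the
difference is negligible. On geographic (lon/lat) grids distances are
spherical haversine with the configured radius, consistent with the
spherical curvature model; ellipsoidal geodesy is deliberately out of
scope.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `curved` | `FALSE` | apply the $d^2/(2R)$ drop; recommended beyond a few km |
| `earth_radius_m` | 6,371,000 m | standard mean Earth radius; configurable for sensitivity checks or to reproduce other tools' constants |
| `sample_step_m` | half the smaller cell size | terrain sampling interval along the sight line |
| `endpoint_exclusion_m` | half the smaller cell size | self-occlusion guard near both endpoints |
| `max_range_m` (per tower) | extent-limited | reception range; cells farther away are false without any LOS test |
| `target_height_m` | — | target height above the local surface; one precalculated set per height |

A finer `sample_step_m` catches narrower obstacles at proportional cost.
Half a cell is a good default for smooth terrain; the test suite runs the
engine at one tenth of a cell when it demands exact agreement with the
brute-force reference, and users worried about single-cell spikes along
grazing lines should do the same.

## Viewsheds and the precalculated cache

`compute_viewshed()` runs the LOS test from one tower to every cell center
of the grid (cells beyond the tower's range are false without testing; the
loop is vectorised in rings of constant sample distance, so results are
bit-identical to calling `line_of_sight()` per cell). Because a full-grid
viewshed is the expensive step and coverage questions are asked many times
— which subsets, which heights, which tower is down this week —
`precalculate_set()` stores one Boolean GeoTIFF per tower per target
height under a directory named like `TransAlt0.3m_Res30` (target 0.3 m
above the surface, 30 m cells), together with a JSON manifest carrying the
grid geometry, Earth model, radius and tower table. Composite analyses
then run in milliseconds from `load_set()`:

* `cumulative_viewshed()` — element-wise sum of the selected Boolean
  grids;
* `subtractive_viewshed()` — AND over the viewing towers, AND NOT OR over
  the obstructed ones.

Both are pure set algebra: reordering towers cannot change a bit, growing
an obstructed set can only shrink the mask, and the count raster equals
the selection size exactly on the intersection of the selected viewsheds.
A cell invalid in *any* participating raster is invalid in the output —
the conservative choice, which keeps islet shadows visible as black
patches in composite maps instead of silently turning them into "covered
by zero towers".

## The aquatic mode

For submerged arrays the bathymetric surface is the blocking terrain and
the water column is treated as fully transparent to the sight line
(acoustic refraction, thermoclines and multipath are out of scope). The
target depth is specified either as metres *above the seabed* (the analogue
of height above ground) or metres *below the water surface* (pelagic
species). Either rule can be impossible at a given cell — a target 5 m
above the seabed in 3 m of water, a target 2 m below the surface where the
shoal rises to 1.5 m, or any dry-land cell — and those cells are marked
*invalid*, a third state distinct from not-visible that survives export
(nodata pixels) and composition. Validity is a property of bathymetry and
depth rule alone; it never depends on where receivers sit. Boundary
equality counts as valid: a target exactly at the water surface, or
exactly on the seabed, is still a well-posed question.

`aquatic_viewshed()` refuses receivers on land or with heads above the
water surface, then delegates to the terrestrial engine with the resolved
target-elevation field — on a basin with water level 0 the aquatic result
equals a terrestrial run on the bathymetry raster away from invalid
cells, which the test suite asserts.

## Synthetic fixtures: what they emulate and what they do not

All tests and demos run on deterministic analytic surfaces from
`make_dem()` — flat planes, a Gaussian hill, a rectangular ridge, a
staircase, and an islet-dotted basin with a submerged shoal — plus
`grid_receivers()` for regular arrays (the marine demo uses the canonical
layout: 90 receivers on a 9 × 10 grid, 300 m apart, 1 m above the seabed,
500 m effective range). Because the surfaces have closed forms, expected
visibility is derivable by hand or by an independent dense-sampling
brute-force oracle, and every grid is bit-reproducible from its parameters
and seed.

These fixtures emulate the *geometry* of real sites — valley-scale relief,
occluding ridges, reception shadows behind islets — but not the *texture*
of real DEMs: no sensor noise, no voids, no land cover (trees and
buildings that block radio but not the bare-earth DEM), no datum
mismatches between chart depths and tide levels. Passing tests therefore
certify the engine's geometry and algebra, not the fidelity of any
particular DEM product; with real data the usual caveats about DEM quality
apply unchanged.

## Numerical choices and degenerate inputs

* Elevations are written as float64 GeoTIFF (bit-exact round trips);
  Boolean and count rasters as uint8/uint16 with nodata 255/65535 for
  invalid cells. The GeoTIFF codec reads either byte order; writes are
  little-endian, single-band, uncompressed.
* Cell registration is cell-center, row 1 northernmost; user-facing
  coordinates are always CRS coordinates, never indices.
* Towers are given in WGS-84 lat/lon and projected to the DEM CRS on load
  (geographic CRSs and WGS-84 UTM zones are supported).
* The sampling rule `{0, s, 2s, …} ∪ {D}` makes the sample set identical
  for every target cell at a given distance ring, which is what lets the
  vectorised engine match the per-pair routine bit-for-bit.
* A tower and target in the same cell (D = 0, or no interior samples) is
  visible by construction; a tower on a nodata cell is an error; a target
  on a nodata cell is invalid.
* Test problem sizes: oracle comparisons use 41 × 41 grids (the dense
  reference is quadratic in resolution), the marine demo 95 × 101 cells at
  30 m. These are the package's chosen demonstration scales; the engine
  itself is routinely used on 500 × 500 grids.

## Known limitations

* No atmospheric refraction, Fresnel zones or signal attenuation: LOS is
  the first-order proxy for detectability, nothing more.
* No ellipsoidal geodesy; the spherical model is consistent but a few
  per-mille off ellipsoidal distances.
* No land-cover attenuation layers and no automated placement
  optimisation — both are natural extensions on top of the precalculated
  sets.
* Precalculated sets are recomputed wholesale when a tower moves.
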