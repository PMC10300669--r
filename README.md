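# sightline

Line-of-sight and viewshed analysis for planning and diagnosing
receiver arrays — radio telemetry towers on land, acoustic receiver
grids under water.

Tracking systems that localise animal-borne tags from signal arrival at
several stationary receivers (reverse-GPS radio arrays, marine acoustic
grids) only work where the tag has a clear line of sight (LOS) to enough
receivers at once. `sightline` computes, from a digital elevation model or
bathymetric grid:

* **point-to-point LOS** with flat- or curved-Earth models and terrain
  profiles along the sight line;
* **per-tower Boolean viewsheds** for targets at any height above the
  surface, cached on disk as reusable "precalculated sets";
* **cumulative viewsheds** — how many selected towers see each cell;
* **subtractive viewsheds** — cells seen by every tower in one set and by
  none in another (the tool for narrowing the search area of a lost tag
  that only two towers still hear);
* **aquatic viewsheds** over bathymetry for submerged receivers, with
  impossible target depths flagged as invalid rather than not-visible;
* exports to **GeoTIFF** and **KMZ** ground overlays, tidy tibbles and
  ggplot2 `autoplot()` methods for every result type.

## The model

A tower at $p_1$ with eye height $h_1$ sees a target at $p_2$ with height
$h_2$ iff no terrain sample along the segment from
$A = e(p_1) + h_1$ to $B = e(p_2) + h_2 - D^2/(2R)$
is strictly above it, where $e$ is the surface elevation, $D$ the ground
distance and $R$ the Earth radius (default 6,371 km). The $d^2/(2R)$ term
is the spherical tangent-plane drop applied to every point at its own
distance from the tower; with the flat-Earth model it is zero. Terrain is
sampled at a fixed step (default half a cell) with nearest-cell lookup;
samples within half a cell of either endpoint never block. Cumulative and
subtractive maps are plain grid summation and Boolean algebra over the
per-tower rasters. See `vignette("coverage-analysis")` for the full
account, including the aquatic validity rules.

## A worked example

Four 8 m towers on a 600 m grid around a 50 m Gaussian hill, 30 m cells:

```r
library(sightline)

dem <- make_dem("gaussian_hill", nrows = 41, ncols = 41, resolution = 30,
                height = 50, sigma = 150)
towers <- grid_receivers(2, 2, 600, height_m = 8, range_m = 900,
                         origin = cell_center(dem, 11, 11)[1, ],
                         name_prefix = "T")

sets <- precalculate_set(dem, towers, target_heights = c(0.3, 5),
                         out_dir = tempdir())
set <- sets[[1]]
set
#> <precalc_set> /tmp/.../TransAlt0.3m_Res30: 4 towers, target +0.3 m, flat-Earth model

cumulative_viewshed(set, "all")
#> <count_raster> 4 towers (T001, T002, T003, T004)
#>   counts 0..3 over 41 x 41 cells, 0 invalid

subtractive_viewshed(set, viewing = c("T001", "T002"),
                     obstructed = c("T003", "T004"))
#> <mask_raster> viewing {T001, T002} \ obstructed {T003, T004}
#>   225 cells in mask, 0 invalid

r <- line_of_sight(dem, towers[1, ], cell_center(dem, 31, 31)[1, ],
                   to_height_m = 0.3)
glance(r)
#> # A tibble: 1 × 5
#>   visible valid distance_m blocking_distance_m n_samples
#>   <lgl>   <lgl>      <dbl>               <dbl>     <int>
#> 1 FALSE   TRUE        849.                 150        58
```

Reading: no cell of the hill's far side is seen by more than 3 of the 4
towers (the hill shadows each tower somewhere), 225 cells are seen by both
northern towers but by neither southern one, and the sample sight line
toward the southeast is blocked 150 m out — by the hill — on its 849 m
path. `autoplot()` on any of these objects draws the map;
`write_geotiff()` / `write_kmz()` export it.

The same engine drives submerged arrays: `aquatic_viewshed()` takes a
water level and a target rule ("metres above seabed" or "metres below
surface"), marks impossible cells invalid (e.g. a target 5 m above the
seabed in 3 m of water), and islets render as black patches through every
composite map.

## Command line

A thin CLI wraps the same functions for shell pipelines
(`inst/cli/sightline`, installed under the package's `cli/` directory):

```sh
sightline fixtures  --kind basin_with_islets --out demo --receivers 9x10 \
                    --spacing 300 --height 1 --range 500
sightline prepare   --dem demo/dem.tif --towers demo/towers.csv \
                    --heights 0.3,5 --out sets --curved
sightline cumulative sets/TransAlt0.3m_Res30 --towers all --out cum.kmz --format kmz
sightline subtract  sets/TransAlt0.3m_Res30 --viewing T2,T12 \
                    --obstructed all-except --out search.tif
sightline los       --dem demo/dem.tif --from 32.53,35.43,10 --to 32.54,35.44,0.3
```

Exit codes: 0 success, 1 runtime error, 2 usage error. Outputs are
byte-identical to the equivalent library calls.

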