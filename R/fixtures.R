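# Deterministic synthetic terrain, bathymetry, and receiver layouts.
#
# Every fixture is an analytic surface evaluated at cell centers, so
# expected LOS outcomes are derivable in closed form or by the dense
# brute-force oracle; identical spec + seed always reproduces the grid
# bit-exactly. Defaults use a projected metre-unit CRS (UTM 36N) so LOS
# tests are decoupled from geodesy; pass a geographic CRS to exercise the
# haversine paths.

#' Generate a synthetic elevation or bathymetry grid
#'
#' Kinds:
#' * `flat` — constant elevation `value`.
#' * `gaussian_hill` — Gaussian bump of height `height` (m) and standard
#'   deviation `sigma` (CRS units) centred at `center` (default: grid
#'   center), on a base plane `value`.
#' * `ridge` — rectangular ridge of height `height` and width `width`
#'   (CRS units) whose crest runs north-south at x-fraction `position`.
#' * `staircase` — `n_steps` flat steps rising west to east by
#'   `step_height` m each.
#' * `basin_with_islets` — basin floor at `depth` (negative, m) with
#'   `n_islets` flat-top cylindrical islets of height `islet_height` (m,
#'   above datum) and radius `islet_radius` (CRS units), placed by `seed`,
#'   plus one submerged Gaussian shoal.
#'
#' @param kind fixture kind, see above.
#' @param nrows,ncols grid dimensions.
#' @param resolution cell size in CRS units (metres for the default CRS).
#' @param crs raster CRS; default a metre-unit UTM zone.
#' @param origin `c(xmin, ymax)`, the northwest corner in CRS units.
#' @param seed integer seed for randomised placement (islets).
#' @param value,height,sigma,center,position,width,n_steps,step_height,depth,n_islets,islet_height,islet_radius
#'   shape parameters, see the kind list.
#' @return a [dem_grid].
#' @examples
#' make_dem("gaussian_hill", height = 50, sigma = 150)
#' @export
make_dem <- function(kind = c("flat", "gaussian_hill", "ridge", "staircase",
                              "basin_with_islets"),
                     nrows = 41, ncols = 41, resolution = 30,
                     crs = "EPSG:32636", origin = c(500000, 3600000),
                     seed = 1L, value = 0, height = 50, sigma = 150,
                     center = NULL, position = 0.5, width = 2 * resolution,
                     n_steps = 5, step_height = 10, depth = -20,
                     n_islets = 3, islet_height = 2, islet_radius = 3 * resolution) {
  kind <- match.arg(kind)
  stopifnot(nrows >= 1, ncols >= 1, resolution > 0)
  xmin <- origin[1]; ymax <- origin[2]
  cx <- xmin + (seq_len(ncols) - 0.5) * resolution
  cy <- ymax - (seq_len(nrows) - 0.5) * resolution
  X <- matrix(cx, nrows, ncols, byrow = TRUE)
  Y <- matrix(cy, nrows, ncols)

  vals <- switch(kind,
    flat = matrix(value, nrows, ncols),
    gaussian_hill = {
      ctr <- center %||% c(mean(range(cx)), mean(range(cy)))
      value + height * exp(-((X - ctr[1])^2 + (Y - ctr[2])^2) / (2 * sigma^2))
    },
    ridge = {
      xr <- xmin + position * ncols * resolution
      value + ifelse(abs(X - xr) <= width / 2, height, 0)
    },
    staircase = {
      frac <- (X - xmin) / (ncols * resolution)
      value + step_height * floor(frac * n_steps)
    },
    basin_with_islets = {
      set.seed(seed)
      v <- matrix(depth, nrows, ncols)
      ex <- xmin + ncols * resolution
      ey <- ymax - nrows * resolution
      pad <- islet_radius + resolution
      icx <- stats::runif(n_islets, xmin + pad, ex - pad)
      icy <- stats::runif(n_islets, ey + pad, ymax - pad)
      for (i in seq_len(n_islets))
        v[(X - icx[i])^2 + (Y - icy[i])^2 <= islet_radius^2] <- islet_height
      # a submerged shoal: rises to half depth, never breaks the surface
      scx <- stats::runif(1, xmin + pad, ex - pad)
      scy <- stats::runif(1, ey + pad, ymax - pad)
      shoal <- (-depth / 2) * exp(-((X - scx)^2 + (Y - scy)^2) / (2 * (3 * resolution)^2))
      ifelse(v > 0, v, pmin(v + shoal, depth / 4))
    })

  dem_grid(vals, xmin = xmin, ymax = ymax, xres = resolution,
           yres = resolution, crs = crs)
}

#' Generate a regular grid of receivers
#'
#' Places `rows x cols` identical receivers on a square grid (spacing =
#' nearest-neighbour separation), names them `R001`, `R002`, ... row by
#' row from the northwest corner, and back-projects positions to WGS-84
#' lat/lon. The marine demo layout of 90 receivers, 300 m apart, 1 m above
#' the seabed with a 500 m effective range is
#' `grid_receivers(9, 10, 300, 1, 500, origin)`.
#'
#' @param rows,cols grid dimensions (`rows * cols >= 1`).
#' @param spacing_m separation between neighbours, CRS units, `> 0`.
#' @param height_m receiver height above the local surface, metres.
#' @param range_m effective reception range, metres (`NA` = extent-limited).
#' @param origin `c(x, y)` of the northwest receiver, CRS units.
#' @param crs CRS the origin/spacing are expressed in.
#' @param name_prefix prefix for generated names.
#' @return a `tower_set` tibble with `x`, `y` columns in `crs`.
#' @export
grid_receivers <- function(rows, cols, spacing_m, height_m, range_m = NA,
                           origin = c(500000 + 135, 3600000 - 135),
                           crs = "EPSG:32636", name_prefix = "R") {
  stopifnot(rows >= 1, cols >= 1, spacing_m > 0)
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- origin[1] + (ij$col - 1) * spacing_m
  y <- origin[2] - (ij$row - 1) * spacing_m
  ll <- unproject_to_wgs84(x, y, crs)
  tb <- towers(sprintf("%s%03d", name_prefix, seq_len(rows * cols)),
               lat = ll$lat, lon = ll$lon, height_m = height_m,
               max_range_m = range_m)
  tb$x <- x
  tb$y <- y
  tb
}
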