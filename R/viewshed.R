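# Per-tower Boolean viewshed rasters and the precalculated-set cache.
#
# compute_viewshed() runs the same sampling rule as line_of_sight() for
# every cell center of the grid, vectorised over chunks of cells: for
# sample index j the whole chunk advances one step along its sight lines at
# once, and cells already blocked drop out. The result is bit-identical to
# looping line_of_sight() cell by cell (asserted in the test suite).

#' Compute a per-tower Boolean viewshed
#'
#' For each valid in-range cell, tests the line of sight from the tower head
#' to the cell center at its target elevation (terrestrial default: ground
#' plus `target_height_m`). Cells beyond `max_range_m` are false; cells
#' where the LOS question is undefined (missing data, aquatic invalidity)
#' are false *and* marked invalid.
#'
#' @param dem a [dem_grid] (terrain, or bathymetry in the aquatic mode).
#' @param tower a one-row tower table (see [towers()]); its `height_m` is
#'   the eye height above the local surface and its `max_range_m` the range
#'   mask (`NA` = extent-limited).
#' @param target_height_m target height above the local surface, metres.
#' @param cfg a [sight_config].
#' @param target_elevation optional matrix of absolute target elevations
#'   (supplied by [aquatic_viewshed()]); default ground + `target_height_m`.
#' @param validity optional logical matrix; `FALSE` cells are invalid.
#' @param chunk_size cells processed per vectorised batch.
#' @return a `viewshed_raster`: list with logical matrices `visible` and
#'   `valid` plus tower/grid metadata.
#' @examples
#' dem <- make_dem("flat", nrows = 21, ncols = 21, resolution = 30)
#' tw <- grid_receivers(1, 1, 300, height_m = 10, range_m = 250,
#'                      origin = cell_center(dem, 11, 11)[1, ])
#' vs <- compute_viewshed(dem, tw, target_height_m = 0.3)
#' sum(vs$visible)
#' @export
compute_viewshed <- function(dem, tower, target_height_m = 0,
                             cfg = sight_config(), target_elevation = NULL,
                             validity = NULL, chunk_size = 4096L) {
  stopifnot(target_height_m >= 0)
  tw <- .resolve_point(tower, dem)
  .check_inside(dem, tw$xy, "tower")
  rc <- .resolve_cfg(cfg, dem)
  ground1 <- .elev_at(dem, tw$xy[1], tw$xy[2])
  if (is.na(ground1)) stop("tower '", tw$name %||% "?", "' sits on a missing-data cell")
  A <- ground1 + tw$height

  nr <- nrow(dem$values); nc <- ncol(dem$values)
  valid <- !dem$nodata_mask
  if (!is.null(validity)) {
    stopifnot(identical(dim(validity), dim(dem$values)))
    valid <- valid & validity
  }
  tgt <- if (is.null(target_elevation)) dem$values + target_height_m else {
    stopifnot(identical(dim(target_elevation), dim(dem$values)))
    target_elevation
  }

  # cell-center coordinates and ground distance to the tower, all cells
  cx <- dem$xmin + (rep(seq_len(nc), each = nr) - 0.5) * dem$xres
  cy <- dem$ymax - (rep(seq_len(nr), times = nc) - 0.5) * dem$yres
  D <- .dist_xy(dem$crs, tw$xy[1], tw$xy[2], cx, cy, rc$R)

  inrange <- if (is.na(tw$range)) rep(TRUE, nr * nc) else D <= tw$range
  cand <- which(as.vector(valid) & inrange)

  visible <- matrix(FALSE, nr, nc)
  if (length(cand) > 0L) {
    for (lo in seq(1L, length(cand), by = chunk_size)) {
      idx <- cand[lo:min(lo + chunk_size - 1L, length(cand))]
      visible[idx] <- .chunk_visible(dem, idx, cx[idx], cy[idx], D[idx],
                                     A, tw$xy, as.vector(tgt)[idx], rc)
    }
  }

  structure(list(visible = visible, valid = valid,
                 tower_name = tw$name %||% "tower",
                 target_height_m = target_height_m,
                 curved = rc$curved, earth_radius_m = rc$R,
                 max_range_m = tw$range,
                 xmin = dem$xmin, ymax = dem$ymax, xres = dem$xres,
                 yres = dem$yres, crs = dem$crs),
            class = "viewshed_raster")
}

# vectorised LOS over one chunk of target cells; mirrors los_core() exactly.
# Sample j sits at distance j*step from the tower for *every* cell, so the
# whole chunk advances one ring at a time.
.chunk_visible <- function(dem, idx, x2, y2, D, A, p1, tgt, rc) {
  m <- length(idx)
  drop_D <- if (rc$curved) D^2 / (2 * rc$R) else 0
  B <- tgt - drop_D
  k <- floor(D / rc$step)               # samples beyond k*step are endpoints
  blocked <- rep(FALSE, m)
  alive <- which(k >= 1L & D > 0)
  max_j <- if (length(alive)) max(k[alive]) else 0L
  nrr <- nrow(dem$values)
  j <- 1L
  while (j <= max_j && length(alive) > 0L) {
    d <- j * rc$step
    a <- alive[j <= k[alive]]
    if (length(a) > 0L) {
      interior <- d >= rc$excl & (D[a] - d) >= rc$excl
      if (any(interior)) {
        a2 <- a[interior]
        t <- d / D[a2]
        sx <- p1[1] + t * (x2[a2] - p1[1])
        sy <- p1[2] + t * (y2[a2] - p1[2])
        col <- pmin(ncol(dem$values), pmax(1L, floor((sx - dem$xmin) / dem$xres) + 1L))
        row <- pmin(nrr, pmax(1L, floor((dem$ymax - sy) / dem$yres) + 1L))
        terr <- dem$values[as.integer(row) + (as.integer(col) - 1L) * nrr]
        tc <- terr - (if (rc$curved) d^2 / (2 * rc$R) else 0)
        sl <- A + (B[a2] - A) * t
        hit <- !is.na(tc) & tc > sl
        if (any(hit)) {
          blocked[a2[hit]] <- TRUE
          alive <- setdiff(alive, a2[hit])
        }
      }
    }
    j <- j + 1L
  }
  !blocked
}

#' @export
print.viewshed_raster <- function(x, ...) {
  cat(sprintf("<viewshed_raster> tower '%s', target %+g m, %s model\n",
              x$tower_name, x$target_height_m,
              if (x$curved) "curved-Earth" else "flat-Earth"))
  cat(sprintf("  %d x %d cells: %d visible, %d invalid\n",
              nrow(x$visible), ncol(x$visible), sum(x$visible), sum(!x$valid)))
  invisible(x)
}

# ---- precalculated sets -----------------------------------------------------

.set_dirname <- function(target_height_m, xres) {
  sprintf("TransAlt%sm_Res%s",
          format(target_height_m, scientific = FALSE, trim = TRUE),
          format(round(xres), scientific = FALSE, trim = TRUE))
}

.grid_geom <- function(x) {
  list(xmin = x$xmin, ymax = x$ymax, xres = x$xres, yres = x$yres,
       crs = x$crs, nrows = nrow(x$visible %||% x$values),
       ncols = ncol(x$visible %||% x$values))
}

#' Precalculate viewshed sets for several target heights
#'
#' Runs [compute_viewshed()] for every tower and every target height and
#' stores the results on disk, one directory per target height, named
#' `TransAlt{h}m_Res{r}` (h = target height in metres, r = rounded cell
#' size). Each directory holds one uint8 GeoTIFF per tower (1 = visible,
#' 0 = not visible, nodata 255 = invalid) and a `manifest.json` recording
#' grid geometry, Earth model, and the tower table. Re-running with
#' identical inputs reproduces bit-identical rasters.
#'
#' @param dem a [dem_grid].
#' @param tw a `tower_set` (all towers must fall inside the DEM extent).
#' @param target_heights numeric vector of target heights above the
#'   surface, metres.
#' @param cfg a [sight_config].
#' @param out_dir parent directory for the set directories.
#' @param overwrite replace an existing set directory; without it an
#'   existing manifest is an error.
#' @param aquatic optional [aquatic_config()]; switches target elevations
#'   and validity to the aquatic rules, with `target_heights` interpreted
#'   as offsets in the configured height mode.
#' @param progress log per-tower progress via `message()`.
#' @return invisibly, a list of `precalc_set` objects (one per height).
#' @export
precalculate_set <- function(dem, tw, target_heights, cfg = sight_config(),
                             out_dir = ".", overwrite = FALSE, aquatic = NULL,
                             progress = FALSE) {
  stopifnot(length(target_heights) >= 1L)
  if (!all(c("x", "y") %in% names(tw))) tw <- attach_towers(tw, dem)
  sets <- vector("list", length(target_heights))
  for (k in seq_along(target_heights)) {
    h <- target_heights[k]
    set_dir <- file.path(out_dir, .set_dirname(h, dem$xres))
    manifest_path <- file.path(set_dir, "manifest.json")
    if (file.exists(manifest_path) && !overwrite)
      stop("precalculated set already exists (pass overwrite = TRUE to replace): ",
           set_dir)
    dir.create(set_dir, recursive = TRUE, showWarnings = FALSE)

    field <- NULL; validity <- NULL
    if (!is.null(aquatic)) {
      aq <- aquatic_config(aquatic$water_level_m, aquatic$mode, offset_m = h)
      tf <- target_elevation_field(dem, aq)
      field <- tf$elevation; validity <- tf$valid
    }

    for (i in seq_len(nrow(tw))) {
      if (progress)
        message(sprintf("[%s] tower %s (%d/%d)", .set_dirname(h, dem$xres),
                        tw$name[i], i, nrow(tw)))
      vs <- compute_viewshed(dem, tw[i, ], target_height_m = h, cfg = cfg,
                             target_elevation = field, validity = validity)
      write_geotiff(vs, file.path(set_dir, paste0(tw$name[i], ".tif")))
    }

    rc <- .resolve_cfg(cfg, dem)
    manifest <- list(
      crs = dem$crs,
      transform = list(xmin = dem$xmin, ymax = dem$ymax,
                       xres = dem$xres, yres = dem$yres),
      nrows = nrow(dem$values), ncols = ncol(dem$values),
      target_height_m = h, curved = rc$curved, earth_radius_m = rc$R,
      sample_step_m = rc$step, endpoint_exclusion_m = rc$excl,
      towers = lapply(seq_len(nrow(tw)), function(i)
        list(name = tw$name[i], lat = tw$lat[i], lon = tw$lon[i],
             height_m = tw$height_m[i],
             max_range_m = if (is.na(tw$max_range_m[i])) NULL else tw$max_range_m[i])))
    if (!is.null(aquatic))
      manifest$aquatic <- list(water_level_m = aquatic$water_level_m,
                               mode = aquatic$mode, offset_m = h)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    sets[[k]] <- load_set(set_dir)
  }
  invisible(sets)
}

#' Load a precalculated viewshed set
#'
#' @param dir a set directory written by [precalculate_set()].
#' @return a `precalc_set`: list with `dir`, the parsed `manifest`, and
#'   `rasters` (named list of `viewshed_raster`, in manifest order).
#' @export
load_set <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  rasters <- list()
  for (twm in man$towers) {
    f <- file.path(dir, paste0(twm$name, ".tif"))
    if (!file.exists(f))
      stop("raster for tower '", twm$name, "' listed in manifest but missing: ", f)
    g <- geotiff_read_raw(f)
    geom_ok <- isTRUE(all.equal(g$xmin, man$transform$xmin)) &&
      isTRUE(all.equal(g$ymax, man$transform$ymax)) &&
      isTRUE(all.equal(g$xres, man$transform$xres)) &&
      isTRUE(all.equal(g$yres, man$transform$yres)) &&
      nrow(g$values) == man$nrows && ncol(g$values) == man$ncols &&
      identical(g$crs, man$crs)
    if (!geom_ok)
      stop("geometry mismatch between manifest and raster for tower '",
           twm$name, "' in ", dir)
    inv <- !is.na(g$values) & g$values == (g$nodata %||% 255)
    rasters[[twm$name]] <- structure(list(
      visible = !inv & !is.na(g$values) & g$values == 1,
      valid = !inv & !is.na(g$values),
      tower_name = twm$name, target_height_m = man$target_height_m,
      curved = isTRUE(man$curved), earth_radius_m = man$earth_radius_m,
      max_range_m = twm$max_range_m %||% NA_real_,
      xmin = g$xmin, ymax = g$ymax, xres = g$xres, yres = g$yres,
      crs = g$crs), class = "viewshed_raster")
  }
  structure(list(dir = dir, manifest = man, rasters = rasters),
            class = "precalc_set")
}

#' @export
print.precalc_set <- function(x, ...) {
  cat(sprintf("<precalc_set> %s: %d towers, target %+g m, %s model\n",
              x$dir, length(x$rasters), x$manifest$target_height_m,
              if (isTRUE(x$manifest$curved)) "curved-Earth" else "flat-Earth"))
  invisible(x)
}
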