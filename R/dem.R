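# Georeferenced elevation grids (terrain or bathymetry).

#' Construct an elevation grid
#'
#' A `dem_grid` is a matrix of elevations in metres (row 1 is the
#' northernmost row, column 1 the westernmost) with an affine cell-center
#' georeference and a missing-data mask. Bathymetry is carried the same
#' way, with negative elevations below the vertical datum.
#'
#' @param values numeric matrix of elevations (metres); `NA` marks missing.
#' @param xmin,ymax coordinates of the grid's northwest *corner* in CRS units.
#' @param xres,yres cell size in CRS units, strictly positive.
#' @param crs CRS identifier, e.g. `"EPSG:32636"` or `"EPSG:4326"`.
#' @param nodata_mask optional logical matrix, `TRUE` where elevation is
#'   missing; defaults to `is.na(values)`.
#' @return an object of class `dem_grid`.
#' @export
dem_grid <- function(values, xmin, ymax, xres, yres, crs, nodata_mask = NULL) {
  stopifnot(is.matrix(values), xres > 0, yres > 0)
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  stopifnot(identical(dim(values), dim(nodata_mask)))
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, xmin = xmin, ymax = ymax, xres = xres, yres = yres,
         crs = crs, nodata_mask = nodata_mask),
    class = "dem_grid")
}

#' @export
dim.dem_grid <- function(x) dim(x$values)

#' Extent of a grid in CRS units
#' @param dem a [dem_grid].
#' @return named list `xmin, ymin, xmax, ymax`.
#' @export
dem_extent <- function(dem) {
  list(xmin = dem$xmin,
       ymin = dem$ymax - nrow(dem$values) * dem$yres,
       xmax = dem$xmin + ncol(dem$values) * dem$xres,
       ymax = dem$ymax)
}

#' @export
print.dem_grid <- function(x, ...) {
  e <- dem_extent(x)
  cat(sprintf("<dem_grid> %d x %d cells, %s, res %g x %g\n",
              nrow(x$values), ncol(x$values), x$crs, x$xres, x$yres))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n", e$xmin, e$xmax, e$ymin, e$ymax))
  cat(sprintf("  elevation: [%g, %g] m, %d missing cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(x$nodata_mask)))
  invisible(x)
}

.min_cell <- function(dem) min(dem$xres, dem$yres)

#' Convert CRS coordinates to cell indices and back
#'
#' `coord_to_cell()` maps coordinates to the indices of the cell containing
#' them; `cell_center()` returns the center coordinates of given cells. The
#' two are mutually inverse up to cell quantization.
#'
#' @param dem a [dem_grid].
#' @param x,y coordinate vectors in the grid's CRS.
#' @param row,col 1-based cell indices (row 1 = northernmost).
#' @return `coord_to_cell()`: integer matrix with columns `row`, `col`;
#'   `cell_center()`: numeric matrix with columns `x`, `y`.
#' @export
coord_to_cell <- function(dem, x, y) {
  e <- dem_extent(dem)
  eps <- 1e-9 * max(dem$xres, dem$yres)
  bad <- x < e$xmin - eps | x > e$xmax + eps | y < e$ymin - eps | y > e$ymax + eps
  if (any(bad))
    stop(sprintf("coordinate (%g, %g) outside the raster extent", x[bad][1], y[bad][1]))
  col <- pmin(ncol(dem$values), pmax(1L, floor((x - dem$xmin) / dem$xres) + 1L))
  row <- pmin(nrow(dem$values), pmax(1L, floor((dem$ymax - y) / dem$yres) + 1L))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname coord_to_cell
#' @export
cell_center <- function(dem, row, col) {
  if (any(row < 1L | row > nrow(dem$values) | col < 1L | col > ncol(dem$values)))
    stop("cell index out of range")
  cbind(x = dem$xmin + (col - 0.5) * dem$xres,
        y = dem$ymax - (row - 0.5) * dem$yres)
}

# nearest-cell elevation lookup; NA outside mask handling left to callers
.elev_at <- function(dem, x, y) {
  rc <- coord_to_cell(dem, x, y)
  dem$values[rc]
}

#' Read a single-band GeoTIFF elevation raster
#'
#' @param path path to a single-band GeoTIFF with a CRS and affine
#'   transform. The declared nodata value (GDAL_NODATA tag) is mapped into
#'   the grid's missing-data mask.
#' @param extent optional named list/vector `xmin, ymin, xmax, ymax`; the
#'   raster is cropped to the cells whose centers fall inside it.
#' @return a [dem_grid].
#' @export
read_dem <- function(path, extent = NULL) {
  g <- geotiff_read_raw(path)
  mask <- if (!is.null(g$nodata)) {
    if (is.nan(g$nodata)) is.nan(g$values) else
      !is.na(g$values) & abs(g$values - g$nodata) < 1e-9 * max(1, abs(g$nodata))
  } else {
    matrix(FALSE, nrow(g$values), ncol(g$values))
  }
  mask <- mask | is.na(g$values)
  dem <- dem_grid(g$values, g$xmin, g$ymax, g$xres, g$yres, g$crs, nodata_mask = mask)
  if (!is.null(extent)) dem <- crop_dem(dem, extent)
  dem
}

#' Crop a grid to an extent
#' @param dem a [dem_grid].
#' @param extent named list/vector `xmin, ymin, xmax, ymax` in the grid CRS.
#' @return the cropped [dem_grid].
#' @export
crop_dem <- function(dem, extent) {
  extent <- as.list(extent)
  stopifnot(extent$xmin < extent$xmax, extent$ymin < extent$ymax)
  nc <- ncol(dem$values); nr <- nrow(dem$values)
  cx <- dem$xmin + (seq_len(nc) - 0.5) * dem$xres
  cy <- dem$ymax - (seq_len(nr) - 0.5) * dem$yres
  keep_c <- which(cx >= extent$xmin & cx <= extent$xmax)
  keep_r <- which(cy >= extent$ymin & cy <= extent$ymax)
  if (length(keep_c) == 0L || length(keep_r) == 0L)
    stop("crop extent does not intersect the raster")
  dem_grid(dem$values[keep_r, keep_c, drop = FALSE],
           xmin = dem$xmin + (min(keep_c) - 1L) * dem$xres,
           ymax = dem$ymax - (min(keep_r) - 1L) * dem$yres,
           xres = dem$xres, yres = dem$yres, crs = dem$crs,
           nodata_mask = dem$nodata_mask[keep_r, keep_c, drop = FALSE])
}
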