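# Raster exports: GeoTIFF and KMZ ground overlays.

#' Write a raster to GeoTIFF
#'
#' Georeferencing is identical to the source grid. Encodings: elevation
#' grids as float32 (nodata -9999); Boolean viewsheds and subtractive masks
#' as uint8 (1 visible / in mask, 0 not, nodata 255 invalid); count rasters
#' as uint16 (nodata 65535 invalid). Exports round-trip losslessly through
#' [read_dem()] / [load_set()].
#'
#' @param x a [dem_grid], `viewshed_raster`, `count_raster` or `mask_raster`.
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(x, path, ...) UseMethod("write_geotiff")

#' @rdname write_geotiff
#' @export
write_geotiff.dem_grid <- function(x, path, dtype = "float64", ...) {
  geotiff_write_raw(path, x$values, x$xmin, x$ymax, x$xres, x$yres, x$crs,
                    dtype = dtype,
                    nodata = if (any(x$nodata_mask)) -9999 else NULL)
  invisible(path)
}

#' @rdname write_geotiff
#' @export
write_geotiff.viewshed_raster <- function(x, path, ...) {
  v <- matrix(0, nrow(x$visible), ncol(x$visible))
  v[x$visible] <- 1
  v[!x$valid] <- 255
  geotiff_write_raw(path, v, x$xmin, x$ymax, x$xres, x$yres, x$crs,
                    dtype = "uint8", nodata = 255)
  invisible(path)
}

#' @rdname write_geotiff
#' @export
write_geotiff.count_raster <- function(x, path, ...) {
  v <- x$counts
  v[!x$valid] <- 65535
  geotiff_write_raw(path, v, x$xmin, x$ymax, x$xres, x$yres, x$crs,
                    dtype = "uint16", nodata = 65535)
  invisible(path)
}

#' @rdname write_geotiff
#' @export
write_geotiff.mask_raster <- function(x, path, ...) {
  v <- matrix(0, nrow(x$mask), ncol(x$mask))
  v[x$mask] <- 1
  v[!x$valid] <- 255
  geotiff_write_raw(path, v, x$xmin, x$ymax, x$xres, x$yres, x$crs,
                    dtype = "uint8", nodata = 255)
  invisible(path)
}

# ---- palettes ---------------------------------------------------------------

#' Colour palette for raster overlays
#'
#' @param colors character vector of R colours forming a ramp from the
#'   lowest to the highest value (counts: darker = seen by more towers).
#' @param invalid_color colour for invalid cells (opaque black by default,
#'   so islet shadows render as black patches).
#' @param transparent_zero render zero / false cells fully transparent.
#' @return an object of class `sl_palette`.
#' @export
overlay_palette <- function(colors = c("#deebf7", "#08306b"),
                            invalid_color = "#000000",
                            transparent_zero = TRUE) {
  structure(list(colors = colors, invalid_color = invalid_color,
                 transparent_zero = isTRUE(transparent_zero)),
            class = "sl_palette")
}

# render a raster object to an nrows x ncols x 4 RGBA array in [0,1]
.render_rgba <- function(x, palette) {
  if (inherits(x, "count_raster")) {
    vals <- x$counts; vmax <- max(1L, x$n_selected)
  } else if (inherits(x, "mask_raster")) {
    vals <- x$mask + 0L; vmax <- 1L
  } else if (inherits(x, "viewshed_raster")) {
    vals <- x$visible + 0L; vmax <- 1L
  } else if (inherits(x, "dem_grid")) {
    rng <- range(x$values, na.rm = TRUE)
    vals <- (x$values - rng[1]) / max(rng[2] - rng[1], 1e-12); vmax <- 1
  } else stop("cannot render object of class ", class(x)[1])
  valid <- if (!is.null(x$valid)) x$valid else !is.na(vals)
  if (all(!valid)) stop("empty raster: no valid cells to render")

  ramp <- grDevices::colorRamp(palette$colors)
  frac <- pmin(1, pmax(0, vals / vmax))
  frac[!valid | is.na(frac)] <- 0
  rgb <- ramp(as.vector(frac)) / 255
  nr <- nrow(vals); nc <- ncol(vals)
  out <- array(0, dim = c(nr, nc, 4))
  out[, , 1] <- matrix(rgb[, 1], nr, nc)
  out[, , 2] <- matrix(rgb[, 2], nr, nc)
  out[, , 3] <- matrix(rgb[, 3], nr, nc)
  alpha <- matrix(1, nr, nc)
  if (palette$transparent_zero) alpha[vals == 0] <- 0
  inv_rgb <- grDevices::col2rgb(palette$invalid_color) / 255
  for (k in 1:3) { ch <- out[, , k]; ch[!valid] <- inv_rgb[k]; out[, , k] <- ch }
  alpha[!valid] <- 1
  out[, , 4] <- alpha
  out
}

# ---- KMZ --------------------------------------------------------------------

.crc32_tab <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(bitwShiftR(c, 1L), -306674912L)
           else bitwShiftR(c, 1L)
    tab[i + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    c <- bitwXor(bitwShiftR(c, 8L), .crc32_tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  bitwXor(c, -1L)
}

# store-only ZIP archive (no external zip binary required)
.zip_store <- function(path, entries) {
  locals <- raw(0); central <- raw(0); offset <- 0L
  for (nm in names(entries)) {
    data <- entries[[nm]]
    crc <- .crc32(data)
    name_raw <- charToRaw(nm)
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .pack_u16(20L), .pack_u16(0L),
             .pack_u16(0L), .pack_u16(0L), .pack_u16(0x21L),
             .pack(crc, 4L), .pack_u32(length(data)), .pack_u32(length(data)),
             .pack_u16(length(name_raw)), .pack_u16(0L), name_raw)
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)), .pack_u16(20L), .pack_u16(20L),
                 .pack_u16(0L), .pack_u16(0L), .pack_u16(0L), .pack_u16(0x21L),
                 .pack(crc, 4L), .pack_u32(length(data)), .pack_u32(length(data)),
                 .pack_u16(length(name_raw)), .pack_u16(0L), .pack_u16(0L),
                 .pack_u16(0L), .pack_u16(0L), .pack_u32(0L), .pack_u32(offset),
                 name_raw)
    locals <- c(locals, hdr, data)
    offset <- offset + length(hdr) + length(data)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .pack_u16(0L), .pack_u16(0L),
            .pack_u16(length(entries)), .pack_u16(length(entries)),
            .pack_u32(length(central)), .pack_u32(length(locals)),
            .pack_u16(0L))
  writeBin(c(locals, central, eocd), path)
  invisible(path)
}

.wgs84_bounds <- function(x) {
  e <- list(xmin = x$xmin, ymax = x$ymax,
            xmax = x$xmin + ncol(x$visible %||% x$counts %||% x$mask %||% x$values) * x$xres,
            ymin = x$ymax - nrow(x$visible %||% x$counts %||% x$mask %||% x$values) * x$yres)
  cx <- c(e$xmin, e$xmin, e$xmax, e$xmax)
  cy <- c(e$ymin, e$ymax, e$ymin, e$ymax)
  ll <- unproject_to_wgs84(cx, cy, x$crs)
  list(north = max(ll$lat), south = min(ll$lat),
       east = max(ll$lon), west = min(ll$lon))
}

#' Write a raster as a KMZ ground overlay
#'
#' Produces a ZIP archive containing `doc.kml` (a KML 2.2 GroundOverlay
#' whose lat/lon box is the raster's WGS-84 bounds) and `overlay.png`
#' rendered at the raster's own resolution.
#'
#' @param x a `viewshed_raster`, `count_raster`, `mask_raster` or
#'   [dem_grid].
#' @param path output `.kmz` path.
#' @param palette an [overlay_palette()].
#' @param name overlay name shown in the KML document.
#' @return `path`, invisibly.
#' @export
write_kmz <- function(x, path, palette = overlay_palette(), name = "coverage") {
  rgba <- .render_rgba(x, palette)
  png_bytes <- png::writePNG(rgba)
  b <- .wgs84_bounds(x)
  kml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<kml xmlns="http://www.opengis.net/kml/2.2">\n',
    '  <GroundOverlay>\n',
    '    <name>', name, '</name>\n',
    '    <Icon><href>overlay.png</href></Icon>\n',
    '    <LatLonBox>\n',
    sprintf('      <north>%.9f</north>\n', b$north),
    sprintf('      <south>%.9f</south>\n', b$south),
    sprintf('      <east>%.9f</east>\n', b$east),
    sprintf('      <west>%.9f</west>\n', b$west),
    '    </LatLonBox>\n',
    '  </GroundOverlay>\n',
    '</kml>\n')
  .zip_store(path, list(doc.kml = charToRaw(kml), overlay.png = png_bytes))
  invisible(path)
}
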