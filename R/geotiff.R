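# Minimal single-band GeoTIFF codec.
#
# No package in this stack reads or writes georeferenced TIFF, so the codec
# is implemented here directly: uncompressed strips, little- or big-endian
# read, little-endian write, baseline tags plus ModelPixelScale (33550),
# ModelTiepoint (33922), GeoKeyDirectory (34735) and GDAL_NODATA (42113).
# Cell registration is pixel-is-area with the tiepoint at the raster's
# northwest corner, i.e. the cell (1,1) *center* sits half a cell inside.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

.pack <- function(x, size, endian = "little") {
  writeBin(x, raw(), size = size, endian = endian)
}

.pack_u16 <- function(x) .pack(as.integer(ifelse(x > 32767L, x - 65536L, x)), 2L)
.pack_u32 <- function(x) .pack(as.integer(ifelse(x > 2147483647, x - 4294967296, x)), 4L)

# ---- writer -----------------------------------------------------------------

#' @keywords internal
geotiff_write_raw <- function(path, values, xmin, ymax, xres, yres, crs,
                              dtype = c("float32", "int16", "uint8", "uint16", "float64"),
                              nodata = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(is.matrix(values))
  nr <- nrow(values); nc <- ncol(values)
  vec <- as.vector(t(values))          # TIFF strips are row-major, row 1 = north
  if (anyNA(vec)) {
    if (is.null(nodata)) stop("raster contains missing cells but no nodata value was given")
    vec[is.na(vec)] <- nodata
  }

  spec <- switch(dtype,
    float32 = list(bits = 32L, fmt = 3L),
    float64 = list(bits = 64L, fmt = 3L),
    int16   = list(bits = 16L, fmt = 2L),
    uint16  = list(bits = 16L, fmt = 1L),
    uint8   = list(bits = 8L,  fmt = 1L))

  pix <- switch(dtype,
    float32 = .pack(as.numeric(vec), 4L),
    float64 = .pack(as.numeric(vec), 8L),
    int16   = .pack(as.integer(vec), 2L),
    uint16  = .pack_u16(round(vec)),
    uint8   = as.raw(round(vec)))

  epsg <- crs_epsg(crs)
  geokeys <- if (crs_is_geographic(crs)) {
    c(1L, 1L, 0L, 3L,
      1024L, 0L, 1L, 2L,        # model type: geographic
      1025L, 0L, 1L, 1L,        # raster type: pixel is area
      2048L, 0L, 1L, epsg)
  } else {
    c(1L, 1L, 0L, 4L,
      1024L, 0L, 1L, 1L,        # model type: projected
      1025L, 0L, 1L, 1L,
      3072L, 0L, 1L, epsg,
      3076L, 0L, 1L, 9001L)     # linear units: metre
  }

  nodata_ascii <- if (!is.null(nodata)) {
    c(charToRaw(format(nodata, scientific = FALSE, trim = TRUE)), as.raw(0L))
  }

  # entries: tag, type, count, value (inline) or payload (out-of-line)
  ent <- list(
    list(tag = 256L,   type = 4L, count = 1L, value = nc),
    list(tag = 257L,   type = 4L, count = 1L, value = nr),
    list(tag = 258L,   type = 3L, count = 1L, value = spec$bits),
    list(tag = 259L,   type = 3L, count = 1L, value = 1L),
    list(tag = 262L,   type = 3L, count = 1L, value = 1L),
    list(tag = 273L,   type = 4L, count = 1L, value = NA),   # strip offset, patched below
    list(tag = 277L,   type = 3L, count = 1L, value = 1L),
    list(tag = 278L,   type = 4L, count = 1L, value = nr),
    list(tag = 279L,   type = 4L, count = 1L, value = length(pix)),
    list(tag = 284L,   type = 3L, count = 1L, value = 1L),
    list(tag = 339L,   type = 3L, count = 1L, value = spec$fmt),
    list(tag = 33550L, type = 12L, count = 3L, payload = .pack(c(xres, yres, 0), 8L)),
    list(tag = 33922L, type = 12L, count = 6L, payload = .pack(c(0, 0, 0, xmin, ymax, 0), 8L)),
    list(tag = 34735L, type = 3L, count = length(geokeys), payload = .pack_u16(geokeys)))
  if (!is.null(nodata_ascii)) {
    ent <- c(ent, list(list(tag = 42113L, type = 2L, count = length(nodata_ascii),
                            payload = nodata_ascii)))
  }

  n <- length(ent)
  ifd_size <- 2L + 12L * n + 4L
  cursor <- 8L + ifd_size
  for (i in seq_along(ent)) {
    if (!is.null(ent[[i]]$payload) && length(ent[[i]]$payload) > 4L) {
      ent[[i]]$offset <- cursor
      cursor <- cursor + length(ent[[i]]$payload)
    }
  }
  strip_offset <- cursor
  ent[[6]]$value <- strip_offset

  entry_raw <- function(e) {
    val <- if (!is.null(e$payload)) {
      if (length(e$payload) > 4L) .pack_u32(e$offset) else c(e$payload, raw(4L - length(e$payload)))
    } else if (e$type == 3L) {
      c(.pack_u16(e$value), raw(2L))
    } else {
      .pack_u32(e$value)
    }
    c(.pack_u16(e$tag), .pack_u16(e$type), .pack_u32(e$count), val)
  }

  out <- c(charToRaw("II"), .pack_u16(42L), .pack_u32(8L),
           .pack_u16(n), do.call(c, lapply(ent, entry_raw)), .pack_u32(0L),
           do.call(c, c(lapply(ent, function(e)
             if (!is.null(e$payload) && length(e$payload) > 4L) e$payload else raw(0)),
             list(raw(0)))),
           pix)
  writeBin(out, path)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

#' @keywords internal
geotiff_read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 8L) stop("not a readable raster (file too short): ", path)
  order_tag <- rawToChar(bytes[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a readable raster (no TIFF byte-order mark): ", path)

  rd_int <- function(off, n, size, signed = TRUE) {
    readBin(bytes[(off + 1L):(off + n * size)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  }
  rd_u32 <- function(off, n = 1L) {
    lo <- rd_int(off, n, 4L)
    ifelse(lo < 0, lo + 4294967296, lo)
  }
  rd_dbl <- function(off, n, size) {
    readBin(bytes[(off + 1L):(off + n * size)], "numeric", n = n, size = size, endian = endian)
  }

  if (rd_int(2L, 1L, 2L, signed = FALSE) != 42L)
    stop("not a readable raster (bad TIFF magic): ", path)
  ifd <- rd_u32(4L)

  n_ent <- rd_int(ifd, 1L, 2L, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_ent)) {
    base <- ifd + 2L + 12L * (i - 1L)
    tag <- rd_int(base, 1L, 2L, signed = FALSE)
    type <- rd_int(base + 2L, 1L, 2L, signed = FALSE)
    count <- rd_u32(base + 4L)
    size <- .tiff_type_size[[as.character(type)]]
    if (is.null(size)) next
    total <- size * count
    off <- if (total <= 4L) base + 8L else rd_u32(base + 8L)
    vals <- switch(as.character(type),
      `1` = rd_int(off, count, 1L, signed = FALSE),
      `2` = {
        seg <- bytes[(off + 1L):(off + count)]
        seg <- seg[cumsum(seg == as.raw(0L)) == 0L]
        rawToChar(seg)
      },
      `3` = rd_int(off, count, 2L, signed = FALSE),
      `4` = rd_u32(off, count),
      `8` = rd_int(off, count, 2L),
      `9` = rd_int(off, count, 4L),
      `11` = rd_dbl(off, count, 4L),
      `12` = rd_dbl(off, count, 8L),
      NULL)
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }

  need <- function(tag, what) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("not a readable raster (missing ", what, "): ", path)
    v
  }
  nc <- need(256L, "image width"); nr <- need(257L, "image length")
  bits <- need(258L, "bits per sample")
  if (!is.null(tags[["277"]]) && tags[["277"]] > 1L)
    stop("multi-band raster without an elevation band selector: ", path,
         " has ", tags[["277"]], " samples per pixel")
  if (length(bits) > 1L)
    stop("multi-band raster without an elevation band selector: ", path)
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  if (comp != 1L) stop("unsupported TIFF compression (", comp, ") in ", path)
  fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
  offsets <- need(273L, "strip offsets")
  counts <- need(279L, "strip byte counts")

  vec <- numeric(0)
  for (s in seq_along(offsets)) {
    seg <- bytes[(offsets[s] + 1L):(offsets[s] + counts[s])]
    npx <- counts[s] / (bits / 8L)
    vals <- if (fmt == 3L) {
      readBin(seg, "numeric", n = npx, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      as.integer(seg)
    } else if (bits == 16L) {
      readBin(seg, "integer", n = npx, size = 2L, signed = (fmt == 2L), endian = endian)
    } else if (bits == 32L && fmt == 2L) {
      readBin(seg, "integer", n = npx, size = 4L, endian = endian)
    } else {
      stop("unsupported sample layout (", bits, " bits, format ", fmt, ") in ", path)
    }
    vec <- c(vec, vals)
  }
  if (length(vec) != nr * nc) stop("corrupt raster: pixel count mismatch in ", path)
  values <- matrix(vec, nrow = nr, ncol = nc, byrow = TRUE)

  ps <- tags[["33550"]]; tp <- tags[["33922"]]
  if (is.null(ps) || is.null(tp))
    stop("raster has no affine transform (ModelPixelScale/ModelTiepoint missing): ", path)
  xres <- ps[1]; yres <- ps[2]
  xmin <- tp[4] - tp[1] * xres
  ymax <- tp[5] + tp[2] * yres

  gk <- tags[["34735"]]
  crs <- NULL
  if (!is.null(gk) && length(gk) >= 4L) {
    nk <- gk[4]
    for (k in seq_len(nk)) {
      id <- gk[4L * k + 1L]; val <- gk[4L * k + 4L]
      if (id == 3072L && val != 32767L) crs <- paste0("EPSG:", val)
      if (is.null(crs) && id == 2048L && val != 32767L) crs <- paste0("EPSG:", val)
    }
  }
  if (is.null(crs)) stop("raster has no CRS (GeoKeyDirectory missing or user-defined): ", path)

  nodata <- if (!is.null(tags[["42113"]])) suppressWarnings(as.numeric(tags[["42113"]]))

  list(values = values, xmin = xmin, ymax = ymax, xres = xres, yres = yres,
       crs = crs, nodata = nodata)
}
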