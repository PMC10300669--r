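# Raster and tower I/O, coordinate transforms, distances.

test_that("GeoTIFF round-trip preserves values, georeference and nodata", {
  d <- make_dem("flat", nrows = 10, ncols = 10, resolution = 30)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(d, f)
  d2 <- read_dem(f)
  expect_identical(d2$values, d$values)
  expect_identical(dim(d2), c(10L, 10L))
  expect_false(any(d2$nodata_mask))
  expect_equal(d2$xmin, d$xmin)
  expect_equal(d2$ymax, d$ymax)
  expect_equal(d2$xres, 30)
  expect_identical(d2$crs, d$crs)

  # float grid with one nodata cell
  h <- make_dem("gaussian_hill", nrows = 8, ncols = 9)
  h$values[3, 4] <- NA
  h$nodata_mask[3, 4] <- TRUE
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(h, f2)
  h2 <- read_dem(f2)
  expect_identical(which(h2$nodata_mask), which(h$nodata_mask))
  expect_lt(max(abs(h2$values - h$values), na.rm = TRUE), 1e-6)

  # integer grids round-trip bit-exactly
  g <- matrix(as.numeric(0:99), 10, 10)
  f3 <- withr::local_tempfile(fileext = ".tif")
  sightline:::geotiff_write_raw(f3, g, 0, 300, 30, 30, "EPSG:32636", dtype = "int16")
  g2 <- read_dem(f3)
  expect_identical(g2$values, g)
})

test_that("pixel data agrees with an independent TIFF reader", {
  skip_if_not_installed("tiff")
  d <- make_dem("gaussian_hill", nrows = 12, ncols = 7)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(d, f, dtype = "float32")
  px <- tiff::readTIFF(f)
  expect_equal(matrix(as.numeric(px), nrow(px), ncol(px)), d$values,
               tolerance = 1e-6)
})

test_that("unreadable or band-less input gives a clear error", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,lat,lon\nT1,1,2", csv)
  expect_error(read_dem(csv), "not a readable raster")
  expect_error(read_dem(file.path(tempdir(), "nope-does-not-exist.tif")),
               "not found")
})

test_that("coord_to_cell and cell_center are mutually inverse", {
  d <- make_dem("flat", nrows = 5, ncols = 5, resolution = 30,
                origin = c(0, 300))
  expect_equal(cell_center(d, 1, 1), cbind(x = 15, y = 285))
  for (r in 1:5) for (cc in 1:5) {
    ctr <- cell_center(d, r, cc)
    expect_identical(coord_to_cell(d, ctr[1, "x"], ctr[1, "y"]),
                     cbind(row = r, col = cc))
  }
  expect_error(coord_to_cell(d, 300 + 1, 150), "outside")
  expect_error(cell_center(d, 6, 1), "out of range")
})

test_that("ground_distance: haversine closed form, symmetry, triangle inequality", {
  # one degree of longitude on the equator: R * pi/180
  expect_equal(ground_distance(c(0, 0), c(1, 0), "EPSG:4326"),
               111194.9, tolerance = 0.1 / 111194.9)
  expect_equal(ground_distance(c(35, 32), c(35, 32), "EPSG:4326"), 0)
  set.seed(42)
  for (i in 1:100) {
    a <- c(runif(1, -180, 180), runif(1, -89, 89))
    b <- c(runif(1, -180, 180), runif(1, -89, 89))
    expect_identical(ground_distance(a, b, "EPSG:4326"),
                     ground_distance(b, a, "EPSG:4326"))
  }
  for (i in 1:50) {
    pts <- replicate(3, c(runif(1, -30, 30), runif(1, -30, 30)), simplify = FALSE)
    dab <- ground_distance(pts[[1]], pts[[2]], "EPSG:4326")
    dbc <- ground_distance(pts[[2]], pts[[3]], "EPSG:4326")
    dac <- ground_distance(pts[[1]], pts[[3]], "EPSG:4326")
    expect_lte(dac, dab + dbc + 1e-6 * (dab + dbc))
  }
})

test_that("haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  for (i in 1:20) {
    a <- c(runif(1, -180, 180), runif(1, -85, 85))
    b <- a + runif(2, -0.5, 0.5)
    expect_equal(ground_distance(a, b, "EPSG:4326"),
                 geosphere::distHaversine(a, b, r = 6371000),
                 tolerance = 1e-9)
  }
})

test_that("UTM projection round-trips and matches haversine locally", {
  lat <- 32.53; lon <- 35.43
  p <- sightline:::project_from_wgs84(lat, lon, "EPSG:32636")
  ll <- sightline:::unproject_to_wgs84(p$x, p$y, "EPSG:32636")
  expect_equal(ll$lat, lat, tolerance = 1e-9)
  expect_equal(ll$lon, lon, tolerance = 1e-9)
  # short projected distances approximate great-circle distances (the UTM
  # scale factor and sphere-vs-ellipsoid radius differ by a few per mille)
  q <- sightline:::project_from_wgs84(lat + 0.01, lon, "EPSG:32636")
  d_utm <- sqrt((p$x - q$x)^2 + (p$y - q$y)^2)
  d_hav <- ground_distance(c(lon, lat), c(lon, lat + 0.01), "EPSG:4326")
  expect_equal(d_utm, d_hav, tolerance = 5e-3)
})

test_that("tower CSV parsing: defaults, flags, and row-level errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,lat,lon,height_m,max_range_m",
               "T1,32.53,35.43,10,20000",
               "T2,32.54,35.44,5,"), f)
  # a geographic dem covering the towers
  dg <- make_dem("flat", nrows = 10, ncols = 10, resolution = 0.01,
                 crs = "EPSG:4326", origin = c(35.40, 32.60))
  tw <- read_towers(f, dg)
  expect_s3_class(tw, "tower_set")
  expect_identical(tw$name, c("T1", "T2"))
  expect_equal(tw$height_m, c(10, 5))
  expect_equal(tw$max_range_m[1], 20000)
  expect_true(is.na(tw$max_range_m[2]))   # extent-limited default
  expect_true(all(tw$in_extent))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,lat,lon,height_m,max_range_m",
               "T1,32.5,35.4,10,100", "T1,32.6,35.5,5,100"), dup)
  expect_error(read_towers(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,lat,lon,height_m,max_range_m", "T9,32.5,35.4,-2,100"), neg)
  expect_error(read_towers(neg), "T9")

  txt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,lat,lon,height_m,max_range_m", "T3,32.5,abc,2,100"), txt)
  expect_error(read_towers(txt), "non-numeric lon.*T3")

  out <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,lat,lon,height_m,max_range_m", "Far,10.0,10.0,2,100"), out)
  expect_message(read_towers(out, dg), "outside the DEM extent")

  # round trip through write_towers
  back <- withr::local_tempfile(fileext = ".csv")
  write_towers(tw, back)
  tw2 <- read_towers(back)
  expect_equal(tw2$max_range_m, tw$max_range_m)
  expect_equal(tw2$lat, tw$lat)
})

test_that("geo tags are readable by an independent GeoTIFF parser", {
  skip_if(Sys.which("python") == "", "no python on PATH")
  has_tifffile <- suppressWarnings(
    system2("python", c("-c", shQuote("import tifffile")),
            stdout = FALSE, stderr = FALSE)) == 0L
  skip_if_not(has_tifffile, "python tifffile not available")
  d <- make_dem("gaussian_hill", nrows = 6, ncols = 5)
  d$values[2, 2] <- NA; d$nodata_mask[2, 2] <- TRUE
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(d, f)
  script <- paste(
    "import tifffile, json, sys",
    "p = tifffile.TiffFile(sys.argv[1]).pages[0]",
    "print(json.dumps({'shape': list(p.shape),",
    "  'scale': list(p.tags['ModelPixelScaleTag'].value),",
    "  'tie': list(p.tags['ModelTiepointTag'].value),",
    "  'nodata': p.tags['GDAL_NODATA'].value,",
    "  'geokeys': list(p.tags['GeoKeyDirectoryTag'].value),",
    "  'v00': float(p.asarray()[0, 0])}))",
    sep = "\n")
  out <- system2("python", c("-", f), input = script, stdout = TRUE)
  got <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(got$shape, c(6, 5))
  expect_equal(got$scale, c(30, 30, 0))
  expect_equal(got$tie, c(0, 0, 0, d$xmin, d$ymax, 0))
  expect_equal(as.numeric(got$nodata), -9999)
  epsg_key <- which(got$geokeys == 3072)
  expect_equal(got$geokeys[epsg_key + 3], 32636)
  expect_equal(got$v00, d$values[1, 1])
})
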