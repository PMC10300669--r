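# Coordinate reference systems.
#
# Rasters carry an EPSG code. Two families are supported: geographic WGS-84
# style CRSs (coordinates are lon/lat degrees) and UTM zones on WGS-84
# (EPSG 326xx / 327xx, metre units). Tower tables are always WGS-84 lat/lon
# and are projected onto the raster CRS at load time with an ellipsoidal
# transverse-Mercator transform (series expansion, sub-mm accurate over a
# UTM zone). Geographic-CRS distances use a spherical haversine with a
# configurable Earth radius, consistent with the spherical curvature model.

.wgs84_a <- 6378137
.wgs84_f <- 1 / 298.257223563

#' @keywords internal
crs_epsg <- function(crs) {
  if (is.numeric(crs)) return(as.integer(crs))
  m <- regmatches(crs, regexpr("[0-9]+$", crs))
  if (length(m) == 0L) stop("cannot parse CRS identifier: ", crs)
  as.integer(m)
}

#' @keywords internal
crs_is_geographic <- function(crs) {
  crs_epsg(crs) %in% c(4326L, 4269L, 4258L, 4283L)
}

.utm_zone <- function(epsg) {
  if (epsg >= 32601L && epsg <= 32660L) list(zone = epsg - 32600L, north = TRUE)
  else if (epsg >= 32701L && epsg <= 32760L) list(zone = epsg - 32700L, north = FALSE)
  else NULL
}

.tm_forward <- function(lat, lon, lon0, k0 = 0.9996, fe = 500000, fn = 0) {
  a <- .wgs84_a; f <- .wgs84_f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dl <- (lon - lon0) * pi / 180
  sp <- sin(phi); cp <- cos(phi); tp <- tan(phi)
  n <- a / sqrt(1 - e2 * sp^2)
  t <- tp^2; c <- ep2 * cp^2
  aa <- dl * cp
  m <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- fe + k0 * n * (aa + (1 - t + c) * aa^3 / 6 +
                      (5 - 18 * t + t^2 + 72 * c - 58 * ep2) * aa^5 / 120)
  y <- fn + k0 * (m + n * tp * (aa^2 / 2 + (5 - t + 9 * c + 4 * c^2) * aa^4 / 24 +
                  (61 - 58 * t + t^2 + 600 * c - 330 * ep2) * aa^6 / 720))
  list(x = x, y = y)
}

.tm_inverse <- function(x, y, lon0, k0 = 0.9996, fe = 500000, fn = 0) {
  a <- .wgs84_a; f <- .wgs84_f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  m <- (y - fn) / k0
  mu <- m / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
          (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
          (151 * e1^3 / 96) * sin(6 * mu) +
          (1097 * e1^4 / 512) * sin(8 * mu)
  sp <- sin(phi1); cp <- cos(phi1); tp <- tan(phi1)
  c1 <- ep2 * cp^2; t1 <- tp^2
  n1 <- a / sqrt(1 - e2 * sp^2)
  r1 <- a * (1 - e2) / (1 - e2 * sp^2)^1.5
  d <- (x - fe) / (n1 * k0)
  phi <- phi1 - (n1 * tp / r1) * (d^2 / 2 -
          (5 + 3 * t1 + 10 * c1 - 4 * c1^2 - 9 * ep2) * d^4 / 24 +
          (61 + 90 * t1 + 298 * c1 + 45 * t1^2 - 252 * ep2 - 3 * c1^2) * d^6 / 720)
  lam <- lon0 * pi / 180 + (d - (1 + 2 * t1 + c1) * d^3 / 6 +
          (5 - 2 * c1 + 28 * t1 - 3 * c1^2 + 8 * ep2 + 24 * t1^2) * d^5 / 120) / cp
  list(lat = phi * 180 / pi, lon = lam * 180 / pi)
}

#' Project WGS-84 latitude/longitude into a raster's CRS
#'
#' @param lat,lon numeric vectors of WGS-84 degrees.
#' @param crs target CRS, e.g. `"EPSG:32636"` or `"EPSG:4326"`.
#' @return a list with numeric vectors `x` and `y` in CRS units.
#' @keywords internal
project_from_wgs84 <- function(lat, lon, crs) {
  if (crs_is_geographic(crs)) return(list(x = lon, y = lat))
  utm <- .utm_zone(crs_epsg(crs))
  if (is.null(utm))
    stop("unsupported projected CRS for tower reprojection: ", crs,
         " (geographic and WGS-84 UTM zones are supported)")
  .tm_forward(lat, lon, lon0 = -183 + 6 * utm$zone,
              fn = if (utm$north) 0 else 1e7)
}

#' @keywords internal
unproject_to_wgs84 <- function(x, y, crs) {
  if (crs_is_geographic(crs)) return(list(lat = y, lon = x))
  utm <- .utm_zone(crs_epsg(crs))
  if (is.null(utm)) stop("unsupported projected CRS: ", crs)
  .tm_inverse(x, y, lon0 = -183 + 6 * utm$zone,
              fn = if (utm$north) 0 else 1e7)
}

#' @keywords internal
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = 6371000) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * radius_m * asin(pmin(1, sqrt(h)))
}

#' Ground distance between two points
#'
#' Great-circle (haversine, spherical) distance for geographic CRSs,
#' Euclidean distance for projected CRSs.
#'
#' @param p1,p2 numeric length-2 vectors `c(x, y)` in CRS units (for a
#'   geographic CRS: `c(lon, lat)` degrees).
#' @param crs the CRS both points are expressed in.
#' @param earth_radius_m sphere radius for the haversine branch, metres.
#' @return distance in metres (CRS units for a non-metric projected CRS).
#' @examples
#' ground_distance(c(0, 0), c(1, 0), "EPSG:4326")  # one degree of longitude
#' @export
ground_distance <- function(p1, p2, crs, earth_radius_m = 6371000) {
  if (crs_is_geographic(crs)) {
    haversine_m(p1[2], p1[1], p2[2], p2[1], earth_radius_m)
  } else {
    sqrt((p1[1] - p2[1])^2 + (p1[2] - p2[2])^2)
  }
}

# vectorised variant used by the viewshed loop
.dist_xy <- function(crs, x1, y1, x2, y2, earth_radius_m = 6371000) {
  if (crs_is_geographic(crs)) {
    haversine_m(y1, x1, y2, x2, earth_radius_m)
  } else {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  }
}
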