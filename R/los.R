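# Point-to-point line of sight over a DEM.
#
# The sight line is the straight 3-D segment from the tower head to the
# target; the terrain along it is sampled at a fixed step with nearest-cell
# elevation lookup, and the LOS exists when no interior sample is strictly
# above the segment. Under the curved-Earth model every point at ground
# distance d from the tower is lowered by the spherical tangent-plane drop
# d^2 / (2R) (second-order Taylor expansion, valid while d << R), target
# endpoint included.

#' Sight-model configuration
#'
#' @param curved apply the curved-Earth model (`FALSE` = flat Earth).
#' @param earth_radius_m Earth radius in metres; the default is the standard
#'   mean radius 6,371,000 m.
#' @param sample_step_m spacing between terrain samples along the sight
#'   line, metres. `NULL` (default) resolves to half the smaller cell
#'   dimension of the DEM in use.
#' @param endpoint_exclusion_m samples within this ground distance of either
#'   endpoint never count as blockers, so a tower's or target's own cell
#'   cannot occlude itself. `NULL` resolves to half the smaller cell
#'   dimension.
#' @return an object of class `sight_config`.
#' @export
sight_config <- function(curved = FALSE, earth_radius_m = 6371000,
                         sample_step_m = NULL, endpoint_exclusion_m = NULL) {
  stopifnot(earth_radius_m > 0,
            is.null(sample_step_m) || sample_step_m > 0,
            is.null(endpoint_exclusion_m) || endpoint_exclusion_m >= 0)
  structure(list(curved = isTRUE(curved), earth_radius_m = earth_radius_m,
                 sample_step_m = sample_step_m,
                 endpoint_exclusion_m = endpoint_exclusion_m),
            class = "sight_config")
}

.resolve_cfg <- function(cfg, dem) {
  half <- .min_cell(dem) / 2
  if (!crs_is_geographic(dem$crs)) {
    step <- cfg$sample_step_m %||% half
    excl <- cfg$endpoint_exclusion_m %||% half
  } else {
    # cell size is in degrees; convert the half-cell default to metres
    half_m <- half * pi / 180 * cfg$earth_radius_m
    step <- cfg$sample_step_m %||% half_m
    excl <- cfg$endpoint_exclusion_m %||% half_m
  }
  list(curved = cfg$curved, R = cfg$earth_radius_m, step = step, excl = excl)
}

#' Curvature drop below the tangent plane
#'
#' Height by which a point at ground distance `d` from the observer falls
#' below the observer's horizontal tangent plane on a sphere of radius `R`:
#' `d^2 / (2 R)`. Returns 0 when the configuration selects the flat model.
#'
#' @param d ground distance(s) in metres, `>= 0`.
#' @param cfg a [sight_config].
#' @return drop in metres, same length as `d`.
#' @examples
#' curvature_drop(10000, sight_config(curved = TRUE))  # ~7.85 m
#' @export
curvature_drop <- function(d, cfg = sight_config(curved = TRUE)) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (!cfg$curved) return(rep(0, length(d)))
  d^2 / (2 * cfg$earth_radius_m)
}

.check_inside <- function(dem, p, what = "point") {
  e <- dem_extent(dem)
  if (p[1] < e$xmin || p[1] > e$xmax || p[2] < e$ymin || p[2] > e$ymax)
    stop(sprintf("%s (%g, %g) outside the DEM extent", what, p[1], p[2]))
}

# shared sampling rule: fixed spacing from the observer, endpoints always
# included ({0, step, 2*step, ...} up to D, plus D itself)
.sample_distances <- function(D, step) {
  k <- floor(D / step)
  d <- (0:k) * step
  if (d[k + 1L] < D) d <- c(d, D)
  d
}

#' Sample a terrain profile along a segment
#'
#' Samples the straight segment between two points at fixed spacing
#' (endpoints always included) with nearest-cell elevation lookup, and
#' applies the curvature drop with the first point as zero-drop origin.
#'
#' @param dem a [dem_grid].
#' @param p1,p2 numeric `c(x, y)` in the DEM CRS; both inside the extent.
#' @param cfg a [sight_config].
#' @return an `elevation_profile`: a tibble with columns `distance_m`,
#'   `terrain_m`, `terrain_curved_m`, `sightline_m` (NA here; filled by
#'   [line_of_sight()]), plus attributes `any_nodata` and `crs`.
#' @export
sample_profile <- function(dem, p1, p2, cfg = sight_config()) {
  p1 <- unname(as.numeric(p1[1:2])); p2 <- unname(as.numeric(p2[1:2]))
  .check_inside(dem, p1, "start point")
  .check_inside(dem, p2, "end point")
  rc <- .resolve_cfg(cfg, dem)
  D <- .dist_xy(dem$crs, p1[1], p1[2], p2[1], p2[2], rc$R)
  if (D <= 0) stop("profile endpoints coincide")
  d <- .sample_distances(D, rc$step)
  t <- d / D
  x <- p1[1] + t * (p2[1] - p1[1])
  y <- p1[2] + t * (p2[2] - p1[2])
  terrain <- .elev_at(dem, x, y)
  drop <- curvature_drop(d, cfg)
  prof <- tibble::tibble(distance_m = d, terrain_m = terrain,
                         terrain_curved_m = terrain - drop,
                         sightline_m = NA_real_)
  attr(prof, "any_nodata") <- anyNA(terrain)
  attr(prof, "crs") <- dem$crs
  class(prof) <- c("elevation_profile", class(prof))
  prof
}

.resolve_point <- function(p, dem) {
  # accepts c(x, y) in DEM CRS, or a one-row tower_set tibble
  if (inherits(p, "data.frame")) {
    stopifnot(nrow(p) == 1L)
    if (!all(c("x", "y") %in% names(p))) p <- attach_towers(p, dem)
    list(xy = c(p$x[1], p$y[1]), height = p$height_m[1], name = p$name[1],
         range = p$max_range_m[1])
  } else {
    list(xy = as.numeric(p[1:2]), height = NA_real_, name = NULL, range = NA_real_)
  }
}

#' Point-to-point line of sight
#'
#' Tests whether an observer at `from` (eye at ground + `from_height_m`)
#' sees a target at `to` (at ground + `to_height_m`), given the flat- or
#' curved-Earth model in `cfg`. A terrain sample blocks only when it is
#' *strictly* above the sight line; samples within the endpoint exclusion
#' distance of either end never block; missing-data samples never block but
#' are flagged.
#'
#' @param dem a [dem_grid].
#' @param from observer: `c(x, y)` in the DEM CRS, or a one-row tower table
#'   (its `height_m` is used unless `from_height_m` is given).
#' @param to target: `c(x, y)` in the DEM CRS.
#' @param from_height_m,to_height_m heights above the local surface, metres.
#' @param cfg a [sight_config].
#' @return a `los_result`: list with `visible`, `blocking_distance_m`
#'   (`NA` when visible), `valid` (`FALSE` when an endpoint sits on a
#'   missing-data cell), `distance_m`, and `profile` (the
#'   `elevation_profile` with `sightline_m` filled).
#' @examples
#' dem <- make_dem("flat", nrows = 21, ncols = 21, resolution = 30)
#' p <- cell_center(dem, 11, 3)[1, ]
#' q <- cell_center(dem, 11, 19)[1, ]
#' line_of_sight(dem, p, q, from_height_m = 10, to_height_m = 0.3)
#' @export
line_of_sight <- function(dem, from, to, from_height_m = NULL, to_height_m = 0,
                          cfg = sight_config()) {
  f <- .resolve_point(from, dem)
  h1 <- from_height_m %||% f$height
  if (is.null(h1) || is.na(h1)) stop("observer height is required")
  if (h1 < 0 || to_height_m < 0) stop("heights must be >= 0")
  .check_inside(dem, f$xy, "observer")
  .check_inside(dem, to, "target")
  ground2 <- .elev_at(dem, to[1], to[2])
  los_core(dem, f$xy, to, h1,
           target_elev = ground2 + to_height_m, cfg = cfg)
}

# target_elev is the *absolute* target elevation before the curvature drop
los_core <- function(dem, p1, p2, h1, target_elev, cfg) {
  p1 <- unname(as.numeric(p1[1:2])); p2 <- unname(as.numeric(p2[1:2]))
  target_elev <- unname(target_elev)
  rc <- .resolve_cfg(cfg, dem)
  ground1 <- .elev_at(dem, p1[1], p1[2])
  if (is.na(ground1)) stop("observer sits on a missing-data cell")
  D <- .dist_xy(dem$crs, p1[1], p1[2], p2[1], p2[2], rc$R)
  A <- ground1 + h1
  valid <- !is.na(target_elev)
  B <- if (valid) target_elev - (if (rc$curved) D^2 / (2 * rc$R) else 0) else NA_real_

  if (D <= 0) {
    prof <- tibble::tibble(distance_m = c(0, 0), terrain_m = rep(ground1, 2),
                           terrain_curved_m = rep(ground1, 2),
                           sightline_m = c(A, B))
    class(prof) <- c("elevation_profile", class(prof))
    return(.los_result(valid, TRUE, NA_real_, D, prof))
  }

  d <- .sample_distances(D, rc$step)
  t <- d / D
  x <- p1[1] + t * (p2[1] - p1[1])
  y <- p1[2] + t * (p2[2] - p1[2])
  terrain <- .elev_at(dem, x, y)
  tc <- terrain - (if (rc$curved) d^2 / (2 * rc$R) else 0)
  sl <- A + (B - A) * t
  interior <- d >= rc$excl & (D - d) >= rc$excl
  block <- interior & !is.na(tc) & !is.na(sl) & tc > sl

  prof <- tibble::tibble(distance_m = d, terrain_m = terrain,
                         terrain_curved_m = tc, sightline_m = sl)
  attr(prof, "any_nodata") <- anyNA(terrain)
  attr(prof, "crs") <- dem$crs
  class(prof) <- c("elevation_profile", class(prof))

  visible <- valid && !any(block)
  bd <- if (!visible && valid && any(block)) d[which(block)[1]] else NA_real_
  .los_result(valid, visible && valid, bd, D, prof)
}

.los_result <- function(valid, visible, blocking_distance_m, distance_m, profile) {
  structure(list(visible = visible && valid, valid = valid,
                 blocking_distance_m = blocking_distance_m,
                 distance_m = distance_m, profile = profile),
            class = "los_result")
}

#' @export
print.los_result <- function(x, ...) {
  if (!x$valid) {
    cat("<los_result> INVALID (endpoint on missing data)\n")
  } else if (x$visible) {
    cat(sprintf("<los_result> VISIBLE over %.1f m\n", x$distance_m))
  } else {
    cat(sprintf("<los_result> BLOCKED at %.1f m (of %.1f m)\n",
                x$blocking_distance_m, x$distance_m))
  }
  invisible(x)
}

#' Write a profile to CSV
#'
#' Plain CSV `distance_m,terrain_m,terrain_curved_m,sightline_m`, suitable
#' for external plotting of the terrain/sight-line inset.
#' @param profile an `elevation_profile` (or a `los_result`, whose profile
#'   is used).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (inherits(profile, "los_result")) profile <- profile$profile
  utils::write.csv(
    profile[, c("distance_m", "terrain_m", "terrain_curved_m", "sightline_m")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
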