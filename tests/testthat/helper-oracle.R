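# Independent brute-force LOS oracle: plain scalar code, dense sampling at
# one tenth of a cell, same strict tie rule and endpoint exclusion as the
# engine's definition. Deliberately written without reusing any engine
# internals so engine bugs cannot cancel out.

oracle_los_visible <- function(dem, p1, h1, p2, target_elev, curved,
                               R = 6371000, step = NULL, excl = NULL) {
  step <- if (is.null(step)) min(dem$xres, dem$yres) / 10 else step
  excl <- if (is.null(excl)) min(dem$xres, dem$yres) / 2 else excl
  g1 <- dem$values[coord_to_cell(dem, p1[1], p1[2])]
  A <- g1 + h1
  D <- sqrt(sum((p2 - p1)^2))
  B <- target_elev - if (curved) D^2 / (2 * R) else 0
  if (D == 0) return(TRUE)
  d <- seq(0, D, by = step)
  if (d[length(d)] < D) d <- c(d, D)
  d <- d[d >= excl & (D - d) >= excl]
  if (length(d) == 0) return(TRUE)
  t <- d / D
  px <- p1[1] + t * (p2[1] - p1[1])
  py <- p1[2] + t * (p2[2] - p1[2])
  terr <- dem$values[coord_to_cell(dem, px, py)]
  tc <- terr - if (curved) d^2 / (2 * R) else 0
  sl <- A + (B - A) * t
  !any(!is.na(tc) & tc > sl)
}

oracle_viewshed <- function(dem, tower_xy, tower_h, target_height_m = 0,
                            curved = FALSE, range_m = NA, R = 6371000,
                            target_elev = NULL, valid = NULL) {
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  if (is.null(valid)) valid <- !dem$nodata_mask
  if (is.null(target_elev)) target_elev <- dem$values + target_height_m
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!valid[r, cc]) next
    ctr <- cell_center(dem, r, cc)[1, ]
    D <- sqrt(sum((ctr - tower_xy)^2))
    if (!is.na(range_m) && D > range_m) next
    out[r, cc] <- oracle_los_visible(dem, tower_xy, tower_h, ctr,
                                     target_elev[r, cc], curved, R)
  }
  out
}

# the five standard small fixtures used across the suite
standard_fixtures <- function(n = 41) {
  list(
    flat = make_dem("flat", nrows = n, ncols = n),
    hill = make_dem("gaussian_hill", nrows = n, ncols = n, height = 50, sigma = 150),
    ridge = make_dem("ridge", nrows = n, ncols = n, height = 50),
    stairs = make_dem("staircase", nrows = n, ncols = n),
    basin = make_dem("basin_with_islets", nrows = n, ncols = n, seed = 7))
}

# a single tower/receiver centred on a given cell
tower_at <- function(dem, row, col, height_m, range_m = NA, name = "T1") {
  ctr <- cell_center(dem, row, col)[1, ]
  tw <- grid_receivers(1, 1, 300, height_m = height_m, range_m = range_m,
                       origin = ctr, crs = dem$crs, name_prefix = "X")
  tw$name <- name
  tw
}

# engine config matched to the oracle's sampling density
dense_cfg <- function(dem, curved = FALSE) {
  sight_config(curved = curved, sample_step_m = min(dem$xres, dem$yres) / 10)
}
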