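# Submerged-receiver viewsheds over bathymetry.
#
# Receivers and tags sit under water; the bathymetric surface is the
# blocking terrain and the water column is treated as fully transparent to
# the line of sight (acoustic refraction is out of scope). The target depth
# specification can leave some cells with no well-posed LOS question at
# all — e.g. a target 5 m above the seabed in 3 m of water, or any land
# cell — and those are *invalid*, distinct from "not visible".

#' Aquatic target configuration
#'
#' @param water_level_m elevation of the water surface on the bathymetry's
#'   vertical datum (0 for oceans; lake level for lakes).
#' @param mode `"above_seabed"`: targets sit `offset_m` metres above the
#'   seabed (like height-above-ground on land); `"below_surface"`: targets
#'   sit `offset_m` metres below the water surface (pelagic species).
#' @param offset_m the height/depth offset in metres, `>= 0`.
#' @return an object of class `aquatic_config`.
#' @export
aquatic_config <- function(water_level_m = 0,
                           mode = c("above_seabed", "below_surface"),
                           offset_m = 0) {
  mode <- match.arg(mode)
  stopifnot(offset_m >= 0)
  structure(list(water_level_m = water_level_m, mode = mode,
                 offset_m = offset_m), class = "aquatic_config")
}

#' Resolve target elevations and validity over bathymetry
#'
#' In `above_seabed` mode the target elevation is seabed + offset, valid
#' while the target stays at or below the water surface. In
#' `below_surface` mode it is water level − offset, valid while the target
#' stays at or above the seabed. Land cells (seabed at or above the water
#' surface) are always invalid. Validity depends only on bathymetry and the
#' configuration, never on receiver placement.
#'
#' @param bathy a [dem_grid] of seabed elevations (negative below datum).
#' @param cfg an [aquatic_config].
#' @return list with `elevation` (numeric matrix, `NA` where invalid) and
#'   `valid` (logical matrix).
#' @examples
#' basin <- make_dem("flat", nrows = 5, ncols = 5, resolution = 30, value = -10)
#' target_elevation_field(basin, aquatic_config(0, "above_seabed", 1))$elevation[1, 1]
#' @export
target_elevation_field <- function(bathy, cfg) {
  stopifnot(inherits(cfg, "aquatic_config"))
  seabed <- bathy$values
  wet <- !is.na(seabed) & seabed < cfg$water_level_m
  if (cfg$mode == "above_seabed") {
    elev <- seabed + cfg$offset_m
    valid <- wet & (elev <= cfg$water_level_m)
  } else {
    elev <- matrix(cfg$water_level_m - cfg$offset_m, nrow(seabed), ncol(seabed))
    valid <- wet & !is.na(seabed) & (seabed <= cfg$water_level_m - cfg$offset_m)
  }
  elev[!valid] <- NA_real_
  list(elevation = elev, valid = valid)
}

#' Viewshed of a submerged receiver
#'
#' Delegates to [compute_viewshed()] with the aquatic target-elevation
#' field and validity mask; the bathymetric surface is the blocking
#' terrain. Invalid cells (land, impossible target depths) come back as
#' invalid, not merely not-visible, so composite maps keep the islet
#' shadows.
#'
#' @param bathy a [dem_grid] of seabed elevations.
#' @param receiver a one-row tower table; `height_m` is metres above the
#'   seabed. The receiver must sit underwater: seabed below the water
#'   surface and seabed + `height_m` at or below it.
#' @param cfg_sight a [sight_config].
#' @param cfg_aquatic an [aquatic_config] giving the water level and the
#'   target height mode/offset.
#' @return a `viewshed_raster`.
#' @export
aquatic_viewshed <- function(bathy, receiver, cfg_sight = sight_config(),
                             cfg_aquatic = aquatic_config()) {
  rcv <- .resolve_point(receiver, bathy)
  .check_inside(bathy, rcv$xy, "receiver")
  seabed <- .elev_at(bathy, rcv$xy[1], rcv$xy[2])
  if (is.na(seabed))
    stop("receiver '", rcv$name %||% "?", "' sits on a missing-data cell")
  if (seabed >= cfg_aquatic$water_level_m)
    stop("receiver '", rcv$name %||% "?", "' sits on land (seabed ", seabed,
         " m >= water level ", cfg_aquatic$water_level_m, " m)")
  if (seabed + rcv$height > cfg_aquatic$water_level_m)
    stop("receiver '", rcv$name %||% "?", "' would sit above the water surface (",
         seabed + rcv$height, " m > ", cfg_aquatic$water_level_m, " m)")
  tf <- target_elevation_field(bathy, cfg_aquatic)
  compute_viewshed(bathy, receiver, target_height_m = cfg_aquatic$offset_m,
                   cfg = cfg_sight, target_elevation = tf$elevation,
                   validity = tf$valid)
}
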