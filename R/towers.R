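# Tower / receiver tables.
#
# Towers live in a plain tibble (one row per tower) so they compose with
# dplyr verbs; `height_m` is metres above the *local surface* (ground or
# seabed) and `max_range_m` is the maximum reception range in metres, with
# NA meaning "limited by the DEM extent only".

#' Build a tower table
#'
#' @param name unique tower names.
#' @param lat,lon WGS-84 coordinates in degrees.
#' @param height_m height above the local surface (ground or seabed), `>= 0`.
#' @param max_range_m maximum reception range in metres (`> 0`), or `NA`
#'   for extent-limited reception.
#' @return a tibble of class `tower_set` with columns
#'   `name, lat, lon, height_m, max_range_m`.
#' @examples
#' towers("T1", lat = 32.53, lon = 35.43, height_m = 10, max_range_m = 20000)
#' @export
towers <- function(name, lat, lon, height_m, max_range_m = NA_real_) {
  tb <- tibble::tibble(name = as.character(name), lat = as.numeric(lat),
                       lon = as.numeric(lon), height_m = as.numeric(height_m),
                       max_range_m = as.numeric(max_range_m))
  validate_towers(tb)
}

validate_towers <- function(tb) {
  if (anyDuplicated(tb$name))
    stop("duplicate tower name(s): ",
         paste(unique(tb$name[duplicated(tb$name)]), collapse = ", "))
  if (any(is.na(tb$height_m)) || any(tb$height_m < 0)) {
    bad <- which(is.na(tb$height_m) | tb$height_m < 0)[1]
    stop("invalid height for tower '", tb$name[bad], "' (row ", bad,
         "): height_m must be numeric and >= 0")
  }
  if (any(!is.na(tb$max_range_m) & tb$max_range_m <= 0)) {
    bad <- which(!is.na(tb$max_range_m) & tb$max_range_m <= 0)[1]
    stop("invalid max_range_m for tower '", tb$name[bad], "' (row ", bad,
         "): must be > 0 or empty for extent-limited")
  }
  class(tb) <- unique(c("tower_set", class(tb)))
  tb
}

#' Read a tower table from CSV
#'
#' Expects a header `name,lat,lon,height_m,max_range_m`. An empty
#' `max_range_m` means the tower's reception is limited only by the DEM
#' extent. Towers falling outside the DEM extent are kept but reported.
#'
#' @param path CSV file path.
#' @param dem optional [dem_grid]; when given, towers are projected onto the
#'   DEM CRS (columns `x`, `y`) and checked against its extent
#'   (column `in_extent`).
#' @return a `tower_set` tibble.
#' @export
read_towers <- function(path, dem = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  need <- c("name", "lat", "lon", "height_m", "max_range_m")
  if (!all(need %in% names(raw)))
    stop("tower CSV must have header columns ", paste(need, collapse = ","),
         "; missing: ", paste(setdiff(need, names(raw)), collapse = ","))
  num <- function(col, required = TRUE) {
    v <- raw[[col]]
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " for tower '", raw$name[bad[1]],
           "' (row ", bad[1], "): '", v[bad[1]], "'")
    if (required && anyNA(out))
      stop("missing ", col, " in row ", which(is.na(out))[1])
    out
  }
  tb <- tibble::tibble(name = raw$name, lat = num("lat"), lon = num("lon"),
                       height_m = num("height_m"),
                       max_range_m = num("max_range_m", required = FALSE))
  tb <- validate_towers(tb)
  if (!is.null(dem)) tb <- attach_towers(tb, dem)
  tb
}

#' Project a tower table onto a DEM grid
#'
#' Adds `x`, `y` (tower position in the DEM CRS) and `in_extent` columns.
#'
#' @param tw a `tower_set` tibble.
#' @param dem a [dem_grid].
#' @return the augmented `tower_set`.
#' @export
attach_towers <- function(tw, dem) {
  p <- project_from_wgs84(tw$lat, tw$lon, dem$crs)
  e <- dem_extent(dem)
  tw$x <- p$x
  tw$y <- p$y
  tw$in_extent <- p$x >= e$xmin & p$x <= e$xmax & p$y >= e$ymin & p$y <= e$ymax
  if (any(!tw$in_extent))
    message("tower(s) outside the DEM extent: ",
            paste(tw$name[!tw$in_extent], collapse = ", "))
  tw
}

#' Write a tower table to CSV
#'
#' Inverse of [read_towers()]: extent-limited ranges are written as empty
#' fields.
#' @param tw a `tower_set` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_towers <- function(tw, path) {
  out <- data.frame(name = tw$name, lat = tw$lat, lon = tw$lon,
                    height_m = tw$height_m,
                    max_range_m = ifelse(is.na(tw$max_range_m), "",
                                         format(tw$max_range_m, scientific = FALSE,
                                                trim = TRUE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
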