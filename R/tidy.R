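# Tidiers and autoplot methods: every result type flattens to a tibble and
# draws itself with ggplot2, so results compose with dplyr pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.grid_xy <- function(x, mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  cx <- rep(x$xmin + (seq_len(nc) - 0.5) * x$xres, each = nr)
  cy <- rep(x$ymax - (seq_len(nr) - 0.5) * x$yres, times = nc)
  tibble::tibble(x = cx, y = cy)
}

#' Tidy a grid or raster into a long tibble
#'
#' One row per cell with the cell-center coordinates, ready for dplyr /
#' ggplot2.
#'
#' @param x a [dem_grid], `viewshed_raster`, `count_raster`, `mask_raster`
#'   or `los_result`.
#' @param ... unused.
#' @return a tibble with `x`, `y` and the object's per-cell values.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.dem_grid <- function(x, ...) {
  out <- .grid_xy(x, x$values)
  out$elevation_m <- as.vector(x$values)
  out
}

#' @rdname tidiers
#' @export
tidy.viewshed_raster <- function(x, ...) {
  out <- .grid_xy(x, x$visible)
  out$visible <- as.vector(x$visible)
  out$valid <- as.vector(x$valid)
  out
}

#' @rdname tidiers
#' @export
tidy.count_raster <- function(x, ...) {
  out <- .grid_xy(x, x$counts)
  out$n_towers <- as.vector(x$counts)
  out$valid <- as.vector(x$valid)
  out
}

#' @rdname tidiers
#' @export
tidy.mask_raster <- function(x, ...) {
  out <- .grid_xy(x, x$mask)
  out$in_mask <- as.vector(x$mask)
  out$valid <- as.vector(x$valid)
  out
}

#' @rdname tidiers
#' @export
tidy.los_result <- function(x, ...) tibble::as_tibble(x$profile)

#' One-row summary of a line-of-sight test
#' @param x a `los_result`.
#' @param ... unused.
#' @return tibble with `visible`, `valid`, `distance_m`,
#'   `blocking_distance_m`, `n_samples`.
#' @export
glance.los_result <- function(x, ...) {
  tibble::tibble(visible = x$visible, valid = x$valid,
                 distance_m = x$distance_m,
                 blocking_distance_m = x$blocking_distance_m,
                 n_samples = nrow(x$profile))
}

# ---- autoplot ---------------------------------------------------------------

#' @export
autoplot.dem_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$elevation_m)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "elevation (m)", na.value = "grey20") +
    ggplot2::coord_fixed() + ggplot2::theme_minimal()
}

#' @export
autoplot.viewshed_raster <- function(object, ...) {
  d <- tidy(object)
  d$state <- ifelse(!d$valid, "invalid", ifelse(d$visible, "visible", "hidden"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(visible = "#2b8cbe", hidden = "#f7fbff",
                                          invalid = "black"), name = NULL) +
    ggplot2::coord_fixed() + ggplot2::theme_minimal() +
    ggplot2::ggtitle(sprintf("tower %s, target %+g m", object$tower_name,
                             object$target_height_m))
}

#' @export
autoplot.count_raster <- function(object, ...) {
  d <- tidy(object)
  d$n_towers[!d$valid] <- NA
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$n_towers)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#deebf7", high = "#08306b",
                                 na.value = "black", name = "towers",
                                 limits = c(0, object$n_selected)) +
    ggplot2::coord_fixed() + ggplot2::theme_minimal()
}

#' @export
autoplot.mask_raster <- function(object, ...) {
  d <- tidy(object)
  d$state <- ifelse(!d$valid, "invalid", ifelse(d$in_mask, "in mask", "out"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`in mask` = "#ffd92f", out = "grey95",
                                          invalid = "black"), name = NULL) +
    ggplot2::coord_fixed() + ggplot2::theme_minimal()
}

#' @export
autoplot.los_result <- function(object, ...) {
  p <- object$profile
  long <- tibble::tibble(
    distance_m = rep(p$distance_m, 3),
    elevation_m = c(p$terrain_m, p$terrain_curved_m, p$sightline_m),
    line = rep(c("terrain", "terrain (curved model)", "sight line"),
               each = nrow(p)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance_m, y = .data$elevation_m,
                                     colour = .data$line)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(
      terrain = "black", `terrain (curved model)` = "#2171b5",
      `sight line` = if (isTRUE(object$visible)) "#31a354" else "#756bb1")) +
    ggplot2::labs(x = "distance from observer (m)", y = "elevation (m)",
                  colour = NULL,
                  title = if (!object$valid) "invalid (missing data)"
                          else if (object$visible) "visible"
                          else sprintf("blocked at %.0f m", object$blocking_distance_m)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.elevation_profile <- function(object, ...) {
  long <- tibble::tibble(
    distance_m = rep(object$distance_m, 2),
    elevation_m = c(object$terrain_m, object$terrain_curved_m),
    line = rep(c("terrain", "terrain (curved model)"), each = nrow(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance_m, y = .data$elevation_m,
                                     colour = .data$line)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(terrain = "black",
                                            `terrain (curved model)` = "#2171b5")) +
    ggplot2::labs(x = "distance (m)", y = "elevation (m)", colour = NULL) +
    ggplot2::theme_minimal()
}
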