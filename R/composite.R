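# Cumulative and subtractive viewshed algebra over a precalculated set.
#
# Pure Boolean/set algebra on aligned rasters: cumulative coverage is
# element-wise summation of the selected towers' Boolean grids, subtractive
# coverage is AND over the viewing towers and NOT OR over the obstructed
# ones. A cell invalid in any participating raster is invalid in the
# output (conservative: islet shadows persist through composites).

.select_names <- function(set, selected) {
  avail <- names(set$rasters)
  if (length(selected) == 1L && identical(selected, "all")) return(avail)
  unknown <- setdiff(selected, avail)
  if (length(unknown) > 0L)
    stop("unknown tower name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  selected
}

#' Cumulative viewshed: how many selected towers see each cell
#'
#' @param set a `precalc_set` from [precalculate_set()] / [load_set()].
#' @param selected character vector of tower names, or `"all"`.
#' @return a `count_raster`: list with integer matrix `counts`
#'   (0..`n_selected`), logical `valid`, `n_selected`, `tower_names`, and
#'   the grid georeference.
#' @export
cumulative_viewshed <- function(set, selected = "all") {
  if (length(selected) == 0L) stop("no towers selected")
  sel <- .select_names(set, selected)
  if (length(sel) == 0L) stop("no towers selected")
  rs <- set$rasters[sel]
  counts <- Reduce(`+`, lapply(rs, function(r) r$visible + 0L))
  valid <- Reduce(`&`, lapply(rs, function(r) r$valid))
  g <- rs[[1]]
  structure(list(counts = counts, valid = valid, n_selected = length(sel),
                 tower_names = sel, xmin = g$xmin, ymax = g$ymax,
                 xres = g$xres, yres = g$yres, crs = g$crs),
            class = "count_raster")
}

#' Subtractive viewshed: seen by all viewing towers, by no obstructed one
#'
#' @param set a `precalc_set`.
#' @param viewing tower names the target must be visible from (all of
#'   them); `"all"` selects every tower.
#' @param obstructed tower names the target must be hidden from (every one
#'   of them); may be empty, in which case the result is the intersection
#'   of the viewing viewsheds.
#' @return a `mask_raster`: list with logical matrices `mask` and `valid`,
#'   the two name lists, and the grid georeference.
#' @export
subtractive_viewshed <- function(set, viewing, obstructed = character()) {
  if (length(viewing) == 0L) stop("no viewing towers selected")
  viewing <- .select_names(set, viewing)
  if (length(obstructed) > 0L) obstructed <- .select_names(set, obstructed)
  both <- intersect(viewing, obstructed)
  if (length(both) > 0L)
    stop("tower(s) named as both viewing and obstructed: ",
         paste(both, collapse = ", "))
  rv <- set$rasters[viewing]
  ro <- set$rasters[obstructed]
  mask <- Reduce(`&`, lapply(rv, function(r) r$visible))
  if (length(ro) > 0L)
    mask <- mask & !Reduce(`|`, lapply(ro, function(r) r$visible))
  valid <- Reduce(`&`, lapply(c(rv, ro), function(r) r$valid))
  g <- rv[[1]]
  structure(list(mask = mask & valid, valid = valid,
                 viewing_names = viewing, obstructed_names = obstructed,
                 xmin = g$xmin, ymax = g$ymax, xres = g$xres, yres = g$yres,
                 crs = g$crs),
            class = "mask_raster")
}

#' @export
print.count_raster <- function(x, ...) {
  cat(sprintf("<count_raster> %d towers (%s)\n", x$n_selected,
              paste(x$tower_names, collapse = ", ")))
  cat(sprintf("  counts 0..%d over %d x %d cells, %d invalid\n",
              max(x$counts[x$valid], 0), nrow(x$counts), ncol(x$counts),
              sum(!x$valid)))
  invisible(x)
}

#' @export
print.mask_raster <- function(x, ...) {
  cat(sprintf("<mask_raster> viewing {%s} \\ obstructed {%s}\n",
              paste(x$viewing_names, collapse = ", "),
              paste(x$obstructed_names, collapse = ", ")))
  cat(sprintf("  %d cells in mask, %d invalid\n", sum(x$mask), sum(!x$valid)))
  invisible(x)
}
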