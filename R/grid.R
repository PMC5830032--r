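#' Regular raster grid
#'
#' A light container for a co-registered raster layer: a numeric matrix of
#' cell values (row-major, 0-based addressing in the on-disk format; cell
#' `[1, 1]` is the north-west corner), a cell edge length in km, and a
#' per-row latitude vector in decimal degrees. `NA` cells are nodata.
#'
#' Latitude is carried per row rather than through a projection: the
#' latitudinal-range indicator needs latitude only, and all grids in a
#' landscape share one regular lattice.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_km cell edge length, km (> 0).
#' @param row_latitudes latitudes of row centres, decimal degrees, length
#'   `nrow(values)`. Defaults to a 0-centred ramp of `cell_km / 111.32`
#'   degrees per row, northernmost row first.
#' @param units free-text unit label (m, degC, mm, degrees, id, ...).
#'
#' @return An object of class `pa_grid`.
#' @examples
#' g <- pa_grid(matrix(1:9, 3, 3), cell_km = 1)
#' grid_dim(g)
#' @export
pa_grid <- function(values, cell_km = 1, row_latitudes = NULL, units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_km) || length(cell_km) != 1L || !is.finite(cell_km) ||
      cell_km <= 0) {
    stop("`cell_km` must be a single positive number", call. = FALSE)
  }
  if (is.null(row_latitudes)) {
    n <- nrow(values)
    deg_per_row <- cell_km / 111.32
    row_latitudes <- (seq_len(n) - (n + 1) / 2) * -deg_per_row
  }
  if (length(row_latitudes) != nrow(values)) {
    stop("`row_latitudes` must have one entry per row", call. = FALSE)
  }
  structure(
    list(values = values, cell_km = cell_km,
         row_latitudes = as.double(row_latitudes), units = units),
    class = "pa_grid"
  )
}

#' @export
print.pa_grid <- function(x, ...) {
  v <- x$values
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("<pa_grid> %d x %d cells, %.3g km cells%s\n",
              nrow(v), ncol(v), x$cell_km,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  cat(sprintf("  values: %s .. %s (%d nodata)\n",
              format(rng[1]), format(rng[2]), sum(is.na(v))))
  cat(sprintf("  latitudes: %.4f .. %.4f deg\n",
              min(x$row_latitudes), max(x$row_latitudes)))
  invisible(x)
}

#' @export
dim.pa_grid <- function(x) dim(x$values)

#' Grid dimensions
#' @param grid a [pa_grid()].
#' @return Integer vector `c(n_rows, n_cols)`.
#' @export
grid_dim <- function(grid) dim(grid$values)

#' Check that grids share one lattice
#'
#' All moving-window and indicator computations require their input layers to
#' be co-registered: same shape, same cell size, same row latitudes.
#'
#' @param ... two or more [pa_grid()] objects.
#' @return Invisibly `TRUE`; errors with a co-registration message otherwise.
#' @export
check_coregistered <- function(...) {
  gs <- list(...)
  gs <- gs[!vapply(gs, is.null, logical(1))]
  if (length(gs) < 2L) return(invisible(TRUE))
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(g$cell_km, ref$cell_km)) ||
        !isTRUE(all.equal(g$row_latitudes, ref$row_latitudes))) {
      stop("grids are not co-registered (shape, cell size and row latitudes ",
           "must match)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Latitude surface of a grid
#'
#' Expands the per-row latitude vector to a full grid layer, for use as the
#' value layer of the latitudinal-range indicator.
#'
#' @param grid a [pa_grid()].
#' @return A `pa_grid` whose cell values are row latitudes in degrees.
#' @export
latitude_grid <- function(grid) {
  v <- matrix(grid$row_latitudes, nrow = nrow(grid$values),
              ncol = ncol(grid$values))
  pa_grid(v, cell_km = grid$cell_km, row_latitudes = grid$row_latitudes,
          units = "degrees")
}

#' @importFrom tibble as_tibble
#' @method as_tibble pa_grid
#' @export
as_tibble.pa_grid <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    latitude = rep(x$row_latitudes, times = ncol(v)),
    value = as.vector(v)
  )
}

#' Plot a grid layer
#'
#' @param object a [pa_grid()].
#' @param title optional plot title.
#' @param ... unused.
#' @return A ggplot object (tile map, north up).
#' @importFrom ggplot2 autoplot
#' @method autoplot pa_grid
#' @export
autoplot.pa_grid <- function(object, title = NULL, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = object$units) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
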