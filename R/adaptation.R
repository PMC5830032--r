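#' Max-normalize an indicator surface
#'
#' Divides a non-negative indicator by its global maximum over all computed
#' (non-nodata) focal cells, so values range from 0 (little to no adaptation
#' potential) to 1 (highest on the grid). With `invert = TRUE` the scale is
#' flipped to `1 - value/max`, used for climate-area velocity so all five
#' indicators point the same way (higher = better for adaptation).
#' Normalization is idempotent: a layer whose maximum is already 1 is
#' unchanged.
#'
#' @param grid indicator [pa_grid()], non-negative, with a positive finite
#'   maximum.
#' @param invert flip the scale after normalizing.
#' @return A dimensionless [pa_grid()] in `[0, 1]`.
#' @export
normalize_indicator <- function(grid, invert = FALSE) {
  stopifnot(inherits(grid, "pa_grid"))
  mx <- suppressWarnings(max(grid$values, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    stop("indicator grid has no positive finite maximum to normalize by",
         call. = FALSE)
  }
  out <- grid
  out$values <- grid$values / mx
  if (invert) out$values <- 1 - out$values
  out$units <- ""
  out
}

#' Combine indicators into an adaptation-potential surface
#'
#' Max-normalizes each indicator and averages them cell-wise into a single
#' `[0, 1]` climate-change adaptation potential. The two velocity layers
#' (temperature and precipitation) are first averaged into one velocity
#' indicator so exactly five indicators enter the mean, and velocity is
#' inverted after normalization so low velocity (an easily retained climate
#' space) scores high. Nodata in any layer propagates to the output.
#'
#' @param iset an `indicator_set` from [run_scenario()].
#' @param velocity `"merged"` (default) averages the two velocity layers
#'   into one indicator before inversion; `"split"` keeps them separate and
#'   averages six normalized layers instead.
#' @return An object of class `adaptation_potential` wrapping the potential
#'   [pa_grid()].
#' @export
combine_potential <- function(iset, velocity = c("merged", "split")) {
  stopifnot(inherits(iset, "indicator_set"))
  velocity <- match.arg(velocity)
  pos <- lapply(c("area_A", "relief_hydro_H", "lat_range_L", "elev_range_E"),
                function(nm) normalize_indicator(iset[[nm]]))
  if (velocity == "merged") {
    vmerge <- iset$velocity_T
    vmerge$values <- (iset$velocity_T$values + iset$velocity_P$values) / 2
    layers <- c(pos, list(normalize_indicator(vmerge, invert = TRUE)))
  } else {
    layers <- c(pos,
                list(normalize_indicator(iset$velocity_T, invert = TRUE),
                     normalize_indicator(iset$velocity_P, invert = TRUE)))
  }
  if (!length(layers)) stop("no layers to combine", call. = FALSE)
  acc <- layers[[1]]$values * 0
  for (l in layers) acc <- acc + l$values  # NA propagates
  g <- layers[[1]]
  g$values <- acc / length(layers)
  g$units <- "potential"
  structure(list(potential = g, n_layers = length(layers),
                 velocity = velocity, mode = iset$mode,
                 radius_km = iset$radius_km),
            class = "adaptation_potential")
}

#' @export
print.adaptation_potential <- function(x, ...) {
  v <- x$potential$values
  cat(sprintf(
    "<adaptation_potential> %s, r = %s km (%d layers, velocity %s)\n",
    x$mode, format(x$radius_km %||% NA), x$n_layers, x$velocity))
  cat(sprintf("  mean %.3f over %d cells (range %.3f .. %.3f)\n",
              mean(v, na.rm = TRUE), sum(!is.na(v)),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @rdname combine_potential
#' @param object an `adaptation_potential`.
#' @param ... unused.
#' @method autoplot adaptation_potential
#' @export
autoplot.adaptation_potential <- function(object, ...) {
  autoplot(object$potential,
           title = sprintf("Adaptation potential (%s)", object$mode))
}

#' @method glance adaptation_potential
#' @export
glance.adaptation_potential <- function(x, ...) {
  v <- as.vector(x$potential$values)
  tibble::tibble(mode = x$mode, radius_km = x$radius_km %||% NA_real_,
                 n_layers = x$n_layers,
                 mean = mean(v, na.rm = TRUE),
                 min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
                 n_cells = sum(!is.na(v)))
}

#' Zonal means of adaptation potential
#'
#' Averages a potential surface within each zone of a zone map (biomes,
#' ecoregions), reporting zones with no valid cells as flagged empty rows
#' rather than dropping them.
#'
#' @param potential an `adaptation_potential` or a bare [pa_grid()].
#' @param zones a [zone_map()].
#' @return A tibble: `zone_id`, `label`, `mean`, `n_cells`, `empty`.
#' @export
zonal_mean <- function(potential, zones) {
  stopifnot(inherits(zones, "zone_map"))
  g <- if (inherits(potential, "adaptation_potential")) potential$potential
       else potential
  stopifnot(inherits(g, "pa_grid"))
  check_coregistered(g, zones$zones)
  ids <- zones$zones$values
  purrr::map_dfr(seq_len(nrow(zones$labels)), function(i) {
    id <- zones$labels$zone_id[i]
    v <- g$values[!is.na(ids) & ids == id]
    v <- v[!is.na(v)]
    tibble::tibble(zone_id = id, label = zones$labels$label[i],
                   mean = if (length(v)) mean(v) else NA_real_,
                   n_cells = length(v), empty = length(v) == 0L)
  })
}

#' @method tidy adaptation_potential
#' @export
tidy.adaptation_potential <- function(x, zones = NULL, ...) {
  if (is.null(zones)) glance(x) else zonal_mean(x, zones)
}
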