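#' Land and freshwater area within the partnership window
#'
#' Tallies the qualifying target cells (PA or non-PA, per the scenario's
#' target mask) in each circular window and multiplies by the cell area, so
#' A is the total area, km^2, available to the focal cell at that partnership
#' scale. Windows with no qualifying cell are nodata.
#'
#' @param target logical matrix or 0/1 [pa_grid()] of potential partner
#'   cells.
#' @param kernel a [build_kernel()] kernel.
#' @param template a [pa_grid()] supplying lattice geometry when `target` is
#'   a bare matrix.
#' @return A [pa_grid()] of areas, km^2.
#' @export
compute_area <- function(target, kernel, template = NULL) {
  g <- target_as_grid(target, template)
  cnt <- focal_stat(g, kernel, target = g, stat = "count")
  cnt$values <- cnt$values * g$cell_km^2
  cnt$units <- "km^2"
  cnt
}

target_as_grid <- function(target, template = NULL) {
  if (inherits(target, "pa_grid")) return(target)
  if (is.null(template)) {
    stop("a bare target matrix needs a `template` grid for geometry",
         call. = FALSE)
  }
  pa_grid(target + 0, cell_km = template$cell_km,
          row_latitudes = template$row_latitudes)
}

#' Latitudinal range within the partnership window
#'
#' Maximum minus minimum latitude (degrees) of the qualifying target cells,
#' irrespective of longitude. Captures the pole-ward breadth a partnership
#' offers to species shifting their ranges in latitude.
#'
#' @param latitudes a latitude [pa_grid()] (see [latitude_grid()]).
#' @inheritParams compute_area
#' @return A [pa_grid()] of ranges, degrees (0 for single-cell windows).
#' @export
compute_lat_range <- function(latitudes, target, kernel) {
  st <- focal_stat(latitudes, kernel, target = target, stat = c("max", "min"))
  out <- st$max
  out$values <- st$max$values - st$min$values
  out$units <- "degrees"
  out
}

#' Elevational range within the partnership window
#'
#' Maximum minus minimum (mean cell) elevation of qualifying target cells, m.
#'
#' @param elevation elevation [pa_grid()], m.
#' @inheritParams compute_area
#' @return A [pa_grid()] of ranges, m.
#' @export
compute_elev_range <- function(elevation, target, kernel) {
  st <- focal_stat(elevation, kernel, target = target, stat = c("max", "min"))
  out <- st$max
  out$values <- st$max$values - st$min$values
  out$units <- "m"
  out
}

#' Relief-weighted hydrologic area within the partnership window
#'
#' For each qualifying target cell that also lies on the hydrologic network,
#' takes its elevation above the minimum elevation over *all* qualifying
#' target cells in the window, and sums these reliefs:
#' `H = sum_i (e_i - min(e))` over network cells i. The relief is treated as
#' a dimensionless weight multiplying cell area, so H carries units of km^2
#' and reads as valley-bottom area weighted by available elevational relief.
#' Windows with qualifying target cells but no network cells give 0; windows
#' with no qualifying cells at all are nodata.
#'
#' @param elevation elevation [pa_grid()], m.
#' @param hydro 0/1 hydrologic-network [pa_grid()] or logical matrix.
#' @inheritParams compute_area
#' @return A [pa_grid()], km^2.
#' @export
compute_relief_hydro <- function(elevation, hydro, target, kernel) {
  tmask <- as_mask(target)
  hmask <- as_mask(hydro) & tmask
  # window minimum over ALL qualifying target cells (not only network cells)
  mn <- focal_stat(elevation, kernel, target = tmask, stat = "min")
  # accumulate sum of (e_i - min) over network cells, one kernel offset at a
  # time, so evaluation order matches a per-window sequential sum exactly
  mv <- elevation$values
  mv[!hmask | is.na(mv)] <- NA_real_
  h <- matrix(0, nrow(mv), ncol(mv))
  offs <- kernel$offsets
  for (k in seq_len(nrow(offs))) {
    sv <- shift_matrix(mv, offs[k, 1L], offs[k, 2L])
    qa <- !is.na(sv)
    h <- h + ifelse(qa, sv - mn$values, 0)
  }
  # windows with no qualifying target cells at all stay nodata; windows with
  # target cells but no network cells read 0
  h[is.na(mn$values)] <- NA_real_
  h <- h * elevation$cell_km^2
  out <- mn
  out$values <- h
  out$units <- "km^2"
  out
}

as_mask <- function(x) {
  if (inherits(x, "pa_grid")) !is.na(x$values) & x$values != 0
  else if (is.logical(x)) x
  else !is.na(x) & x != 0
}

#' Climate-area velocity within the partnership window
#'
#' The climate-area velocity V is the absolute window-mean rate of climate
#' change divided by the spatial standard deviation of the baseline climate
#' across the window's qualifying target cells:
#' `V = |mean((future - now) / dt)| / (sd(now) + c)`, with a small floor
#' constant `c` (default 0.1) added to the denominator to avoid division by
#' zero, so the no-partnering limit (a single cell, sd = 0) is the continuous
#' limit of the general formula. Units are 1/yr, read as the factor per year
#' by which partnership area must grow to retain the current climate space.
#' Spatially variable baseline climate (a large denominator) makes climate
#' change locally absorbable and V small.
#'
#' @param now,future baseline and future climate [pa_grid()]s, same units
#'   (degC or mm).
#' @param years_elapsed interval between the two surfaces, years (> 0).
#' @param floor_constant denominator floor, same units as `now` (default
#'   0.1).
#' @inheritParams compute_area
#' @return A [pa_grid()], 1/yr (non-negative).
#' @export
compute_climate_area_velocity <- function(now, future, years_elapsed,
                                          target, kernel,
                                          floor_constant = 0.1) {
  stopifnot(inherits(now, "pa_grid"), inherits(future, "pa_grid"))
  check_coregistered(now, future)
  if (!is.numeric(years_elapsed) || years_elapsed <= 0) {
    stop("`years_elapsed` must be positive", call. = FALSE)
  }
  rate <- now
  rate$values <- (future$values - now$values) / years_elapsed
  num <- focal_stat(rate, kernel, target = target, stat = "mean")
  den <- focal_stat(now, kernel, target = target, stat = "sd")
  out <- num
  out$values <- abs(num$values) / (den$values + floor_constant)
  out$units <- "1/yr"
  out
}

#' Simulate retention of the current climate space
#'
#' Monte-Carlo illustration of what a climate-area velocity of a given size
#' means: draw `n` baseline values from Normal(0, sd) and `n` future values
#' from Normal(mean_shift, sd), and compute the fraction of future draws that
#' still fall inside the observed range of the baseline sample. The
#' reciprocal of that retention is the factor by which area would have to
#' grow to recover the full current climate space; adding 1 expresses it as
#' growth on top of the current area.
#'
#' @param mean_shift mean climate change between the two samples (same units
#'   as `sd`).
#' @param sd spatial standard deviation of climate (> 0).
#' @param n sample size (>= 2).
#' @param seed optional integer seed.
#' @return A one-row tibble: `retention` in `[0, 1]`, `area_factor`
#'   (`1 / retention`, `Inf` when retention is 0), and
#'   `area_factor_adjusted` (`area_factor + 1`, accounting for the current
#'   climate space).
#' @examples
#' simulate_climate_space_retention(1, 1, n = 1000, seed = 1)
#' @export
simulate_climate_space_retention <- function(mean_shift, sd, n = 1000,
                                             seed = NULL) {
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cur <- stats::rnorm(n, 0, sd)
  fut <- stats::rnorm(n, mean_shift, sd)
  retention <- sum(fut >= min(cur) & fut <= max(cur)) / n
  tibble::tibble(
    mean_shift = mean_shift, sd = sd, n = as.integer(n),
    retention = retention,
    area_factor = if (retention > 0) 1 / retention else Inf,
    area_factor_adjusted = if (retention > 0) 1 / retention + 1 else Inf
  )
}
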