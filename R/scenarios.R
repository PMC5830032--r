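#' Run a partnership scenario on a landscape
#'
#' Computes the full indicator set (A, L, E, H, and climate-area velocity for
#' temperature and precipitation) for one scenario:
#'
#' * `pa_partnership` — focal cells are PA cells; potential partners are PA
#'   cells within radius `radius_km` (partnering only with other protected
#'   land).
#' * `pa_nonpa_partnership` — focal cells are PA cells; partners are *all*
#'   land cells within the radius (the idealized scenario ignoring
#'   socio-political boundaries).
#' * `pixel_null` — no partnering: every cell acts alone (radius 0), so
#'   A equals one cell area, L = E = H = 0, and V is the local rate divided
#'   by the denominator floor.
#' * `pa_null` — partnering only within each administratively distinct PA:
#'   each indicator is computed once over all cells of each PA id and
#'   broadcast to that PA's cells.
#'
#' @param landscape a [synthetic_landscape()] or equivalent `pa_landscape`
#'   list (elevation, hydro, pa_ids, the four climate grids,
#'   `years_elapsed`).
#' @param mode one of `"pixel_null"`, `"pa_null"`, `"pa_partnership"`,
#'   `"pa_nonpa_partnership"`.
#' @param radius_km partnership radius, km (> 0; ignored by the null modes).
#' @param focal `"pa"` (default) restricts computed focal cells to PA cells,
#'   the "what does my PA gain" framing used for scenario means; `"all"`
#'   computes every land cell, for map products.
#' @param floor_constant velocity denominator floor (default 0.1).
#' @return An object of class `indicator_set`: grids `area_A`,
#'   `lat_range_L`, `elev_range_E`, `relief_hydro_H`, `velocity_T`,
#'   `velocity_P`, plus `mode`, `radius_km`, `focal`, `floor_constant`,
#'   `years_elapsed`.
#' @examples
#' ls <- synthetic_landscape(landscape_params(n_rows = 32, n_cols = 32,
#'                                            n_pas = 3, seed = 2))
#' iset <- run_scenario(ls, "pa_partnership", radius_km = 3)
#' tidy(iset)
#' @export
run_scenario <- function(landscape, mode = c("pa_partnership",
                                             "pa_nonpa_partnership",
                                             "pixel_null", "pa_null"),
                         radius_km = NULL, focal = c("pa", "all"),
                         floor_constant = 0.1) {
  mode <- match.arg(mode)
  focal <- match.arg(focal)
  elev <- landscape$elevation
  pa_mask <- landscape$pa_ids$values > 0
  if (mode %in% c("pa_partnership", "pa_nonpa_partnership", "pa_null") &&
      !any(pa_mask)) {
    stop("landscape has no PA cells; a PA-focal mode has an empty domain",
         call. = FALSE)
  }
  dt <- landscape$years_elapsed
  meta <- list(mode = mode, radius_km = radius_km, focal = focal,
               floor_constant = floor_constant, years_elapsed = dt)

  if (mode == "pixel_null") {
    grids <- pixel_null_indicators(landscape, floor_constant)
  } else if (mode == "pa_null") {
    grids <- pa_null_indicators(landscape, floor_constant)
    meta$radius_km <- NULL
  } else {
    if (is.null(radius_km) || radius_km <= 0) {
      stop("partnership modes need `radius_km` > 0", call. = FALSE)
    }
    kern <- build_kernel(radius_km, elev$cell_km)
    target <- if (mode == "pa_partnership") pa_mask else !is.na(elev$values)
    grids <- list(
      area_A = compute_area(target, kern, template = elev),
      lat_range_L = compute_lat_range(latitude_grid(elev), target, kern),
      elev_range_E = compute_elev_range(elev, target, kern),
      relief_hydro_H = compute_relief_hydro(elev, landscape$hydro, target, kern),
      velocity_T = compute_climate_area_velocity(
        landscape$temp_now, landscape$temp_future, dt, target, kern,
        floor_constant),
      velocity_P = compute_climate_area_velocity(
        landscape$precip_now, landscape$precip_future, dt, target, kern,
        floor_constant)
    )
  }
  if (focal == "pa") {
    grids <- lapply(grids, function(g) {
      g$values[!pa_mask] <- NA_real_
      g
    })
  }
  structure(c(grids, meta), class = "indicator_set")
}

pixel_null_indicators <- function(landscape, floor_constant) {
  elev <- landscape$elevation
  land <- !is.na(elev$values)
  dt <- landscape$years_elapsed
  const <- function(x, u) {
    m <- matrix(x, nrow(elev$values), ncol(elev$values))
    m[!land] <- NA_real_
    pa_grid(m, elev$cell_km, elev$row_latitudes, units = u)
  }
  vel <- function(now, fut) {
    v <- abs((fut$values - now$values) / dt) / floor_constant
    v[!land] <- NA_real_
    pa_grid(v, elev$cell_km, elev$row_latitudes, units = "1/yr")
  }
  list(area_A = const(elev$cell_km^2, "km^2"),
       lat_range_L = const(0, "degrees"),
       elev_range_E = const(0, "m"),
       relief_hydro_H = const(0, "km^2"),
       velocity_T = vel(landscape$temp_now, landscape$temp_future),
       velocity_P = vel(landscape$precip_now, landscape$precip_future))
}

pa_null_indicators <- function(landscape, floor_constant) {
  elev <- landscape$elevation
  ids <- landscape$pa_ids$values
  dt <- landscape$years_elapsed
  hydro <- as_mask(landscape$hydro)
  latm <- matrix(elev$row_latitudes, nrow(elev$values), ncol(elev$values))
  rate_t <- (landscape$temp_future$values - landscape$temp_now$values) / dt
  rate_p <- (landscape$precip_future$values - landscape$precip_now$values) / dt
  blank <- matrix(NA_real_, nrow(elev$values), ncol(elev$values))
  out <- list(area_A = blank, lat_range_L = blank, elev_range_E = blank,
              relief_hydro_H = blank, velocity_T = blank, velocity_P = blank)
  pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  for (id in setdiff(unique(as.vector(ids)), c(0, NA))) {
    cells <- which(ids == id)
    e <- elev$values[cells]
    out$area_A[cells] <- length(cells) * elev$cell_km^2
    out$lat_range_L[cells] <- max(latm[cells]) - min(latm[cells])
    out$elev_range_E[cells] <- max(e) - min(e)
    hcells <- cells[hydro[cells]]
    out$relief_hydro_H[cells] <-
      sum(elev$values[hcells] - min(e)) * elev$cell_km^2
    out$velocity_T[cells] <-
      abs(mean(rate_t[cells])) / (pop_sd(landscape$temp_now$values[cells]) +
                                    floor_constant)
    out$velocity_P[cells] <-
      abs(mean(rate_p[cells])) / (pop_sd(landscape$precip_now$values[cells]) +
                                    floor_constant)
  }
  units <- c(area_A = "km^2", lat_range_L = "degrees", elev_range_E = "m",
             relief_hydro_H = "km^2", velocity_T = "1/yr", velocity_P = "1/yr")
  Map(function(m, u) pa_grid(m, elev$cell_km, elev$row_latitudes, units = u),
      out, units[names(out)])
}

indicator_names <- function() {
  c("area_A", "lat_range_L", "elev_range_E", "relief_hydro_H",
    "velocity_T", "velocity_P")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set> mode = %s%s, focal = %s\n", x$mode,
              if (!is.null(x$radius_km)) sprintf(", r = %g km", x$radius_km)
              else "", x$focal))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize an indicator set
#'
#' `tidy()` gives one row per indicator with its mean, s.d. and valid-cell
#' count over computed focal cells (nodata excluded); `glance()` gives a
#' one-row scenario summary with indicator means in columns.
#'
#' @param x an `indicator_set` from [run_scenario()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy indicator_set
#' @export
tidy.indicator_set <- function(x, ...) {
  purrr::map_dfr(indicator_names(), function(nm) {
    v <- as.vector(x[[nm]]$values)
    v <- v[!is.na(v)]
    tibble::tibble(indicator = nm, units = x[[nm]]$units,
                   mean = mean(v), sd = stats::sd(v), n_cells = length(v))
  }) |>
    dplyr::mutate(mode = x$mode,
                  radius_km = x$radius_km %||% NA_real_,
                  .before = 1L)
}

#' @rdname tidy.indicator_set
#' @method glance indicator_set
#' @export
glance.indicator_set <- function(x, ...) {
  tidy(x) |>
    dplyr::select("mode", "radius_km", "indicator", "mean") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "mean")
}

#' Plot an indicator set
#'
#' @param object an `indicator_set`.
#' @param ... unused.
#' @return A faceted ggplot of the six indicator surfaces (each rescaled to
#'   `[0, 1]` so one fill scale serves all panels).
#' @method autoplot indicator_set
#' @export
autoplot.indicator_set <- function(object, ...) {
  df <- purrr::map_dfr(indicator_names(), function(nm) {
    d <- as_tibble(object[[nm]])
    rng <- range(d$value, na.rm = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    d$value <- (d$value - rng[1]) / span
    d$indicator <- nm
    d
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~indicator) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled") +
    ggplot2::theme_minimal()
}

#' Scenario comparison factor
#'
#' Expresses the ratio of two scenario means as a signed factor: ratios >= 1
#' are reported as-is (a factor increase), ratios below 1 as the negative
#' reciprocal (a decrease by x prints as -x), so `|value| >= 1` always.
#'
#' @param mean_a,mean_b positive scenario means (numerator, denominator).
#' @return The signed factor (length follows the inputs).
#' @examples
#' comparison_factor(2, 1)    # +2
#' comparison_factor(0.4, 0.6)  # -1.5
#' @export
comparison_factor <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a)) || any(!is.finite(mean_b)) ||
      any(mean_a <= 0) || any(mean_b <= 0)) {
    stop("comparison factors need positive finite means", call. = FALSE)
  }
  ratio <- mean_a / mean_b
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Compare partnership scenarios against the null models
#'
#' Runs the requested scenario pairs at one partnership radius and reports
#' the factor increase or decrease of every indicator mean, the form of the
#' scenario-comparison table (positive factors favour adaptation for A, H,
#' L, E; a negative factor, i.e. a decrease, favours it for velocity).
#' Means are taken over PA focal cells, nodata excluded.
#'
#' @inheritParams run_scenario
#' @param pairs list of 2-vectors `c(numerator_mode, denominator_mode)`;
#'   default the five standard comparisons.
#' @return A tibble: `numerator`, `denominator`, `indicator`, `factor`.
#' @export
compare_scenarios <- function(landscape, radius_km,
                              pairs = list(
                                c("pa_null", "pixel_null"),
                                c("pa_partnership", "pixel_null"),
                                c("pa_partnership", "pa_null"),
                                c("pa_nonpa_partnership", "pixel_null"),
                                c("pa_nonpa_partnership", "pa_null")),
                              floor_constant = 0.1) {
  modes <- unique(unlist(pairs))
  runs <- purrr::map(rlang::set_names(modes), function(m) {
    glance(run_scenario(landscape, m, radius_km = radius_km,
                        floor_constant = floor_constant))
  })
  purrr::map_dfr(pairs, function(pr) {
    a <- unlist(runs[[pr[1]]][indicator_names()])
    b <- unlist(runs[[pr[2]]][indicator_names()])
    # a zero mean (e.g. ranges under the pixel-null model) leaves the ratio
    # undefined; report NA rather than a fabricated factor
    ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    fac <- rep(NA_real_, length(a))
    fac[ok] <- comparison_factor(a[ok], b[ok])
    tibble::tibble(
      numerator = pr[1], denominator = pr[2], radius_km = radius_km,
      indicator = indicator_names(), factor = fac
    )
  })
}

#' Partner composition: how much of the partnership area is protected?
#'
#' For every focal land cell, the percentage of the window's land cells that
#' are PA cells — who a cell would actually be partnering with at this scale.
#' Summaries are reported separately for PA and non-PA focal cells: the mean
#' percentage, and the share of cells whose window is majority-PA (> 50%),
#' the area-under-curve style summary. Values near 100 mean PAs dominate the
#' available partners; values near 0 mean partnerships must be built mostly
#' with non-protected land.
#'
#' @param pa_mask 0/1 [pa_grid()] (or logical matrix with `template`) of PA
#'   cells.
#' @param kernel a [build_kernel()] kernel.
#' @param template geometry template when `pa_mask` is a bare matrix.
#' @return A list of class `partner_composition`: `percent_pa` (a
#'   [pa_grid()], `[0, 100]`) and `summary`, a tibble with rows for focal
#'   classes `"pa"` and `"non_pa"`: `mean_pct`, `pct_gt50`, `n_cells`.
#'   Cells with empty windows are excluded from summaries.
#' @export
partner_composition <- function(pa_mask, kernel, template = NULL) {
  g <- target_as_grid(pa_mask, template)
  land <- !is.na(g$values)
  pa <- land & g$values != 0
  ones <- g
  ones$values <- land + 0
  ones$values[!land] <- NA_real_
  n_land <- focal_stat(ones, kernel, target = land, stat = "count")
  n_pa <- focal_stat(ones, kernel, target = pa, stat = "count")
  pct <- n_land
  npa <- n_pa$values
  npa[is.na(npa) & !is.na(n_land$values)] <- 0  # window has land, no PAs
  pct$values <- 100 * npa / n_land$values
  pct$units <- "%"
  summarize_class <- function(mask, label) {
    v <- pct$values[mask & land]
    v <- v[!is.na(v)]
    tibble::tibble(focal_class = label,
                   mean_pct = if (length(v)) mean(v) else NA_real_,
                   pct_gt50 = if (length(v)) 100 * mean(v > 50) else NA_real_,
                   n_cells = length(v))
  }
  structure(list(
    percent_pa = pct,
    summary = dplyr::bind_rows(summarize_class(pa, "pa"),
                               summarize_class(land & !pa, "non_pa"))
  ), class = "partner_composition")
}

#' @export
print.partner_composition <- function(x, ...) {
  cat("<partner_composition>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy partner_composition
#' @export
tidy.partner_composition <- function(x, ...) x$summary

#' Percentiles of established partnership sizes
#'
#' The 5th, 50th (median) and 95th percentiles of a table of established
#' partnership areas, by linear interpolation of the sorted values, the
#' scales used to anchor the moving-window radii.
#'
#' @param table tibble/data frame with an `area_km2` column, or a bare
#'   numeric vector of areas (km^2); must be non-empty, all positive.
#' @return A tibble: `percentile` (5, 50, 95) and `area_km2`.
#' @export
partnership_percentiles <- function(table) {
  areas <- if (is.data.frame(table)) table$area_km2 else as.numeric(table)
  if (length(areas) == 0 || anyNA(areas)) {
    stop("partnership size table must be non-empty with no missing areas",
         call. = FALSE)
  }
  if (any(areas <= 0)) stop("partnership areas must be positive", call. = FALSE)
  q <- stats::quantile(areas, probs = c(0.05, 0.5, 0.95), names = FALSE,
                       type = 7)
  tibble::tibble(percentile = c(5, 50, 95), area_km2 = q)
}

#' Equivalent circular radius of an area
#'
#' Converts a partnership area to the radius of the circle of equal area,
#' `sqrt(area / pi)`, matching areas to moving-window radii.
#'
#' @param area_km2 area, km^2 (> 0); vectorized.
#' @param rounded return the nearest-integer convenience form.
#' @return Radius in km.
#' @examples
#' area_to_radius(3.3e4)          # 102.48...
#' area_to_radius(185502, rounded = TRUE)  # 243
#' @export
area_to_radius <- function(area_km2, rounded = FALSE) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    stop("`area_km2` must be positive and finite", call. = FALSE)
  }
  r <- sqrt(area_km2 / pi)
  if (rounded) round(r) else r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
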