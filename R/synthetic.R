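#' Parameters for a synthetic landscape
#'
#' Collects the knobs of the synthetic-landscape generator: grid shape and
#' cell size, terrain relief, protected-area (PA) cover, the linear climate
#' model (lapse rate, latitudinal gradient, precipitation-relief coupling,
#' noise), and the future-climate delta surface. Defaults describe a
#' mid-latitude mountainous landscape on 1 km cells with ~14% PA cover (the
#' approximate global terrestrial PA share) and a 95-year climate interval
#' (the midpoint of a 1950-2000 baseline to a 2070 future), over which a
#' ~4.3 degC warming corresponds to the ~0.05 degC/yr rates typical of a
#' high-emission trajectory.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_km cell edge length, km.
#' @param relief_m target elevation range, m.
#' @param n_hills number of Gaussian hills summed into the terrain.
#' @param pa_fraction target PA cover fraction in `[0, 1]`.
#' @param n_pas number of distinct PAs (>= 0).
#' @param lapse_rate temperature lapse rate, degC per m (negative).
#' @param lat_gradient temperature change per degree latitude, degC/deg.
#' @param t_intercept sea-level, reference-latitude temperature, degC.
#' @param lat_origin latitude of the grid's northern row, decimal degrees.
#' @param precip_base,precip_relief_coeff baseline precipitation, mm, and its
#'   increase per m of elevation, mm/m.
#' @param noise_sd_t,noise_sd_p i.i.d. noise s.d. for temperature (degC) and
#'   precipitation (mm).
#' @param delta_t_mean,delta_p_mean mean future change, degC and mm.
#' @param delta_spatial_sd spatial s.d. of the smooth change surface, in each
#'   variable's units.
#' @param years_elapsed climate interval, years (> 0).
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @return A list of class `landscape_params`.
#' @export
landscape_params <- function(n_rows = 128, n_cols = 128, cell_km = 1,
                             relief_m = 2000, n_hills = 25,
                             pa_fraction = 0.14, n_pas = 12,
                             lapse_rate = -0.0065, lat_gradient = -0.8,
                             t_intercept = 25, lat_origin = 45,
                             precip_base = 800, precip_relief_coeff = 0.5,
                             noise_sd_t = 0.25, noise_sd_p = 40,
                             delta_t_mean = 4.3, delta_p_mean = -60,
                             delta_spatial_sd = 0.5,
                             years_elapsed = 95, seed = 1L) {
  p <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            cell_km = cell_km, relief_m = relief_m, n_hills = as.integer(n_hills),
            pa_fraction = pa_fraction, n_pas = as.integer(n_pas),
            lapse_rate = lapse_rate, lat_gradient = lat_gradient,
            t_intercept = t_intercept, lat_origin = lat_origin,
            precip_base = precip_base,
            precip_relief_coeff = precip_relief_coeff,
            noise_sd_t = noise_sd_t, noise_sd_p = noise_sd_p,
            delta_t_mean = delta_t_mean, delta_p_mean = delta_p_mean,
            delta_spatial_sd = delta_spatial_sd,
            years_elapsed = years_elapsed, seed = as.integer(seed))
  if (p$n_rows < 1L || p$n_cols < 1L) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (p$pa_fraction < 0 || p$pa_fraction > 1) {
    stop("`pa_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_pas < 0L) stop("`n_pas` must be >= 0", call. = FALSE)
  if (p$cell_km <= 0) stop("`cell_km` must be positive", call. = FALSE)
  if (p$years_elapsed <= 0) stop("`years_elapsed` must be positive", call. = FALSE)
  if (p$relief_m < 0) stop("`relief_m` must be non-negative", call. = FALSE)
  structure(p, class = "landscape_params")
}

param_latitudes <- function(params) {
  deg_per_row <- params$cell_km / 111.32
  params$lat_origin - (seq_len(params$n_rows) - 1L) * deg_per_row
}

#' Generate terrain as a sum of Gaussian hills
#'
#' Sums `n_hills` randomly placed, randomly signed Gaussian bumps and
#' rescales the field linearly to span exactly `[0, relief_m]` metres.
#' The summed-hill construction yields nested valleys suitable for D8 flow
#' routing while staying simple and exactly reproducible; `relief_m = 0`
#' produces a flat (all-zero) grid.
#'
#' @param params a [landscape_params()].
#' @return A [pa_grid()] of elevations, m.
#' @export
generate_elevation <- function(params) {
  stopifnot(inherits(params, "landscape_params"))
  nr <- params$n_rows; nc <- params$n_cols
  set.seed(params$seed)
  e <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(params$n_hills)) {
    cy <- stats::runif(1, 1, nr)
    cx <- stats::runif(1, 1, nc)
    sigma <- stats::runif(1, 0.05, 0.25) * max(nr, nc)
    amp <- stats::runif(1, 0.3, 1) * sample(c(-1, 1), 1)
    e <- e + amp * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * sigma^2))
  }
  rng <- max(e) - min(e)
  e <- if (rng > 0) (e - min(e)) / rng * params$relief_m else e * 0
  pa_grid(e, cell_km = params$cell_km, row_latitudes = param_latitudes(params),
          units = "m")
}

# D8 receivers on an epsilon-perturbed surface: for each cell, the steepest
# downslope neighbour of the 8 (drop / distance, sqrt(2) on diagonals);
# 0 when the cell is a pit/outlet. Flats are broken by adding
# 1e-6 * (row0 * n_cols + col0) before routing, a deterministic tie-break.
d8_receivers <- function(elev) {
  nr <- nrow(elev); nc <- ncol(elev)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  row0 <- matrix(0:(nr - 1L), nr, nc)
  col0 <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  z <- elev + 1e-6 * (row0 * nc + col0)
  best_grad <- matrix(0, nr, nc)
  recv <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    zn <- shift_matrix(z, di, dj)
    idn <- matrix(NA_integer_, nr, nc)
    r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
    c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
    if (r1 <= r2 && c1 <= c2) {
      idn[r1:r2, c1:c2] <- idx[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
    }
    grad <- (z - zn) / sqrt(di^2 + dj^2)
    better <- !is.na(grad) & grad > best_grad
    best_grad[better] <- grad[better]
    recv[better] <- idn[better]
  }
  list(recv = recv, z = z)
}

#' Derive a drainage network from terrain
#'
#' Routes flow by steepest descent over the 8-neighbourhood (D8), resolves
#' flats with a deterministic epsilon perturbation, accumulates drainage area
#' from high to low cells (each cell contributes itself plus everything
#' upstream), and marks a cell as on-network when its accumulation reaches
#' `accumulation_threshold` cells. Pits and edge outlets simply terminate
#' flow. A threshold of 1 puts every cell on the network; the network is
#' non-empty for any threshold up to the total cell count.
#'
#' @param elevation elevation [pa_grid()], finite values.
#' @param accumulation_threshold minimum upstream cell count (>= 1).
#' @return A 0/1 [pa_grid()] marking network cells.
#' @export
derive_hydro_network <- function(elevation, accumulation_threshold) {
  stopifnot(inherits(elevation, "pa_grid"))
  if (!is.numeric(accumulation_threshold) || accumulation_threshold < 1) {
    stop("`accumulation_threshold` must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(elevation$values))) {
    stop("elevation must be finite everywhere", call. = FALSE)
  }
  acc <- flow_accumulation(elevation)
  net <- (acc$values >= accumulation_threshold) + 0
  pa_grid(net, cell_km = elevation$cell_km,
          row_latitudes = elevation$row_latitudes, units = "presence")
}

#' @rdname derive_hydro_network
#' @return `flow_accumulation()` returns the upstream cell-count
#'   [pa_grid()] itself (each cell counts itself, so values are >= 1).
#' @export
flow_accumulation <- function(elevation) {
  stopifnot(inherits(elevation, "pa_grid"))
  d8 <- d8_receivers(elevation$values)
  ord <- order(d8$z, decreasing = TRUE)
  acc <- rep(1, length(d8$z))
  rv <- as.vector(d8$recv)
  for (i in ord) {
    r <- rv[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  pa_grid(matrix(acc, nrow(elevation$values), ncol(elevation$values)),
          cell_km = elevation$cell_km,
          row_latitudes = elevation$row_latitudes, units = "cells")
}

#' Generate a protected-area mosaic
#'
#' Seeds `n_pas` distinct cells and grows each PA outward by random frontier
#' expansion (4-neighbourhood) until the mosaic reaches
#' `round(pa_fraction * n_cells)` cells, so each PA id is one contiguous
#' connected component. Growth interleaves PAs at random, giving a mix of
#' sizes around the common target.
#'
#' @param params a [landscape_params()].
#' @return A [pa_grid()] of PA ids: 0 = non-PA, 1..n_pas = distinct PAs.
#' @export
generate_pa_mosaic <- function(params) {
  stopifnot(inherits(params, "landscape_params"))
  nr <- params$n_rows; nc <- params$n_cols
  ncell <- nr * nc
  target <- round(params$pa_fraction * ncell)
  if (target < params$n_pas) {
    stop(sprintf("pa_fraction * cells (%d) is below n_pas (%d)", target,
                 params$n_pas), call. = FALSE)
  }
  ids <- matrix(0L, nr, nc)
  if (target == 0L || params$n_pas == 0L) {
    return(pa_grid(ids, cell_km = params$cell_km,
                   row_latitudes = param_latitudes(params), units = "id"))
  }
  set.seed(params$seed + 1L)
  seeds <- sample.int(ncell, params$n_pas)
  frontiers <- vector("list", params$n_pas)
  assigned <- 0L
  for (k in seq_len(params$n_pas)) {
    ids[seeds[k]] <- k
    frontiers[[k]] <- seeds[k]
    assigned <- assigned + 1L
  }
  neighbours4 <- function(i) {
    r <- (i - 1L) %% nr + 1L
    cc <- (i - 1L) %/% nr + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < nr) out <- c(out, i + 1L)
    if (cc > 1L) out <- c(out, i - nr)
    if (cc < nc) out <- c(out, i + nr)
    out
  }
  active <- seq_len(params$n_pas)
  while (assigned < target && length(active)) {
    k <- if (length(active) == 1L) active else sample(active, 1L)
    grew <- FALSE
    while (length(frontiers[[k]]) && !grew) {
      j <- if (length(frontiers[[k]]) == 1L) 1L
           else sample.int(length(frontiers[[k]]), 1L)
      cell <- frontiers[[k]][j]
      nb <- neighbours4(cell)
      free <- nb[ids[nb] == 0L]
      if (length(free)) {
        pick <- if (length(free) == 1L) free else sample(free, 1L)
        ids[pick] <- k
        frontiers[[k]] <- c(frontiers[[k]], pick)
        assigned <- assigned + 1L
        grew <- TRUE
      } else {
        frontiers[[k]] <- frontiers[[k]][-j]
      }
    }
    if (!grew) active <- setdiff(active, k)
  }
  pa_grid(ids, cell_km = params$cell_km,
          row_latitudes = param_latitudes(params), units = "id")
}

# Separable Gaussian blur with edge renormalization; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-half:half)^2 / (2 * sigma^2))
  conv1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (t in seq_along(w)) {
      off <- t - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok] <- out[ok] + w[t] * x[src[ok]]
    }
    norm <- numeric(n)
    for (t in seq_along(w)) {
      off <- t - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      norm[ok] <- norm[ok] + w[t]
    }
    out / norm
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

#' Generate current and future climate surfaces
#'
#' Current climate follows a linear model: temperature is
#' `t_intercept + lapse_rate * elevation + lat_gradient * (latitude -
#' lat_origin) + noise`, precipitation is `precip_base +
#' precip_relief_coeff * elevation + noise`. Future surfaces add a spatially
#' smooth delta field (Gaussian-smoothed white noise standardized to
#' `delta_spatial_sd`, plus the mean change), emulating an ensemble-averaged
#' projection whose change surface varies gently in space.
#'
#' @param elevation elevation [pa_grid()].
#' @param params a [landscape_params()] (latitudes are taken from
#'   `elevation`).
#' @return A list of four [pa_grid()]s: `temp_now`, `temp_future` (degC),
#'   `precip_now`, `precip_future` (mm).
#' @export
generate_climate <- function(elevation, params) {
  stopifnot(inherits(elevation, "pa_grid"), inherits(params, "landscape_params"))
  nr <- nrow(elevation$values); nc <- ncol(elevation$values)
  if (nr != params$n_rows || nc != params$n_cols) {
    stop("elevation grid is not co-registered with `params` dimensions",
         call. = FALSE)
  }
  set.seed(params$seed + 2L)
  latm <- matrix(elevation$row_latitudes, nr, nc)
  e <- elevation$values
  t_now <- params$t_intercept + params$lapse_rate * e +
    params$lat_gradient * (latm - params$lat_origin)
  if (params$noise_sd_t > 0) {
    t_now <- t_now + matrix(stats::rnorm(nr * nc, 0, params$noise_sd_t), nr, nc)
  }
  p_now <- params$precip_base + params$precip_relief_coeff * e
  if (params$noise_sd_p > 0) {
    p_now <- p_now + matrix(stats::rnorm(nr * nc, 0, params$noise_sd_p), nr, nc)
  }
  smooth_delta <- function(mean_delta, spatial_sd) {
    if (spatial_sd == 0) return(matrix(mean_delta, nr, nc))
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                         sigma = max(nr, nc) / 16)
    f <- (f - mean(f)) / stats::sd(as.vector(f))
    mean_delta + spatial_sd * f
  }
  t_fut <- t_now + smooth_delta(params$delta_t_mean, params$delta_spatial_sd)
  p_fut <- p_now + smooth_delta(params$delta_p_mean,
                                params$delta_spatial_sd * 40)
  wrap <- function(m, u) pa_grid(m, cell_km = elevation$cell_km,
                                 row_latitudes = elevation$row_latitudes,
                                 units = u)
  list(temp_now = wrap(t_now, "degC"), temp_future = wrap(t_fut, "degC"),
       precip_now = wrap(p_now, "mm"), precip_future = wrap(p_fut, "mm"))
}

#' Sizes of established conservation partnerships
#'
#' Draws `n` log-normally distributed partnership areas in km^2, emulating
#' the heavy-tailed size distribution of established trans-boundary
#' conservation partnerships (hundreds to over a million km^2).
#'
#' @param n number of partnerships (>= 1).
#' @param log_mean,log_sd parameters of the log-normal on the log scale.
#'   The defaults centre the distribution near 1.8e5 km^2, the median scale
#'   of established partnerships, with a spread reaching from order 1e4 to
#'   order 1e6 km^2.
#' @param seed integer RNG seed.
#' @return A tibble with column `area_km2`, all values > 0.
#' @export
generate_partnership_sizes <- function(n, log_mean = log(1.8e5),
                                       log_sd = 1.2, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  tibble::tibble(area_km2 = stats::rlnorm(as.integer(n), log_mean, log_sd))
}

#' Generate a complete synthetic landscape
#'
#' Runs every generator with one parameter set: terrain, drainage network,
#' PA mosaic, and the four climate surfaces, all co-registered and
#' deterministic for a fixed seed.
#'
#' @param params a [landscape_params()].
#' @param accumulation_threshold drainage threshold in cells; defaults to
#'   `max(8, n_rows)`, giving a sparse valley network.
#' @return A list of class `pa_landscape` with elements `elevation`,
#'   `hydro`, `pa_ids`, `temp_now`, `temp_future`, `precip_now`,
#'   `precip_future`, `years_elapsed`, and `params`.
#' @examples
#' ls <- synthetic_landscape(landscape_params(n_rows = 32, n_cols = 32,
#'                                            n_pas = 4, seed = 7))
#' mean(ls$pa_ids$values > 0)
#' @export
synthetic_landscape <- function(params = landscape_params(),
                                accumulation_threshold = NULL) {
  stopifnot(inherits(params, "landscape_params"))
  if (is.null(accumulation_threshold)) {
    accumulation_threshold <- max(8L, params$n_rows)
  }
  elev <- generate_elevation(params)
  hydro <- derive_hydro_network(elev, accumulation_threshold)
  pas <- generate_pa_mosaic(params)
  clim <- generate_climate(elev, params)
  structure(
    c(list(elevation = elev, hydro = hydro, pa_ids = pas), clim,
      list(years_elapsed = params$years_elapsed, params = params)),
    class = "pa_landscape"
  )
}

#' @export
print.pa_landscape <- function(x, ...) {
  d <- dim(x$elevation$values)
  cat(sprintf("<pa_landscape> %d x %d cells (%g km), %d PAs covering %.1f%%\n",
              d[1], d[2], x$elevation$cell_km,
              length(setdiff(unique(as.vector(x$pa_ids$values)), 0)),
              100 * mean(x$pa_ids$values > 0)))
  cat(sprintf("  relief %.0f m; hydro cells %.1f%%; delta-T mean %+.2f degC over %g yr\n",
              diff(range(x$elevation$values)),
              100 * mean(x$hydro$values > 0),
              mean(x$temp_future$values - x$temp_now$values),
              x$years_elapsed))
  invisible(x)
}
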