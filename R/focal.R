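#' Discrete circular moving-window kernel
#'
#' Builds the set of integer cell offsets forming a discrete circular window
#' of radius `radius_km` on a grid of `cell_km` cells. A cell offset
#' `(i, j)` belongs to the kernel when its cell-centre distance satisfies
#' `(i^2 + j^2) * cell_km^2 <= radius_km^2`. The partnership scale of an
#' analysis is the maximum linear distance between potential partnering
#' locations, i.e. the window diameter `2 r`.
#'
#' With 1 km cells the radius-3 kernel contains exactly 29 cells, the
#' smallest window of the standard partnership-scale ladder
#' (r = 3, 9, 27, 81, 243, 729 km). Radius 0 gives the identity window
#' `{(0, 0)}`, the no-partnering limit.
#'
#' @param radius_km window radius, km (>= 0).
#' @param cell_km cell edge length, km (> 0).
#' @return An object of class `pa_kernel`: a list with `radius_km`,
#'   `cell_km`, and `offsets`, an n x 2 integer matrix of (delta-row,
#'   delta-col) offsets in deterministic row-major order.
#' @examples
#' nrow(build_kernel(3, 1)$offsets)  # 29
#' @export
build_kernel <- function(radius_km, cell_km = 1) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L ||
      !is.finite(radius_km) || radius_km < 0) {
    stop("`radius_km` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0) {
    stop("`cell_km` must be a single positive number", call. = FALSE)
  }
  rmax <- floor(radius_km / cell_km)
  ij <- expand.grid(dj = -rmax:rmax, di = -rmax:rmax)  # row-major in di
  keep <- (ij$di^2 + ij$dj^2) * cell_km^2 <= radius_km^2
  offsets <- cbind(di = as.integer(ij$di[keep]), dj = as.integer(ij$dj[keep]))
  structure(list(radius_km = radius_km, cell_km = cell_km, offsets = offsets),
            class = "pa_kernel")
}

#' @export
print.pa_kernel <- function(x, ...) {
  cat(sprintf("<pa_kernel> r = %g km on %g km cells: %d cells (%g km^2)\n",
              x$radius_km, x$cell_km, nrow(x$offsets),
              nrow(x$offsets) * x$cell_km^2), sep = "")
  invisible(x)
}

#' Number of cells in a kernel
#' @param kernel a [build_kernel()] result.
#' @return Integer cell count.
#' @export
kernel_size <- function(kernel) nrow(kernel$offsets)

# Shift a matrix by (di, dj): out[i, j] = m[i + di, j + dj], NA out of bounds.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r1 <- max(1L, 1L - di); r2 <- min(nr, nr - di)
  c1 <- max(1L, 1L - dj); c2 <- min(nc, nc - dj)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
  }
  out
}

#' Masked moving-window statistic
#'
#' For every focal cell, computes a statistic over the value-grid cells at
#' kernel offsets that are in bounds, not nodata, and `TRUE` in the target
#' mask. Windows are truncated at grid edges (no wraparound or padding),
#' matching continental rasters bordered by ocean nodata. Focal cells whose
#' window holds zero qualifying cells yield nodata (`NA`) — never zero, since
#' zero is a meaningful indicator value.
#'
#' `sd` is the population standard deviation (divisor n), the raster focal-
#' statistics convention, computed by a two-pass sweep (window mean first,
#' then squared deviations) so results are reproducible to the bit against a
#' sequential per-window evaluation.
#'
#' @param values a [pa_grid()] of cell values.
#' @param kernel a [build_kernel()] kernel.
#' @param target logical matrix (or 0/1 [pa_grid()]) marking potential
#'   partner cells; `NULL` means all non-nodata cells qualify.
#' @param stat one or more of `"count"`, `"min"`, `"max"`, `"mean"`,
#'   `"sum"`, `"sd"`.
#' @return A [pa_grid()] for a single statistic, or a named list of grids
#'   when `stat` has several (computed in one sweep).
#' @examples
#' g <- pa_grid(matrix(1:16, 4, 4))
#' focal_stat(g, build_kernel(1), stat = "mean")
#' @export
focal_stat <- function(values, kernel, target = NULL,
                       stat = c("count", "min", "max", "mean", "sum", "sd")) {
  stopifnot(inherits(values, "pa_grid"), inherits(kernel, "pa_kernel"))
  stat <- match.arg(stat, several.ok = TRUE)
  v <- values$values
  if (inherits(target, "pa_grid")) target <- !is.na(target$values) & target$values != 0
  if (is.null(target)) target <- !is.na(v)
  if (!identical(dim(target), dim(v))) {
    stop("target mask is not co-registered with the value grid", call. = FALSE)
  }
  mv <- v
  mv[!target | is.na(v)] <- NA_real_

  nr <- nrow(v); nc <- ncol(v)
  offs <- kernel$offsets
  cnt <- matrix(0, nr, nc)
  need_sum <- any(stat %in% c("sum", "mean", "sd"))
  need_min <- "min" %in% stat
  need_max <- "max" %in% stat
  s <- if (need_sum) matrix(0, nr, nc)
  mn <- if (need_min) matrix(NA_real_, nr, nc)
  mx <- if (need_max) matrix(NA_real_, nr, nc)
  for (k in seq_len(nrow(offs))) {
    sv <- shift_matrix(mv, offs[k, 1L], offs[k, 2L])
    qa <- !is.na(sv)
    cnt <- cnt + qa
    if (need_sum) s <- s + ifelse(qa, sv, 0)
    if (need_min) mn <- pmin(mn, sv, na.rm = TRUE)
    if (need_max) mx <- pmax(mx, sv, na.rm = TRUE)
  }
  empty <- cnt == 0
  out <- list()
  if ("count" %in% stat) {
    cc <- cnt; cc[empty] <- NA_real_
    out$count <- cc
  }
  if ("sum" %in% stat) {
    ss <- s; ss[empty] <- NA_real_
    out$sum <- ss
  }
  if (any(stat %in% c("mean", "sd"))) {
    mu <- s / cnt  # empty windows give NaN -> overwritten below
    if ("mean" %in% stat) {
      mm <- mu; mm[empty] <- NA_real_
      out$mean <- mm
    }
    if ("sd" %in% stat) {
      d2 <- matrix(0, nr, nc)
      for (k in seq_len(nrow(offs))) {
        sv <- shift_matrix(mv, offs[k, 1L], offs[k, 2L])
        qa <- !is.na(sv)
        d2 <- d2 + ifelse(qa, (sv - mu)^2, 0)
      }
      sdv <- sqrt(d2 / cnt)
      sdv[empty] <- NA_real_
      out$sd <- sdv
    }
  }
  if ("min" %in% stat) { mn[empty] <- NA_real_; out$min <- mn }
  if ("max" %in% stat) { mx[empty] <- NA_real_; out$max <- mx }
  out <- out[stat]
  wrap <- function(m) pa_grid(m, cell_km = values$cell_km,
                              row_latitudes = values$row_latitudes)
  if (length(stat) == 1L) wrap(out[[1L]]) else lapply(out, wrap)
}
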