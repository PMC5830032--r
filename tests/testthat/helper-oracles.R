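# Independent brute-force oracles used across the suite.
# They evaluate every window by direct per-cell loops, sequentially in kernel
# offset order, so agreement with the optimized sweeps can be asserted
# bit for bit.

# Per-cell moving-window statistics by double loop.
brute_focal <- function(values, kernel, target = NULL, stat = "mean") {
  v <- if (inherits(values, "pa_grid")) values$values else values
  if (is.null(target)) target <- !is.na(v)
  if (inherits(target, "pa_grid")) target <- !is.na(target$values) & target$values != 0
  nr <- nrow(v); nc <- ncol(v)
  offs <- kernel$offsets
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(0)
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs[k, 1L]; jj <- j + offs[k, 2L]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
          target[ii, jj] && !is.na(v[ii, jj])) {
        vals <- c(vals, v[ii, jj])
      }
    }
    n <- length(vals)
    if (n == 0L) next
    out[i, j] <- switch(stat,
      count = n,
      sum = seq_sum(vals),
      mean = seq_sum(vals) / n,
      sd = {
        m <- seq_sum(vals) / n
        sqrt(seq_sum((vals - m)^2) / n)
      },
      min = min(vals),
      max = max(vals),
      stop("unknown stat in oracle: ", stat)
    )
  }
  out
}

# Sequential left-to-right double-precision sum (base sum() uses extended
# precision, which would not match the sweep's accumulation order).
seq_sum <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi
  s
}

# Relief-weighted hydrologic area by direct window evaluation: for every
# window, sum (e_i - min over target cells) over hydro-and-target cells,
# in kernel offset order.
brute_relief_hydro <- function(elev, hydro, target, kernel, cell_km = 1) {
  nr <- nrow(elev); nc <- ncol(elev)
  offs <- kernel$offsets
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tvals <- numeric(0); hvals <- numeric(0)
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs[k, 1L]; jj <- j + offs[k, 2L]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && target[ii, jj]) {
        tvals <- c(tvals, elev[ii, jj])
        if (hydro[ii, jj]) hvals <- c(hvals, elev[ii, jj])
      }
    }
    if (length(tvals) == 0L) next
    mn <- min(tvals)
    out[i, j] <- seq_sum(vapply(hvals, function(e) e - mn, 0)) * cell_km^2
  }
  out
}

# D8 flow accumulation by path walking: every cell contributes one unit to
# itself and to every cell on its downstream path. Receivers are recomputed
# here with independent code (explicit neighbour scan per cell).
brute_accumulation <- function(elev) {
  nr <- nrow(elev); nc <- ncol(elev)
  z <- elev
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    z[i, j] <- z[i, j] + 1e-6 * ((i - 1) * nc + (j - 1))
  }
  receiver <- function(i, j) {
    best <- 0; bi <- 0L; bj <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      g <- (z[i, j] - z[ii, jj]) / sqrt(di^2 + dj^2)
      if (g > best) { best <- g; bi <- ii; bj <- jj }
    }
    if (best > 0) c(bi, bj) else NULL
  }
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ci <- i; cj <- j
    acc[ci, cj] <- acc[ci, cj] + 1
    repeat {
      r <- receiver(ci, cj)
      if (is.null(r)) break
      ci <- r[1]; cj <- r[2]
      acc[ci, cj] <- acc[ci, cj] + 1
    }
  }
  acc
}

# Blockwise any() aggregation by explicit loops.
brute_aggregate_presence <- function(fine, factor) {
  nr <- nrow(fine) %/% factor; nc <- ncol(fine) %/% factor
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- fine[((i - 1) * factor + 1):(i * factor),
                  ((j - 1) * factor + 1):(j * factor)]
    out[i, j] <- as.numeric(any(block != 0, na.rm = TRUE))
  }
  out
}

# Small complete landscape for scenario tests.
test_landscape <- function(n = 32, seed = 3, n_pas = 4, pa_fraction = 0.2,
                           relief_m = 800) {
  synthetic_landscape(landscape_params(
    n_rows = n, n_cols = n, n_pas = n_pas, pa_fraction = pa_fraction,
    relief_m = relief_m, n_hills = 8, seed = seed))
}

# Connected-component check: is every cell of `id` reachable from the first
# one through 4-neighbour steps inside the id?
is_contiguous <- function(ids, id) {
  cells <- which(ids == id)
  if (length(cells) <= 1L) return(TRUE)
  nr <- nrow(ids)
  seen <- logical(length(ids))
  queue <- cells[1L]
  seen[queue] <- TRUE
  inset <- logical(length(ids)); inset[cells] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    r <- (cur - 1L) %% nr + 1L
    nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
            cur - nr, cur + nr)
    nb <- nb[nb >= 1L & nb <= length(ids)]
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen[cells])
}

# All six statistics from one window gather (still a per-cell double loop,
# independent of the offset-sweep implementation).
brute_focal_all <- function(values, kernel, target) {
  v <- if (inherits(values, "pa_grid")) values$values else values
  nr <- nrow(v); nc <- ncol(v)
  offs <- kernel$offsets
  K <- nrow(offs)
  stats <- c("count", "min", "max", "mean", "sum", "sd")
  out <- lapply(stats, function(s) matrix(NA_real_, nr, nc))
  names(out) <- stats
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(K); n <- 0L
    for (k in seq_len(K)) {
      ii <- i + offs[k, 1L]; jj <- j + offs[k, 2L]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
          target[ii, jj] && !is.na(v[ii, jj])) {
        n <- n + 1L
        vals[n] <- v[ii, jj]
      }
    }
    if (n == 0L) next
    vals <- vals[seq_len(n)]
    s <- seq_sum(vals)
    m <- s / n
    out$count[i, j] <- n
    out$sum[i, j] <- s
    out$mean[i, j] <- m
    out$sd[i, j] <- sqrt(seq_sum((vals - m)^2) / n)
    out$min[i, j] <- min(vals)
    out$max[i, j] <- max(vals)
  }
  out
}
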