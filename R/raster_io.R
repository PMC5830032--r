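#' Read and write grids in the plain-text ASCII grid dialect
#'
#' The on-disk raster format is an ESRI-ASCII-style header (`ncols`, `nrows`,
#' `cellsize` in km, `NODATA_value`) followed by `nrows` whitespace-separated
#' data rows, northernmost row first. Two optional header keys, `lat_top` and
#' `lat_step` (degrees), carry the per-row latitude vector so a round trip
#' preserves the full [pa_grid()]; when absent the default latitude ramp is
#' used. The format is bit-exact for fixture purposes: values are written with
#' full `%.17g` precision.
#'
#' @param path file path.
#' @param units unit label to attach to the grid read.
#' @return `read_grid()` returns a [pa_grid()]; `write_grid()` invisibly
#'   returns `path`.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_grid(pa_grid(matrix(1:6, 2, 3)), f)
#' read_grid(f)
#' @export
read_grid <- function(path, units = "") {
  if (!file.exists(path)) stop("no such grid file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]", trimws(lines[[i]]))) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(parts) != 2L) {
      stop("malformed grid header line: '", lines[[i]], "'", call. = FALSE)
    }
    hdr[[tolower(parts[[1L]])]] <- suppressWarnings(as.numeric(parts[[2L]]))
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]]) || !is.finite(hdr[[key]])) {
      stop("grid header is missing or has non-numeric field '", key, "'",
           call. = FALSE)
    }
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("grid body has %d values, header declares nrows*ncols = %d",
                 length(body), nr * nc), call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  lats <- NULL
  if (!is.null(hdr$lat_top) && !is.null(hdr$lat_step)) {
    lats <- hdr$lat_top - (seq_len(nr) - 1L) * hdr$lat_step
  }
  pa_grid(m, cell_km = hdr$cellsize, row_latitudes = lats, units = units)
}

#' @rdname read_grid
#' @param grid a [pa_grid()] to write.
#' @param nodata numeric value used to encode `NA` cells on disk.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "pa_grid"))
  v <- grid$values
  v[is.na(v)] <- nodata
  lats <- grid$row_latitudes
  step <- if (length(lats) > 1L) lats[1L] - lats[2L] else 0
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("cellsize %.17g", grid$cell_km),
    sprintf("NODATA_value %.17g", nodata),
    sprintf("lat_top %.17g", lats[1L]),
    sprintf("lat_step %.17g", step)
  )
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read or write a zone map
#'
#' A zone map pairs an integer id raster (0 = no zone) with a two-column
#' delimited label table (`zone_id`, `label`), the form used for biome and
#' ecoregion summaries.
#'
#' @param grid_path path of the id raster (ASCII grid dialect).
#' @param labels_path path of the tab-delimited label table.
#' @return A list of class `zone_map` with elements `zones` (a [pa_grid()] of
#'   integer ids) and `labels` (a tibble `zone_id`, `label`).
#' @export
read_zone_map <- function(grid_path, labels_path) {
  zones <- read_grid(grid_path, units = "id")
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  names(labels) <- c("zone_id", "label")[seq_along(names(labels))]
  zone_map(zones, tibble::as_tibble(labels))
}

#' @rdname read_zone_map
#' @param zones integer id [pa_grid()] (0 = no zone).
#' @param labels tibble with columns `zone_id` and `label` covering every
#'   nonzero id present in `zones`.
#' @export
zone_map <- function(zones, labels) {
  ids <- setdiff(unique(as.vector(zones$values)), c(0, NA))
  missing <- setdiff(ids, labels$zone_id)
  if (length(missing)) {
    stop("zone ids without a label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(zones = zones, labels = tibble::as_tibble(labels)),
            class = "zone_map")
}

#' @rdname read_zone_map
#' @param x a `zone_map`.
#' @export
write_zone_map <- function(x, grid_path, labels_path) {
  write_grid(x$zones, grid_path)
  utils::write.table(x$labels, labels_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(grid_path)
}

#' Any-presence block aggregation
#'
#' Coarsens a fine-resolution boolean presence grid by an integer factor: a
#' coarse cell is present if at least one of its `factor^2` fine cells is
#' present. This is the rule used to carry small protected areas from a 250 m
#' rasterization to the 1 km analysis grid (one presence cell of 16 possible
#' suffices), so PAs smaller than a single coarse cell are retained.
#'
#' @param fine a [pa_grid()] with 0/1 (or logical) values; `NA` counts as
#'   absent.
#' @param factor integer aggregation factor >= 1; both grid dimensions must be
#'   divisible by it.
#' @return A [pa_grid()] of 0/1 values with cell size `cell_km * factor`.
#' @examples
#' fine <- pa_grid(matrix(c(1, rep(0, 15)), 4, 4), cell_km = 0.25)
#' aggregate_presence(fine, 4)$values  # single presence cell is kept
#' @export
aggregate_presence <- function(fine, factor) {
  stopifnot(inherits(fine, "pa_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0L || nc %% factor != 0L) {
    stop(sprintf("grid %d x %d does not tile by factor %d", nr, nc, factor),
         call. = FALSE)
  }
  pres <- !is.na(v) & v != 0
  cr <- nr %/% factor; cc <- nc %/% factor
  # block-wise any(): fold rows then columns
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  folded <- rowsum(pres + 0, ri)            # cr x nc counts
  folded <- t(rowsum(t(folded), ci))        # cr x cc counts
  coarse <- (folded > 0) + 0
  dimnames(coarse) <- NULL
  # coarse rows inherit the mean latitude of their fine rows
  lat <- as.vector(rowsum(fine$row_latitudes, ri) / factor)
  pa_grid(coarse, cell_km = fine$cell_km * factor, row_latitudes = lat,
          units = "presence")
}
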