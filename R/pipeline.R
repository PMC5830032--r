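config_error <- function(msg) {
  stop(structure(class = c("partnerscape_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

data_error <- function(msg) {
  stop(structure(class = c("partnerscape_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pipeline run configuration
#'
#' Builds (or reads from a flat `key value` text file) the configuration of a
#' full pipeline run: one path per input layer, the partnership radii, the
#' scenario modes, the velocity floor constant, the climate interval, a seed
#' and an output directory.
#'
#' @param elevation,hydro,pa_ids,temp_now,temp_future,precip_now,precip_future
#'   paths of the input layers (ASCII grid dialect).
#' @param zones,zone_labels optional zone-map paths for zonal summaries.
#' @param radii partnership radii, km, positive and ascending (default
#'   3, 9, 27, 81, 243, 729 — the standard scale ladder).
#' @param modes scenario modes to run.
#' @param compare_radius radius for scenario comparisons and the potential
#'   surface; defaults to the median entry of `radii`, following the
#'   median-partnership-scale convention.
#' @param floor_constant velocity denominator floor.
#' @param years_elapsed climate interval, years.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(elevation, hydro, pa_ids, temp_now, temp_future,
                       precip_now, precip_future,
                       zones = NULL, zone_labels = NULL,
                       radii = c(3, 9, 27, 81, 243, 729),
                       modes = c("pixel_null", "pa_null", "pa_partnership",
                                 "pa_nonpa_partnership"),
                       compare_radius = NULL, floor_constant = 0.1,
                       years_elapsed = 95, seed = 1L, out_dir = "products") {
  cfg <- list(elevation = elevation, hydro = hydro, pa_ids = pa_ids,
              temp_now = temp_now, temp_future = temp_future,
              precip_now = precip_now, precip_future = precip_future,
              zones = zones, zone_labels = zone_labels,
              radii = as.numeric(radii), modes = modes,
              compare_radius = compare_radius,
              floor_constant = floor_constant,
              years_elapsed = years_elapsed, seed = as.integer(seed),
              out_dir = out_dir)
  if (length(cfg$radii) == 0 || any(cfg$radii <= 0) ||
      is.unsorted(cfg$radii, strictly = TRUE)) {
    config_error("`radii` must be positive and strictly ascending")
  }
  bad <- setdiff(cfg$modes, c("pixel_null", "pa_null", "pa_partnership",
                              "pa_nonpa_partnership"))
  if (length(bad)) {
    config_error(paste0("unknown scenario mode(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$compare_radius)) {
    cfg$compare_radius <- cfg$radii[[ceiling(length(cfg$radii) / 2)]]
  }
  for (field in c("elevation", "hydro", "pa_ids", "temp_now", "temp_future",
                  "precip_now", "precip_future")) {
    if (is.null(cfg[[field]]) || !nzchar(cfg[[field]])) {
      config_error(paste0("missing input layer path: `", field, "`"))
    }
    if (!file.exists(cfg[[field]])) {
      config_error(paste0("input layer `", field, "` not found at ",
                          cfg[[field]]))
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path a flat key/value config file (one `key value` pair per line;
#'   `#` comments; list values comma-separated).
#' @param overrides named list of values overriding config-file keys (the
#'   CLI maps every flag onto its key this way).
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^(\\S+)\\s+(.*)$", l))[[1]]
    if (length(m) != 3L) config_error(paste0("malformed config line: '", l, "'"))
    kv[[m[2]]] <- m[3]
  }
  kv[names(overrides)] <- overrides
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  numlist <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x)) return(x)
    as.numeric(strsplit(x, "[,\\s]+")[[1]])
  }
  strlist <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) > 1L) return(x)
    strsplit(x, "[,\\s]+")[[1]]
  }
  args <- list(
    elevation = kv$elevation, hydro = kv$hydro, pa_ids = kv$pa_ids,
    temp_now = kv$temp_now, temp_future = kv$temp_future,
    precip_now = kv$precip_now, precip_future = kv$precip_future,
    zones = kv$zones, zone_labels = kv$zone_labels,
    compare_radius = num(kv$compare_radius),
    out_dir = kv$out_dir %||% "products"
  )
  if (!is.null(kv$radii)) args$radii <- numlist(kv$radii)
  if (!is.null(kv$modes)) args$modes <- strlist(kv$modes)
  if (!is.null(kv$floor_constant)) args$floor_constant <- num(kv$floor_constant)
  if (!is.null(kv$years_elapsed)) args$years_elapsed <- num(kv$years_elapsed)
  if (!is.null(kv$seed)) args$seed <- as.integer(num(kv$seed))
  do.call(run_config, args)
}

load_landscape <- function(cfg) {
  grids <- tryCatch(list(
    elevation = read_grid(cfg$elevation, units = "m"),
    hydro = read_grid(cfg$hydro, units = "presence"),
    pa_ids = read_grid(cfg$pa_ids, units = "id"),
    temp_now = read_grid(cfg$temp_now, units = "degC"),
    temp_future = read_grid(cfg$temp_future, units = "degC"),
    precip_now = read_grid(cfg$precip_now, units = "mm"),
    precip_future = read_grid(cfg$precip_future, units = "mm")
  ), error = function(e) data_error(conditionMessage(e)))
  tryCatch(do.call(check_coregistered, unname(grids)),
           error = function(e) data_error(conditionMessage(e)))
  structure(c(grids, list(years_elapsed = cfg$years_elapsed, params = NULL)),
            class = "pa_landscape")
}

#' Write a synthetic-landscape fixture directory
#'
#' Generates a complete landscape and writes every layer in the ASCII grid
#' dialect plus a plain-text `params.txt` manifest of the generator
#' parameters, ready to feed [run_pipeline()].
#'
#' @param params a [landscape_params()].
#' @param dir output directory (created if needed).
#' @param accumulation_threshold drainage threshold (see
#'   [synthetic_landscape()]).
#' @return Invisibly, the landscape object.
#' @export
make_fixture <- function(params, dir, accumulation_threshold = NULL) {
  ls <- synthetic_landscape(params, accumulation_threshold)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- c("elevation", "hydro", "pa_ids", "temp_now", "temp_future",
              "precip_now", "precip_future")
  for (nm in layers) write_grid(ls[[nm]], file.path(dir, paste0(nm, ".asc")))
  p <- unclass(params)
  writeLines(sprintf("%s %s", names(p), vapply(p, format, "")),
             file.path(dir, "params.txt"))
  invisible(ls)
}

#' Run the full pipeline
#'
#' Loads the configured layers, runs every scenario mode at every radius,
#' and writes a deterministic product tree under `cfg$out_dir`:
#' `indicators/<mode>/r<radius>/<layer>.asc`, an indicator summary table,
#' scenario comparison factors at the comparison radius, the combined
#' adaptation-potential surface (PA & non-PA scenario at the comparison
#' radius), zonal means when a zone map is configured, and a `manifest.txt`
#' recording every numerical convention of the run (kernel inclusion rule,
#' sd divisor, climate interval, floor constant, seed). Rerunning with the
#' same config and seed reproduces the tree bit for bit. On failure, partial
#' outputs are removed.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ls <- load_landscape(cfg)
  out <- cfg$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) {
    if (created) unlink(out, recursive = TRUE)
    else unlink(file.path(out, c("indicators", "summaries", "comparisons",
                                 "potential", "manifest.txt")),
                recursive = TRUE)
  }, add = TRUE)

  summaries <- list()
  for (mode in cfg$modes) {
    for (r in cfg$radii) {
      iset <- run_scenario(ls, mode,
                           radius_km = if (grepl("partnership", mode)) r,
                           floor_constant = cfg$floor_constant)
      d <- file.path(out, "indicators", mode, sprintf("r%g", r))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (nm in indicator_names()) {
        write_grid(iset[[nm]], file.path(d, paste0(nm, ".asc")))
      }
      tt <- tidy(iset)
      tt$radius_km <- r  # null modes are radius-invariant; keep the row key
      summaries[[paste(mode, r)]] <- tt
    }
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  dir.create(file.path(out, "summaries"), showWarnings = FALSE)
  utils::write.table(summary_tbl,
                     file.path(out, "summaries", "indicator_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cmp_r <- cfg$compare_radius
  cmp <- compare_scenarios(ls, radius_km = cmp_r,
                           floor_constant = cfg$floor_constant)
  dir.create(file.path(out, "comparisons"), showWarnings = FALSE)
  utils::write.table(cmp,
                     file.path(out, "comparisons", "comparison_factors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  pot <- combine_potential(
    run_scenario(ls, "pa_nonpa_partnership", radius_km = cmp_r,
                 floor_constant = cfg$floor_constant))
  dir.create(file.path(out, "potential"), showWarnings = FALSE)
  write_grid(pot$potential, file.path(out, "potential", "potential.asc"))
  if (!is.null(cfg$zones)) {
    zm <- tryCatch(read_zone_map(cfg$zones, cfg$zone_labels),
                   error = function(e) data_error(conditionMessage(e)))
    utils::write.table(zonal_mean(pot, zm),
                       file.path(out, "potential", "zonal_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- c(
    sprintf("package partnerscape %s",
            as.character(utils::packageVersion("partnerscape"))),
    "kernel_rule cell-center distance (i^2+j^2)*cell_km^2 <= r^2",
    "sd_divisor n (population sd)",
    "empty_window nodata",
    sprintf("floor_constant %g", cfg$floor_constant),
    sprintf("years_elapsed %g", cfg$years_elapsed),
    sprintf("radii %s", paste(cfg$radii, collapse = ",")),
    sprintf("modes %s", paste(cfg$modes, collapse = ",")),
    sprintf("compare_radius %g", cmp_r),
    sprintf("seed %d", cfg$seed),
    "velocity_layers merged before inversion (5 indicators combined)"
  )
  writeLines(manifest, file.path(out, "manifest.txt"))
  ok <- TRUE
  invisible(out)
}
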