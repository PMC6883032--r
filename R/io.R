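# CSV schemas for the four data products. All files are UTF-8, '.' decimal,
# with units embedded in column names; unknown columns pass through.

schema_cols <- list(
  sites = c("site_id", "source_id", "lat", "lon", "region", "state",
            "vegetation", "salinity_ppt", "sar_mm_yr", "c_density_gC_cm3",
            "car_gC_m2_yr", "rslr_mm_yr"),
  gauges = c("gauge_id", "lat", "lon", "year", "msl_mm"),
  inventory = c("polygon_id", "lat", "lon", "area_km2", "vegetation",
                "region", "state"),
  scenarios = c("rcp", "pop_threshold", "segment_id", "decade",
                "rslr_mm_yr", "area_fraction", "car0", "car0_se", "rslr0",
                "area0_km2"))

read_schema <- function(path, schema) {
  need <- schema_cols[[schema]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("file '", basename(path), "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read and write the pipeline CSV schemas
#'
#' Typed CSV readers/writers for the four data products (sites, tide
#' gauges, polygon inventory, scenario trajectories) and the derived
#' estimate/summary tables. Readers validate that every mandatory column is
#' present (the error names the missing column); unknown columns are
#' preserved. `read(write(x))` round-trips values.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name pipeline_io
#' @export
read_sites <- function(path) read_schema(path, "sites")

#' @rdname pipeline_io
#' @export
write_sites <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_gauges <- function(path) read_schema(path, "gauges")

#' @rdname pipeline_io
#' @export
write_gauges <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_inventory <- function(path) read_schema(path, "inventory")

#' @rdname pipeline_io
#' @export
write_inventory <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_scenarios <- function(path) {
  df <- read_schema(path, "scenarios")
  rcp <- unique(df$rcp)
  thr <- unique(df$pop_threshold)
  if (length(rcp) != 1 || length(thr) != 1) {
    stop("a scenario file must hold exactly one rcp / pop_threshold",
         call. = FALSE)
  }
  segments <- df |>
    dplyr::distinct(.data$segment_id, .data$car0, .data$car0_se,
                    .data$rslr0, .data$area0_km2)
  structure(list(
    rcp = rcp, pop_threshold = thr, segments = segments,
    paths = dplyr::select(df, "segment_id", "decade", "rslr_mm_yr",
                          "area_fraction")),
    class = "scenario_spec")
}

#' @rdname pipeline_io
#' @param spec A `scenario_spec` object.
#' @export
write_scenarios <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  df <- spec$paths |>
    dplyr::left_join(spec$segments, by = "segment_id") |>
    dplyr::mutate(rcp = spec$rcp, pop_threshold = spec$pop_threshold) |>
    dplyr::select("rcp", "pop_threshold", "segment_id", "decade",
                  "rslr_mm_yr", "area_fraction", "car0", "car0_se",
                  "rslr0", "area0_km2")
  readr::write_csv(df, path)
  invisible(spec)
}

#' @rdname pipeline_io
#' @export
write_estimates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
write_summaries <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Write all four synthetic data products to a directory
#'
#' Runs the four generators under one configuration and writes
#' `sites.csv`, `gauges.csv`, `inventory.csv` and one scenario CSV per
#' RCP at the given population threshold.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @param pop_threshold Population threshold for the scenario files.
#' @return Invisibly, the vector of written file paths.
#' @export
simulate_to_dir <- function(config = synth_config(), out_dir,
                            pop_threshold = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sites = file.path(out_dir, "sites.csv"),
    gauges = file.path(out_dir, "gauges.csv"),
    inventory = file.path(out_dir, "inventory.csv"))
  write_sites(generate_sites(config), paths["sites"])
  write_gauges(generate_gauges(config), paths["gauges"])
  write_inventory(generate_inventory(config), paths["inventory"])
  for (rcp in c("RCP2.6", "RCP4.5", "RCP8.5")) {
    p <- file.path(out_dir, paste0("scenario_",
                                   gsub("[.]", "", rcp), ".csv"))
    write_scenarios(generate_scenarios(config, rcp, pop_threshold), p)
    paths[paste0("scenario_", rcp)] <- p
  }
  invisible(paths)
}
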