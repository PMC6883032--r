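# Orchestration: configuration object, the staged pipeline
# (derive -> rslr -> upscale -> stats -> project) and its run manifest.

#' Pipeline configuration
#'
#' Paths to the four input CSVs plus the tunable parameters of every stage.
#' Validated up front so a bad parameter fails before any stage runs.
#'
#' @param sites,gauges,inventory Paths to input CSVs (sites and inventory
#'   mandatory; gauges optional — without gauges the sites' own RSLR column
#'   is used as-is).
#' @param scenarios Character vector of scenario CSV paths (optional).
#' @param out_dir Output directory.
#' @param params A [conversion_params()] object.
#' @param radius_km Interpolation radius, km (> 0).
#' @param z CI multiplier (default 1.96).
#' @param critical_rslr Critical RSLR for the projection stage, mm yr^-1.
#' @param fit_mode Fit mode for the CAR~RSLR model.
#' @param n_draws Monte-Carlo draws for projection bands.
#' @param seed Root seed.
#' @param report_digits Rounding (decimals, Tg) applied in summary CSVs;
#'   internal math is full precision.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sites, inventory, gauges = NULL,
                            scenarios = NULL, out_dir = ".",
                            params = conversion_params(), radius_km = 100,
                            z = 1.96, critical_rslr = 10,
                            fit_mode = "cluster_robust", n_draws = 10000,
                            seed = 1, report_digits = 2) {
  assert_number(radius_km, "radius_km", lower = 1e-9)
  assert_number(z, "z", lower = 0)
  assert_number(critical_rslr, "critical_rslr", lower = 1e-9)
  fit_mode <- match.arg(fit_mode,
                        c("cluster_robust", "ols", "random_intercept"))
  structure(list(sites = sites, inventory = inventory, gauges = gauges,
                 scenarios = scenarios, out_dir = out_dir, params = params,
                 radius_km = radius_km, z = z,
                 critical_rslr = critical_rslr, fit_mode = fit_mode,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 report_digits = report_digits),
            class = "pipeline_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — derive (dating filter + CAR completion),
#' rslr (gauge trends, bridging, nearest-gauge assignment), upscale
#' (per-polygon estimates and state/region/vegetation/national summaries),
#' stats (ANOVA + Tukey letters, correlation table, CAR~RSLR model) and,
#' when scenario files are configured, project. All outputs are written
#' under `config$out_dir` and a JSON run manifest reconciling record counts
#' is emitted.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$sites, config$inventory, config$gauges,
              config$scenarios)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "tidalcarbon",
                   version = as.character(utils::packageVersion("tidalcarbon")),
                   seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())

  # -- derive ---------------------------------------------------------------
  sites <- read_sites(config$sites)
  n_in <- nrow(sites)
  if ("dating_method" %in% names(sites)) {
    fd <- filter_dating(sites)
    sites <- fd$retained
    pipeline_log("derive", fd$log)
  } else {
    fd <- list(excluded = sites[0, ])
  }
  fill <- is.na(sites$car_gC_m2_yr) & !is.na(sites$c_density_gC_cm3) &
    !is.na(sites$sar_mm_yr)
  sites$car_gC_m2_yr[fill] <- car_from_sar(sites$c_density_gC_cm3[fill],
                                           sites$sar_mm_yr[fill],
                                           config$params)
  manifest$stages$derive <- list(input = n_in, retained = nrow(sites),
                                 excluded = nrow(fd$excluded),
                                 car_filled = sum(fill))
  pipeline_log("derive", "%d sites retained (%d excluded)", nrow(sites),
               nrow(fd$excluded))

  # -- rslr -----------------------------------------------------------------
  if (!is.null(config$gauges)) {
    gauges <- read_gauges(config$gauges)
    trends <- fit_all_gauges(gauges)
    sites <- assign_rslr_sites(sites, trends)
    trend_df <- dplyr::bind_rows(lapply(trends, function(t) {
      tibble::tibble(gauge_id = t$gauge_id, lat = t$lat, lon = t$lon,
                     slope_mm_yr = t$slope, slope_se = t$slope_se,
                     n_years = t$n_years, window_start = t$window[1],
                     window_end = t$window[2], bridged = t$bridged)
    }))
    readr::write_csv(trend_df, file.path(config$out_dir, "gauge_trends.csv"))
    manifest$stages$rslr <- list(gauges = length(unique(gauges$gauge_id)),
                                 trends = nrow(trend_df),
                                 bridged = sum(trend_df$bridged))
    pipeline_log("rslr", "%d trends (%d bridged)", nrow(trend_df),
                 sum(trend_df$bridged))
  }
  write_sites(sites, file.path(config$out_dir, "sites_derived.csv"))

  # -- upscale --------------------------------------------------------------
  inventory <- read_inventory(config$inventory)
  reg_stats <- regional_car_stats(sites)
  estimates <- upscale_inventory(inventory, sites, reg_stats,
                                 config$radius_km)
  write_estimates(estimates, file.path(config$out_dir, "estimates.csv"))
  summaries <- dplyr::bind_rows(lapply(
    c("national", "region", "state", "vegetation"),
    function(lv) aggregate_flux(estimates, lv, config$z)))
  summaries <- dplyr::mutate(summaries, dplyr::across(
    c("total_flux", "flux_se", "ci95"),
    ~ round(.x, config$report_digits)))
  write_summaries(summaries, file.path(config$out_dir, "summaries.csv"))
  manifest$stages$upscale <- list(
    polygons = nrow(inventory),
    interpolated = sum(estimates$method == "interpolated"),
    regional_fallback = sum(estimates$method == "regional_fallback"))
  pipeline_log("upscale", "%d polygons (%d interpolated, %d fallback)",
               nrow(inventory), sum(estimates$method == "interpolated"),
               sum(estimates$method == "regional_fallback"))

  # -- stats ----------------------------------------------------------------
  anova_rows <- list()
  letter_rows <- list()
  for (fac in c("vegetation", "region")) {
    ok <- !is.na(sites$car_gC_m2_yr) & !is.na(sites[[fac]])
    an <- oneway_anova(sites$car_gC_m2_yr[ok], sites[[fac]][ok])
    anova_rows[[fac]] <- tibble::tibble(
      response = "car_gC_m2_yr", factor = fac, F = an$F, df1 = an$df1,
      df2 = an$df2, p = an$p)
    tk <- tukey_hsd(sites$car_gC_m2_yr[ok], sites[[fac]][ok])
    letter_rows[[fac]] <- tibble::tibble(
      factor = fac, group = names(tk$letters), letters = unname(tk$letters))
  }
  readr::write_csv(dplyr::bind_rows(anova_rows),
                   file.path(config$out_dir, "anova.csv"))
  readr::write_csv(dplyr::bind_rows(letter_rows),
                   file.path(config$out_dir, "tukey_letters.csv"))
  cors <- correlation_table(sites)
  readr::write_csv(cors, file.path(config$out_dir, "correlations.csv"))
  model <- fit_car_rslr(sites, config$fit_mode)
  jsonlite::write_json(unclass(model),
                       file.path(config$out_dir, "car_rslr_model.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$stats <- list(anova_factors = 2, correlations = nrow(cors),
                                fit_mode = model$fit_mode,
                                slope = model$slope)
  pipeline_log("stats", "CAR~RSLR slope %.2f +/- %.2f (%s)", model$slope,
               model$slope_se, model$fit_mode)

  # -- project --------------------------------------------------------------
  if (!is.null(config$scenarios)) {
    pp <- projection_params(config$critical_rslr, config$n_draws,
                            substream_seed(config$seed, "projection"))
    results <- list()
    for (p in config$scenarios) {
      spec <- read_scenarios(p)
      key <- paste0(spec$rcp, "_thr", spec$pop_threshold)
      results[[key]] <- project_national(spec, model, pp)
    }
    cmp <- compare_scenarios(results)
    readr::write_csv(cmp, file.path(config$out_dir, "projection.csv"))
    manifest$stages$project <- list(scenarios = length(results),
                                    n_draws = pp$n_draws,
                                    critical_rslr = pp$critical_rslr)
    pipeline_log("project", "%d scenario(s) projected to 2100",
                 length(results))
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
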