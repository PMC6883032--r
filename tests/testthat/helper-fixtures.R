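# Small fixtures shared across test files; everything is built in code.

small_config <- function(seed = 1, n_sites_per_region = 15,
                         n_polygons_per_region = 10, n_gauges = 12, ...) {
  synth_config(seed = seed, n_sites_per_region = n_sites_per_region,
               n_polygons_per_region = n_polygons_per_region,
               n_gauges = n_gauges, ...)
}

# sites table with hand-set values for the upscaling tests
toy_sites <- function(cars, lats, lons, region = "Mid Atlantic") {
  tibble::tibble(
    site_id = sprintf("s%02d", seq_along(cars)),
    source_id = "src001", lat = lats, lon = lons, region = region,
    state = "NJ", vegetation = "salt_marsh", salinity_ppt = 25,
    sar_mm_yr = 4, c_density_gC_cm3 = 0.04, car_gC_m2_yr = cars,
    rslr_mm_yr = 3)
}

toy_polygon <- function(lat, lon, area_km2 = 1, region = "Mid Atlantic") {
  list(polygon_id = "p1", lat = lat, lon = lon, area_km2 = area_km2,
       region = region, state = "NJ", vegetation = "salt_marsh")
}

toy_regional_stats <- function(region = "Mid Atlantic", mean = 176.5,
                               se = 14) {
  tibble::tibble(region = region, car_mean = mean, car_se = se, n = 85)
}

# degenerate generator configuration: every stochastic spread set to zero
noise_free_config <- function(seed = 3) {
  r0 <- default_region_table()
  r0$car_se <- 0
  r0$sar_se <- 0
  v0 <- default_vegetation_table()
  v0$cdensity_se <- 0
  synth_config(seed = seed, regions = r0, vegetation = v0,
               rslr_jitter_sd = 0, source_sd = 0)
}
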