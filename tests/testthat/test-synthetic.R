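# Synthetic study system: determinism, calibration, internal consistency.

test_that("all four generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 23)
  expect_identical(generate_sites(cfg), generate_sites(cfg))
  expect_identical(generate_gauges(cfg), generate_gauges(cfg))
  expect_identical(generate_inventory(cfg), generate_inventory(cfg))
  s1 <- generate_scenarios(cfg, "RCP4.5", 20)
  s2 <- generate_scenarios(cfg, "RCP4.5", 20)
  expect_identical(s1$paths, s2$paths)
})

test_that("a noise-free configuration yields CAR exactly c_density x SAR x 1000", {
  s <- generate_sites(noise_free_config())
  expect_equal(s$car_gC_m2_yr, s$c_density_gC_cm3 * s$sar_mm_yr * 1000)
  expect_true(all(s$car_noise == 0))
})

test_that("the CAR identity holds exactly through the stored noise term", {
  s <- generate_sites(small_config(seed = 29))
  expect_equal(s$car_gC_m2_yr,
               s$c_density_gC_cm3 * s$sar_mm_yr * 1000 + s$car_noise)
  expect_true(all(s$car_gC_m2_yr >= 0))
  expect_true(all(s$c_density_gC_cm3 > 0 & s$c_density_gC_cm3 < 0.6))
})

test_that("generated coordinates stay inside their region's bounding box", {
  layout <- region_layout()
  s <- generate_sites(small_config(seed = 31))
  inv <- generate_inventory(small_config(seed = 31))
  for (df in list(s, inv)) {
    j <- match(df$region, layout$region)
    expect_true(all(df$lon >= layout$lon_min[j] &
                      df$lon <= layout$lon_max[j]))
    expect_true(all(df$lat >= layout$lat_min[j] &
                      df$lat <= layout$lat_max[j]))
  }
})

test_that("regional mean CAR averaged over 20 seeds stays within 2 regional SEs", {
  tab <- default_region_table()
  sums <- setNames(numeric(nrow(tab)), tab$region)
  for (seed in 1:20) {
    s <- generate_sites(synth_config(seed = seed, n_sites_per_region = 50))
    m <- tapply(s$car_gC_m2_yr, s$region, mean)
    sums[names(m)] <- sums[names(m)] + m
  }
  means <- sums / 20
  for (i in seq_len(nrow(tab))) {
    expect_lt(abs(means[[tab$region[i]]] - tab$car_mean[i]),
              2 * tab$car_se[i])
  }
})

test_that("the realized CAR-RSLR correlation is close to the configured target", {
  for (seed in c(2, 7, 12)) {
    s <- generate_sites(synth_config(seed = seed, n_sites_per_region = 50))
    expect_gt(nrow(s), 300)
    r <- cor(s$car_gC_m2_yr, s$rslr_mm_yr)
    expect_lt(abs(r - 0.40), 0.1)
  }
})

test_that("salinity draws are consistent with the vegetation class boundaries", {
  s <- generate_sites(small_config(seed = 37))
  non_mangrove <- s$vegetation != "mangrove"
  expect_equal(classify_vegetation(s$salinity_ppt[non_mangrove]),
               s$vegetation[non_mangrove])
  expect_true(all(s$salinity_ppt[s$vegetation == "mangrove"] >= 15))
})

test_that("sites carry source groups of 5-10 and a valid dating method", {
  s <- generate_sites(small_config(seed = 41))
  sizes <- table(s$source_id)
  # the last chunk may be truncated; all others are 5-10
  expect_true(all(head(sort(names(sizes)), -1) |>
                    vapply(function(x) sizes[[x]], numeric(1)) |>
                    dplyr::between(5, 10)))
  expect_true(all(s$dating_method %in% c("Pb210", "Cs137", "SET")))
})

test_that("noise-free gauges recover their ground-truth trend exactly", {
  g <- generate_gauges(small_config(seed = 43, gauge_noise_sd = 0))
  trends <- fit_all_gauges(g)
  truth <- tapply(g$true_trend_mm_yr, g$gauge_id, unique)
  for (t in trends) {
    if (!t$bridged) expect_equal(t$slope, truth[[t$gauge_id]],
                                 tolerance = 1e-9)
  }
})

test_that("short-gauge fraction zero means every record spans 60 years", {
  g <- generate_gauges(small_config(seed = 47, short_gauge_fraction = 0))
  spans <- tapply(g$year, g$gauge_id, function(y) length(y))
  expect_true(all(spans == 60))
})

test_that("noisy 60-yr gauges recover truth within 3 SEs at the expected rate", {
  cfg <- synth_config(seed = 53, n_gauges = 200, short_gauge_fraction = 0)
  g <- generate_gauges(cfg)
  trends <- fit_all_gauges(g)
  truth <- tapply(g$true_trend_mm_yr, g$gauge_id, unique)
  hits <- vapply(trends, function(t)
    abs(t$slope - truth[[t$gauge_id]]) <= 3 * t$slope_se, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inventory areas rescale to the configured regional totals", {
  cfg <- small_config(seed = 59)
  inv <- generate_inventory(cfg)
  areas <- tapply(inv$area_km2, inv$region, sum)
  tab <- default_region_table()
  for (r in tab$region) {
    expect_equal(areas[[r]], tab$area_km2[tab$region == r])
  }
  expect_true(all(inv$area_km2 > 0))
})

test_that("requesting zero polygons yields an empty typed inventory", {
  cfg <- small_config(seed = 61)
  cfg$n_polygons_per_region <- 0L
  inv <- generate_inventory(cfg)
  expect_equal(nrow(inv), 0)
  expect_true(all(c("polygon_id", "area_km2", "region") %in% names(inv)))
})

test_that("a single polygon of 1 km2 at CAR 100 yields 1e-4 Tg downstream", {
  poly <- tibble::tibble(polygon_id = "p1", lat = 39, lon = -74,
                         area_km2 = 1, vegetation = "salt_marsh",
                         region = "Mid Atlantic", state = "NJ")
  sites <- toy_sites(cars = c(100, 100, 100), lats = c(39, 39.1, 39.2),
                     lons = rep(-74, 3))
  est <- upscale_inventory(poly, sites)
  expect_equal(est$flux, 1e-4)
})

test_that("scenario RSLR paths are monotone and ordered by RCP severity", {
  cfg <- small_config(seed = 67)
  for (thr in c(5, 300)) {
    s26 <- generate_scenarios(cfg, "RCP2.6", thr)
    s85 <- generate_scenarios(cfg, "RCP8.5", thr)
    p26 <- s26$paths[order(s26$paths$segment_id, s26$paths$decade), ]
    p85 <- s85$paths[order(s85$paths$segment_id, s85$paths$decade), ]
    for (seg in unique(p26$segment_id)) {
      r26 <- p26$rslr_mm_yr[p26$segment_id == seg]
      r85 <- p85$rslr_mm_yr[p85$segment_id == seg]
      expect_true(all(diff(r26) >= 0))
      expect_true(all(diff(r85) >= 0))
      expect_gte(r85[length(r85)], r26[length(r26)])
    }
    expect_true(all(p26$area_fraction[p26$decade == 2020] == 1))
  }
})

test_that("the least-restricted threshold grows national area to 1.0-1.6x by 2100", {
  cfg <- small_config(seed = 71)
  s <- generate_scenarios(cfg, "RCP8.5", 300)
  a <- s$paths |>
    dplyr::left_join(s$segments, by = "segment_id") |>
    dplyr::group_by(decade) |>
    dplyr::summarise(area = sum(area0_km2 * area_fraction))
  ratio <- a$area[a$decade == 2100] / a$area[a$decade == 2020]
  expect_gte(ratio, 1.0)
  expect_lte(ratio, 1.6)
  s5 <- generate_scenarios(cfg, "RCP8.5", 5)
  a5 <- s5$paths |>
    dplyr::left_join(s5$segments, by = "segment_id") |>
    dplyr::group_by(decade) |>
    dplyr::summarise(area = sum(area0_km2 * area_fraction))
  expect_lt(a5$area[a5$decade == 2100] / a5$area[a5$decade == 2020], 1)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_sites_per_region = 0), "positive")
  expect_error(generate_scenarios(small_config(), "RCP9.9"), "arg")
  expect_error(generate_scenarios(small_config(), "RCP8.5", 42),
               "pop_threshold")
})
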